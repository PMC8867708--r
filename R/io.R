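#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts GT fields to
#' alternate-allele dosages. Multi-allelic records are skipped (the container
#' is strictly biallelic); the number skipped is reported with a message and
#' recorded in the `n_multiallelic_skipped` attribute. Missing genotypes
#' (`./.`, `.|.` or `.`) become `NA`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param popmap either a path to a two-column CSV (`sample,population`) or a
#'   data frame with those columns. Every sample in the VCF must appear.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(n_multi, " multi-allelic or ALT-less record(s) skipped")
  }
  if (all(multi)) stop("no biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]

  dosage <- gt_to_dosage(gt) # loci x samples
  pm <- read_popmap(popmap)
  missing_samples <- setdiff(colnames(dosage), pm$sample)
  if (length(missing_samples)) {
    stop(
      "sample(s) absent from population map: ",
      paste(missing_samples, collapse = ", "),
      call. = FALSE
    )
  }
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  loci <- tibble::tibble(
    locus = make.unique(id),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  g <- genotype_matrix(
    t(dosage),
    populations = pm$population[match(colnames(dosage), pm$sample)],
    loci = loci
  )
  attr(g, "n_multiallelic_skipped") <- n_multi
  g
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & !grepl("^\\.([/|]\\.)?$", gt)
  alleles <- strsplit(gt[called], "[/|]")
  bad <- vapply(alleles, function(a) any(!a %in% c("0", "1", ".")), logical(1))
  if (any(bad)) {
    stop("malformed GT field(s), e.g. ", gt[called][which(bad)[1]], call. = FALSE)
  }
  d[called] <- vapply(
    alleles,
    function(a) if (any(a == ".")) NA_real_ else sum(a == "1"),
    numeric(1)
  )
  d
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a plain-text, GT-only VCF that round-trips exactly through
#' [read_vcf()]. Imputed (fractional) matrices cannot be serialized.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("cannot write an imputed matrix as VCF", call. = FALSE)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- t(g$dosage) # loci x samples
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=adaptscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      g$samples
    ), collapse = "\t")
  )
  body <- paste(
    g$loci$chrom, g$loci$pos, g$loci$locus, g$loci$ref, g$loci$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or validate a sample-to-population map
#'
#' @param popmap a path to a CSV with columns `sample,population`, or a data
#'   frame with those columns.
#' @return A tibble with columns `sample` and `population`.
#' @export
read_popmap <- function(popmap) {
  pm <- if (is.character(popmap)) {
    readr::read_csv(popmap, show_col_types = FALSE)
  } else {
    tibble::as_tibble(popmap)
  }
  if (!all(c("sample", "population") %in% names(pm))) {
    stop("population map needs columns 'sample' and 'population'", call. = FALSE)
  }
  pm$sample <- as.character(pm$sample)
  pm$population <- as.character(pm$population)
  pm
}

#' Construct or read a site-level environmental table
#'
#' One row per collection site with decimal-degree coordinates and any number
#' of site-constant environmental variables. Site ids are expected to match
#' the population labels of the genotype data they are analysed with.
#'
#' @param x a data frame (or path to a CSV) with columns `site`, `latitude`,
#'   `longitude` and one column per environmental variable. No missing values
#'   are allowed.
#' @return A tibble of class `env_table`.
#' @export
env_table <- function(x) {
  env <- if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else tibble::as_tibble(x)
  req <- c("site", "latitude", "longitude")
  if (!all(req %in% names(env))) {
    stop("environmental table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  env$site <- as.character(env$site)
  if (anyDuplicated(env$site)) stop("duplicate site ids", call. = FALSE)
  if (anyNA(env)) stop("environmental table contains missing values", call. = FALSE)
  class(env) <- c("env_table", class(env))
  env
}

#' @rdname env_table
#' @export
read_env_table <- function(x) env_table(x)

#' Environmental variable names of an env_table
#' @param env an [env_table()].
#' @param exclude additional columns to drop from the variable list.
#' @return Character vector of variable column names.
#' @export
env_variables <- function(env, exclude = character()) {
  setdiff(names(env), c("site", "latitude", "longitude", "n_final", exclude))
}

#' The four *Ambystoma barbouri* study sites
#'
#' Environmental table for the four salamander collection localities (range
#' core and the northern, southern and western range edges): coordinates,
#' final per-site sample sizes, and the six environmental factors retained
#' for genetic-environment association analysis (mean annual temperature,
#' temperature seasonality, mean temperature of the wettest quarter,
#' elevation, percent soil organic carbon, annual precipitation).
#'
#' @return An [env_table()] with 4 rows.
#' @export
#' @examples
#' barbouri_sites()
barbouri_sites <- function() {
  env_table(system.file("extdata", "barbouri_sites_env.csv",
    package = "adaptscan", mustWork = TRUE
  ))
}
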