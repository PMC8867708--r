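#' Construct a genotype matrix object
#'
#' The central data container of the package: a samples-by-loci matrix of
#' alternate-allele dosages (0, 1 or 2 copies of the ALT allele; `NA` when the
#' genotype was not called), plus a population label for every sample and a
#' locus table carrying genomic coordinates and alleles. All loci are
#' biallelic by construction.
#'
#' @param dosage numeric matrix, samples in rows, loci in columns. Values must
#'   be 0, 1, 2 or `NA` unless `imputed = TRUE`, in which case fractional
#'   expected dosages in `[0, 2]` are allowed.
#' @param populations character vector of population labels, one per row of
#'   `dosage`.
#' @param loci data frame with one row per column of `dosage` and columns
#'   `locus`, `chrom`, `pos` (1-based), `ref`, `alt`. Generated automatically
#'   when omitted.
#' @param imputed logical; `TRUE` marks a matrix whose missing entries were
#'   replaced by expected dosages. Imputed matrices are accepted by PCA-based
#'   operations only, never by allele-count statistics.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `samples`, `populations`, `loci`, `imputed`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   rbind(a = c(0, 1), b = c(2, NA)),
#'   populations = c("P1", "P1")
#' )
#' g
genotype_matrix <- function(dosage, populations, loci = NULL, imputed = FALSE) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%03d", seq_len(nrow(dosage)))
  }
  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus = colnames(dosage) %||% sprintf("locus%05d", seq_len(ncol(dosage))),
      chrom = "chr1",
      pos = seq_len(ncol(dosage)),
      ref = "A",
      alt = "T"
    )
  }
  loci <- tibble::as_tibble(loci)
  stopifnot(
    nrow(loci) == ncol(dosage),
    all(c("locus", "chrom", "pos", "ref", "alt") %in% names(loci)),
    length(populations) == nrow(dosage)
  )
  if (anyDuplicated(loci$locus)) {
    stop("locus ids must be unique", call. = FALSE)
  }
  colnames(dosage) <- loci$locus
  obs <- dosage[!is.na(dosage)]
  if (!imputed && length(obs) && !all(obs %in% DOSAGE_LEVELS)) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (imputed && length(obs) && (min(obs) < 0 || max(obs) > 2)) {
    stop("imputed dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(
    list(
      dosage = dosage,
      samples = rownames(dosage),
      populations = stats::setNames(as.character(populations), rownames(dosage)),
      loci = loci,
      imputed = imputed
    ),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci, %d populations, %.1f%% missing%s\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$populations)),
    100 * miss, if (x$imputed) " (imputed)" else ""
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param samples,loci character vectors of ids (or logical/integer indices)
#'   to keep; `NULL` keeps everything.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ri <- if (is.null(samples)) seq_along(g$samples) else {
    if (is.character(samples)) match(samples, g$samples) else which_idx(samples, length(g$samples))
  }
  ci <- if (is.null(loci)) seq_len(ncol(g$dosage)) else {
    if (is.character(loci)) match(loci, g$loci$locus) else which_idx(loci, ncol(g$dosage))
  }
  if (anyNA(ri)) stop("unknown sample id(s)", call. = FALSE)
  if (anyNA(ci)) stop("unknown locus id(s)", call. = FALSE)
  genotype_matrix(
    g$dosage[ri, ci, drop = FALSE],
    populations = g$populations[ri],
    loci = g$loci[ci, , drop = FALSE],
    imputed = g$imputed
  )
}

which_idx <- function(i, n) {
  if (is.logical(i)) which(rep_len(i, n)) else as.integer(i)
}

#' Tidy a genotype matrix into long format
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with columns `sample`, `population`, `locus`, `dosage`.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples, times = ncol(x$dosage)),
    population = rep(unname(x$populations), times = ncol(x$dosage)),
    locus = rep(x$loci$locus, each = nrow(x$dosage)),
    dosage = as.vector(x$dosage)
  )
}

#' Per-sample and per-locus missingness
#'
#' Missingness is the share of `NA` dosages. Per-locus missingness is reported
#' within each population, the unit at which SNP filtering operates.
#'
#' @param g a [genotype_matrix()].
#' @return A list of two tibbles: `samples` (`sample`, `population`,
#'   `missingness`) and `loci` (`locus`, `population`, `missingness`).
#' @export
missingness_summary <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  samples <- tibble::tibble(
    sample = g$samples,
    population = unname(g$populations),
    missingness = rowMeans(is.na(g$dosage))
  )
  pops <- unique(unname(g$populations))
  loci <- purrr::map_dfr(pops, function(p) {
    sub <- g$dosage[g$populations == p, , drop = FALSE]
    tibble::tibble(
      locus = g$loci$locus,
      population = p,
      missingness = colMeans(is.na(sub))
    )
  })
  list(samples = samples, loci = loci)
}
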