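#' Read a gene-model BED file
#'
#' BED intervals are 0-based half-open; they are validated (`start < end`)
#' and sorted per chromosome on loading.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, gene id;
#'   optional 5th column symbol), or a data frame with those columns.
#' @return A tibble of class `gene_models`: `chrom`, `start`, `end`, `gene`,
#'   optionally `symbol`.
#' @export
read_gene_bed <- function(path) {
  bed <- if (is.character(path)) {
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(path)
  }
  if (ncol(bed) < 4) stop("BED needs >= 4 columns (chrom, start, end, gene)", call. = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "gene")
  if (ncol(bed) >= 5) names(bed)[5] <- "symbol"
  bed <- tibble::as_tibble(bed[, intersect(names(bed), c("chrom", "start", "end", "gene", "symbol"))])
  if (any(bed$start >= bed$end)) {
    stop("invalid BED interval(s): start must be < end", call. = FALSE)
  }
  bed <- dplyr::arrange(bed, .data$chrom, .data$start, .data$end)
  class(bed) <- c("gene_models", class(bed))
  bed
}

#' Nearest gene model for each SNP
#'
#' BEDTools-`closest -d` semantics: a SNP inside a gene interval has
#' distance 0; otherwise the distance is the gap to the nearest interval
#' edge plus one (bookended features report 1). The sign is positive when
#' the nearest gene lies downstream (higher coordinates) of the SNP and
#' negative when upstream. Equidistant genes are all reported with a tie
#' flag. SNPs on chromosomes without gene models are returned unannotated
#' (`gene = NA`).
#'
#' @param loci tibble with columns `locus`, `chrom`, `pos` (1-based), e.g.
#'   the `loci` element of a [genotype_matrix()].
#' @param genes a [read_gene_bed()] result.
#' @param report_ties keep all equidistant genes (`TRUE`) or the first by
#'   coordinate (`FALSE`).
#' @return A tibble: `locus`, `gene`, `distance` (signed; `NA` when
#'   unannotated), `tie`.
#' @export
nearest_gene <- function(loci, genes, report_ties = TRUE) {
  stopifnot(all(c("locus", "chrom", "pos") %in% names(loci)))
  if (!inherits(genes, "gene_models")) genes <- read_gene_bed(genes)
  snp_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$pos, loci$pos)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end)
  )
  hits <- GenomicRanges::distanceToNearest(snp_gr, gene_gr, select = "all")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  dist <- ifelse(gap == 0, 0L, gap + 1L)
  # truly overlapping vs bookended: gap 0 covers both in GenomicRanges
  overlapping <- loci$pos[qh] >= genes$start[sh] + 1 & loci$pos[qh] <= genes$end[sh]
  dist[gap == 0 & !overlapping] <- 1L
  sign_v <- ifelse(overlapping, 0L, ifelse(genes$start[sh] + 1 > loci$pos[qh], 1L, -1L))
  ann <- tibble::tibble(
    locus = loci$locus[qh],
    gene = genes$gene[sh],
    distance = as.integer(dist * ifelse(sign_v == 0, 1, sign_v))
  )
  ann <- dplyr::group_by(ann, .data$locus) |>
    dplyr::mutate(tie = dplyr::n() > 1) |>
    dplyr::ungroup()
  if (!report_ties) {
    ann <- dplyr::distinct(ann, .data$locus, .keep_all = TRUE)
  }
  missing <- setdiff(loci$locus, ann$locus)
  if (length(missing)) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      locus = missing, gene = NA_character_, distance = NA_integer_, tie = FALSE
    ))
  }
  ann[match2_order(ann$locus, loci$locus), ]
}

# stable ordering of annotation rows by the input locus order
match2_order <- function(x, levels) order(match(x, levels))

#' Fisher-exact term enrichment
#'
#' Two-sided Fisher's exact test per term on the 2x2 table of (candidate vs
#' non-candidate reference genes) x (annotated with the term vs not), with
#' Benjamini-Hochberg FDR correction. The reference set is typically the
#' genes nearest all SNPs in the dataset; candidates the genes nearest the
#' significant SNPs.
#'
#' @param candidate_genes character vector (must be a subset of
#'   `reference_genes`).
#' @param reference_genes character vector of the gene universe.
#' @param term_map data frame with columns `gene`, `term` (a gene may map to
#'   many terms), or a path to a two-column TSV.
#' @param fdr FDR threshold.
#' @return A tibble: `term`, `n_candidate`, `n_reference`, `odds_ratio`
#'   (sample odds ratio; `Inf` allowed), `p_value`, `q_value`, `direction`
#'   (`"over"`/`"under"`), `significant`.
#' @export
fisher_enrichment <- function(candidate_genes, reference_genes, term_map, fdr = 0.05) {
  candidate_genes <- unique(candidate_genes)
  reference_genes <- unique(reference_genes)
  if (!length(candidate_genes)) stop("empty candidate set", call. = FALSE)
  if (!all(candidate_genes %in% reference_genes)) {
    stop("candidates must be a subset of the reference set", call. = FALSE)
  }
  tm <- if (is.character(term_map) && length(term_map) == 1 && file.exists(term_map)) {
    readr::read_tsv(term_map, col_names = c("gene", "term"), show_col_types = FALSE)
  } else {
    tibble::as_tibble(term_map)
  }
  stopifnot(all(c("gene", "term") %in% names(tm)))
  tm <- dplyr::filter(tm, .data$gene %in% reference_genes)
  n_cand <- length(candidate_genes)
  n_ref <- length(reference_genes)
  terms <- unique(tm$term)
  res <- purrr::map_dfr(terms, function(t) {
    with_term <- unique(tm$gene[tm$term == t])
    a <- sum(candidate_genes %in% with_term)
    b <- n_cand - a
    c_ <- sum(!(with_term %in% candidate_genes))
    d <- (n_ref - n_cand) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- (a * d) / (b * c_) # sample odds ratio; Inf for extreme tables
    tibble::tibble(
      term = t, n_candidate = a, n_reference = length(with_term),
      odds_ratio = or, p_value = ft$p.value,
      direction = ifelse(is.nan(or) || or >= 1, "over", "under")
    )
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  dplyr::arrange(res, .data$p_value)
}
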