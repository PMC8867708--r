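#' Build an iterative filtering schedule
#'
#' A schedule is an ordered list of filtering steps, each dropping either
#' SNPs whose within-population missingness exceeds a threshold in any one
#' population, or individuals whose overall missingness exceeds a threshold.
#' Alternating progressively stricter steps retains more individuals and
#' higher-quality markers than a single strict pass. Thresholds of each kind
#' must be non-increasing across the schedule.
#'
#' The default alternates SNP thresholds 0.5 -> 0.3 -> 0.25 with individual
#' thresholds 0.7 -> 0.5.
#'
#' @param steps data frame with columns `kind` (`"snp"` or `"individual"`)
#'   and `threshold` (in `(0, 1]`), in application order. `NULL` gives the
#'   default schedule.
#' @return A tibble of class `filter_schedule`.
#' @export
filter_schedule <- function(steps = NULL) {
  if (is.null(steps)) {
    steps <- tibble::tibble(
      kind = c("snp", "individual", "snp", "individual", "snp"),
      threshold = c(0.5, 0.7, 0.3, 0.5, 0.25)
    )
  }
  steps <- tibble::as_tibble(steps)
  stopifnot(all(c("kind", "threshold") %in% names(steps)), nrow(steps) >= 1)
  if (!all(steps$kind %in% c("snp", "individual"))) {
    stop("step kind must be 'snp' or 'individual'", call. = FALSE)
  }
  if (any(steps$threshold <= 0 | steps$threshold > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  for (k in unique(steps$kind)) {
    th <- steps$threshold[steps$kind == k]
    if (is.unsorted(rev(th))) {
      stop("thresholds for kind '", k, "' must be non-increasing", call. = FALSE)
    }
  }
  class(steps) <- c("filter_schedule", class(steps))
  steps
}

#' Iterative missingness filtering
#'
#' Applies a [filter_schedule()] step by step. A SNP step removes loci whose
#' missingness strictly exceeds the threshold in at least one population; an
#' individual step removes samples whose overall missingness strictly exceeds
#' the threshold. The per-step removal counts are attached as a report.
#'
#' @param g a [genotype_matrix()].
#' @param schedule a [filter_schedule()] (default schedule when omitted).
#' @return The filtered `genotype_matrix`, with a tibble report in
#'   `attr(, "filter_report")` (columns `step`, `kind`, `threshold`,
#'   `n_removed`, `n_loci_after`, `n_samples_after`).
#' @export
iterative_filter <- function(g, schedule = filter_schedule()) {
  stopifnot(inherits(g, "genotype_matrix"))
  schedule <- filter_schedule(schedule)
  report <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    kind <- schedule$kind[i]
    th <- schedule$threshold[i]
    if (kind == "snp") {
      worst <- locus_max_pop_missingness(g)
      keep <- worst <= th
      n_removed <- sum(!keep)
      if (!any(keep)) {
        stop("schedule step ", i, " (snp <= ", th, ") removes all loci", call. = FALSE)
      }
      g <- subset_genotypes(g, loci = keep)
    } else {
      miss <- rowMeans(is.na(g$dosage))
      keep <- miss <= th
      n_removed <- sum(!keep)
      if (!any(keep)) {
        stop("schedule step ", i, " (individual <= ", th, ") removes all samples", call. = FALSE)
      }
      g <- subset_genotypes(g, samples = keep)
    }
    report[[i]] <- tibble::tibble(
      step = i, kind = kind, threshold = th, n_removed = n_removed,
      n_loci_after = ncol(g$dosage), n_samples_after = nrow(g$dosage)
    )
  }
  attr(g, "filter_report") <- dplyr::bind_rows(report)
  g
}

locus_max_pop_missingness <- function(g) {
  pops <- unique(unname(g$populations))
  per_pop <- vapply(pops, function(p) {
    colMeans(is.na(g$dosage[g$populations == p, , drop = FALSE]))
  }, numeric(ncol(g$dosage)))
  if (is.null(dim(per_pop))) per_pop <- matrix(per_pop, nrow = 1)
  apply(per_pop, 1, max)
}

#' Write a filter report as TSV
#' @param g a filtered [genotype_matrix()] carrying a `filter_report` attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(g, path) {
  rep <- attr(g, "filter_report")
  if (is.null(rep)) stop("no filter report attached", call. = FALSE)
  readr::write_tsv(rep, path)
  invisible(path)
}
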