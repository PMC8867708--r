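#' Assemble a scan result tibble
#'
#' Internal constructor shared by all per-locus selection scans. A scan
#' result is a tibble (one row per locus, or per locus-variable combination
#' for association scans) with a `test` label, the per-locus statistic,
#' p-value / Bayes factor / rank correlation where applicable, and a
#' `significant` flag matching the threshold descriptor stored in
#' `attr(, "threshold")`.
#'
#' @param df tibble of per-locus results.
#' @param test test label.
#' @param threshold human-readable threshold descriptor.
#' @return The tibble with class `scan_result`.
#' @keywords internal
new_scan_result <- function(df, test, threshold) {
  df$test <- test
  attr(df, "threshold") <- threshold
  class(df) <- c("scan_result", class(df))
  df
}

#' Significant locus ids of a scan result
#' @param scan a `scan_result` tibble.
#' @return Character vector of locus ids flagged significant.
#' @export
significant_loci <- function(scan) {
  stopifnot(inherits(scan, "scan_result") || is.data.frame(scan))
  unique(scan$locus[scan$significant %in% TRUE])
}

#' Write a scan result as TSV
#' @param scan a `scan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path)
  invisible(path)
}

#' Manhattan-style plot of a scan result
#'
#' Plots `-log10(p)` (or the raw statistic when no p-value is present) by
#' locus index, colored by chromosome, with significant loci highlighted.
#'
#' @param object a `scan_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- match(df$locus, unique(df$locus))
  yvar <- if ("p_value" %in% names(df) && !all(is.na(df$p_value))) {
    df$y <- -log10(pmax(df$p_value, 1e-300))
    "-log10(p)"
  } else {
    df$y <- df$statistic
    "statistic"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"), na.value = "grey80"
    ) +
    ggplot2::labs(
      x = "locus index", y = yvar,
      title = unique(df$test)[1],
      subtitle = attr(object, "threshold")
    ) +
    ggplot2::theme_minimal()
  if ("variable" %in% names(df) && length(unique(df$variable)) > 1) {
    p <- p + ggplot2::facet_wrap(~variable)
  }
  p
}
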