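#' Orient alleles by their environmental association
#'
#' For each candidate locus, identifies which allele (REF or ALT) is
#' positively associated with an environmental variable: the sign of the
#' Pearson correlation between the population alternate-allele frequency and
#' the site value. Positive correlation orients toward ALT, negative toward
#' REF; loci with zero or undefined correlation (no frequency variance) are
#' excluded with a message.
#'
#' @param freqs a [population_allele_freqs()] result (>= 3 sites).
#' @param env an [env_table()] with sites matching the populations.
#' @param variable name of the environmental variable (or `"latitude"` /
#'   `"longitude"` for the geography comparison models).
#' @param loci candidate locus ids.
#' @return A tibble of class `orientation`: `locus`, `allele` (`"alt"` or
#'   `"ref"`), `r`; the variable name in `attr(, "variable")`.
#' @export
orient_alleles <- function(freqs, env, variable, loci) {
  stopifnot(inherits(freqs, "pop_freqs"))
  env <- env_table(env)
  if (nrow(env) < 3) stop("allele orientation needs at least 3 sites", call. = FALSE)
  ord <- match(freqs$pops, env$site)
  if (anyNA(ord)) stop("site ids do not match population labels", call. = FALSE)
  x <- env[[variable]][ord]
  if (is.null(x)) stop("unknown variable: ", variable, call. = FALSE)
  idx <- match(loci, freqs$loci)
  if (anyNA(idx)) stop("unknown locus id(s) in candidate set", call. = FALSE)
  r_vec <- vapply(idx, function(l) {
    p <- freqs$freq[, l]
    ok <- !is.na(p)
    if (sum(ok) < 3 || sd(p[ok]) == 0) return(NA_real_)
    cor(p[ok], x[ok])
  }, numeric(1))
  drop <- is.na(r_vec) | r_vec == 0
  if (any(drop)) {
    message(sum(drop), " locus/loci without a signed association excluded from orientation")
  }
  if (all(drop)) stop("no orientable loci in the candidate set", call. = FALSE)
  out <- tibble::tibble(
    locus = loci[!drop],
    allele = ifelse(r_vec[!drop] > 0, "alt", "ref"),
    r = r_vec[!drop]
  )
  attr(out, "variable") <- variable
  class(out) <- c("orientation", class(out))
  out
}

#' Additive polygenic scores
#'
#' Per individual, the raw score is the summed dosage of the positively
#' associated allele across the candidate loci with data present (ALT-
#' oriented loci contribute the dosage `d`, REF-oriented loci `2 - d`). The
#' percent score divides the raw score by twice the number of non-missing
#' candidate loci, i.e. the maximum score the individual could have had
#' given its missing data. Individuals with no data at any candidate locus
#' are excluded with a message.
#'
#' @param g a [genotype_matrix()] (integer dosages).
#' @param orientation an [orient_alleles()] result.
#' @return A tibble of class `polygenic_scores`: `sample`, `site`,
#'   `variable`, `raw`, `n_nonmissing`, `percent`.
#' @export
additive_scores <- function(g, orientation) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(orientation, "orientation"))
  if (g$imputed) stop("polygenic scores require called genotypes", call. = FALSE)
  if (!nrow(orientation)) stop("empty orientation", call. = FALSE)
  idx <- match(orientation$locus, g$loci$locus)
  if (anyNA(idx)) stop("orientation loci absent from the genotype matrix", call. = FALSE)
  d <- g$dosage[, idx, drop = FALSE]
  flip <- orientation$allele == "ref"
  d[, flip] <- 2 - d[, flip, drop = FALSE]
  n_nonmiss <- unname(rowSums(!is.na(d)))
  raw <- unname(rowSums(d, na.rm = TRUE))
  keep <- n_nonmiss > 0
  if (any(!keep)) {
    message(sum(!keep), " individual(s) with no data at candidate loci excluded")
  }
  raw_kept <- raw[keep]
  n_kept <- n_nonmiss[keep]
  out <- tibble::tibble(
    sample = g$samples[keep],
    site = unname(g$populations)[keep],
    variable = attr(orientation, "variable"),
    raw = raw_kept,
    n_nonmissing = n_kept,
    percent = raw_kept / (2 * n_kept)
  )
  class(out) <- c("polygenic_scores", class(out))
  out
}

#' Plot polygenic scores against a site-level predictor
#'
#' @param object a [additive_scores()] tibble.
#' @param env an [env_table()] supplying the site values of the scored
#'   variable (or of `predictor` when given).
#' @param predictor variable to place on the x axis (defaults to the scored
#'   variable).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot polygenic_scores
#' @export
autoplot.polygenic_scores <- function(object, env, predictor = NULL, ...) {
  env <- env_table(env)
  predictor <- predictor %||% object$variable[1]
  df <- dplyr::left_join(
    tibble::as_tibble(object),
    tibble::tibble(site = env$site, x = env[[predictor]]),
    by = "site"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$percent, colour = .data$site)) +
    ggplot2::geom_jitter(width = diff(range(df$x)) / 80, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 3, colour = "black") +
    ggplot2::labs(
      x = predictor, y = "percent polygenic score",
      title = paste("Additive polygenic scores ~", predictor)
    ) +
    ggplot2::theme_minimal()
}
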