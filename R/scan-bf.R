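#' Bayes-factor + Spearman genetic-environment association scan
#'
#' Frequency-level association test in the Bayenv2 style, with the MCMC
#' replaced by closed forms. Per locus, the standardized deviation vector
#' `d = (p - pi_hat 1) / sqrt(pi_hat (1 - pi_hat))` is whitened by the
#' Cholesky inverse of the covariance model; (i) a Zellner g-prior
#' (unit-information, `g = n_pops`) Bayes factor compares the whitened linear
#' model on the standardized environmental variable against the
#' intercept-only null, and (ii) Spearman's rank correlation is taken between
#' the whitened frequencies and the site values. A locus-variable pair is
#' significant when its BF lies above the empirical `bf_quantile` AND its
#' absolute rho above the empirical `rho_quantile`, both quantiles taken
#' across all locus-variable pairs. Monomorphic loci are retained with
#' statistic values corresponding to zero association.
#'
#' @param freqs a [population_allele_freqs()] result (>= 3 populations).
#' @param cov a [estimate_pop_covariance()] model.
#' @param env an [env_table()] whose sites match the populations.
#' @param variables environmental variables to test (default all).
#' @param bf_quantile,rho_quantile empirical quantile thresholds (defaults:
#'   BF top 5%, |rho| top 1%).
#' @return A `scan_result` tibble: `locus`, `variable`, `statistic` (log10
#'   BF), `bf`, `rho`, `significant`, `test`.
#' @export
env_assoc_scan <- function(freqs, cov, env, variables = NULL,
                           bf_quantile = 0.95, rho_quantile = 0.99) {
  stopifnot(inherits(freqs, "pop_freqs"), inherits(cov, "covariance_model"))
  r <- length(freqs$pops)
  if (r < 3) stop("rank correlation needs at least 3 populations", call. = FALSE)
  env <- env_table(env)
  variables <- variables %||% env_variables(env)
  ord <- match(freqs$pops, env$site)
  if (anyNA(ord)) stop("site ids do not match population labels", call. = FALSE)

  p <- freqs$freq
  pi_hat <- colMeans(p)
  defined <- colSums(is.na(p)) == 0
  poly <- defined & pi_hat > 0 & pi_hat < 1
  Linv <- solve(t(chol(cov$omega))) # whitening: z = L^-1 d
  dev <- sweep(p[, poly, drop = FALSE], 2, pi_hat[poly]) /
    rep(sqrt(pi_hat[poly] * (1 - pi_hat[poly])), each = r)
  Z <- Linv %*% dev # whitened standardized frequencies (pops x loci)
  one_w <- as.numeric(Linv %*% rep(1, r))
  g_prior <- r

  res <- purrr::map_dfr(variables, function(v) {
    x <- env[[v]][ord]
    if (sd(x) == 0) stop("environmental variable '", v, "' is constant", call. = FALSE)
    x_std <- as.numeric(scale(x))
    x_w <- as.numeric(Linv %*% x_std)
    X0 <- matrix(one_w, ncol = 1)
    X1 <- cbind(one_w, x_w)
    q0 <- qr(X0)
    q1 <- qr(X1)
    bf <- rep((1 + g_prior)^(-1 / 2), length(freqs$loci))
    rho <- rep(0, length(freqs$loci))
    if (any(poly)) {
      rss0 <- colSums(qr.resid(q0, Z)^2)
      rss1 <- colSums(qr.resid(q1, Z)^2)
      r2 <- ifelse(rss0 > 1e-12, pmin(pmax(1 - rss1 / rss0, 0), 1), 0)
      # Zellner g-prior BF for one added regressor (n = r observations)
      bf_poly <- (1 + g_prior)^((r - 2) / 2) / (1 + g_prior * (1 - r2))^((r - 1) / 2)
      rho_poly <- suppressWarnings(apply(Z, 2, function(z) cor(z, x, method = "spearman")))
      rho_poly[is.na(rho_poly)] <- 0
      bf[poly] <- bf_poly
      rho[poly] <- rho_poly
    }
    tibble::tibble(locus = freqs$loci, variable = v, bf = bf, rho = rho)
  })
  bf_thr <- quantile(res$bf, bf_quantile, names = FALSE)
  rho_thr <- quantile(abs(res$rho), rho_quantile, names = FALSE)
  res$statistic <- log10(res$bf)
  res$significant <- res$bf >= bf_thr & abs(res$rho) >= rho_thr
  out <- new_scan_result(
    res[, c("locus", "variable", "statistic", "bf", "rho", "significant")],
    "bf-lite",
    sprintf(
      "BF >= empirical %g quantile (%.3g) AND |rho| >= empirical %g quantile (%.3g)",
      bf_quantile, bf_thr, rho_quantile, rho_thr
    )
  )
  attr(out, "bf_threshold") <- bf_thr
  attr(out, "rho_threshold") <- rho_thr
  out
}
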