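#' Method-of-moments population covariance model
#'
#' Estimates the among-population allele-frequency covariance matrix Omega of
#' the Gaussian drift model `p ~ Normal(pi 1, pi (1 - pi) Omega)` from
#' per-locus frequencies. The per-locus ancestral frequency is estimated by
#' the across-population mean `pi_hat`; because centering on an estimated
#' mean absorbs covariance, the raw moment matrix
#' `M = mean_l [(p - pi_hat 1)(p - pi_hat 1)' / (pi_hat (1 - pi_hat))]`
#' has expectation `A Omega A` with `A = I - 11'/r`. Because `A` annihilates
#' the all-ones direction, the common component of Omega is unidentifiable
#' from centered frequencies; the estimator returns the unique completion
#' `M + 1v' + v1'` minimizing the off-diagonal sum of squares, which
#' reconstructs any diagonal (independent-drift) Omega exactly and
#' attributes unresolvable shared drift to the diagonal. Linear shrinkage
#' toward the diagonal then guarantees positive-definiteness.
#'
#' @param freqs a [population_allele_freqs()] result.
#' @param shrinkage shrinkage intensity in `[0, 1]` toward `diag(Omega)`;
#'   automatically increased (with a message) if the result is not
#'   positive-definite.
#' @return An object of class `covariance_model`: list with `omega`,
#'   `pi_hat` (per usable locus), `shrinkage`, `n_loci`.
#' @export
estimate_pop_covariance <- function(freqs, shrinkage = 0.05) {
  stopifnot(inherits(freqs, "pop_freqs"), shrinkage >= 0, shrinkage <= 1)
  r <- length(freqs$pops)
  p <- freqs$freq
  pi_hat <- colMeans(p)
  usable <- !is.na(pi_hat) & pi_hat > 0 & pi_hat < 1
  if (!any(usable)) stop("all loci monomorphic or undefined", call. = FALSE)
  if (sum(usable) < 100) {
    warning("fewer than 100 usable loci; covariance estimate will be noisy")
  }
  pu <- p[, usable, drop = FALSE]
  piu <- pi_hat[usable]
  dev <- sweep(pu, 2, piu) / rep(sqrt(piu * (1 - piu)), each = r)
  M <- tcrossprod(dev) / ncol(dev)

  # minimum-off-diagonal completion: E[M] = A Omega A leaves Omega known only
  # up to M + 1v' + v1'; choose v minimizing the off-diagonal sum of squares
  # (normal equations (r-2) v_i + sum(v) = -R_i with R_i the off-diagonal row
  # sums of M), exact for diagonal Omega
  if (r >= 3) {
    R_i <- rowSums(M) - diag(M)
    S_v <- -sum(R_i) / (2 * r - 2)
    v <- (-R_i - S_v) / (r - 2)
    omega <- M + outer(v, rep(1, r)) + outer(rep(1, r), v)
  } else {
    omega <- M
  }
  omega <- (omega + t(omega)) / 2

  lam <- shrinkage
  repeat {
    shrunk <- (1 - lam) * omega + lam * diag(diag(omega), r)
    ev <- eigen(shrunk, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8 * max(ev)) break
    lam <- min(1, lam + 0.05)
    if (lam >= 1) {
      shrunk <- diag(pmax(diag(omega), 1e-6), r)
      break
    }
    message("increasing shrinkage to ", lam, " for positive-definiteness")
  }
  dimnames(shrunk) <- list(freqs$pops, freqs$pops)
  structure(
    list(
      omega = shrunk,
      pi_hat = stats::setNames(pi_hat, freqs$loci),
      shrinkage = lam,
      n_loci = sum(usable)
    ),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf(
    "<covariance_model> %d populations, %d loci, shrinkage %.2f\n",
    nrow(x$omega), x$n_loci, x$shrinkage
  ))
  print(round(x$omega, 4))
  invisible(x)
}

#' Covariance-standardized XtX differentiation scan
#'
#' Per-locus quadratic-form differentiation statistic
#' `XtX = (p - pi_hat 1)' Omega^-1 (p - pi_hat 1) / (pi_hat (1 - pi_hat))`,
#' analogous to F_ST but standardized by the estimated neutral covariance of
#' population allele frequencies. Significance is declared against an
#' empirical threshold calibrated on a pseudo-observed dataset
#' ([pod_calibrate()]). Loci monomorphic across populations get statistic 0;
#' loci with undefined frequencies in any population are skipped with a
#' message.
#'
#' @param freqs a [population_allele_freqs()] result.
#' @param cov a [estimate_pop_covariance()] model.
#' @param pod_threshold numeric threshold (e.g. from [pod_calibrate()]);
#'   `NULL` leaves the `significant` column `NA`.
#' @return A `scan_result` tibble: `locus`, `statistic`, `significant`, `test`.
#' @export
xtx_scan <- function(freqs, cov, pod_threshold = NULL) {
  stopifnot(inherits(freqs, "pop_freqs"), inherits(cov, "covariance_model"))
  r <- length(freqs$pops)
  omega_inv <- solve(cov$omega)
  p <- freqs$freq
  pi_hat <- colMeans(p)
  stat <- rep(NA_real_, length(freqs$loci))
  defined <- colSums(is.na(p)) == 0
  if (any(!defined)) {
    message(sum(!defined), " locus/loci with undefined frequencies skipped")
  }
  mono <- defined & (pi_hat <= 0 | pi_hat >= 1)
  stat[mono] <- 0
  use <- defined & !mono
  if (any(use)) {
    dev <- sweep(p[, use, drop = FALSE], 2, pi_hat[use])
    qf <- colSums(dev * (omega_inv %*% dev))
    stat[use] <- qf / (pi_hat[use] * (1 - pi_hat[use]))
  }
  sig <- if (is.null(pod_threshold)) {
    rep(NA, length(stat))
  } else {
    !is.na(stat) & stat > pod_threshold
  }
  out <- tibble::tibble(locus = freqs$loci, statistic = stat, significant = sig)
  new_scan_result(
    out, "xtx-lite",
    if (is.null(pod_threshold)) "uncalibrated" else sprintf("XtX > POD threshold %.3f", pod_threshold)
  )
}

#' Calibrate an XtX significance threshold on a pseudo-observed dataset
#'
#' Simulates `L_pod` neutral loci from the fitted covariance model (ancestral
#' frequencies Uniform(0.05, 0.95), population frequencies from the clipped
#' Gaussian drift model, observed frequencies from binomial sampling with
#' per-locus allele counts resampled with replacement from the observed
#' data), computes XtX for each simulated locus with the same model, and
#' returns the `1 - q` quantile.
#'
#' @param cov a [estimate_pop_covariance()] model.
#' @param sample_sizes pops-by-loci matrix of observed called allele counts
#'   (the `n_alleles` element of a [population_allele_freqs()] result).
#' @param L_pod number of simulated neutral loci; values below `1/q` trigger
#'   a warning because the quantile then rests on very few order statistics.
#' @param q upper tail mass of the threshold (default 0.0001, the top 0.01%).
#' @param seed integer seed.
#' @return The threshold (scalar), with the simulated statistics in
#'   `attr(, "pod_stats")`.
#' @export
pod_calibrate <- function(cov, sample_sizes, L_pod = 1e5, q = 1e-4, seed = 1) {
  stopifnot(inherits(cov, "covariance_model"))
  if (L_pod < 1 / q) {
    warning("L_pod below 1/q; the POD quantile rests on very few order statistics")
  }
  r <- nrow(cov$omega)
  sample_sizes <- as.matrix(sample_sizes)
  stopifnot(nrow(sample_sizes) == r)
  withr::with_seed(seed, {
    pi0 <- runif(L_pod, 0.05, 0.95)
    cl <- chol(cov$omega)
    z <- matrix(rnorm(r * L_pod), r, L_pod)
    p_true <- rep(pi0, each = r) + crossprod(cl, z) * rep(sqrt(pi0 * (1 - pi0)), each = r)
    p_true <- matrix(pmin(pmax(p_true, 0), 1), r, L_pod)
    size_idx <- sample.int(ncol(sample_sizes), L_pod, replace = TRUE)
    n_all <- sample_sizes[, size_idx, drop = FALSE]
    n_all[n_all < 2] <- 2
    counts <- matrix(rbinom(r * L_pod, as.vector(n_all), as.vector(p_true)), r, L_pod)
    p_obs <- counts / n_all
  })
  pi_hat <- colMeans(p_obs)
  omega_inv <- solve(cov$omega)
  use <- pi_hat > 0 & pi_hat < 1
  dev <- sweep(p_obs[, use, drop = FALSE], 2, pi_hat[use])
  stats <- colSums(dev * (omega_inv %*% dev)) / (pi_hat[use] * (1 - pi_hat[use]))
  stats <- c(stats, rep(0, sum(!use)))
  thr <- unname(quantile(stats, 1 - q, type = 7))
  attr(thr, "pod_stats") <- stats
  thr
}
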