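make_cov_model <- function(omega, pi_hat = NULL) {
  structure(
    list(omega = omega, pi_hat = pi_hat, shrinkage = 0, n_loci = NA_integer_),
    class = "covariance_model"
  )
}

test_that("a known independent-drift covariance is recovered", {
  omega <- diag(c(0.10, 0.15, 0.20, 0.25))
  sim <- simulate_dataset(sim_config(
    n_pops = 4, n_per_pop = 25, n_loci = 5000, omega = omega,
    n_adaptive = 0, missing_rate = 0, seed = 3
  ))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr, shrinkage = 0)
  expect_lt(norm(cv$omega - omega, "F") / norm(omega, "F"), 0.15)
  off <- cv$omega[upper.tri(cv$omega)]
  expect_true(all(abs(off) < 0.02))
})

test_that("full shrinkage gives an exactly diagonal matrix", {
  sim <- simulate_dataset(sim_config(n_loci = 300, seed = 5))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr, shrinkage = 1)
  expect_equal(cv$omega, diag(diag(cv$omega)), ignore_attr = TRUE)
  expect_equal(cv$shrinkage, 1)
})

test_that("XtX reduces to the squared deviation sum under identity covariance", {
  freqs <- structure(
    list(
      pops = c("A", "B", "C"),
      loci = c("l1", "l2"),
      freq = cbind(l1 = c(0.2, 0.5, 0.8), l2 = c(0.4, 0.4, 0.4)),
      n_alleles = matrix(40L, 3, 2, dimnames = list(NULL, c("l1", "l2")))
    ),
    class = "pop_freqs"
  )
  cv <- make_cov_model(diag(3))
  xt <- xtx_scan(freqs, cv)
  pi1 <- 0.5
  z <- (c(0.2, 0.5, 0.8) - pi1) / sqrt(pi1 * (1 - pi1))
  expect_equal(xt$statistic[1], sum(z^2))
  # frequencies equal to the ancestral mean give exactly zero
  expect_equal(xt$statistic[2], 0)
})

test_that("the neutral XtX mean matches a Monte-Carlo oracle of the quadratic form", {
  # deep samples keep binomial sampling noise small relative to drift, so the
  # closed-form drift model is the appropriate oracle
  omega <- diag(c(0.10, 0.15, 0.20, 0.25))
  sim <- simulate_dataset(sim_config(
    n_pops = 4, n_per_pop = 100, n_loci = 3000, omega = omega,
    n_adaptive = 0, missing_rate = 0, pi_range = c(0.2, 0.8), seed = 13
  ))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr)
  xt <- xtx_scan(fr, cv)

  # independent oracle: expectation of d' Omega^-1 d / (pi(1-pi)) when d is
  # centered on the across-population mean -- Monte Carlo on the closed-form
  # drift model with the true omega (the centering consumes one degree of
  # freedom, so the expectation sits near n_pops - 1, not n_pops)
  set.seed(99)
  r <- 4
  cl <- chol(omega)
  mc <- replicate(20000, {
    pi0 <- runif(1, 0.2, 0.8)
    p <- pi0 + as.numeric(crossprod(cl, rnorm(r))) * sqrt(pi0 * (1 - pi0))
    p <- pmin(pmax(p, 0), 1)
    ph <- mean(p)
    if (ph <= 0 || ph >= 1) return(NA_real_)
    d <- p - ph
    as.numeric(crossprod(d, solve(omega, d))) / (ph * (1 - ph))
  })
  oracle_mean <- mean(mc, na.rm = TRUE)
  expect_equal(mean(xt$statistic, na.rm = TRUE), oracle_mean, tolerance = 0.10)
})

test_that("XtX is invariant to population relabeling", {
  sim <- simulate_dataset(sim_config(n_loci = 400, missing_rate = 0, seed = 19))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr)
  xt <- xtx_scan(fr, cv)

  perm <- c(3, 1, 4, 2)
  fr2 <- fr
  fr2$pops <- fr$pops[perm]
  fr2$freq <- fr$freq[perm, ]
  fr2$n_alleles <- fr$n_alleles[perm, ]
  cv2 <- make_cov_model(cv$omega[perm, perm])
  xt2 <- xtx_scan(fr2, cv2)
  expect_equal(xt2$statistic, xt$statistic, tolerance = 1e-10)
})

test_that("the POD threshold flags its own tail at the nominal rate", {
  sim <- simulate_dataset(sim_config(n_loci = 500, seed = 23))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr)
  L_pod <- 20000
  q <- 1e-3
  thr <- pod_calibrate(cv, fr$n_alleles, L_pod = L_pod, q = q, seed = 1)
  stats <- attr(thr, "pod_stats")
  n_flagged <- sum(stats > as.numeric(thr))
  expect_lt(abs(n_flagged - q * L_pod), 4 * sqrt(q * L_pod) + 1)

  # threshold is monotone in the quantile level
  thr2 <- pod_calibrate(cv, fr$n_alleles, L_pod = L_pod, q = 0.01, seed = 1)
  expect_gte(as.numeric(thr), as.numeric(thr2))

  # and stable across seeds
  thrs <- vapply(1:3, function(s) {
    as.numeric(pod_calibrate(cv, fr$n_alleles, L_pod = 1e5, q = 1e-3, seed = s))
  }, numeric(1))
  expect_lt((max(thrs) - min(thrs)) / mean(thrs), 0.05)

  expect_warning(pod_calibrate(cv, fr$n_alleles, L_pod = 100, q = 1e-4, seed = 1), "L_pod")
})
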