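sim_scores <- function(beta_std, n_sites = 8, n_per = 25, sigma_u = 0.25,
                       n_loci = 200, seed = 1) {
  set.seed(seed)
  x <- rnorm(n_sites)
  x_std <- as.numeric(scale(x))
  u <- rnorm(n_sites, 0, sigma_u)
  n <- n_sites * n_per
  trials <- 2 * n_loci
  scores <- tibble::tibble(
    sample = sprintf("i%03d", seq_len(n)),
    site = rep(sprintf("S%d", seq_len(n_sites)), each = n_per),
    variable = "env",
    n_nonmissing = n_loci,
    raw = rbinom(n, trials, plogis(-0.5 + rep(beta_std * x_std + u, each = n_per)))
  )
  scores$percent <- scores$raw / trials
  env <- env_table(tibble::tibble(
    site = sprintf("S%d", seq_len(n_sites)),
    latitude = seq_len(n_sites), longitude = seq_len(n_sites), env = x
  ))
  list(scores = scores, env = env)
}

test_that("the GLMM validates its inputs", {
  s <- sim_scores(0, n_sites = 4, seed = 3)
  expect_warning(fit_score_glmm(s$scores, s$env, "env"), "weakly identified")

  const_env <- s$env
  const_env$env <- 1
  expect_error(
    suppressWarnings(fit_score_glmm(s$scores, const_env, "env")),
    "constant"
  )
  one_site <- s$scores[s$scores$site == "S1", ]
  expect_error(suppressWarnings(fit_score_glmm(one_site, s$env, "env")), "2 sites")
})

test_that("identical scores give a null slope and near-zero site variance", {
  s <- sim_scores(0, seed = 5)
  s$scores$raw <- 200
  fit <- suppressWarnings(fit_score_glmm(s$scores, s$env, "env"))
  expect_lte(fit$ci_lo, 0)
  expect_gte(fit$ci_hi, 0)
  expect_lt(fit$sigma2_site, 1e-6)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$beta)
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
  expect_equal(glance(fit)$n_sites, 8)
})

test_that("coefficients are reported on the original predictor scale", {
  s <- sim_scores(1, seed = 7)
  fit <- fit_score_glmm(s$scores, s$env, "env")
  x_sd <- sd(s$env$env)
  expect_equal(fit$beta, fit$beta_std / x_sd)
  # rescaling the predictor rescales the coefficient inversely
  env10 <- s$env
  env10$env <- env10$env * 10
  fit10 <- fit_score_glmm(s$scores, env10, "env")
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-6)
  expect_equal(fit10$beta_std, fit$beta_std, tolerance = 1e-6)
})

test_that("random-subset null p-values are bounded and power shows on planted sets", {
  sim <- simulate_dataset(sim_config(
    n_pops = 8, n_per_pop = 15, n_loci = 400, fst = 0.1,
    n_adaptive = 40, effect_size = 2.5, missing_rate = 0.1, seed = 9
  ))
  g <- sim$genotypes
  fr <- population_allele_freqs(g)
  truth <- sim$truth$locus[sim$truth$adaptive]

  ori <- suppressMessages(orient_alleles(fr, sim$env, "temp", truth))
  sc <- suppressMessages(additive_scores(g, ori))
  fit <- fit_score_glmm(sc, sim$env, "temp")
  expect_gt(fit$beta, 0)

  nul <- suppressMessages(random_subset_null(
    g, fr, sim$env, "temp",
    n_loci = length(truth), reps = 199, seed = 2,
    observed_beta = fit$beta
  ))
  expect_gte(nul$p_value, 1 / 200)
  expect_lte(nul$p_value, 1)
  expect_lte(nul$p_value, 0.01)

  # reproducible under the same seed
  nul2 <- suppressMessages(random_subset_null(
    g, fr, sim$env, "temp",
    n_loci = length(truth), reps = 199, seed = 2,
    observed_beta = fit$beta
  ))
  expect_identical(nul$null_beta, nul2$null_beta)
})

test_that("random observed sets give approximately uniform empirical p-values", {
  sim <- simulate_dataset(sim_config(
    n_pops = 8, n_per_pop = 15, n_loci = 300, fst = 0.1,
    n_adaptive = 0, missing_rate = 0.1, seed = 29
  ))
  g <- sim$genotypes
  fr <- population_allele_freqs(g)
  n_sub <- 25
  reps <- 39
  ps <- vapply(1:24, function(i) {
    set.seed(1000 + i)
    loci <- g$loci$locus[sample.int(ncol(g$dosage), n_sub)]
    ori <- suppressMessages(orient_alleles(fr, sim$env, "temp", loci))
    sc <- suppressMessages(additive_scores(g, ori))
    fit <- fit_score_glmm(sc, sim$env, "temp")
    suppressMessages(random_subset_null(
      g, fr, sim$env, "temp",
      n_loci = n_sub, reps = reps, seed = i,
      observed_beta = fit$beta
    ))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
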