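test_that("the PCA-regression scan is calibrated on neutral data", {
  for (seed in 1:2) {
    sim <- simulate_dataset(sim_config(
      n_pops = 4, n_per_pop = 25, n_loci = 2000, fst = 0.05,
      n_adaptive = 0, missing_rate = 0.1, seed = seed
    ))
    gi <- impute_by_population(sim$genotypes, global_fallback = TRUE)
    pc <- suppressMessages(pcadapt_scan(gi, K = 3))
    expect_lte(mean(pc$significant), 0.001)
    expect_gt(attr(pc, "gif"), 0.8)
    expect_lt(attr(pc, "gif"), 1.2)
  }
})

test_that("the PCA-regression scan flags planted fixed differences", {
  sim <- simulate_dataset(sim_config(
    n_pops = 4, n_per_pop = 25, n_loci = 2000, fst = 0.1,
    n_adaptive = 0, missing_rate = 0, seed = 31
  ))
  g <- sim$genotypes
  d <- g$dosage
  planted <- sample(colnames(d), 20)
  pops <- unname(g$populations)
  for (l in planted) {
    d[, l] <- ifelse(pops %in% c("P1", "P2"), 0, 2)
  }
  g2 <- genotype_matrix(d, populations = pops, loci = g$loci)
  pc <- suppressMessages(pcadapt_scan(impute_by_population(g2), K = 3))
  hit <- intersect(significant_loci(pc), planted)
  expect_gte(length(hit) / length(planted), 0.8)
})

test_that("FLK vanishes for undifferentiated loci and matches scalar algebra", {
  freqs <- structure(
    list(
      pops = c("A", "B", "C"),
      loci = c("flat", "var"),
      freq = cbind(flat = c(0.4, 0.4, 0.4), var = c(0.2, 0.5, 0.9)),
      n_alleles = matrix(30L, 3, 2, dimnames = list(NULL, c("flat", "var")))
    ),
    class = "pop_freqs"
  )
  kin <- diag(c(0.1, 0.2, 0.3))
  fl <- flk_scan(freqs, kinship = kin)
  expect_equal(fl$statistic[fl$locus == "flat"], 0)

  # hand-evaluated quadratic form with diagonal kinship
  p <- c(0.2, 0.5, 0.9)
  w <- 1 / diag(kin)
  p0 <- sum(w * p) / sum(w)
  oracle <- sum((p - p0)^2 / diag(kin)) / (p0 * (1 - p0))
  expect_equal(fl$statistic[fl$locus == "var"], oracle, tolerance = 1e-12)
})

test_that("FLK requires enough populations and flags monomorphic loci as null", {
  freqs2 <- structure(
    list(
      pops = c("A", "B"), loci = "l1",
      freq = cbind(l1 = c(0.1, 0.9)),
      n_alleles = matrix(10L, 2, 1)
    ),
    class = "pop_freqs"
  )
  expect_error(flk_scan(freqs2), "3 populations")

  sim <- simulate_dataset(sim_config(n_loci = 300, missing_rate = 0, seed = 41))
  fr <- population_allele_freqs(sim$genotypes)
  fl <- flk_scan(fr)
  mono <- colMeans(fr$freq) %in% c(0, 1)
  if (any(mono)) {
    expect_true(all(fl$statistic[mono] == 0))
    expect_true(all(fl$p_value[mono] == 1))
  }
  expect_true(all(fl$p_value >= 0 & fl$p_value <= 1, na.rm = TRUE))
})

test_that("the latent-factor scan is calibrated in the weak-structure regime", {
  for (seed in 1:2) {
    sim <- simulate_dataset(sim_config(
      n_pops = 8, n_per_pop = 25, n_loci = 2000, fst = 0.002,
      n_adaptive = 0, missing_rate = 0, seed = seed
    ))
    gi <- impute_by_population(sim$genotypes)
    lf <- suppressMessages(lfmm_scan(gi, sim$env, K = 3, variables = "temp"))
    expect_lte(mean(lf$significant), 0.001)
    expect_gt(attr(lf, "gif")[["temp"]], 0.8)
    expect_lt(attr(lf, "gif")[["temp"]], 1.2)
  }
})

test_that("latent-factor p-values are uniform under a permuted environment", {
  sim <- simulate_dataset(sim_config(
    n_pops = 8, n_per_pop = 25, n_loci = 2000, fst = 0.002,
    n_adaptive = 0, missing_rate = 0, seed = 51
  ))
  env <- sim$env
  set.seed(1)
  env$temp <- sample(env$temp) # environment decoupled from any structure
  gi <- impute_by_population(sim$genotypes)
  lf <- suppressMessages(lfmm_scan(gi, env, K = 3, variables = "temp"))
  ks <- suppressWarnings(ks.test(lf$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("scans are equivariant to locus order and allele coding", {
  sim <- simulate_dataset(sim_config(
    n_pops = 4, n_per_pop = 20, n_loci = 300, fst = 0.1,
    n_adaptive = 10, effect_size = 2, missing_rate = 0, seed = 61
  ))
  gi <- impute_by_population(sim$genotypes)

  pc <- suppressMessages(pcadapt_scan(gi, K = 3))
  perm <- sample(ncol(gi$dosage))
  gi_perm <- subset_genotypes(gi, loci = perm)
  pc_perm <- suppressMessages(pcadapt_scan(gi_perm, K = 3))
  expect_equal(
    pc_perm$p_value[match(pc$locus, pc_perm$locus)],
    pc$p_value,
    tolerance = 1e-8
  )

  # flipping allele coding at a locus leaves its p-value unchanged
  flip_idx <- c(5, 50, 150)
  d <- gi$dosage
  d[, flip_idx] <- 2 - d[, flip_idx]
  gi_flip <- genotype_matrix(d, populations = gi$populations, loci = gi$loci, imputed = TRUE)
  pc_flip <- suppressMessages(pcadapt_scan(gi_flip, K = 3))
  expect_equal(pc_flip$p_value[flip_idx], pc$p_value[flip_idx], tolerance = 1e-8)

  lf <- suppressMessages(lfmm_scan(gi, sim$env, K = 3, variables = "temp"))
  lf_flip <- suppressMessages(lfmm_scan(gi_flip, sim$env, K = 3, variables = "temp"))
  expect_equal(lf_flip$p_value[flip_idx], lf$p_value[flip_idx], tolerance = 1e-8)
})

test_that("the frequency-level association scan ranks and gates correctly", {
  freqs <- structure(
    list(
      pops = c("A", "B", "C", "D"),
      loci = c("mono", "graded"),
      freq = cbind(mono = c(0.5, 0.5, 0.5, 0.5), graded = c(0.1, 0.3, 0.5, 0.7)),
      n_alleles = matrix(40L, 4, 2, dimnames = list(NULL, c("mono", "graded")))
    ),
    class = "pop_freqs"
  )
  cv <- structure(
    list(omega = diag(4), pi_hat = NULL, shrinkage = 0, n_loci = 100L),
    class = "covariance_model"
  )
  env <- env_table(tibble::tibble(
    site = c("A", "B", "C", "D"), latitude = 1:4, longitude = 1:4,
    x = c(1, 2, 3, 4)
  ))
  res <- env_assoc_scan(freqs, cv, env, variables = "x")
  g_res <- res[res$locus == "graded", ]
  expect_equal(abs(g_res$rho), 1) # perfectly rank-ordered by the environment
  m_res <- res[res$locus == "mono", ]
  expect_lte(m_res$bf, 1) # no frequency variance: the null wins
})

test_that("the joint BF and rho gate enriches for planted associations", {
  sim <- simulate_dataset(sim_config(
    n_pops = 8, n_per_pop = 25, n_loci = 2000, fst = 0.05,
    n_adaptive = 40, effect_size = 2, missing_rate = 0.1, seed = 71
  ))
  fr <- population_allele_freqs(sim$genotypes)
  cv <- estimate_pop_covariance(fr)
  bf <- env_assoc_scan(fr, cv, sim$env, variables = "temp")
  flagged <- significant_loci(bf)
  truth <- sim$truth$locus[sim$truth$adaptive]
  a <- length(intersect(flagged, truth))
  b <- length(setdiff(flagged, truth))
  c_ <- length(setdiff(truth, flagged))
  d <- 2000 - a - b - c_
  or <- (a * d) / max(b * c_, 1)
  expect_gt(or, 5)
})
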