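test_that("haversine distance obeys metric properties", {
  expect_equal(great_circle_km(38.3, -84.8, 38.3, -84.8), 0)
  set.seed(14)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -180, 180))
    b <- c(runif(1, -80, 80), runif(1, -180, 180))
    cc <- c(runif(1, -80, 80), runif(1, -180, 180))
    dab <- great_circle_km(a[1], a[2], b[1], b[2])
    dba <- great_circle_km(b[1], b[2], a[1], a[2])
    dac <- great_circle_km(a[1], a[2], cc[1], cc[2])
    dcb <- great_circle_km(cc[1], cc[2], b[1], b[2])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-6)
  }
})

test_that("site geography reproduces the study distances", {
  env <- barbouri_sites()
  d <- geo_distance(env)
  expect_equal(d$values["N", "S"], 267, tolerance = 0.01)
  expect_equal(mean(tidy(d)$value), 190.62, tolerance = 0.01)
})

test_that("environmental distance equals the scaled-Euclidean oracle", {
  env <- barbouri_sites()
  ed <- env_distance(env)
  xs <- scale(as.matrix(env[, env_variables(env)]))
  oracle <- as.matrix(dist(xs))
  dimnames(oracle) <- list(env$site, env$site)
  expect_equal(ed$values, oracle, tolerance = 1e-10)

  same <- env_table(tibble::tibble(
    site = c("a", "b"), latitude = 1:2, longitude = 1:2,
    v1 = c(3, 3), v2 = c(1, 2)
  ))
  expect_error(env_distance(same), "zero-variance.*v1")
  dup <- env_table(tibble::tibble(
    site = c("a", "b", "c"), latitude = 1:3, longitude = 1:3,
    v1 = c(1, 1, 5), v2 = c(2, 2, 9)
  ))
  expect_equal(env_distance(dup)$values["a", "b"], 0)
})

test_that("variable pruning matches a brute-force greedy oracle", {
  env <- barbouri_sites()
  # perfectly correlated duplicate is dropped
  env2 <- env
  env2$mat_copy <- env2$mean_annual_temp_c
  kept <- prune_env_variables(env2, r_max = 0.9)
  expect_true(xor("mean_annual_temp_c" %in% kept, FALSE))
  expect_false(all(c("mean_annual_temp_c", "mat_copy") %in% kept))

  # everything below the threshold is retained
  set.seed(2)
  indep <- env_table(tibble::tibble(
    site = sprintf("s%d", 1:20), latitude = 1:20, longitude = 1:20,
    a = rnorm(20), b = rnorm(20), c = rnorm(20)
  ))
  expect_setequal(prune_env_variables(indep, r_max = 0.9), c("a", "b", "c"))

  # correlation-block fixture vs an independent greedy recomputation
  set.seed(7)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  tbl <- tibble::tibble(site = sprintf("s%d", 1:30), latitude = 1:30, longitude = 1:30)
  for (i in 1:5) tbl[[paste0("g1_", i)]] <- base1 + rnorm(30, sd = 0.05)
  for (i in 1:5) tbl[[paste0("g2_", i)]] <- base2 + rnorm(30, sd = 0.05)
  envb <- env_table(tbl)
  groups <- list(
    g1 = paste0("g1_", 1:5),
    g2 = paste0("g2_", 1:5)
  )
  greedy_oracle <- function(vars) {
    kept <- character()
    for (v in vars) {
      if (all(vapply(kept, function(k) abs(cor(envb[[v]], envb[[k]])) <= 0.9, logical(1)))) {
        kept <- c(kept, v)
      }
    }
    kept
  }
  oracle <- greedy_oracle(unlist(lapply(groups, greedy_oracle), use.names = FALSE))
  expect_setequal(prune_env_variables(envb, groups, r_max = 0.9), oracle)

  # force_keep survives pruning
  kept_fk <- prune_env_variables(env2, r_max = 0.9, force_keep = "mat_copy")
  expect_true("mat_copy" %in% kept_fk)
})

test_that("matrix correlations and F_ST linearization follow their definitions", {
  env <- barbouri_sites()
  gd <- geo_distance(env)
  expect_equal(matrix_correlations(list(a = gd, b = gd))$r, 1.0)

  m <- matrix(0.5, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  diag(m) <- 0
  lin <- linearize_fst(pairwise_matrix(m, "fst"))
  expect_equal(lin$values["x", "y"], 1.0)

  other <- pairwise_matrix(
    matrix(0, 2, 2, dimnames = list(c("x", "z"), c("x", "z"))), "d"
  )
  expect_error(matrix_correlations(list(a = lin, b = other)), "label mismatch")
})

test_that("isolation by distance yields positive geo/F_ST matrix correlation", {
  for (seed in 1:5) {
    lat <- c(37, 37.8, 38.6, 39.4)
    env <- env_table(tibble::tibble(
      site = sprintf("P%d", 1:4), latitude = lat, longitude = rep(-85, 4),
      temp = 4:1, precip = c(2, 4, 3, 1)
    ))
    dgeo <- outer(lat, lat, function(a, b) abs(a - b))
    omega <- 0.35 * exp(-dgeo / 0.8) + diag(0.05, 4)
    sim <- simulate_dataset(sim_config(
      n_pops = 4, n_per_pop = 15, n_loci = 500, omega = omega, env = env,
      n_adaptive = 0, missing_rate = 0, seed = seed
    ))
    fstm <- fst_matrix(pairwise_wc_fst(sim$genotypes))
    res <- matrix_correlations(list(
      geo = geo_distance(env), fst = linearize_fst(fstm)
    ))
    expect_gt(res$r, 0)
  }
})
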