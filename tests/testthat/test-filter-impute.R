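test_that("SNP steps drop loci exceeding the threshold in any population", {
  # locus 1 missing in 50% of pop A, locus 2 complete
  dA <- rbind(c(NA, 0), c(NA, 1), c(0, 2), c(1, 0))
  dB <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1))
  g <- toy_genotypes(list(A = dA, B = dB))
  out <- iterative_filter(g, filter_schedule(
    tibble::tibble(kind = "snp", threshold = 0.4)
  ))
  expect_equal(ncol(out$dosage), 1)
  expect_equal(attr(out, "filter_report")$n_removed, 1)
})

test_that("a schedule of thresholds 1.0 changes nothing and filtering is idempotent", {
  sim <- simulate_dataset(sim_config(n_loci = 300, seed = 5))
  sched <- filter_schedule(tibble::tibble(
    kind = c("snp", "individual"), threshold = c(1, 1)
  ))
  out <- iterative_filter(sim$genotypes, sched)
  expect_equal(out$dosage, sim$genotypes$dosage)

  f1 <- iterative_filter(sim$genotypes)
  f2 <- iterative_filter(f1)
  expect_equal(dim(f2), dim(f1))
  expect_equal(sum(attr(f2, "filter_report")$n_removed), 0)
})

test_that("per-step removal counts match a brute-force recount", {
  sim <- simulate_dataset(sim_config(
    n_pops = 4, n_per_pop = 25, n_loci = 500, missing_rate = 0.05, seed = 9
  ))
  g <- sim$genotypes
  # plant a block of loci with ~30% extra missingness in population P2
  d <- g$dosage
  rows <- which(unname(g$populations) == "P2")
  set.seed(1)
  for (l in 1:80) {
    hit <- rows[runif(length(rows)) < 0.30]
    d[hit, l] <- NA
  }
  g <- genotype_matrix(d, populations = g$populations, loci = g$loci)
  sched <- filter_schedule(tibble::tibble(
    kind = c("snp", "snp"), threshold = c(0.5, 0.25)
  ))
  out <- iterative_filter(g, sched)
  rep_tbl <- attr(out, "filter_report")

  # brute-force recount, step by step
  worst_miss <- function(dm, pops) {
    sapply(seq_len(ncol(dm)), function(l) {
      max(tapply(is.na(dm[, l]), pops, mean))
    })
  }
  pops <- unname(g$populations)
  w1 <- worst_miss(g$dosage, pops)
  expect_equal(rep_tbl$n_removed[1], sum(w1 > 0.5))
  d2 <- g$dosage[, w1 <= 0.5, drop = FALSE]
  w2 <- worst_miss(d2, pops)
  expect_equal(rep_tbl$n_removed[2], sum(w2 > 0.25))
  expect_equal(ncol(out$dosage), sum(w2 <= 0.25))
})

test_that("schedules are validated and emptying the matrix is fatal", {
  expect_error(filter_schedule(tibble::tibble(kind = "snp", threshold = 0)), "thresholds")
  expect_error(
    filter_schedule(tibble::tibble(kind = c("snp", "snp"), threshold = c(0.3, 0.5))),
    "non-increasing"
  )
  d <- rbind(c(NA, NA), c(0, NA), c(NA, 1), c(0, 1))
  g <- toy_genotypes(list(A = d))
  expect_error(
    iterative_filter(g, filter_schedule(tibble::tibble(kind = "snp", threshold = 0.1))),
    "removes all loci"
  )
})

test_that("population-mean imputation fills missing dosages with 2 p-hat", {
  d <- rbind(c(0, 1), c(2, 1), c(NA, 1))
  g <- toy_genotypes(list(A = d))
  gi <- impute_by_population(g)
  expect_true(gi$imputed)
  expect_equal(unname(gi$dosage[3, 1]), 1.0) # mean of {0, 2}
  expect_equal(unname(gi$dosage[, 2]), c(1, 1, 1))

  # no missing data: identity
  g2 <- toy_genotypes(list(A = rbind(c(0, 2), c(1, 1))))
  expect_equal(impute_by_population(g2)$dosage, g2$dosage)
})

test_that("imputation preserves per-population column means", {
  sim <- simulate_dataset(sim_config(n_loci = 400, missing_rate = 0.25, seed = 3))
  g <- sim$genotypes
  gi <- impute_by_population(g, global_fallback = TRUE)
  for (p in unique(unname(g$populations))) {
    rows <- unname(g$populations) == p
    obs_mean <- colMeans(g$dosage[rows, , drop = FALSE], na.rm = TRUE)
    imp_mean <- colMeans(gi$dosage[rows, , drop = FALSE])
    ok <- is.finite(obs_mean)
    expect_equal(imp_mean[ok], obs_mean[ok], tolerance = 1e-12)
  }
})

test_that("fully missing loci in a population error without the fallback", {
  d <- rbind(c(NA, 0), c(NA, 1))
  e <- rbind(c(1, 1), c(2, 0))
  g <- toy_genotypes(list(A = d, B = e))
  expect_error(impute_by_population(g), "global_fallback")
  gi <- impute_by_population(g, global_fallback = TRUE)
  expect_false(anyNA(gi$dosage))
  expect_equal(unname(gi$dosage[1, 1]), 1.5) # across-population mean of {1, 2}
})
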