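toy_freqs <- function(freq_mat, pops = rownames(freq_mat)) {
  structure(
    list(
      pops = pops, loci = colnames(freq_mat), freq = freq_mat,
      n_alleles = matrix(40L, nrow(freq_mat), ncol(freq_mat),
        dimnames = dimnames(freq_mat)
      )
    ),
    class = "pop_freqs"
  )
}

toy_env4 <- function(x = c(1, 2, 3, 4)) {
  env_table(tibble::tibble(
    site = c("A", "B", "C", "D"), latitude = 1:4, longitude = 1:4, env = x
  ))
}

test_that("allele orientation follows the sign of the frequency correlation", {
  fm <- rbind(A = c(0.1, 0.7), B = c(0.3, 0.5), C = c(0.5, 0.3), D = c(0.7, 0.1))
  colnames(fm) <- c("up", "down")
  fr <- toy_freqs(fm)
  ori <- orient_alleles(fr, toy_env4(), "env", c("up", "down"))
  expect_equal(ori$allele[ori$locus == "up"], "alt")
  expect_equal(ori$allele[ori$locus == "down"], "ref")

  # reversing the environment flips every orientation
  ori_rev <- orient_alleles(fr, toy_env4(c(4, 3, 2, 1)), "env", c("up", "down"))
  expect_equal(ori_rev$allele[ori_rev$locus == "up"], "ref")

  # zero-variance loci are excluded
  fm2 <- cbind(fm, flat = c(0.5, 0.5, 0.5, 0.5))
  expect_message(
    ori2 <- orient_alleles(toy_freqs(fm2), toy_env4(), "env", colnames(fm2)),
    "excluded"
  )
  expect_false("flat" %in% ori2$locus)
})

test_that("additive scores implement the percent formula exactly", {
  loci <- tibble::tibble(
    locus = c("l1", "l2", "l3"), chrom = "c1", pos = 1:3, ref = "A", alt = "T"
  )
  d <- rbind(
    max_ind = c(2, 2, 2),
    part_ind = c(1, 2, NA),
    zero_ind = c(0, 0, 0)
  )
  g <- genotype_matrix(d, populations = rep("A", 3), loci = loci)
  ori <- structure(
    tibble::tibble(locus = c("l1", "l2", "l3"), allele = "alt", r = 0.9),
    variable = "env", class = c("orientation", "data.frame")
  )
  sc <- additive_scores(g, ori)
  expect_equal(sc$raw[sc$sample == "max_ind"], 6)
  expect_equal(sc$percent[sc$sample == "max_ind"], 1.0)
  expect_equal(sc$raw[sc$sample == "part_ind"], 3)
  expect_equal(sc$n_nonmissing[sc$sample == "part_ind"], 2)
  expect_equal(sc$percent[sc$sample == "part_ind"], 0.75)
  expect_equal(sc$percent[sc$sample == "zero_ind"], 0)

  # an individual missing every candidate locus is excluded
  d2 <- rbind(d, gone = c(NA, NA, NA))
  g2 <- genotype_matrix(d2, populations = rep("A", 4), loci = loci)
  expect_message(sc2 <- additive_scores(g2, ori), "excluded")
  expect_false("gone" %in% sc2$sample)
  # exclusion must not corrupt the retained rows
  expect_false(anyNA(sc2$percent))
  expect_equal(sc2$percent, sc$percent)

  # scoring is invariant to locus order
  ori_rev <- ori[3:1, ]
  class(ori_rev) <- class(ori)
  attr(ori_rev, "variable") <- "env"
  expect_equal(additive_scores(g, ori_rev)$raw, sc$raw)
})

test_that("recoding ref/alt at every locus maps percent scores to 1 - p", {
  sim <- simulate_dataset(sim_config(
    n_loci = 100, n_adaptive = 20, effect_size = 2, seed = 19
  ))
  g <- sim$genotypes
  fr <- population_allele_freqs(g)
  loci <- sim$truth$locus[sim$truth$adaptive]
  ori <- suppressMessages(orient_alleles(fr, sim$env, "temp", loci))
  sc <- suppressMessages(additive_scores(g, ori))

  # flip dosage coding (and swap ref/alt) at every locus
  d_flip <- 2 - g$dosage
  loci_flip <- g$loci
  names(loci_flip)[names(loci_flip) == "ref"] <- ".tmp"
  names(loci_flip)[names(loci_flip) == "alt"] <- "ref"
  names(loci_flip)[names(loci_flip) == ".tmp"] <- "alt"
  loci_flip <- loci_flip[, c("locus", "chrom", "pos", "ref", "alt")]
  g_flip <- genotype_matrix(d_flip, populations = g$populations, loci = loci_flip)

  # keeping the original orientation labels: every contribution flips, so
  # each percent score maps to 1 - p exactly
  sc_fixed <- suppressMessages(additive_scores(g_flip, ori))
  m <- match(sc$sample, sc_fixed$sample)
  expect_equal(sc_fixed$percent[m], 1 - sc$percent, tolerance = 1e-12)
  expect_equal(sc_fixed$raw[m] + sc$raw, 2 * sc$n_nonmissing)

  # re-deriving the orientation on the recoded data restores the scores
  fr_flip <- population_allele_freqs(g_flip)
  ori_flip <- suppressMessages(orient_alleles(fr_flip, sim$env, "temp", loci))
  sc_flip <- suppressMessages(additive_scores(g_flip, ori_flip))
  m2 <- match(sc$sample, sc_flip$sample)
  expect_equal(sc_flip$percent[m2], sc$percent, tolerance = 1e-12)
})
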