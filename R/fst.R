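#' Weir-Cockerham pairwise F_ST with bootstrap confidence interval
#'
#' Multi-locus ratio-of-averages estimator of Weir and Cockerham's theta for
#' one pair of populations, computed from the per-locus variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals), summed over loci polymorphic in the pooled pair:
#' `theta = sum(a) / sum(a + b + c)`. The 95% interval is a bias-corrected
#' percentile bootstrap across loci. Negative estimates are reported as-is
#' with a zero-clamped convenience column.
#'
#' @param g a [genotype_matrix()] (integer dosages; not imputed).
#' @param pop_a,pop_b population labels.
#' @param n_boot bootstrap replicates over loci (0 skips the interval).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A one-row tibble: `pop_a`, `pop_b`, `n_loci`, `theta`,
#'   `theta_clamped`, `ci_lo`, `ci_hi`.
#' @export
wc_fst <- function(g, pop_a, pop_b, n_boot = 1000, conf = 0.95, seed = 1) {
  comp <- wc_pair_components(g, pop_a, pop_b)
  if (nrow(comp) == 0) {
    stop("no loci polymorphic in the pooled pair ", pop_a, "/", pop_b, call. = FALSE)
  }
  theta_of <- function(idx) {
    s <- colSums(comp[idx, , drop = FALSE])
    s[["a"]] / (s[["a"]] + s[["b"]] + s[["c"]])
  }
  est <- theta_of(seq_len(nrow(comp)))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- bc_bootstrap_ci(comp, theta_of, n_boot = n_boot, conf = conf, seed = seed)
  }
  tibble::tibble(
    pop_a = pop_a, pop_b = pop_b, n_loci = nrow(comp),
    theta = est, theta_clamped = max(est, 0),
    ci_lo = ci[1], ci_hi = ci[2]
  )
}

#' All pairwise Weir-Cockerham F_ST estimates
#'
#' @inheritParams wc_fst
#' @return A tibble with one row per population pair (see [wc_fst()]), plus a
#'   `linearized` column `theta / (1 - theta)`.
#' @export
pairwise_wc_fst <- function(g, n_boot = 0, conf = 0.95, seed = 1) {
  pops <- unique(unname(g$populations))
  pairs <- utils::combn(pops, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    wc_fst(g, pairs[1, i], pairs[2, i], n_boot = n_boot, conf = conf, seed = seed)
  })
  out$linearized <- out$theta / (1 - out$theta)
  out
}

# Per-locus W&C (1984) variance components for two populations, restricted to
# loci polymorphic in the pooled pair with >= 2 called genotypes in each pop.
wc_pair_components <- function(g, pop_a, pop_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("F_ST requires called genotypes, not imputed dosages", call. = FALSE)
  pops <- unname(g$populations)
  if (!pop_a %in% pops || !pop_b %in% pops) {
    stop("unknown population label", call. = FALSE)
  }
  da <- g$dosage[pops == pop_a, , drop = FALSE]
  db <- g$dosage[pops == pop_b, , drop = FALSE]
  stats_of <- function(d) {
    n <- colSums(!is.na(d))
    s <- colSums(d, na.rm = TRUE)
    list(
      n = n,
      p = ifelse(n > 0, s / (2 * n), NA_real_),
      h = ifelse(n > 0, colSums(d == 1, na.rm = TRUE) / n, NA_real_)
    )
  }
  A <- stats_of(da)
  B <- stats_of(db)
  usable <- A$n >= 2 & B$n >= 2
  pooled_p <- (2 * A$n * A$p + 2 * B$n * B$p) / (2 * (A$n + B$n))
  usable <- usable & !is.na(pooled_p) & pooled_p > 0 & pooled_p < 1
  idx <- which(usable)
  if (!length(idx)) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c"))))
  }
  r <- 2
  n1 <- A$n[idx]; n2 <- B$n[idx]
  p1 <- A$p[idx]; p2 <- B$p[idx]
  h1 <- A$h[idx]; h2 <- B$h[idx]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  m <- cbind(a = a, b = b, c = c_)
  rownames(m) <- g$loci$locus[idx]
  m
}

#' Weir-Cockerham F_IS for one population with bootstrap interval
#'
#' Per-locus observed heterozygosity Ho and sample-corrected expected
#' heterozygosity (gene diversity) `Hs = n/(n-1) (1 - p^2 - q^2 - Ho/(2n))`,
#' combined across polymorphic loci as a ratio of averages:
#' `F_IS = 1 - mean(Ho) / mean(Hs)`. The interval is a bias-corrected
#' percentile bootstrap over loci.
#'
#' @param g a [genotype_matrix()].
#' @param pop population label.
#' @inheritParams wc_fst
#' @return One-row tibble: `population`, `n_loci`, `fis`, `ci_lo`, `ci_hi`.
#' @export
wc_fis <- function(g, pop, n_boot = 1000, conf = 0.95, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("F_IS requires called genotypes", call. = FALSE)
  d <- g$dosage[unname(g$populations) == pop, , drop = FALSE]
  if (!nrow(d)) stop("unknown population label ", pop, call. = FALSE)
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  ho <- ifelse(n > 0, colSums(d == 1, na.rm = TRUE) / n, NA_real_)
  usable <- n >= 2 & !is.na(p) & p > 0 & p < 1
  if (!any(usable)) stop("no polymorphic loci in population ", pop, call. = FALSE)
  n <- n[usable]; p <- p[usable]; ho <- ho[usable]
  hs <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
  comp <- cbind(ho = ho, hs = hs)
  fis_of <- function(idx) {
    s <- colSums(comp[idx, , drop = FALSE])
    1 - s[["ho"]] / s[["hs"]]
  }
  est <- fis_of(seq_len(nrow(comp)))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- bc_bootstrap_ci(comp, fis_of, n_boot = n_boot, conf = conf, seed = seed)
  }
  tibble::tibble(
    population = pop, n_loci = nrow(comp), fis = est, ci_lo = ci[1], ci_hi = ci[2]
  )
}

# Bias-corrected (BC, not BCa) percentile bootstrap over rows of `comp`.
bc_bootstrap_ci <- function(comp, stat_fn, n_boot, conf, seed) {
  est <- stat_fn(seq_len(nrow(comp)))
  boots <- withr::with_seed(seed, {
    vapply(
      seq_len(n_boot),
      function(i) stat_fn(sample.int(nrow(comp), replace = TRUE)),
      numeric(1)
    )
  })
  boots <- boots[is.finite(boots)]
  if (!length(boots)) return(c(NA_real_, NA_real_))
  z0 <- qnorm(pmin(pmax(mean(boots < est), 1 / (length(boots) + 1)),
    1 - 1 / (length(boots) + 1)
  ))
  alpha <- (1 - conf) / 2
  lo <- pnorm(2 * z0 + qnorm(alpha))
  hi <- pnorm(2 * z0 + qnorm(1 - alpha))
  unname(quantile(boots, c(lo, hi), names = FALSE, type = 6))
}
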