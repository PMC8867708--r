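# Shared fixture builders and independent oracles used across the suite.

# small genotype matrix from explicit per-population dosage rows
toy_genotypes <- function(pop_dosages, loci = NULL) {
  d <- do.call(rbind, unname(pop_dosages))
  pops <- rep(names(pop_dosages), vapply(pop_dosages, nrow, integer(1)))
  rownames(d) <- sprintf("%s_i%02d", pops, unlist(lapply(
    vapply(pop_dosages, nrow, integer(1)), seq_len
  )))
  genotype_matrix(d, populations = pops, loci = loci)
}

# independent, loop-based Weir & Cockerham (1984) two-population theta:
# per-locus variance components computed from first principles
oracle_wc_theta <- function(d1, d2) {
  r <- 2
  num <- 0
  den <- 0
  for (l in seq_len(ncol(d1))) {
    x1 <- d1[, l][!is.na(d1[, l])]
    x2 <- d2[, l][!is.na(d2[, l])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    pooled <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
    if (pooled <= 0 || pooled >= 1) next
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# all-pairs linear-scan nearest-gene oracle with BEDTools closest -d
# distances (0 when inside; gap + 1 otherwise) and all ties reported
oracle_nearest <- function(loci, genes) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    gl <- genes[genes$chrom == loci$chrom[i], ]
    if (!nrow(gl)) {
      out[[i]] <- data.frame(
        locus = loci$locus[i], gene = NA_character_,
        distance = NA_integer_, tie = FALSE
      )
      next
    }
    pos <- loci$pos[i]
    dists <- integer(nrow(gl))
    for (j in seq_len(nrow(gl))) {
      s1 <- gl$start[j] + 1
      e1 <- gl$end[j]
      dists[j] <- if (pos >= s1 && pos <= e1) 0L else max(s1 - pos, pos - e1)
    }
    best <- which(dists == min(dists))
    sign_v <- ifelse(dists[best] == 0, 1L, ifelse(gl$start[best] + 1 > pos, 1L, -1L))
    out[[i]] <- data.frame(
      locus = loci$locus[i], gene = gl$gene[best],
      distance = as.integer(dists[best] * sign_v), tie = length(best) > 1
    )
  }
  do.call(rbind, out)
}

# exact two-sided Fisher p for a 2x2 table by direct hypergeometric summation
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
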