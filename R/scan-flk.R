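#' Population kinship matrix from Reynolds distances
#'
#' Builds the drift-tree kinship used by the FLK test: pairwise Reynolds
#' coancestry distances (ratio-of-sums across loci), a neighbor-joining tree,
#' midpoint rooting, and the matrix of shared branch lengths from the root
#' (diagonal: root-to-tip length).
#'
#' @param freqs a [population_allele_freqs()] result with >= 3 populations.
#' @return A symmetric `n_pops x n_pops` kinship matrix.
#' @export
reynolds_kinship <- function(freqs) {
  stopifnot(inherits(freqs, "pop_freqs"))
  r <- length(freqs$pops)
  if (r < 3) stop("kinship tree needs at least 3 populations", call. = FALSE)
  D <- matrix(0, r, r, dimnames = list(freqs$pops, freqs$pops))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      p1 <- freqs$freq[i, ]
      p2 <- freqs$freq[j, ]
      ok <- !is.na(p1) & !is.na(p2)
      # ratio-of-sums coancestry distance scaled so that two independently
      # drifted populations (Var(p_i) = F_i pi q) have expected distance
      # F_i + F_j, making the rooted-tree branch-length shares the drift
      # variances the FLK quadratic form needs
      num <- 2 * (p1[ok] - p2[ok])^2
      den <- 1 - p1[ok] * p2[ok] - (1 - p1[ok]) * (1 - p2[ok])
      D[i, j] <- D[j, i] <- sum(num) / sum(den)
    }
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- phangorn::midpoint(tree)
  Fmat <- ape::vcv(tree)
  Fmat <- Fmat[freqs$pops, freqs$pops]
  Fmat
}

#' FLK differentiation-outlier scan
#'
#' Extension of the Lewontin-Krakauer test: per locus, the vector of
#' population allele frequencies `p` is compared with its kinship-weighted
#' estimate of the ancestral frequency
#' `p0 = (1' F^-1 p) / (1' F^-1 1)` through the quadratic form
#' `FLK = (p - p0 1)' (p0 (1 - p0) F)^-1 (p - p0 1)`, referred to a
#' chi-square with `n_pops - 1` degrees of freedom. Benjamini-Hochberg FDR
#' controls significance at `q < fdr_q`. Loci monomorphic across all
#' populations get statistic 0 and p-value 1.
#'
#' @param freqs a [population_allele_freqs()] result (frequencies defined in
#'   every population at tested loci).
#' @param fdr_q FDR threshold.
#' @param kinship optional precomputed kinship matrix (else
#'   [reynolds_kinship()] is used).
#' @return A `scan_result` tibble: `locus`, `statistic`, `p_value`, `q_value`,
#'   `significant`, `test`; kinship in `attr(, "kinship")`.
#' @export
flk_scan <- function(freqs, fdr_q = 0.05, kinship = NULL) {
  stopifnot(inherits(freqs, "pop_freqs"))
  r <- length(freqs$pops)
  if (r < 3) stop("FLK needs at least 3 populations", call. = FALSE)
  Fmat <- kinship %||% reynolds_kinship(freqs)
  Finv <- tryCatch(solve(Fmat), error = function(e) {
    stop("kinship matrix is singular; consider shrinking toward its diagonal",
      call. = FALSE
    )
  })
  one <- rep(1, r)
  w <- as.numeric(Finv %*% one)
  denom <- sum(w)
  L <- length(freqs$loci)
  stat <- numeric(L)
  defined <- colSums(is.na(freqs$freq)) == 0
  p_mat <- freqs$freq
  p0 <- as.numeric(crossprod(w, p_mat)) / denom
  for (l in which(defined)) {
    v <- p0[l] * (1 - p0[l])
    if (v <= 0) {
      stat[l] <- 0
      next
    }
    d <- p_mat[, l] - p0[l]
    stat[l] <- as.numeric(crossprod(d, Finv %*% d)) / v
  }
  stat[!defined] <- NA_real_
  p <- ifelse(is.na(stat), NA_real_,
    ifelse(stat == 0, 1, pchisq(stat, df = r - 1, lower.tail = FALSE))
  )
  q <- rep(NA_real_, L)
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  out <- tibble::tibble(
    locus = freqs$loci, statistic = stat, p_value = p, q_value = q,
    significant = !is.na(q) & q < fdr_q
  )
  res <- new_scan_result(out, "flk", sprintf("BH FDR q < %g, chi2_%d", fdr_q, r - 1))
  attr(res, "kinship") <- Fmat
  res
}
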