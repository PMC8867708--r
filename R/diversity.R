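#' Genetic diversity summaries
#'
#' Per-individual observed heterozygosity (share of called genotypes that are
#' heterozygous), per-locus per-population nucleotide diversity
#' `pi = 2 p q n/(n-1)` with `n` the number of called allele copies (the
#' unbiased sample correction, equal to the average pairwise difference among
#' allele copies), and the per-population invariant fraction (share of loci
#' with within-population frequency 0 or 1 among loci with calls).
#'
#' @param g a [genotype_matrix()] (not imputed).
#' @return A list of three tibbles: `ho` (`sample`, `population`, `n_called`,
#'   `ho`), `pi` (`locus`, `population`, `pi`), and `invariant`
#'   (`population`, `n_loci_called`, `invariant_fraction`).
#' @export
diversity_summaries <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("diversity summaries require called genotypes", call. = FALSE)
  d <- g$dosage
  ho <- tibble::tibble(
    sample = g$samples,
    population = unname(g$populations),
    n_called = unname(rowSums(!is.na(d))),
    ho = unname(rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d)))
  )
  fr <- population_allele_freqs(g)
  pi_tbl <- purrr::map_dfr(fr$pops, function(p) {
    n <- fr$n_alleles[p, ]
    pv <- fr$freq[p, ]
    pi <- ifelse(n >= 2, 2 * pv * (1 - pv) * n / (n - 1), NA_real_)
    tibble::tibble(locus = fr$loci, population = p, pi = pi)
  })
  inv <- purrr::map_dfr(fr$pops, function(p) {
    pv <- fr$freq[p, ]
    called <- !is.na(pv)
    tibble::tibble(
      population = p,
      n_loci_called = sum(called),
      invariant_fraction = mean(pv[called] %in% c(0, 1))
    )
  })
  list(ho = ho, pi = pi_tbl, invariant = inv)
}
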