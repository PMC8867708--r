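#' Population allele frequencies
#'
#' Alternate-allele frequency per population and locus, together with the
#' number of called allele copies (the denominator). Frequencies are `NA`
#' where a population has no called genotypes at a locus.
#'
#' @param g a [genotype_matrix()] (not imputed: frequencies are allele-count
#'   statistics and only consume integer dosages).
#' @return An object of class `pop_freqs`: list with `pops`, `loci`, and two
#'   pops-by-loci matrices `freq` and `n_alleles`.
#' @export
population_allele_freqs <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) {
    stop("allele frequencies must be computed from called genotypes, not imputed dosages",
      call. = FALSE
    )
  }
  pops <- unique(unname(g$populations))
  L <- ncol(g$dosage)
  freq <- matrix(NA_real_, length(pops), L, dimnames = list(pops, g$loci$locus))
  n_alleles <- matrix(0L, length(pops), L, dimnames = list(pops, g$loci$locus))
  for (p in pops) {
    sub <- g$dosage[g$populations == p, , drop = FALSE]
    called <- colSums(!is.na(sub))
    n_alleles[p, ] <- 2L * called
    s <- colSums(sub, na.rm = TRUE)
    freq[p, ] <- ifelse(called > 0, s / (2 * called), NA_real_)
  }
  structure(
    list(pops = pops, loci = g$loci$locus, freq = freq, n_alleles = n_alleles),
    class = "pop_freqs"
  )
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat(sprintf(
    "<pop_freqs> %d populations x %d loci\n", length(x$pops), length(x$loci)
  ))
  invisible(x)
}

#' Tidy population allele frequencies into long format
#' @param x a `pop_freqs` object.
#' @param ... unused.
#' @return Tibble with columns `population`, `locus`, `freq`, `n_alleles`.
#' @method tidy pop_freqs
#' @export
tidy.pop_freqs <- function(x, ...) {
  tibble::tibble(
    population = rep(x$pops, times = length(x$loci)),
    locus = rep(x$loci, each = length(x$pops)),
    freq = as.vector(x$freq),
    n_alleles = as.vector(x$n_alleles)
  )
}

#' Impute missing dosages by population mean
#'
#' Replaces each missing dosage with the population expected dosage
#' `2 * p_hat` for that locus, where `p_hat` is the within-population
#' alternate-allele frequency among called genotypes. Appropriate for
#' discrete, strongly differentiated populations; imputed values are
#' fractional and are consumed only by PCA-style operations.
#'
#' @param g a [genotype_matrix()].
#' @param global_fallback logical; when a locus has no calls at all inside a
#'   population, fall back to the across-population mean dosage. With
#'   `FALSE` (default) such loci raise an error.
#' @return A `genotype_matrix` with `imputed = TRUE` and no missing values.
#' @export
impute_by_population <- function(g, global_fallback = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!anyNA(g$dosage)) {
    out <- g
    out$imputed <- TRUE
    return(out)
  }
  d <- g$dosage
  pops <- unique(unname(g$populations))
  empty <- character()
  for (p in pops) {
    rows <- which(g$populations == p)
    sub <- d[rows, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE) # 2 * p_hat within population
    has_empty <- !is.finite(m)
    if (any(has_empty)) {
      if (!global_fallback) {
        empty <- union(empty, g$loci$locus[has_empty])
        next
      }
      m[has_empty] <- colMeans(d[, has_empty, drop = FALSE], na.rm = TRUE)
    }
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx)) {
      sub[na_idx] <- m[na_idx[, 2]]
      d[rows, ] <- sub
    }
  }
  if (length(empty)) {
    stop(
      "loci entirely missing within a population (enable global_fallback): ",
      paste(head(empty, 5), collapse = ", "),
      if (length(empty) > 5) " ..." else "",
      call. = FALSE
    )
  }
  if (anyNA(d)) stop("imputation failed to fill all entries", call. = FALSE)
  genotype_matrix(d, populations = g$populations, loci = g$loci, imputed = TRUE)
}

#' Convert pH to hydronium ion concentration
#'
#' pH is a negative log10 scale, so a unit difference in pH is a tenfold
#' difference in hydronium concentration; association tests on the linear
#' concentration scale `10^(-pH)` (mol/L) treat that nonlinearity explicitly.
#'
#' @param ph numeric vector of pH values.
#' @return Hydronium concentration in mol/L.
#' @export
#' @examples
#' ph_to_hydronium(7) # 1e-7
ph_to_hydronium <- function(ph) {
  stopifnot(is.numeric(ph), all(is.finite(ph)))
  10^(-ph)
}
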