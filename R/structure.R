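#' Principal component analysis of genotypes
#'
#' Column-centered (optionally unit-scaled) PCA of the dosage matrix via SVD.
#' Requires a complete matrix; impute first with [impute_by_population()].
#' Constant loci are dropped before scaling.
#'
#' @param g an imputed (or complete) [genotype_matrix()].
#' @param n_components number of components to return.
#' @param scale. logical; divide loci by their standard deviation.
#' @return An object of class `genotype_pca`: list with `scores` (tibble:
#'   `sample`, `population`, `PC1..PCk`), `var_explained` (fraction per
#'   component), `sdev`.
#' @export
genotype_pca <- function(g, n_components = 10, scale. = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) {
    stop("genotype matrix has missing values; impute first", call. = FALSE)
  }
  if (n_components >= nrow(g$dosage)) {
    stop("fewer samples than requested components", call. = FALSE)
  }
  d <- g$dosage
  keep <- apply(d, 2, function(x) var(x) > 0)
  d <- d[, keep, drop = FALSE]
  pc <- prcomp(d, center = TRUE, scale. = scale., rank. = n_components)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample = g$samples, population = unname(g$populations)),
    scores
  )
  structure(
    list(
      scores = scores,
      var_explained = var_frac[seq_len(min(n_components, length(var_frac)))],
      sdev = pc$sdev
    ),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf(
    "<genotype_pca> %d samples, %d components (PC1 %.1f%%)\n",
    nrow(x$scores), length(x$var_explained), 100 * x$var_explained[1]
  ))
  invisible(x)
}

#' Pearson correlations between PC scores and sample covariates
#'
#' Two-sided p-values come from the t transform of r. With few sites the
#' covariates take few distinct values and the p-values are descriptive only.
#'
#' @param pca a [genotype_pca()].
#' @param covariates data frame with a `sample` column and numeric covariate
#'   columns (e.g. latitude, longitude or site-level environmental values
#'   joined to samples).
#' @param components which PCs to test (default all in the object).
#' @return Tibble: `component`, `covariate`, `r`, `p_value`.
#' @export
pca_correlations <- function(pca, covariates, components = NULL) {
  stopifnot(inherits(pca, "genotype_pca"), "sample" %in% names(covariates))
  pcs <- grep("^PC", names(pca$scores), value = TRUE)
  if (!is.null(components)) pcs <- pcs[components]
  df <- dplyr::inner_join(pca$scores, tibble::as_tibble(covariates), by = "sample")
  covs <- setdiff(names(covariates), "sample")
  purrr::map_dfr(pcs, function(pc) {
    purrr::map_dfr(covs, function(cv) {
      ct <- cor.test(df[[pc]], df[[cv]])
      tibble::tibble(
        component = pc, covariate = cv,
        r = unname(ct$estimate), p_value = ct$p.value
      )
    })
  })
}

#' Choose the number of genetic clusters by K-means and BIC
#'
#' Runs K-means for `K = 1..k_max` on PC scores and scores each solution with
#' `BIC = n log(WSS/n) + K log(n)`; the best K minimizes BIC.
#'
#' @param scores numeric matrix or the `scores` tibble of a
#'   [genotype_pca()] (PC columns are used).
#' @param k_max largest K to evaluate.
#' @param nstart random restarts per K.
#' @param seed integer seed.
#' @return List of class `kmeans_bic`: `best_k`, `assignments` (integer
#'   vector for the best K), `bic` (tibble `k`, `bic`).
#' @export
kmeans_bic_clusters <- function(scores, k_max = 10, nstart = 10, seed = 1) {
  if (is.data.frame(scores)) {
    scores <- as.matrix(scores[, grep("^PC", names(scores)), drop = FALSE])
  }
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  n <- nrow(scores)
  if (k_max > n) stop("k_max exceeds the number of samples", call. = FALSE)
  n_distinct <- nrow(unique(scores))
  withr::with_seed(seed, {
    fits <- lapply(seq_len(k_max), function(k) {
      if (k > n_distinct) return(NULL)
      suppressWarnings(kmeans(scores, centers = k, nstart = nstart, iter.max = 50))
    })
  })
  bic <- vapply(fits, function(f) {
    if (is.null(f)) return(Inf)
    wss <- max(sum(f$withinss), .Machine$double.xmin)
    n * log(wss / n) + length(f$size) * log(n)
  }, numeric(1))
  best <- which.min(bic)
  structure(
    list(
      best_k = best,
      assignments = fits[[best]]$cluster,
      bic = tibble::tibble(k = seq_len(k_max), bic = bic)
    ),
    class = "kmeans_bic"
  )
}

#' @export
print.kmeans_bic <- function(x, ...) {
  cat(sprintf("<kmeans_bic> best K = %d\n", x$best_k))
  invisible(x)
}
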