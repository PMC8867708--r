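#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree coordinates (vectorized).
#' @return Distance in kilometres.
#' @export
#' @examples
#' great_circle_km(39.4861, -84.0277, 37.2468, -85.1561) # ~267 km
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(
    cbind(lon1, lat1), cbind(lon2, lat2),
    r = 6371000
  ) / 1000
}

#' Pairwise matrix container
#'
#' Symmetric matrix of pairwise values (distances or differentiation
#' estimates) with ordered labels and zero diagonal for distances.
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param what short description of the quantity.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m, what = "distance") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  structure(list(labels = rownames(m), values = m, what = what),
    class = "pairwise_matrix"
  )
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %s among %d labels\n", x$what, length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Tidy a pairwise matrix into long format
#' @param x a [pairwise_matrix()].
#' @param ... unused.
#' @return Tibble `label_a`, `label_b`, `value` over unordered pairs.
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    label_a = x$labels[idx[, 1]],
    label_b = x$labels[idx[, 2]],
    value = x$values[idx]
  )
}

#' Pairwise great-circle distances among sites
#'
#' @param env an [env_table()].
#' @return A [pairwise_matrix()] in kilometres.
#' @export
geo_distance <- function(env) {
  env <- env_table(env)
  n <- nrow(env)
  m <- matrix(0, n, n, dimnames = list(env$site, env$site))
  for (i in seq_len(n)) {
    m[i, ] <- great_circle_km(
      env$latitude[i], env$longitude[i], env$latitude, env$longitude
    )
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  pairwise_matrix(m, "great-circle distance (km)")
}

#' Environmental distance among sites
#'
#' Centers and scales the selected variables, rotates them by PCA (all
#' components) and takes pairwise Euclidean distances on the full PC scores;
#' by orthogonal invariance this equals the distance on the scaled variables.
#'
#' @param env an [env_table()].
#' @param variables variable columns to use (default all).
#' @return A [pairwise_matrix()].
#' @export
env_distance <- function(env, variables = NULL) {
  env <- env_table(env)
  variables <- variables %||% env_variables(env)
  stopifnot(length(variables) >= 2)
  x <- as.matrix(env[, variables, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance variable(s): ",
      paste(variables[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  xs <- scale(x)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  m <- as.matrix(dist(pc$x))
  dimnames(m) <- list(env$site, env$site)
  pairwise_matrix(m, "environmental distance (scaled PC space)")
}

#' Prune correlated environmental variables
#'
#' Two-stage greedy pruning: within each logical group (e.g.
#' temperature-related, precipitation-related), a variable is dropped when
#' its absolute Pearson correlation with an already-retained variable of that
#' group exceeds `r_max`; the survivors are then pooled and pruned again by
#' the same rule. Variables listed in `force_keep` are never dropped and are
#' re-appended if pruned (the study retained annual precipitation this way).
#'
#' @param env an [env_table()].
#' @param groups named list of character vectors partitioning the variables.
#' @param r_max correlation threshold; a variable is retained only while
#'   `|r| <= r_max` with every previously retained variable.
#' @param force_keep variables that are always retained.
#' @return Character vector of retained variable names (in input order).
#' @export
prune_env_variables <- function(env, groups = NULL, r_max = 0.90,
                                force_keep = character()) {
  env <- env_table(env)
  vars <- env_variables(env)
  groups <- groups %||% list(all = vars)
  stopifnot(setequal(unlist(groups), vars))
  greedy <- function(vs) {
    kept <- character()
    for (v in vs) {
      ok <- TRUE
      for (k in kept) {
        if (abs(cor(env[[v]], env[[k]])) > r_max) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, v)
    }
    kept
  }
  pooled <- unlist(lapply(groups, greedy), use.names = FALSE)
  final <- greedy(pooled)
  final <- union(final, intersect(force_keep, vars))
  vars[vars %in% final]
}

#' Correlations among pairwise matrices
#'
#' Pearson correlation over the off-diagonal (unordered-pair) entries of each
#' pair of matrices, after aligning labels. F_ST matrices can be linearized
#' as `F_ST / (1 - F_ST)` first.
#'
#' @param matrices named list of [pairwise_matrix()] objects with identical
#'   label sets.
#' @return Tibble `matrix_a`, `matrix_b`, `r`, `n_pairs`.
#' @export
matrix_correlations <- function(matrices) {
  stopifnot(length(matrices) >= 2, !is.null(names(matrices)))
  labs <- matrices[[1]]$labels
  vecs <- lapply(matrices, function(m) {
    if (!setequal(m$labels, labs)) stop("label mismatch between matrices", call. = FALSE)
    v <- m$values[labs, labs]
    v[upper.tri(v)]
  })
  pairs <- utils::combn(names(matrices), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(
      matrix_a = a, matrix_b = b,
      r = cor(vecs[[a]], vecs[[b]]),
      n_pairs = length(vecs[[a]])
    )
  })
}

#' Linearize an F_ST matrix
#'
#' @param m a [pairwise_matrix()] of F_ST estimates.
#' @return A [pairwise_matrix()] of `F_ST / (1 - F_ST)`.
#' @export
linearize_fst <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  v <- m$values / (1 - m$values)
  diag(v) <- 0
  pairwise_matrix(v, "linearized F_ST")
}

#' Build a pairwise F_ST matrix from pairwise estimates
#'
#' @param fst_tbl output of [pairwise_wc_fst()].
#' @param clamp use the zero-clamped estimates.
#' @return A [pairwise_matrix()].
#' @export
fst_matrix <- function(fst_tbl, clamp = FALSE) {
  labs <- unique(c(fst_tbl$pop_a, fst_tbl$pop_b))
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  val <- if (clamp) fst_tbl$theta_clamped else fst_tbl$theta
  for (i in seq_len(nrow(fst_tbl))) {
    m[fst_tbl$pop_a[i], fst_tbl$pop_b[i]] <- val[i]
    m[fst_tbl$pop_b[i], fst_tbl$pop_a[i]] <- val[i]
  }
  pairwise_matrix(m, "Weir-Cockerham F_ST")
}
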