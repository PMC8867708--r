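#' Collect per-test significant-locus sets
#'
#' @param scans named list of `scan_result` objects (names become test ids).
#' @param universe character vector of all locus ids in the dataset.
#' @param gea_tests names of the scans that are genetic-environment
#'   association tests (their sets are additionally split by variable).
#' @return An object of class `significance_sets`: list with `universe`,
#'   `sets` (named list of locus-id vectors, one per test), and `gea_sets`
#'   (nested: test -> variable -> locus ids).
#' @export
significance_sets <- function(scans, universe, gea_tests = character()) {
  stopifnot(is.list(scans), !is.null(names(scans)))
  sets <- lapply(scans, significant_loci)
  bad <- names(sets)[vapply(sets, function(s) !all(s %in% universe), logical(1))]
  if (length(bad)) {
    stop("significant loci outside the universe in: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  gea_sets <- lapply(scans[intersect(gea_tests, names(scans))], function(scan) {
    df <- tibble::as_tibble(scan)
    stopifnot("variable" %in% names(df))
    split(
      df$locus[df$significant %in% TRUE],
      df$variable[df$significant %in% TRUE]
    )
  })
  structure(
    list(universe = universe, sets = sets, gea_sets = gea_sets,
         gea_tests = intersect(gea_tests, names(scans))),
    class = "significance_sets"
  )
}

#' @export
print.significance_sets <- function(x, ...) {
  cat(sprintf(
    "<significance_sets> universe %d loci; %s\n",
    length(x$universe),
    paste(sprintf("%s: %d", names(x$sets), lengths(x$sets)), collapse = ", ")
  ))
  invisible(x)
}

#' Permutation test for overlap among significance sets
#'
#' Observed statistics: the proportion of the union of significant loci that
#' was identified by at least two tests, and for each pair of tests the
#' Jaccard shared proportion `|A n B| / |A u B|`. The null redraws each
#' test's set uniformly without replacement (same size) from the universe;
#' one-sided empirical p-values are
#' `(1 + #(null >= observed)) / (reps + 1)`.
#'
#' @param sets a [significance_sets()].
#' @param reps permutation replicates.
#' @param seed integer seed.
#' @return List of class `overlap_permutation`: `ge2` (tibble: observed
#'   proportion, null mean, p) and `pairwise` (tibble per test pair:
#'   observed shared proportion, null mean, p).
#' @export
overlap_permutation <- function(sets, reps = 10000, seed = 1) {
  stopifnot(inherits(sets, "significance_sets"), reps >= 1)
  L <- length(sets$universe)
  sizes <- lengths(sets$sets)
  tests <- names(sets$sets)
  idx_sets <- lapply(sets$sets, function(s) match(s, sets$universe))

  ge2_stat <- function(idx_list) {
    tab <- table(unlist(idx_list))
    if (!length(tab)) return(0)
    sum(tab >= 2) / length(tab)
  }
  jacc <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  obs_ge2 <- ge2_stat(idx_sets)
  pairs <- if (length(tests) >= 2) utils::combn(tests, 2) else matrix(character(0), 2, 0)
  obs_pair <- apply(pairs, 2, function(tp) jacc(idx_sets[[tp[1]]], idx_sets[[tp[2]]]))
  obs_shared <- apply(pairs, 2, function(tp) {
    length(intersect(idx_sets[[tp[1]]], idx_sets[[tp[2]]]))
  })

  null_ge2 <- numeric(reps)
  null_pair <- matrix(0, reps, ncol(pairs))
  null_shared <- matrix(0, reps, ncol(pairs))
  withr::with_seed(seed, {
    for (i in seq_len(reps)) {
      perm <- lapply(sizes, function(s) sample.int(L, s))
      null_ge2[i] <- ge2_stat(perm)
      if (ncol(pairs)) {
        null_pair[i, ] <- apply(pairs, 2, function(tp) jacc(perm[[tp[1]]], perm[[tp[2]]]))
        null_shared[i, ] <- apply(pairs, 2, function(tp) {
          length(intersect(perm[[tp[1]]], perm[[tp[2]]]))
        })
      }
    }
  })
  p_of <- function(obs, null) (1 + sum(null >= obs)) / (length(null) + 1)
  structure(
    list(
      ge2 = tibble::tibble(
        observed = obs_ge2, null_mean = mean(null_ge2),
        p_value = p_of(obs_ge2, null_ge2), reps = reps
      ),
      pairwise = tibble::tibble(
        test_a = pairs[1, ], test_b = pairs[2, ],
        observed = as.numeric(obs_pair),
        null_mean = colMeans(null_pair),
        n_shared = as.integer(obs_shared),
        null_mean_shared = colMeans(null_shared),
        p_value = vapply(seq_len(ncol(pairs)), function(j) {
          p_of(obs_pair[j], null_pair[, j])
        }, numeric(1)),
        reps = reps
      )
    ),
    class = "overlap_permutation"
  )
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf(
    "<overlap_permutation> >=2-test proportion %.3f (null %.3f, p = %.4g)\n",
    x$ge2$observed, x$ge2$null_mean, x$ge2$p_value
  ))
  invisible(x)
}

#' Per-variable consensus locus sets for polygenic scoring
#'
#' For each environmental variable: loci significant in at least one GEA test
#' for that variable AND in at least one other test (another GEA test or any
#' outlier test). Restricting to multi-test support reduces the influence of
#' false positives.
#'
#' @param sets a [significance_sets()] built with `gea_tests` named.
#' @return Named list (one element per variable) of locus-id vectors.
#' @export
gea_consensus_sets <- function(sets) {
  stopifnot(inherits(sets, "significance_sets"))
  if (!length(sets$gea_sets)) stop("no GEA tests in the significance sets", call. = FALSE)
  variables <- unique(unlist(lapply(sets$gea_sets, names)))
  out <- lapply(variables, function(v) {
    gea_hits <- unique(unlist(lapply(sets$gea_sets, function(s) s[[v]])))
    consensus <- vapply(gea_hits, function(loc) {
      n_tests <- sum(vapply(sets$sets, function(s) loc %in% s, logical(1)))
      n_tests >= 2
    }, logical(1))
    sort(gea_hits[consensus])
  })
  stats::setNames(out, variables)
}
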