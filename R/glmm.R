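#' Binomial-logit GLMM of percent polygenic scores
#'
#' Models each individual's raw score as binomial successes out of
#' `2 * n_nonmissing` trials (a proper likelihood realization of the percent
#' score) with a site-level fixed predictor and a random site intercept:
#' `logit(p) = b0 + b1 x_site + u_site`, `u ~ Normal(0, sigma2)`. Estimation
#' is penalized-likelihood (Laplace) via \pkg{lme4}; the predictor is
#' standardized internally and the coefficient reported on the original
#' scale with a Wald 95% interval. With five or fewer sites the site-level
#' effects are weakly identified and a warning is issued.
#'
#' @param scores a [additive_scores()] tibble.
#' @param env an [env_table()] supplying the predictor, or a named numeric
#'   vector of site values.
#' @param predictor variable name in `env` (ignored when `env` is a vector).
#' @return An object of class `glmm_fit`: list with `beta`, `ci_lo`, `ci_hi`
#'   (original scale), `beta_std` (per SD of predictor), `sigma2_site`,
#'   `predictor`, `n_sites`, `backend`, and the underlying `fit`.
#' @export
fit_score_glmm <- function(scores, env, predictor = NULL) {
  stopifnot(is.data.frame(scores), all(c("raw", "n_nonmissing", "site") %in% names(scores)))
  if (is.numeric(env)) {
    x_site <- env
    predictor <- predictor %||% "predictor"
  } else {
    env <- env_table(env)
    predictor <- predictor %||% scores$variable[1]
    x_site <- stats::setNames(env[[predictor]], env$site)
    if (is.null(env[[predictor]])) stop("unknown predictor: ", predictor, call. = FALSE)
  }
  sites <- unique(scores$site)
  if (length(sites) < 2) stop("at least 2 sites required", call. = FALSE)
  if (length(sites) <= 5) {
    warning("site-level fixed effect and random intercept are weakly identified with <= 5 sites")
  }
  x <- x_site[scores$site]
  if (anyNA(x)) stop("sites missing from the predictor values", call. = FALSE)
  x_sd <- sd(x_site[sites])
  if (x_sd == 0) stop("predictor is constant across sites", call. = FALSE)
  df <- data.frame(
    succ = scores$raw,
    fail = 2 * scores$n_nonmissing - scores$raw,
    x_std = (x - mean(x_site[sites])) / x_sd,
    site = scores$site
  )
  if (sd(df$succ / (df$succ + df$fail)) == 0) {
    # degenerate case: identical percent scores carry no information about
    # the slope or the site variance; fall back to a fixed-effects fit
    fit <- stats::glm(cbind(succ, fail) ~ x_std, data = df, family = stats::binomial("logit"))
    est <- coef(fit)[["x_std"]]
    se <- sqrt(diag(vcov(fit))[2])
    sigma2 <- 0
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(cbind(succ, fail) ~ x_std + (1 | site),
        data = df, family = stats::binomial("logit")
      )
    ))
    est <- lme4::fixef(fit)[["x_std"]]
    se <- sqrt(diag(as.matrix(vcov(fit)))[2])
    sigma2 <- as.numeric(lme4::VarCorr(fit)$site[1])
  }
  # a site-level predictor carries roughly n_sites - 2 degrees of freedom;
  # a normal critical value would understate the interval at few sites
  crit <- stats::qt(0.975, df = max(length(sites) - 2, 1))
  structure(
    list(
      beta = est / x_sd,
      ci_lo = (est - crit * se) / x_sd,
      ci_hi = (est + crit * se) / x_sd,
      beta_std = est,
      se_std = se,
      sigma2_site = sigma2,
      predictor = predictor,
      n_sites = length(sites),
      backend = "lme4 Laplace (Wald-t 95% interval)",
      fit = fit
    ),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "<glmm_fit> %s: beta = %.4g [%.4g, %.4g], site variance %.4g (%d sites)\n",
    x$predictor, x$beta, x$ci_lo, x$ci_hi, x$sigma2_site, x$n_sites
  ))
  invisible(x)
}

#' Tidy a fitted score GLMM
#' @param x a `glmm_fit`.
#' @param ... unused.
#' @return One-row tibble of the fixed-effect estimate on the original scale.
#' @method tidy glmm_fit
#' @export
tidy.glmm_fit <- function(x, ...) {
  tibble::tibble(
    term = x$predictor, estimate = x$beta,
    conf.low = x$ci_lo, conf.high = x$ci_hi,
    estimate_std = x$beta_std, std.error_std = x$se_std
  )
}

#' Model-level summary of a fitted score GLMM
#' @param x a `glmm_fit`.
#' @param ... unused.
#' @return One-row tibble: site variance, number of sites, backend.
#' @method glance glmm_fit
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_site = x$sigma2_site, n_sites = x$n_sites, backend = x$backend
  )
}

#' Random-subset null distribution for a polygenic-score GLMM
#'
#' Draws `reps` random locus subsets of the same size as the observed
#' candidate set from the full dataset, orients each subset against the same
#' environmental variable, scores individuals, fits the same binomial-logit
#' GLMM, and records the fixed-effect coefficient. The one-sided empirical
#' p-value for the observed coefficient is
#' `(1 + #(null beta >= observed)) / (reps + 1)`, matching the directional
#' claim that the observed association is greater than expected from random
#' SNP sets. Replicates whose GLMM fails are logged and excluded; more than
#' 10% failures is an error.
#'
#' @param g a [genotype_matrix()].
#' @param freqs the matching [population_allele_freqs()].
#' @param env an [env_table()].
#' @param variable environmental variable (or latitude/longitude).
#' @param n_loci size of each random subset (the observed candidate-set
#'   size).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param observed_beta optional observed coefficient (original scale) for
#'   which the empirical p is computed.
#' @return List of class `subset_null`: `null_beta` (numeric vector),
#'   `n_failed`, `observed_beta`, `p_value` (NULL without `observed_beta`).
#' @export
random_subset_null <- function(g, freqs, env, variable, n_loci, reps = 1000,
                               seed = 1, observed_beta = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), n_loci >= 1)
  L <- ncol(g$dosage)
  if (n_loci > L) stop("n_loci exceeds the number of loci", call. = FALSE)
  betas <- rep(NA_real_, reps)
  withr::with_seed(seed, {
    for (i in seq_len(reps)) {
      loci <- g$loci$locus[sample.int(L, n_loci)]
      betas[i] <- tryCatch(
        {
          ori <- suppressMessages(orient_alleles(freqs, env, variable, loci))
          sc <- suppressMessages(additive_scores(g, ori))
          suppressWarnings(fit_score_glmm(sc, env, variable))$beta
        },
        error = function(e) NA_real_
      )
    }
  })
  n_failed <- sum(is.na(betas))
  if (n_failed > 0.1 * reps) {
    stop(n_failed, " of ", reps, " null replicates failed", call. = FALSE)
  }
  if (n_failed > 0) message(n_failed, " null replicate(s) failed and were excluded")
  null_beta <- betas[!is.na(betas)]
  p <- NULL
  if (!is.null(observed_beta)) {
    p <- (1 + sum(null_beta >= observed_beta)) / (length(null_beta) + 1)
  }
  structure(
    list(
      null_beta = null_beta, n_failed = n_failed,
      observed_beta = observed_beta, p_value = p, variable = variable
    ),
    class = "subset_null"
  )
}

#' @export
print.subset_null <- function(x, ...) {
  cat(sprintf(
    "<subset_null> %d null betas for %s%s\n",
    length(x$null_beta), x$variable,
    if (!is.null(x$p_value)) sprintf("; observed %.4g, p = %.4g", x$observed_beta, x$p_value) else ""
  ))
  invisible(x)
}

#' Null-distribution plot for a random-subset test
#' @param object a [random_subset_null()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot subset_null
#' @export
autoplot.subset_null <- function(object, ...) {
  df <- tibble::tibble(beta = object$null_beta)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = "null beta (random SNP subsets)", y = "count",
      title = paste("Random-subset null:", object$variable)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed_beta)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_beta, colour = "firebrick")
  }
  p
}
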