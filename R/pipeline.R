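#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Every
#' stochastic stage must have an explicit seed; validation happens before
#' any computation. Defaults follow the study-style thresholds: Bonferroni
#' 0.01/L for the PCA-regression and latent-factor scans, BH q < 0.05 for
#' FLK, the top 0.01% POD quantile for XtX, BF top 5% jointly with |rho| top
#' 1% for the frequency-level association scan, 10,000 overlap permutations
#' and 1000 random-subset replicates.
#'
#' @param input named list of paths: `vcf`, `popmap`, `env`, optionally
#'   `genes` (BED) and `term_map` (TSV).
#' @param out_dir output directory.
#' @param filter a [filter_schedule()] or the data frame to build one.
#' @param n_clusters number of genetic clusters; `NULL` selects by
#'   K-means/BIC.
#' @param scan named list overriding scan settings: `pcadapt_K`, `lfmm_K`,
#'   `alpha`, `fdr_q`, `pod_q`, `pod_size`, `bf_quantile`, `rho_quantile`.
#' @param gea_variables variables to test (default: all in the env table).
#' @param overlap_reps,subset_reps permutation and random-subset replicates
#'   (`subset_reps = 0` skips the subset null).
#' @param n_boot bootstrap replicates for F-statistics.
#' @param seeds named list of integer seeds: `pod`, `overlap`, `subset`,
#'   `boot`, `kmeans`.
#' @param simulate optional [sim_config()] used by [make_fixture()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(), out_dir = "adaptscan-out",
                            filter = NULL, n_clusters = NULL,
                            scan = list(), gea_variables = NULL,
                            overlap_reps = 10000, subset_reps = 1000,
                            n_boot = 1000,
                            seeds = list(), simulate = NULL) {
  scan_defaults <- list(
    pcadapt_K = NULL, lfmm_K = NULL, alpha = 0.01, fdr_q = 0.05,
    pod_q = 1e-4, pod_size = 1e5, bf_quantile = 0.95, rho_quantile = 0.99
  )
  scan <- utils::modifyList(scan_defaults, scan)
  seed_names <- c("pod", "overlap", "subset", "boot", "kmeans")
  missing_seeds <- setdiff(seed_names, names(seeds))
  if (length(missing_seeds)) {
    stop("missing seed(s) for stochastic stage(s): ",
      paste(missing_seeds, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(overlap_reps >= 1, subset_reps >= 0, n_boot >= 0)
  cfg <- list(
    input = input, out_dir = out_dir,
    filter = filter_schedule(filter), n_clusters = n_clusters,
    scan = scan, gea_variables = gea_variables,
    overlap_reps = overlap_reps, subset_reps = subset_reps, n_boot = n_boot,
    seeds = seeds, simulate = simulate
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filter)) y$filter <- tibble::as_tibble(as.data.frame(y$filter))
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

#' Write a simulated fixture directory from a pipeline configuration
#'
#' @param config a [pipeline_config()] whose `simulate` element is a
#'   [sim_config()].
#' @param dir output directory (default: `fixture/` under the configured
#'   output directory).
#' @return Named vector of written paths (see [write_fixture()]).
#' @export
make_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$simulate)) stop("config has no simulate block", call. = FALSE)
  dir <- dir %||% file.path(config$out_dir, "fixture")
  sim <- simulate_dataset(config$simulate)
  write_fixture(sim, dir)
}

#' Run the full landscape-genomics pipeline
#'
#' Orchestrates filter -> stats -> scans -> consensus -> polygenic scores ->
#' annotation from one configuration, writing every stage's outputs as TSV
#' under `out_dir` plus a JSON manifest recording versions, seeds,
#' thresholds and per-stage counts. Reruns with the same configuration
#' reproduce all outputs (stochastic stages are seeded). A stage failure
#' aborts with the stage name after writing the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @param until optional stage name (`"filter"`, `"stats"`, `"scans"`,
#'   `"consensus"`, `"polyscore"`, `"annotate"`): stop after that stage.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, until = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages_all <- c("filter", "stats", "scans", "consensus", "polyscore", "annotate")
  if (!is.null(until)) until <- match.arg(until, stages_all)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    invisible(c(results, list(manifest = manifest)))
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("adaptscan")),
    seeds = config$seeds, stages = list()
  )
  results <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "completed"), res$meta)
    results[[name]] <<- res$value
    invisible(NULL)
  }

  run_stage("filter", function() {
    g0 <- read_vcf(config$input$vcf, config$input$popmap)
    g <- iterative_filter(g0, config$filter)
    write_filter_report(g, file.path(out, "filter_report.tsv"))
    list(
      value = g,
      meta = list(
        n_loci_in = ncol(g0$dosage), n_samples_in = nrow(g0$dosage),
        n_loci = ncol(g$dosage), n_samples = nrow(g$dosage)
      )
    )
  })
  if (identical(until, "filter")) return(finish())
  g <- results$filter
  env <- env_table(config$input$env)

  run_stage("stats", function() {
    freqs <- population_allele_freqs(g)
    div <- diversity_summaries(g)
    fst <- pairwise_wc_fst(g, n_boot = config$n_boot, seed = config$seeds$boot)
    gi <- impute_by_population(g, global_fallback = TRUE)
    # cluster on a deep PC basis: with few retained PCs the BIC's log(n)
    # penalty cannot offset the WSS gain of splitting noise dimensions
    pca <- genotype_pca(gi, n_components = min(40, nrow(g$dosage) - 1))
    km <- kmeans_bic_clusters(pca$scores,
      k_max = min(10, nrow(g$dosage)),
      seed = config$seeds$kmeans
    )
    readr::write_tsv(fst, file.path(out, "pairwise_fst.tsv"))
    readr::write_tsv(div$ho, file.path(out, "observed_heterozygosity.tsv"))
    readr::write_tsv(div$invariant, file.path(out, "invariant_fractions.tsv"))
    readr::write_tsv(pca$scores, file.path(out, "pca_scores.tsv"))
    list(
      value = list(freqs = freqs, fst = fst, div = div, pca = pca, km = km,
                   g_imputed = gi),
      meta = list(best_k = km$best_k, mean_fst = mean(fst$theta))
    )
  })
  if (identical(until, "stats")) return(finish())
  st <- results$stats
  k_clusters <- config$n_clusters %||% st$km$best_k

  run_stage("scans", function() {
    scn <- config$scan
    K_pc <- scn$pcadapt_K %||% max(1, k_clusters - 1)
    K_lf <- scn$lfmm_K %||% k_clusters
    vars <- config$gea_variables %||% env_variables(env)
    pc_scan <- pcadapt_scan(st$g_imputed, K = K_pc, alpha = scn$alpha)
    flk <- flk_scan(st$freqs, fdr_q = scn$fdr_q)
    cov <- estimate_pop_covariance(st$freqs)
    thr <- pod_calibrate(cov, st$freqs$n_alleles,
      L_pod = scn$pod_size, q = scn$pod_q, seed = config$seeds$pod
    )
    xtx <- xtx_scan(st$freqs, cov, pod_threshold = as.numeric(thr))
    lfmm <- lfmm_scan(st$g_imputed, env, K = K_lf, variables = vars,
      alpha = scn$alpha)
    bf <- env_assoc_scan(st$freqs, cov, env, variables = vars,
      bf_quantile = scn$bf_quantile, rho_quantile = scn$rho_quantile
    )
    scans <- list(pcadapt = pc_scan, flk = flk, xtx = xtx, lfmm = lfmm, bf = bf)
    for (nm in names(scans)) {
      write_scan_result(scans[[nm]], file.path(out, paste0("scan_", nm, ".tsv")))
    }
    list(
      value = c(scans, list(cov = cov, pod_threshold = as.numeric(thr))),
      meta = c(
        list(pod_threshold = as.numeric(thr), pcadapt_K = K_pc, lfmm_K = K_lf),
        lapply(scans, function(s) length(significant_loci(s)))
      )
    )
  })
  if (identical(until, "scans")) return(finish())
  sc <- results$scans

  run_stage("consensus", function() {
    sets <- significance_sets(
      sc[c("pcadapt", "flk", "xtx", "lfmm", "bf")],
      universe = g$loci$locus, gea_tests = c("lfmm", "bf")
    )
    ov <- overlap_permutation(sets, reps = config$overlap_reps,
      seed = config$seeds$overlap)
    cons <- gea_consensus_sets(sets)
    readr::write_tsv(ov$pairwise, file.path(out, "overlap_pairwise.tsv"))
    readr::write_tsv(
      tibble::tibble(
        variable = rep(names(cons), lengths(cons)),
        locus = unlist(cons, use.names = FALSE)
      ),
      file.path(out, "consensus_sets.tsv")
    )
    list(
      value = list(sets = sets, overlap = ov, consensus = cons),
      meta = list(
        n_union = length(unique(unlist(sets$sets))),
        ge2_proportion = ov$ge2$observed, ge2_p = ov$ge2$p_value
      )
    )
  })
  if (identical(until, "consensus")) return(finish())
  cons <- results$consensus$consensus

  run_stage("polyscore", function() {
    scored <- list()
    fits <- list()
    nulls <- list()
    for (v in names(cons)) {
      loci <- cons[[v]]
      if (length(loci) < 2) next
      ori <- tryCatch(
        suppressMessages(orient_alleles(st$freqs, env, v, loci)),
        error = function(e) NULL
      )
      if (is.null(ori)) next
      scores <- suppressMessages(additive_scores(g, ori))
      scored[[v]] <- scores
      fit <- tryCatch(
        suppressWarnings(fit_score_glmm(scores, env, v)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      fits[[v]] <- fit
      if (config$subset_reps > 0) {
        nulls[[v]] <- random_subset_null(
          g, st$freqs, env, v,
          n_loci = length(loci),
          reps = config$subset_reps, seed = config$seeds$subset,
          observed_beta = fit$beta
        )
        readr::write_tsv(
          tibble::tibble(replicate = seq_along(nulls[[v]]$null_beta),
            beta = nulls[[v]]$null_beta),
          file.path(out, paste0("null_beta_", v, ".tsv"))
        )
      }
    }
    if (length(scored)) {
      readr::write_tsv(dplyr::bind_rows(scored), file.path(out, "polygenic_scores.tsv"))
    }
    if (length(fits)) {
      readr::write_tsv(
        dplyr::bind_rows(lapply(fits, tidy)),
        file.path(out, "glmm_fits.tsv")
      )
    }
    list(
      value = list(scores = scored, fits = fits, nulls = nulls),
      meta = list(
        variables_scored = names(scored),
        beta = lapply(fits, function(f) f$beta),
        subset_p = lapply(nulls, function(x) x$p_value)
      )
    )
  })

  if (identical(until, "polyscore")) return(finish())

  run_stage("annotate", function() {
    if (is.null(config$input$genes)) {
      return(list(value = NULL, meta = list(skipped = "no gene models supplied")))
    }
    genes <- read_gene_bed(config$input$genes)
    union_loci <- unique(unlist(results$consensus$sets$sets))
    all_hits <- nearest_gene(g$loci, genes)
    sig_hits <- all_hits[all_hits$locus %in% union_loci, ]
    readr::write_tsv(sig_hits, file.path(out, "nearest_genes_significant.tsv"))
    enr <- NULL
    if (!is.null(config$input$term_map) && nrow(sig_hits)) {
      cand <- unique(na.omit(sig_hits$gene))
      ref <- unique(na.omit(all_hits$gene))
      if (length(cand)) {
        enr <- fisher_enrichment(cand, ref, config$input$term_map)
        readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
      }
    }
    list(
      value = list(hits = sig_hits, enrichment = enr),
      meta = list(
        n_annotated = sum(!is.na(sig_hits$gene)),
        n_unannotated = sum(is.na(sig_hits$gene))
      )
    )
  })

  finish()
}
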