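#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end discovery pipeline with the
#' analysis defaults: correlation-intersection FDR 0.001, gene-set FDR 0.01,
#' knockout DE filter FDR 0.1 with |logFC| > 1, peak FDR 0.05, and a 2 kb
#' regulatory window.
#'
#' @param driver driver gene identifier.
#' @param fdr_correlation per-cohort FDR threshold for the intersection.
#' @param fdr_geneset FDR threshold for selecting enriched gene sets.
#' @param de_fdr_max,de_min_abs_logfc knockout DE filter thresholds (strict).
#' @param peak_fdr_max peak FDR threshold (strict).
#' @param pad regulatory-window half-width in bp.
#' @param anchor window anchor, `"cds"` or `"tss"`.
#' @param weight GSEA metric weight exponent.
#' @param n_perm GSEA permutations.
#' @param metagene_mode `"zmean"` or `"rawmean"`.
#' @param human_list which human list feeds the cross-species intersection:
#'   the full `"positive"` intersection list (default) or the leading-edge
#'   `"core"`.
#' @param seed global seed; each stage derives its own substream.
#' @param sim a [sim_config()] used when the pipeline simulates its inputs.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(driver = "DRIVER", fdr_correlation = 0.001,
                            fdr_geneset = 0.01, de_fdr_max = 0.1,
                            de_min_abs_logfc = 1.0, peak_fdr_max = 0.05,
                            pad = 2000, anchor = c("cds", "tss"), weight = 1,
                            n_perm = 1000, metagene_mode = c("zmean", "rawmean"),
                            human_list = c("positive", "core"), seed = 1L,
                            sim = NULL) {
  anchor <- match.arg(anchor)
  metagene_mode <- match.arg(metagene_mode)
  human_list <- match.arg(human_list)
  for (th in c(fdr_correlation, fdr_geneset, de_fdr_max, peak_fdr_max)) {
    assert_scalar_number(th, "threshold", 1e-12, 1 - 1e-12)
  }
  assert_scalar_number(pad, "pad", 0)
  assert_scalar_number(weight, "weight", 0)
  assert_scalar_number(n_perm, "n_perm", 100)
  assert_scalar_number(seed, "seed")
  structure(
    list(
      driver = driver, fdr_correlation = fdr_correlation,
      fdr_geneset = fdr_geneset, de_fdr_max = de_fdr_max,
      de_min_abs_logfc = de_min_abs_logfc, peak_fdr_max = peak_fdr_max,
      pad = pad, anchor = anchor, weight = weight, n_perm = as.integer(n_perm),
      metagene_mode = metagene_mode, human_list = human_list,
      seed = as.integer(seed),
      sim = sim %||% sim_config(seed = as.integer(seed))
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; an optional `sim` block
#' holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(cfg$sim)) sim <- do.call(sim_config, cfg$sim)
  cfg$sim <- NULL
  do.call(pipeline_config, c(cfg, list(sim = sim)))
}

#' Run the full discovery pipeline
#'
#' Executes, in order: input simulation ([simulate_bundle()]), the per-cohort
#' correlation screen and cross-cohort intersection with the
#' sign-proportion test, pre-ranked enrichment over the gene-set collection
#' with leading-edge intersection into a core list, metagene scoring with
#' Kaplan-Meier / log-rank / Cox evaluation per cohort, the knockout DE
#' filter and cross-species target nomination, and peak-to-gene binding
#' annotation of the core list. Every intermediate table is written under
#' `out_dir` (when given) and all summary statistics land in a JSON run
#' manifest. Re-running with the same configuration reproduces identical
#' results; a failing stage aborts with the stage name and leaves the
#' partial manifest as `run_manifest.partial.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts and the manifest.
#' @param bundle optional pre-built [simulate_bundle()] output (skips the
#'   simulation stage; must match `config$sim` if determinism across calls
#'   matters).
#' @return the run manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    parameters = config[setdiff(names(config), "sim")],
    sim = unclass(config$sim)
  )
  save_tsv <- function(x, name) {
    if (!is.null(out_dir)) {
      readr::write_tsv(as.data.frame(x), file.path(out_dir, name))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.partial.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  bundle <- stage("simulate", {
    b <- bundle %||% simulate_bundle(config$sim)
    manifest$stages$simulate <- list(
      n_cohorts = length(b$cohorts), n_genes = config$sim$n_genes,
      n_samples = config$sim$n_samples
    )
    b
  })

  tables <- stage("correlate", {
    tb <- map(bundle$cohorts, correlate_with_driver, driver = config$driver)
    for (t in tb) save_tsv(t, sprintf("correlation_%s.tsv", t$cohort_id[[1]]))
    tb
  })

  inter <- stage("intersect", {
    ix <- intersect_cohorts(tables, fdr_threshold = config$fdr_correlation)
    st <- sign_proportion_test(
      length(ix$positive_genes), length(ix$negative_genes), ix$n_universe
    )
    save_tsv(ix$records, "intersection_records.tsv")
    manifest$stages$intersect <- list(
      n_positive = length(ix$positive_genes),
      n_negative = length(ix$negative_genes),
      n_mixed_sign = ix$n_mixed_sign, n_universe = ix$n_universe,
      sign_test_p = st$p_value
    )
    ix
  })

  gsea <- stage("gsea", {
    ranked <- rank_by_correlation(tables)
    res <- gsea_preranked(ranked, bundle$collection,
      n_perm = config$n_perm, weight = config$weight,
      seed = stage_seed(config$seed, 11L)
    )
    core <- intersect_leading_edges(res, q_threshold = config$fdr_geneset)
    save_tsv(select(res, -"leading_edge"), "gsea_results.tsv")
    save_tsv(core, "leading_edge_core.tsv")
    manifest$stages$gsea <- list(
      n_sets_scored = nrow(res), n_sets_significant = sum(res$q < config$fdr_geneset),
      core_size = nrow(core)
    )
    list(results = res, core = core$gene, ranked = ranked)
  })

  surv <- stage("survive", {
    per_cohort <- map(bundle$cohorts, function(co) {
      sc <- metagene_score(co, gsea$core, mode = config$metagene_mode)
      st <- bundle$survival[[co$cohort_id]]
      d <- inner_join(st, select(sc, "sample_id", metagene = "score"), by = "sample_id")
      d$group <- dichotomize_median(d$metagene)
      km <- km_estimate(d, group = "group")
      lr <- logrank_test(d, group = "group")
      cx <- cox_fit(d, covariates = "metagene")
      save_tsv(km, sprintf("km_%s.tsv", co$cohort_id))
      list(
        cohort_id = co$cohort_id, logrank = lr, cox = tidy(cx),
        logrank_p = lr$p_value, cox_p = tidy(cx)$p_value[[1]],
        cox_log_hr = tidy(cx)$estimate[[1]]
      )
    })
    manifest$stages$survive <- map(per_cohort, function(x) {
      list(cohort_id = x$cohort_id, logrank_p = x$logrank_p,
           cox_log_hr = x$cox_log_hr, cox_wald_p = x$cox_p)
    })
    per_cohort
  })

  targets <- stage("targets", {
    de_pass <- filter_de(bundle$de_table,
      fdr_max = config$de_fdr_max, min_abs_logfc = config$de_min_abs_logfc
    )
    human <- if (config$human_list == "positive") inter$positive_genes else gsea$core
    nom <- intersect_targets(human, filter(de_pass, .data$direction == "down")$gene)
    save_tsv(de_pass, "de_filtered.tsv")
    save_tsv(nom, "target_nominations.tsv")
    manifest$stages$targets <- list(
      n_de_pass = nrow(de_pass), human_list = config$human_list,
      n_nominated = nrow(nom), nominated = nom$gene
    )
    nom
  })

  binding <- stage("annotate_peaks", {
    pk <- filter_peaks(bundle$peaks, fdr_max = config$peak_fdr_max)
    bm <- annotate_binding(pk, bundle$gene_models,
      pad = config$pad, anchor = config$anchor
    )
    bs <- binding_summary(bm, gsea$core)
    save_tsv(select(bm, -"peaks"), "binding_matrix.tsv")
    save_tsv(bs, "binding_summary.tsv")
    manifest$stages$annotate_peaks <- list(
      n_peaks_pass = nrow(pk),
      summary = map(seq_len(nrow(bs)), function(i) as.list(bs[i, ]))
    )
    list(matrix = bm, summary = bs)
  })

  manifest$seed <- config$seed
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(manifest)
}
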