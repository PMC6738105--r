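#' Simulation configuration
#'
#' Describes the synthetic study: several cohorts sharing one driver-correlated
#' gene module against an independent background, survival coupled to the
#' module metagene under a proportional-hazards model, gene-set collections
#' containing the module plus decoys, a knockout differential-expression table
#' with module orthologs down-regulated, and ChIP peaks planted in the windows
#' of designated bound genes.
#'
#' Expression follows a single-factor model per cohort: a latent activity
#' `z ~ N(0,1)` per sample, driver `= z + noise_sd * e`, each module gene
#' `= a*z + noise_sd * e` with the loading `a` chosen so the population
#' correlation between gene and driver equals `rho`; anti-correlated genes use
#' `-a`; background genes are independent noise. Because the driver itself is
#' noisy, the attainable |rho| is capped at `1/sqrt(1 + noise_sd^2)`;
#' configurations beyond the cap are rejected.
#'
#' @param n_cohorts number of cohorts.
#' @param n_genes genes per cohort (shared universe).
#' @param n_samples samples per cohort.
#' @param module_size number of positively driver-correlated module genes.
#' @param n_negative number of anti-correlated genes.
#' @param rho target population Pearson correlation between each module gene
#'   and the driver, in (0, 1).
#' @param noise_sd residual standard deviation of the factor model.
#' @param driver_name driver gene identifier.
#' @param baseline_hazard exponential baseline hazard (events per month).
#' @param log_hr log hazard ratio per unit of metagene score.
#' @param censoring_rate target fraction of censored subjects, in \[0, 1).
#' @param seed integer seed; all generators are fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 3, n_genes = 5000, n_samples = 200,
                       module_size = 100, n_negative = 20, rho = 0.6,
                       noise_sd = 0.5, driver_name = "DRIVER",
                       baseline_hazard = 0.02, log_hr = 0.7,
                       censoring_rate = 0.3, seed = 1L) {
  assert_scalar_number(n_cohorts, "n_cohorts", 1)
  assert_scalar_number(n_genes, "n_genes", 3)
  assert_scalar_number(n_samples, "n_samples", 4)
  assert_scalar_number(module_size, "module_size", 1)
  assert_scalar_number(n_negative, "n_negative", 0)
  assert_scalar_number(rho, "rho", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", 1e-8)
  assert_scalar_number(baseline_hazard, "baseline_hazard", 1e-12)
  assert_scalar_number(log_hr, "log_hr")
  assert_scalar_number(censoring_rate, "censoring_rate", 0, 1 - 1e-9)
  assert_scalar_number(seed, "seed")
  if (module_size + n_negative >= n_genes) {
    abort("module_size + n_negative must be smaller than n_genes.")
  }
  if (rho^2 * (1 + noise_sd^2) >= 1) {
    abort(sprintf(
      "rho = %.3f is unattainable: driver noise caps |rho| at %.3f.",
      rho, 1 / sqrt(1 + noise_sd^2)
    ))
  }
  structure(
    list(
      n_cohorts = as.integer(n_cohorts), n_genes = as.integer(n_genes),
      n_samples = as.integer(n_samples), module_size = as.integer(module_size),
      n_negative = as.integer(n_negative), rho = rho, noise_sd = noise_sd,
      driver_name = driver_name, baseline_hazard = baseline_hazard,
      log_hr = log_hr, censoring_rate = censoring_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Factor-model loading giving population cor(gene, driver) = rho when
# driver = z + s*e and gene = a*z + s*e.
module_loading <- function(rho, s) {
  rho * sqrt(1 + s^2) * s / sqrt(1 - rho^2 * (1 + s^2))
}

#' Generate synthetic expression cohorts with a planted module
#'
#' @param config a [sim_config()].
#' @return a list with `cohorts` (list of [expression_cohort()]),
#'   `latent` (per-cohort tibble of the latent factor per sample) and `truth`
#'   (module, negative and background gene identifiers plus the driver name).
#' @export
gen_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n <- config$n_samples
  s <- config$noise_sd
  a <- module_loading(config$rho, s)
  module <- sprintf("MOD%04d", seq_len(config$module_size))
  negative <- if (config$n_negative > 0) sprintf("NEG%04d", seq_len(config$n_negative)) else character()
  n_bg <- g - config$module_size - config$n_negative - 1L
  background <- sprintf("BG%05d", seq_len(n_bg))
  genes <- c(config$driver_name, module, negative, background)
  # per-gene baseline log2 abundance, shared across cohorts
  mu <- with_seed(stage_seed(config$seed, 0L), rnorm(g, mean = 8, sd = 2))
  cohorts <- vector("list", config$n_cohorts)
  latent <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    cid <- sprintf("cohort%d", k)
    res <- with_seed(stage_seed(config$seed, k), {
      z <- rnorm(n)
      vals <- matrix(rnorm(g * n, sd = s), nrow = g)
      load <- c(1, rep(a, config$module_size), rep(-a, config$n_negative),
                rep(0, n_bg))
      # background rows carry unit-variance noise instead of a*z
      vals[load == 0, ] <- matrix(rnorm(n_bg * n), nrow = n_bg)
      vals <- vals + outer(load, z) + mu
      list(vals = vals, z = z)
    })
    rownames(res$vals) <- genes
    colnames(res$vals) <- sprintf("%s_S%03d", cid, seq_len(n))
    cohorts[[k]] <- expression_cohort(res$vals, cid)
    latent[[k]] <- tibble(cohort_id = cid, sample_id = colnames(res$vals), z = res$z)
  }
  list(
    cohorts = cohorts,
    latent = bind_rows(latent),
    truth = list(
      driver = config$driver_name, module = module,
      negative = negative, background = background
    )
  )
}

#' Generate survival data coupled to a metagene score
#'
#' Event times are exponential with hazard `baseline_hazard * exp(log_hr *
#' score)` — proportional hazards by construction. Censoring is independent
#' uniform on `(0, c_max)` with `c_max` solved numerically so the expected
#' censoring fraction matches `censoring_rate`; a rate of 0 disables
#' censoring.
#'
#' @param scores tibble with columns `sample_id` and `score`, or a named
#'   numeric vector (one score per sample).
#' @param config a [sim_config()] (uses `baseline_hazard`, `log_hr`,
#'   `censoring_rate`).
#' @param seed optional seed override (defaults to a substream of
#'   `config$seed`).
#' @return survival tibble: `sample_id`, `time`, `event`, `score`.
#' @export
gen_survival <- function(scores, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample_id", "score") %in% names(scores)))
    ids <- scores$sample_id
    sc <- scores$score
  } else {
    sc <- as.numeric(scores)
    ids <- names(scores) %||% sprintf("S%03d", seq_along(sc))
  }
  if (any(!is.finite(sc))) abort("metagene scores must be finite.")
  seed <- seed %||% stage_seed(config$seed, 101L)
  with_seed(seed, {
    rate <- config$baseline_hazard * exp(config$log_hr * sc)
    t_event <- rexp(length(sc), rate = rate)
    if (config$censoring_rate > 0) {
      # E[censored] with C ~ U(0, cmax) is mean(pmin(T, cmax)) / cmax
      f <- function(cm) mean(pmin(t_event, cm)) / cm - config$censoring_rate
      cmax <- uniroot(f, lower = 1e-9, upper = max(t_event) * 1e4, tol = 1e-9)$root
      cens <- runif(length(sc), 0, cmax)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    } else {
      time <- t_event
      event <- rep(1L, length(sc))
    }
    tibble(sample_id = ids, time = time, event = event, score = sc)
  })
}

#' Generate a gene-set collection with planted motif-like sets and decoys
#'
#' Emulates a transcription-factor-motif collection: `n_motif_sets`
#' "motif" sets share a planted core of module genes (so their leading edges
#' intersect in a known list), each padded with further module genes and a few
#' random background genes; `n_decoy_sets` decoys contain background genes
#' only. With `overlap = "disjoint"` the motif sets partition the module
#' without any shared core.
#'
#' @param truth the `truth` element of [gen_cohorts()] output.
#' @param core_size planted shared-core size.
#' @param n_motif_sets number of module-enriched sets.
#' @param extra_module additional (non-core) module genes per motif set.
#' @param extra_background background genes per motif set.
#' @param n_decoy_sets,decoy_size decoy sets of background genes.
#' @param overlap `"core"` (shared planted core) or `"disjoint"`.
#' @param seed integer seed.
#' @return list with `collection` (a [gene_set_collection()]) and `core`
#'   (planted core gene identifiers; empty for `overlap = "disjoint"`).
#' @export
gen_gmt <- function(truth, core_size = 50, n_motif_sets = 5, extra_module = 25,
                    extra_background = 15, n_decoy_sets = 50, decoy_size = 40,
                    overlap = c("core", "disjoint"), seed = 1L) {
  overlap <- match.arg(overlap)
  with_seed(seed, {
    if (overlap == "core") {
      if (core_size + extra_module > length(truth$module)) {
        abort("core_size + extra_module exceeds the module size.")
      }
      core <- sort(sample(truth$module, core_size))
      rest <- setdiff(truth$module, core)
      motif <- map(seq_len(n_motif_sets), function(i) {
        sample(c(core, sample(rest, extra_module), sample(truth$background, extra_background)))
      })
    } else {
      per <- length(truth$module) %/% n_motif_sets
      if (per < 1) abort("too many motif sets for a disjoint partition.")
      shuffled <- sample(truth$module)
      motif <- map(seq_len(n_motif_sets), function(i) {
        shuffled[((i - 1) * per + 1):(i * per)]
      })
      core <- character()
    }
    names(motif) <- sprintf("MOTIF_SET_%02d", seq_len(n_motif_sets))
    decoys <- map(seq_len(n_decoy_sets), function(i) sample(truth$background, decoy_size))
    names(decoys) <- sprintf("DECOY_SET_%03d", seq_len(n_decoy_sets))
    sets <- c(motif, decoys)
    desc <- setNames(
      c(rep("synthetic motif-like set (module-enriched)", n_motif_sets),
        rep("synthetic decoy set (background only)", n_decoy_sets)),
      names(sets)
    )
    list(collection = gene_set_collection(sets, desc), core = core)
  })
}

# Human symbol -> mouse-style symbol (Rrm2 convention).
mouse_symbol <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Generate a knockout differential-expression table
#'
#' Module orthologs (mouse-cased symbols) are planted as down-regulated:
#' `logFC <= -effect_logfc` with `fdr < fdr_alpha`. Background genes are null
#' (small logFC, large FDR) and never pass the default
#' `fdr < 0.1, |logFC| > 1` filter.
#'
#' @param truth the `truth` element of [gen_cohorts()] output.
#' @param effect_logfc minimum absolute log fold-change of planted genes
#'   (must exceed 1 for the default filter to capture them).
#' @param fdr_alpha upper bound of planted-gene FDRs.
#' @param seed integer seed.
#' @return a DE tibble: `gene`, `logFC`, `fdr`.
#' @export
gen_mouse_de <- function(truth, effect_logfc = 1.5, fdr_alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    down <- mouse_symbol(truth$module)
    null_genes <- mouse_symbol(truth$background)
    tibble(
      gene = c(down, null_genes),
      logFC = c(-(effect_logfc + rexp(length(down), rate = 2)),
                pmax(pmin(rnorm(length(null_genes), 0, 0.35), 0.95), -0.95)),
      fdr = c(runif(length(down), 0, fdr_alpha * 0.999),
              runif(length(null_genes), 0.15, 1))
    ) |>
      dplyr::slice(sample(dplyr::n()))
  })
}

#' Generate synthetic peak calls and gene models
#'
#' Builds one gene model per supplied gene on synthetic chromosomes, then
#' plants (i) significant peaks (score, i.e. FDR, < 0.05) inside the
#' `+/- pad` windows of the designated bound genes, (ii) non-significant peaks
#' (score >= 0.05) inside windows of some unbound genes — so skipping the FDR
#' filter changes the answer — and (iii) significant decoy peaks far from any
#' window.
#'
#' @param genes gene identifiers to build models for.
#' @param bound_genes subset of `genes` designated as bound.
#' @param pad window half-width in bp.
#' @param seed integer seed.
#' @return list with `gene_models` and `peaks`, both `genomic_intervals`, and
#'   `bound_genes`.
#' @export
gen_peaks <- function(genes, bound_genes, pad = 2000, seed = 1L) {
  stopifnot(all(bound_genes %in% genes))
  with_seed(seed, {
    n <- length(genes)
    gene_len <- sample(500:3000, n, replace = TRUE)
    # lay genes along one synthetic chromosome, 20 kb apart: windows never touch
    starts <- 50000L + (seq_len(n) - 1L) * 20000L
    models <- genomic_intervals(
      chrom = "chrS1", start = starts, end = starts + gene_len,
      name = genes, strand = sample(c("+", "-"), n, replace = TRUE)
    )
    idx <- match(bound_genes, genes)
    peak_rows <- list()
    for (i in idx) {
      k <- sample(1:2, 1)
      for (j in seq_len(k)) {
        w_lo <- max(starts[i] - pad, 0L)
        w_hi <- starts[i] + gene_len[i] + pad
        p_start <- sample(w_lo:(w_hi - 150L), 1)
        peak_rows[[length(peak_rows) + 1L]] <- tibble(
          chrom = "chrS1", start = p_start, end = p_start + sample(100:400, 1),
          name = sprintf("peak_sig_%s_%d", genes[i], j),
          score = runif(1, 1e-6, 0.049), strand = "."
        )
      }
    }
    unbound <- setdiff(genes, bound_genes)
    weak <- sample(unbound, min(length(unbound), max(1L, length(unbound) %/% 3L)))
    for (g in weak) {
      i <- match(g, genes)
      p_start <- sample(max(starts[i] - pad, 0L):(starts[i] + gene_len[i] + pad - 150L), 1)
      peak_rows[[length(peak_rows) + 1L]] <- tibble(
        chrom = "chrS1", start = p_start, end = p_start + sample(100:400, 1),
        name = sprintf("peak_weak_%s", g), score = runif(1, 0.05, 0.9), strand = "."
      )
    }
    far_start <- max(starts) + 100000L + cumsum(sample(5000:9000, 20, replace = TRUE))
    decoys <- tibble(
      chrom = c(rep("chrS1", 10), rep("chrS2", 10)),
      start = as.integer(far_start), end = as.integer(far_start + 200L),
      name = sprintf("peak_decoy_%02d", 1:20),
      score = runif(20, 1e-6, 0.049), strand = "."
    )
    peaks <- new_genomic_intervals(bind_rows(c(peak_rows, list(decoys))))
    list(gene_models = models, peaks = peaks, bound_genes = bound_genes)
  })
}

#' Simulate the full input bundle
#'
#' Runs every generator under substreams of one seed and, optionally, writes
#' the complete input bundle (per-cohort expression TSVs, GMT, survival TSV,
#' DE TSV, peak and gene-model BED files) plus a JSON truth manifest to `dir`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if needed.
#' @param n_bound number of core genes designated as ChIP-bound.
#' @inheritParams gen_gmt
#' @return list with `cohorts`, `latent`, `truth`, `collection`, `core`,
#'   `survival` (per cohort), `de_table`, `gene_models`, `peaks`,
#'   `bound_genes`, and `paths` when `dir` is given.
#' @export
simulate_bundle <- function(config = sim_config(), dir = NULL,
                            core_size = NULL, n_motif_sets = 5,
                            n_decoy_sets = 50, n_bound = NULL) {
  gc <- gen_cohorts(config)
  core_size <- core_size %||% min(50L, max(1L, config$module_size %/% 2L))
  gmt <- gen_gmt(gc$truth,
    core_size = core_size, n_motif_sets = n_motif_sets,
    extra_module = min(25L, config$module_size - core_size),
    extra_background = 15, seed = stage_seed(config$seed, 201L),
    n_decoy_sets = n_decoy_sets
  )
  # survival per cohort, driven by the true module metagene
  surv <- map(gc$cohorts, function(co) {
    sc <- metagene_score(co, gc$truth$module, mode = "zmean")
    gen_survival(sc, config, seed = stage_seed(config$seed, 300L + match(co$cohort_id, map_chr(gc$cohorts, "cohort_id"))))
  })
  names(surv) <- map_chr(gc$cohorts, "cohort_id")
  de <- gen_mouse_de(gc$truth, seed = stage_seed(config$seed, 401L))
  core <- gmt$core
  n_bound <- n_bound %||% max(1L, floor(0.85 * length(core)))
  model_genes <- c(core, head(gc$truth$background, 60))
  pk <- gen_peaks(model_genes,
    bound_genes = head(core, n_bound),
    seed = stage_seed(config$seed, 501L)
  )
  out <- c(gc, list(
    collection = gmt$collection, core = core, survival = surv,
    de_table = de, gene_models = pk$gene_models, peaks = pk$peaks,
    bound_genes = pk$bound_genes
  ))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (co in gc$cohorts) {
      paths[[paste0("expression_", co$cohort_id)]] <-
        write_expression(co, file.path(dir, paste0(co$cohort_id, "_expression.tsv")))
    }
    paths$gmt <- write_gmt(gmt$collection, file.path(dir, "gene_sets.gmt"))
    for (cid in names(surv)) {
      p <- file.path(dir, paste0(cid, "_survival.tsv"))
      readr::write_tsv(surv[[cid]], p)
      paths[[paste0("survival_", cid)]] <- p
    }
    readr::write_tsv(de, file.path(dir, "knockout_de.tsv"))
    paths$de <- file.path(dir, "knockout_de.tsv")
    paths$peaks <- write_bed(pk$peaks, file.path(dir, "peaks.bed"))
    paths$gene_models <- write_bed(pk$gene_models, file.path(dir, "gene_models.bed"))
    truth_json <- list(
      driver = gc$truth$driver, module = gc$truth$module,
      negative = gc$truth$negative, core = core, bound_genes = pk$bound_genes
    )
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"), auto_unbox = TRUE)
    paths$truth <- file.path(dir, "truth.json")
    out$paths <- paths
  }
  out
}
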