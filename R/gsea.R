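#' Build a ranked gene list
#'
#' Orders genes by decreasing ranking metric (here typically the Pearson
#' correlation with the driver). Ties in the metric are broken by gene
#' identifier (lexicographic) so the ranking is fully reproducible.
#'
#' @param genes gene identifiers (unique).
#' @param metric finite ranking metric, one value per gene.
#' @return tibble (`gene`, `metric`) of class `ranked_list`, sorted.
#' @export
ranked_list <- function(genes, metric) {
  if (length(genes) != length(metric)) abort("`genes` and `metric` lengths differ.")
  if (anyDuplicated(genes)) abort("ranked list genes must be unique.")
  if (any(!is.finite(metric))) abort("ranking metrics must be finite.")
  ord <- order(-metric, genes)
  out <- tibble(gene = as.character(genes)[ord], metric = as.numeric(metric)[ord])
  class(out) <- c("ranked_list", class(out))
  out
}

#' Rank genes by their cohort-averaged driver correlation
#'
#' Convenience bridge from the correlation screen to pre-ranked enrichment:
#' averages each gene's correlation coefficient over the supplied cohort
#' tables (genes must have a defined `r` in every cohort) and returns the
#' ranked list.
#'
#' @param tables list of `cor_table` tibbles, or a single one.
#' @return a [ranked_list()].
#' @export
rank_by_correlation <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- bind_rows(tables) |> filter(is.finite(.data$r))
  avg <- long |>
    group_by(.data$gene) |>
    summarise(metric = mean(.data$r), n = dplyr::n(), .groups = "drop") |>
    filter(.data$n == length(tables))
  ranked_list(avg$gene, avg$metric)
}

# Enrichment score from sorted hit positions.
#   pos: strictly increasing hit positions in 1..n; w: |metric|^weight at pos.
# The running sum's local maxima sit immediately after a hit and its local
# minima immediately before one, so only those 2k candidate values are needed.
es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  n_miss <- n - k
  if (n_miss == 0) abort("gene set covers the entire ranked list.")
  nr <- sum(w)
  if (nr <= 0) abort("degenerate weights: all hit metrics are zero with weight > 0.")
  cw <- cumsum(w) / nr
  miss_frac <- (pos - seq_len(k)) / n_miss
  after <- cw - miss_frac              # running sum at each hit position
  before <- c(0, cw[-k]) - miss_frac   # running sum just before each hit
  max_after <- max(after)
  min_before <- min(c(before, 0))
  if (max_after >= -min_before) {
    list(es = max_after, peak = which.max(after), positive = TRUE)
  } else {
    trough <- k + 1L - which.min(rev(before)) # latest trough on ties
    list(es = min_before, peak = trough, positive = FALSE)
  }
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like statistic of pre-ranked gene-set
#' enrichment: walking down the ranked list, set members ("hits") increment
#' the running sum by `|metric|^weight / N_R` (`N_R` = sum of those weights)
#' and non-members decrement it by `1 / (N - N_hits)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (signed; a
#' tie between a positive and negative extreme of equal magnitude resolves
#' positive). The leading edge contains the members at or before the peak for
#' a positive score, and at or after the trough for a negative one. With
#' `weight = 0` the statistic reduces to the classical two-sample KS statistic
#' on hit/miss positions (up to sign conventions).
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of member genes (matched
#'   case-insensitively).
#' @param weight metric weight exponent (GSEA "weighted" scheme = 1, the
#'   default).
#' @return list with `es`, `running_sum` (length-N vector), `leading_edge`,
#'   `hit_positions`, `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "metric") %in% names(ranked)))
  n <- nrow(ranked)
  hit <- norm_gene(ranked$gene) %in% norm_gene(gene_set)
  pos <- which(hit)
  k <- length(pos)
  if (k == 0) abort("no gene-set member present in the ranked list.")
  w <- abs(ranked$metric[pos])^weight
  st <- es_from_positions(pos, w, n)
  inc <- rep(-1 / (n - k), n)
  inc[pos] <- w / sum(w)
  running <- cumsum(inc)
  le <- if (st$positive) {
    ranked$gene[pos[seq_len(st$peak)]]
  } else {
    ranked$gene[pos[seq(st$peak, k)]]
  }
  list(
    es = st$es, running_sum = running, leading_edge = le,
    hit_positions = pos, n_hits = k
  )
}

#' Gene-label permutation null for one gene set
#'
#' Draws `n_perm` random same-size member sets from the ranked universe,
#' recomputes the enrichment score for each, and reports the one-sided
#' permutation p-value on the side of the observed score (with a +1
#' pseudo-count) together with the normalised enrichment score
#' `NES = ES / mean(|null ES| of the same sign)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return list with `es`, `nes`, `p_perm`, `null_es`, `leading_edge`,
#'   `n_hits`, `unstable` (TRUE when fewer than 10 same-sign null values
#'   support the NES).
#' @export
permutation_null <- function(ranked, gene_set, n_perm = 1000, weight = 1, seed = 1L) {
  if (n_perm < 100) abort("n_perm must be at least 100.")
  obs <- enrichment_score(ranked, gene_set, weight)
  n <- nrow(ranked)
  k <- obs$n_hits
  mw <- abs(ranked$metric)^weight
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sort.int(sample.int(n, k))
      es_from_positions(p, mw[p], n)$es
    }, numeric(1))
  })
  es <- obs$es
  # tail frequency among same-sign nulls (+1 pseudo-count top and bottom):
  # keeps the p-value uniform under the null on either side
  if (es >= 0) {
    same <- null_es[null_es >= 0]
    p_perm <- (1 + sum(same >= es)) / (1 + length(same))
  } else {
    same <- null_es[null_es < 0]
    p_perm <- (1 + sum(same <= es)) / (1 + length(same))
  }
  unstable <- length(same) < 10
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  list(
    es = es, nes = nes, p_perm = min(p_perm, 1), null_es = null_es,
    leading_edge = obs$leading_edge, n_hits = k, unstable = unstable
  )
}

# Normalise a null ES sample by its own same-sign means (per-set null NES).
normalise_null <- function(null_es) {
  pos_mean <- mean(null_es[null_es >= 0])
  neg_mean <- mean(abs(null_es[null_es < 0]))
  out <- ifelse(null_es >= 0, null_es / pos_mean, null_es / neg_mean)
  out[is.finite(out)]
}

#' Permutation-based FDR across gene sets
#'
#' GSEA-style false discovery rate: for each observed NES, the q-value is the
#' ratio of (fraction of pooled null NES values at least as extreme, same
#' sign) to (fraction of observed NES values at least as extreme, same sign),
#' clipped to \[0, 1\].
#'
#' @param nes observed NES values, one per set.
#' @param null_nes pooled normalised null NES values.
#' @return q-values, one per set.
#' @export
fdr_across_sets <- function(nes, null_nes) {
  n_pool_pos <- sum(null_nes >= 0)
  n_pool_neg <- sum(null_nes < 0)
  n_obs_pos <- sum(nes >= 0)
  n_obs_neg <- sum(nes < 0)
  vapply(nes, function(s) {
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      num <- if (n_pool_pos) sum(null_nes >= s) / n_pool_pos else 1
      den <- if (n_obs_pos) sum(nes >= s) / n_obs_pos else 1
    } else {
      num <- if (n_pool_neg) sum(null_nes <= s) / n_pool_neg else 1
      den <- if (n_obs_neg) sum(nes <= s) / n_obs_neg else 1
    }
    max(min(num / max(den, .Machine$double.eps), 1), 0)
  }, numeric(1))
}

#' Pre-ranked gene-set enrichment over a collection
#'
#' Runs [enrichment_score()] and [permutation_null()] for every set in the
#' collection and attaches a permutation-based FDR ([fdr_across_sets()]; a
#' Benjamini-Hochberg adjustment of the permutation p-values is available via
#' `fdr_method = "bh"`). Sets with no member in the ranked list, or covering
#' it entirely, are skipped with a warning. With fewer than two scored sets
#' the q-value falls back to the permutation p-value, with a warning.
#'
#' @inheritParams permutation_null
#' @param collection a [gene_set_collection()].
#' @param fdr_method `"permutation"` (GSEA-style, default) or `"bh"`.
#' @return tibble of class `gsea_result`: `set_name`, `n_hits`, `es`, `nes`,
#'   `p_perm`, `q`, `n_leading_edge`, `leading_edge` (list-column),
#'   `unstable`; sorted by `q` then `p_perm`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, weight = 1,
                           seed = 1L, fdr_method = c("permutation", "bh")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- norm_gene(ranked$gene)
  res <- list()
  nulls <- list()
  for (i in seq_along(collection)) {
    nm <- names(collection)[[i]]
    members <- collection[[i]]
    n_in <- sum(universe %in% norm_gene(members))
    if (n_in == 0) {
      warn(sprintf("set '%s' has no member in the ranked list; skipped.", nm))
      next
    }
    if (n_in == nrow(ranked)) {
      warn(sprintf("set '%s' covers the whole ranked list; skipped.", nm))
      next
    }
    pr <- permutation_null(ranked, members, n_perm = n_perm, weight = weight,
                           seed = stage_seed(seed, i))
    nulls[[nm]] <- pr$null_es
    res[[nm]] <- tibble(
      set_name = nm, n_hits = pr$n_hits, es = pr$es, nes = pr$nes,
      p_perm = pr$p_perm, n_leading_edge = length(pr$leading_edge),
      leading_edge = list(pr$leading_edge), unstable = pr$unstable
    )
  }
  if (!length(res)) abort("no scorable gene set in the collection.")
  out <- bind_rows(res)
  if (nrow(out) < 2) {
    warn("fewer than 2 scored sets: q falls back to the permutation p-value.")
    out$q <- out$p_perm
  } else if (fdr_method == "bh") {
    out$q <- bh_adjust(out$p_perm)
  } else {
    pool <- unlist(map(nulls, normalise_null), use.names = FALSE)
    out$q <- fdr_across_sets(out$nes, pool)
  }
  out <- out |>
    select("set_name", "n_hits", "es", "nes", "p_perm", "q",
           "n_leading_edge", "leading_edge", "unstable") |>
    arrange(.data$q, .data$p_perm, dplyr::desc(abs(.data$nes)))
  class(out) <- c("gsea_result", class(out))
  out
}

#' Intersect the leading edges of significant gene sets
#'
#' Among sets passing the FDR threshold, returns the genes present in all
#' selected leading edges (the default strict intersection) or in at least
#' `min_sets` of them. An empty selection or empty core is a warning, not an
#' error.
#'
#' @param results a `gsea_result` tibble from [gsea_preranked()].
#' @param q_threshold FDR threshold for selecting sets (strict `<`).
#' @param min_sets membership rule: a gene must occur in at least this many
#'   selected leading edges; `NULL` (default) requires all of them.
#' @return tibble (`gene`, `n_sets`) of core genes with the number of selected
#'   leading edges containing each; the number of selected sets is in the
#'   `"n_selected"` attribute.
#' @export
intersect_leading_edges <- function(results, q_threshold = 0.01, min_sets = NULL) {
  stopifnot(is.data.frame(results), "leading_edge" %in% names(results))
  sel <- results |> filter(.data$q < q_threshold)
  if (nrow(sel) == 0) {
    warn("no gene set passes the FDR threshold; empty core.")
    return(structure(tibble(gene = character(), n_sets = integer()), n_selected = 0L))
  }
  need <- min_sets %||% nrow(sel)
  counts <- table(unlist(sel$leading_edge, use.names = FALSE))
  core <- tibble(gene = names(counts), n_sets = as.integer(counts)) |>
    filter(.data$n_sets >= need) |>
    arrange(.data$gene)
  if (nrow(core) == 0) warn("leading-edge intersection is empty.")
  structure(core, n_selected = nrow(sel))
}
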