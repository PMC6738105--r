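#' Filter a differential-expression table
#'
#' Keeps genes with `fdr < fdr_max` and `|logFC| > min_abs_logfc` — both
#' inequalities strict, so boundary values are excluded — and labels each
#' survivor `up` or `down` by the sign of its log fold-change.
#'
#' @param de_table tibble with `gene`, `logFC`, `fdr`.
#' @param fdr_max FDR cut-off (strict).
#' @param min_abs_logfc absolute log fold-change cut-off (strict).
#' @return the filtered tibble with a `direction` column (`"up"`/`"down"`).
#' @export
filter_de <- function(de_table, fdr_max = 0.1, min_abs_logfc = 1.0) {
  stopifnot(all(c("gene", "logFC", "fdr") %in% names(de_table)))
  assert_scalar_number(fdr_max, "fdr_max", 0, 1)
  assert_scalar_number(min_abs_logfc, "min_abs_logfc", 0)
  de_table |>
    filter(.data$fdr < fdr_max, abs(.data$logFC) > min_abs_logfc) |>
    mutate(direction = ifelse(.data$logFC > 0, "up", "down"))
}

#' Nominate targets by cross-species intersection
#'
#' Intersects a human candidate gene list with a (typically mouse) knockout
#' down-regulated list by case-folded symbol equality — human `RRM2` matches
#' mouse `Rrm2`. Evidence columns from either side are carried along with
#' `human_`/`mouse_` prefixes when tibbles are supplied.
#'
#' @param human character vector of human candidate genes, or a tibble with a
#'   `gene` column plus evidence columns.
#' @param mouse character vector of knockout-responsive genes, or a tibble
#'   with a `gene` column plus evidence columns.
#' @return tibble with `gene` (upper-cased symbol), the original `human_gene`
#'   and `mouse_gene` spellings, and any evidence columns. Empty overlap is a
#'   warning, not an error.
#' @export
intersect_targets <- function(human, mouse) {
  to_tbl <- function(x, side) {
    if (is.data.frame(x)) {
      stopifnot("gene" %in% names(x))
      out <- x |> rename(!!paste0(side, "_gene") := "gene")
      ev <- setdiff(names(out), paste0(side, "_gene"))
      names(out)[match(ev, names(out))] <- paste0(side, "_", ev)
      out
    } else {
      tibble(!!paste0(side, "_gene") := as.character(x))
    }
  }
  h <- to_tbl(human, "human") |> mutate(gene = norm_gene(.data$human_gene))
  m <- to_tbl(mouse, "mouse") |> mutate(gene = norm_gene(.data$mouse_gene))
  if (!nrow(h) || !nrow(m)) abort("both gene lists must be non-empty.")
  out <- inner_join(h, m, by = "gene") |>
    select("gene", dplyr::everything()) |>
    arrange(.data$gene)
  if (!nrow(out)) warn("no shared symbols between the two lists.")
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups (via [stats::wilcox.test()]).
#' The p-value is exact (full enumeration of rank assignments) when the
#' smaller group has at most 8 observations and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return tibble: `statistic` (Mann-Whitney W for `x`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA (pooled variance, via
#' [stats::oneway.test()] with `var.equal = TRUE`): F on `(k - 1, N - k)`
#' degrees of freedom.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return tibble: `f`, `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (length(values) != length(g)) abort("`values` and `groups` lengths differ.")
  tab <- table(g)
  if (any(tab == 0) || nlevels(g) < 2) abort("need >= 2 non-empty groups.")
  if (length(values) - nlevels(g) <= 0) abort("no residual degrees of freedom.")
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  tibble(
    f = unname(ht$statistic), df_between = unname(ht$parameter[1]),
    df_within = unname(ht$parameter[2]), p_value = ht$p.value
  )
}
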