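#' Pearson correlation with a t-based two-sided p-value
#'
#' Pairwise-complete Pearson correlation; the p-value uses the exact-null
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom, as [stats::cor.test()] does.
#'
#' @param x,y numeric vectors of equal length; `NA`s handled
#'   pairwise-complete.
#' @return tibble with columns `r`, `p`, `n_pairs`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) abort("need at least 3 pairwise-complete observations.")
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) {
    abort("correlation undefined: a vector is constant on the complete pairs.")
  }
  r <- cor(xs, ys)
  r <- max(min(r, 1), -1)
  p <- pearson_p(r, n)
  tibble(r = r, p = p, n_pairs = n)
}

pearson_p <- function(r, n) {
  # |r| = 1 gives t = Inf -> p = 0
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps * 4))
  ifelse(abs(r) >= 1, 0, 2 * pt(-abs(t_stat), df = n - 2))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]); input order is
#' preserved and `NA`s propagate without entering the family size.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Correlate every gene with the driver within one cohort
#'
#' Computes the pairwise-complete Pearson correlation of each non-driver gene
#' with the driver gene, with two-sided t-based p-values and
#' Benjamini-Hochberg q-values adjusted within the cohort. Genes failing the
#' correlation preconditions (fewer than `min_pairs` complete pairs, or
#' constant on the complete pairs) are kept with `r = NA` and excluded from
#' the BH family. The driver itself is excluded from its own table.
#'
#' @param cohort an [expression_cohort()].
#' @param driver driver gene identifier (matched case-insensitively).
#' @param min_pairs minimum pairwise-complete sample pairs per gene.
#' @return a tibble (`cohort_id`, `gene`, `r`, `n_pairs`, `p`, `q`) of class
#'   `cor_table`, sorted by decreasing `r`.
#' @export
correlate_with_driver <- function(cohort, driver, min_pairs = 3) {
  stopifnot(inherits(cohort, "expression_cohort"))
  hit <- which(norm_gene(cohort$genes) == norm_gene(driver))
  if (length(hit) != 1) {
    abort(sprintf("driver '%s' not found (or ambiguous) in cohort '%s'.",
                  driver, cohort$cohort_id))
  }
  d <- cohort$values[hit, ]
  vals <- cohort$values[-hit, , drop = FALSE]
  ok_d <- is.finite(d)
  ok <- !is.na(vals) & matrix(ok_d, nrow(vals), ncol(vals), byrow = TRUE)
  n_pairs <- rowSums(ok)
  r <- suppressWarnings(as.numeric(cor(t(vals), d, use = "pairwise.complete.obs")))
  r <- pmax(pmin(r, 1), -1)
  # pairwise-complete sd can be zero even when the full row varies
  bad <- n_pairs < min_pairs | !is.finite(r)
  r[bad] <- NA_real_
  p <- rep(NA_real_, length(r))
  p[!bad] <- pearson_p(r[!bad], n_pairs[!bad])
  out <- tibble(
    cohort_id = cohort$cohort_id, gene = rownames(vals),
    r = r, n_pairs = as.integer(n_pairs), p = p, q = bh_adjust(p)
  ) |>
    arrange(dplyr::desc(.data$r))
  class(out) <- c("cor_table", class(out))
  out
}

#' Intersect per-cohort correlation tables
#'
#' The testable universe is the set of genes with a defined correlation in
#' every cohort. A gene is called positive (negative) when `q < fdr_threshold`
#' in every cohort and its correlation is positive (negative) in every cohort;
#' genes significant everywhere but with inconsistent signs are dropped and
#' counted in `n_mixed_sign`.
#'
#' @param tables list of `cor_table` tibbles from [correlate_with_driver()],
#'   one per cohort (at least two).
#' @param fdr_threshold FDR level applied in every cohort.
#' @return an object of class `cohort_intersection`: list with
#'   `positive_genes`, `negative_genes`, `n_universe`, `n_mixed_sign`,
#'   `threshold`, and `records` (long tibble of per-gene per-cohort r and q).
#' @export
intersect_cohorts <- function(tables, fdr_threshold = 0.001) {
  if (!is.list(tables) || length(tables) < 2) abort("need at least 2 cohort tables.")
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  long <- bind_rows(tables)
  defined <- long |>
    filter(is.finite(.data$r)) |>
    group_by(.data$gene) |>
    summarise(
      n_cohorts = dplyr::n_distinct(.data$cohort_id),
      all_sig = all(.data$q < fdr_threshold),
      all_pos = all(.data$r > 0), all_neg = all(.data$r < 0),
      .groups = "drop"
    ) |>
    filter(.data$n_cohorts == length(tables))
  if (nrow(defined) == 0) abort("empty universe: no gene is testable in every cohort.")
  pos <- defined |> filter(.data$all_sig, .data$all_pos) |> pull(.data$gene)
  neg <- defined |> filter(.data$all_sig, .data$all_neg) |> pull(.data$gene)
  mixed <- defined |> filter(.data$all_sig, !.data$all_pos, !.data$all_neg) |> pull(.data$gene)
  records <- long |>
    filter(.data$gene %in% c(pos, neg)) |>
    select("gene", "cohort_id", "r", "q") |>
    mutate(direction = ifelse(.data$gene %in% pos, "positive", "negative"))
  structure(
    list(
      threshold = fdr_threshold,
      positive_genes = sort(pos), negative_genes = sort(neg),
      n_universe = nrow(defined), n_mixed_sign = length(mixed),
      records = records
    ),
    class = "cohort_intersection"
  )
}

#' @export
print.cohort_intersection <- function(x, ...) {
  cat(sprintf(
    "<cohort_intersection: FDR < %g | %d positive, %d negative, %d mixed-sign of %d testable genes>\n",
    x$threshold, length(x$positive_genes), length(x$negative_genes),
    x$n_mixed_sign, x$n_universe
  ))
  invisible(x)
}

#' @export
tidy.cohort_intersection <- function(x, ...) x$records

#' @export
glance.cohort_intersection <- function(x, ...) {
  tibble(
    threshold = x$threshold, n_positive = length(x$positive_genes),
    n_negative = length(x$negative_genes), n_mixed_sign = x$n_mixed_sign,
    n_universe = x$n_universe
  )
}

#' Test the imbalance between positive and negative correlated genes
#'
#' Compares the proportion of positively and negatively driver-correlated
#' genes out of the same testable universe. The default is the two-sided
#' Fisher exact test on the 2x2 table
#' `[[n_pos, N - n_pos], [n_neg, N - n_neg]]`; a chi-squared two-proportion
#' test (without continuity correction) is available as an alternative.
#'
#' @param n_pos,n_neg counts of positively / negatively correlated genes.
#' @param n_universe number of testable genes (the shared denominator).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return tibble with `p_value`, `method`, and the input counts.
#' @export
sign_proportion_test <- function(n_pos, n_neg, n_universe,
                                 method = c("fisher", "chisq")) {
  method <- match.arg(method)
  for (v in c(n_pos, n_neg, n_universe)) assert_scalar_number(v, "count", 0)
  if (n_pos > n_universe || n_neg > n_universe) abort("counts exceed the universe size.")
  p <- if (method == "fisher") {
    fisher.test(matrix(c(n_pos, n_universe - n_pos, n_neg, n_universe - n_neg),
                       nrow = 2, byrow = TRUE))$p.value
  } else {
    suppressWarnings(
      prop.test(c(n_pos, n_neg), c(n_universe, n_universe), correct = FALSE)$p.value
    )
  }
  tibble(p_value = p, method = method, n_pos = n_pos, n_neg = n_neg,
         n_universe = n_universe)
}
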