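test_that("ranked_list sorts by metric with lexicographic tie-breaks", {
  rl <- ranked_list(c("b", "a", "c"), c(1, 2, 1))
  expect_equal(rl$gene, c("a", "b", "c"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "unique")
  expect_error(ranked_list("a", NaN), "finite")
})

test_that("enrichment_score reproduces the hand-computed running sum", {
  rl <- ranked_list(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(rl, c("g1", "g3"), weight = 1)
  # N_R = 5 + 3 = 8; misses decrement by 1/3
  expect_equal(es$running_sum,
               c(5 / 8, 5 / 8 - 1 / 3, 5 / 8 - 1 / 3 + 3 / 8,
                 1 - 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2 / 3, tolerance = 1e-12)
  expect_setequal(es$leading_edge, c("g1", "g3"))
})

test_that("single-member sets at the extremes reach |ES| = 1", {
  rl <- ranked_list(paste0("g", 1:10), 10:1)
  top <- enrichment_score(rl, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "g1")
  bottom <- enrichment_score(rl, "g10")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "g10")
})

test_that("the running sum is conservative and scale-invariant", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(10:80, 1)
    rl <- ranked_list(paste0("g", 1:n), sort(rnorm(n), decreasing = TRUE))
    k <- sample(1:(n - 1), 1)
    set_genes <- sample(rl$gene, k)
    es <- enrichment_score(rl, set_genes)
    expect_lt(abs(es$running_sum[n]), 1e-9)
    # positive rescaling of the metric leaves ES unchanged
    rl2 <- rl
    rl2$metric <- rl2$metric * 3.7
    expect_equal(enrichment_score(rl2, set_genes)$es, es$es, tolerance = 1e-12)
  }
})

test_that("enrichment_score matches the brute-force prefix oracle", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    rl <- ranked_list(paste0("g", 1:n), sort(rnorm(n), decreasing = TRUE))
    k <- sample(1:(n - 1), 1)
    set_genes <- sample(rl$gene, k)
    w <- sample(c(0, 1, 1.5), 1)
    got <- enrichment_score(rl, set_genes, weight = w)
    oracle <- es_oracle(rl, set_genes, weight = w)
    expect_equal(got$running_sum, oracle$running, tolerance = 1e-12)
    expect_equal(got$es, oracle$es, tolerance = 1e-12)
  }
})

test_that("with weight 0 the ES equals the two-sample KS statistic", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    rl <- ranked_list(paste0("g", 1:n), sort(rnorm(n), decreasing = TRUE))
    k <- sample(2:(n - 2), 1)
    set_genes <- sample(rl$gene, k)
    es <- enrichment_score(rl, set_genes, weight = 0)$es
    hit_pos <- which(rl$gene %in% set_genes)
    miss_pos <- setdiff(seq_len(n), hit_pos)
    ks <- suppressWarnings(stats::ks.test(hit_pos, miss_pos)$statistic)
    expect_equal(abs(es), unname(ks), tolerance = 1e-9)
  }
})

test_that("degenerate sets are rejected", {
  rl <- ranked_list(paste0("g", 1:6), c(3, 2, 1, 0, -1, -2))
  expect_error(enrichment_score(rl, paste0("g", 1:6)), "entire")
  expect_error(enrichment_score(rl, "nope"), "no gene-set member")
  expect_error(enrichment_score(rl, "g4", weight = 1), "degenerate")
})

test_that("permutation p-values are deterministic and detect a planted set", {
  set.seed(3)
  n <- 400
  rl <- ranked_list(paste0("g", 1:n), sort(rnorm(n), decreasing = TRUE))
  planted <- rl$gene[sample(1:25, 15)]    # top decile
  a <- permutation_null(rl, planted, n_perm = 1000, seed = 42L)
  b <- permutation_null(rl, planted, n_perm = 1000, seed = 42L)
  expect_identical(a$nes, b$nes)
  expect_identical(a$p_perm, b$p_perm)
  # no null draw reaches the planted ES: p sits at its attainable minimum
  expect_equal(a$p_perm, 1 / (1 + sum(a$null_es >= 0)), tolerance = 1e-12)
  expect_lt(a$p_perm, 0.005)
  expect_gt(a$nes, 1)
  expect_false(a$unstable)
  expect_error(permutation_null(rl, planted, n_perm = 50), "at least 100")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(17)
  n <- 300
  rl <- ranked_list(paste0("g", 1:n), sort(rnorm(n), decreasing = TRUE))
  p <- vapply(1:400, function(i) {
    permutation_null(rl, sample(rl$gene, 20), n_perm = 200,
                     seed = 5000 + i)$p_perm
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("our ES agrees with fgsea's statistic on random instances", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    stats_vec <- sort(rnorm(n), decreasing = TRUE)
    names(stats_vec) <- paste0("g", 1:n)
    rl <- ranked_list(names(stats_vec), stats_vec)
    k <- sample(3:20, 1)
    sel <- sort(sample.int(n, k))
    ours <- enrichment_score(rl, names(stats_vec)[sel], weight = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = sel, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("collection-level FDR separates planted sets from decoys", {
  b <- small_bundle()
  tabs <- lapply(b$cohorts, correlate_with_driver, driver = b$truth$driver)
  rl <- rank_by_correlation(tabs)
  res <- gsea_preranked(rl, b$collection, n_perm = 500, seed = 101L)
  planted <- grepl("^MOTIF_SET", res$set_name)
  expect_true(all(res$q[planted] < 0.01))
  expect_gte(mean(res$q[!planted] >= 0.01), 0.95)
  # decoy-only collection: q near 1 throughout
  decoys <- b$collection[grepl("^DECOY", names(b$collection))]
  res_d <- gsea_preranked(
    gene_set_collection(decoys[1:10]), ranked = rl, n_perm = 300, seed = 7L
  )
  expect_gt(median(res_d$q), 0.2)
  expect_true(all(res_d$p_perm > 1e-3))
})

test_that("leading-edge intersection follows the membership rule", {
  mk_res <- function(names, q, edges) {
    out <- tibble::tibble(
      set_name = names, q = q, leading_edge = edges
    )
    class(out) <- c("gsea_result", class(out))
    out
  }
  r <- mk_res(c("s1", "s2"), c(0.001, 0.002),
              list(c("A", "B", "C"), c("A", "B", "C")))
  core <- intersect_leading_edges(r, q_threshold = 0.01)
  expect_setequal(core$gene, c("A", "B", "C"))

  r2 <- mk_res(c("s1", "s2"), c(0.001, 0.002), list(c("A", "B"), c("C", "D")))
  expect_warning(core2 <- intersect_leading_edges(r2, 0.01), "empty")
  expect_equal(nrow(core2), 0)

  core3 <- intersect_leading_edges(r2, 0.01, min_sets = 1)
  expect_setequal(core3$gene, c("A", "B", "C", "D"))

  # nothing passes the threshold
  expect_warning(core4 <- intersect_leading_edges(r, q_threshold = 1e-6), "no gene set")
  expect_equal(nrow(core4), 0)
})
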