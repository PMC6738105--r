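test_that("metagene_score reduces to per-gene z-scores and is affine-invariant", {
  co <- toy_cohort()
  one <- metagene_score(co, "G1")
  z <- (co$values["G1", ] - mean(co$values["G1", ])) / sd(co$values["G1", ])
  expect_equal(one$score, unname(z), tolerance = 1e-12)

  # identical rows collapse to the single-gene score
  m <- rbind(A = co$values["G1", ], B = co$values["G1", ], C = co$values["G1", ])
  rep3 <- metagene_score(expression_cohort(m, "x"), c("A", "B", "C"))
  expect_equal(rep3$score, one$score, tolerance = 1e-12)

  # invariant to per-gene affine rescaling (z-mean mode)
  b <- small_bundle()
  co2 <- b$cohorts[[1]]
  scale_fac <- runif(length(co2$genes), 0.5, 3)
  shift <- rnorm(length(co2$genes))
  v2 <- co2$values * scale_fac + shift
  sc_orig <- metagene_score(co2, b$truth$module)
  sc_aff <- metagene_score(expression_cohort(v2, "aff"), b$truth$module)
  expect_equal(sc_aff$score, sc_orig$score, tolerance = 1e-9)

  # raw-mean mode is the plain mean of log2 values
  raw <- metagene_score(co, c("G1", "G2"), mode = "rawmean")
  expect_equal(raw$score, unname(colMeans(co$values[c("G1", "G2"), ])))
})

test_that("metagene_score enforces its preconditions", {
  co <- toy_cohort()
  expect_error(metagene_score(co, c("NOPE1", "NOPE2")), "none of the listed")
  expect_warning(sc <- metagene_score(co, c("G1", "G3")), "zero-variance")
  expect_equal(sc$score, metagene_score(co, "G1")$score)

  m <- co$values
  m["G1", 2] <- NA
  expect_error(metagene_score(expression_cohort(m, "x"), "G1"), "missing values")
})

test_that("the module metagene tracks the latent factor", {
  b <- small_bundle()
  co <- b$cohorts[[1]]
  sc <- metagene_score(co, b$truth$module)
  z <- b$latent[b$latent$cohort_id == co$cohort_id, ]
  expect_gt(cor(sc$score, z$z[match(sc$sample_id, z$sample_id)]), 0.9)
})

test_that("dichotomize_median sends ties and the median to 'low'", {
  expect_equal(as.character(dichotomize_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize_median(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_warning(g <- dichotomize_median(c(2, 2, 2)), "single group")
  expect_true(all(g == "low"))
})

test_that("km_estimate matches the product-limit definition", {
  d <- tibble::tibble(time = c(1, 2), event = c(1L, 1L))
  km <- km_estimate(d)
  expect_equal(km$survival, c(0.5, 0))

  cens <- tibble::tibble(time = c(3, 5, 7), event = 0L)
  expect_true(all(km_estimate(cens)$survival == 1))

  set.seed(12)
  d10 <- tibble::tibble(
    time = c(2, 3, 3, 5, 6, 8, 9, 11, 12, 14),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L)
  )
  km10 <- km_estimate(d10)
  oracle <- km_oracle(d10$time, d10$event)
  got <- km10[km10$n_event > 0, c("time", "survival")]
  expect_equal(as.data.frame(got), as.data.frame(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)

  # record order does not matter
  perm <- d10[sample(nrow(d10)), ]
  expect_equal(km_estimate(perm)$survival, km10$survival)

  expect_error(km_estimate(tibble::tibble(time = -1, event = 1L)), "non-negative")
})

test_that("log-rank reproduces hand-computed moments and is label-symmetric", {
  # A events at 1, 2; B events at 4, 6; no censoring: chi2 = 49/17
  d <- tibble::tibble(time = c(1, 2, 4, 6), event = 1L,
                      group = c("A", "A", "B", "B"))
  lr <- logrank_test(d, "group")
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE), tolerance = 1e-12)

  d2 <- d
  d2$group <- ifelse(d$group == "A", "B", "A")
  expect_equal(logrank_test(d2, "group")$chisq, lr$chisq, tolerance = 1e-12)

  # identical survival experience in both groups
  same <- tibble::tibble(time = rep(c(1, 3, 5), 2), event = rep(1L, 6),
                         group = rep(c("A", "B"), each = 3))
  lr0 <- logrank_test(same, "group")
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(tibble::tibble(time = 1:3, event = 1L,
                                           group = "A"), "group"),
               "two non-empty")
})

test_that("log-rank chi-square equals the Cox score test without ties", {
  set.seed(31)
  for (i in 1:10) {
    n <- 40
    d <- tibble::tibble(
      time = sample(seq(1, 400), n),   # distinct times
      event = rbinom(n, 1, 0.8),
      group = rep(c(0, 1), each = n / 2)
    )
    if (sum(d$event) < 5 || length(unique(d$group[d$event == 1])) < 2) next
    lr <- logrank_test(d, "group")
    sc <- summary(survival::coxph(survival::Surv(time, event) ~ group,
                                  data = d, ties = "breslow"))$sctest
    expect_equal(lr$chisq, unname(sc["test"]), tolerance = 1e-6)
  }
})

test_that("cox_fit matches an independent partial-likelihood maximiser", {
  d8 <- tibble::tibble(
    time = c(4, 7, 9, 12, 15, 18, 22, 30),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L),
    x = c(0.8, -0.4, 0.3, 1.1, -0.9, 0.2, -1.3, 0.5)
  )
  fit <- cox_fit(d8, "x")
  beta_ref <- cox_oracle_beta(d8$time, d8$event, d8$x)
  expect_equal(tidy(fit)$estimate, beta_ref, tolerance = 1e-6)
  expect_equal(tidy(fit)$hazard_ratio, exp(beta_ref), tolerance = 1e-6)
  expect_equal(glance(fit)$n_event, 6)
})

test_that("cox_fit recovers a generating log-hazard ratio and nulls are flat", {
  cfg <- sim_config(seed = 77L, log_hr = 0.7, censoring_rate = 0.25)
  betas <- vapply(1:30, function(i) {
    sc <- with_seed_test(400 + i, rnorm(300))
    st <- gen_survival(sc, cfg, seed = 900 + i)
    tidy(cox_fit(st, "score"))$estimate
  }, numeric(1))
  expect_lt(abs(median(betas) - 0.7), 0.15)

  # permuted covariate: Wald p roughly uniform
  p <- vapply(1:60, function(i) {
    sc <- with_seed_test(600 + i, rnorm(150))
    st <- gen_survival(sc, cfg, seed = 1900 + i)
    st$score <- sample(st$score)
    tidy(cox_fit(st, "score"))$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.0)
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(mean(p > 0.5), 0.3)
})

test_that("cox_fit flags separation and rejects degenerate inputs", {
  # covariate perfectly ordered with event times: monotone likelihood
  sep <- tibble::tibble(time = 1:8, event = 1L, x = 8:1)
  expect_error(cox_fit(sep, "x"), "monotone|infinite")
  expect_error(cox_fit(tibble::tibble(time = 1:4, event = 0L, x = rnorm(4)), "x"),
               "at least one event")
  expect_error(cox_fit(tibble::tibble(time = 1:4, event = 1L, x = 1), "x"),
               "constant")
  expect_error(cox_fit(tibble::tibble(time = 1:4, event = 1L, x = rnorm(4)), "y"),
               "not in data")
})

test_that("multivariate Cox accepts mixed covariate types", {
  b <- small_bundle()
  st <- b$survival[[1]]
  st$grade <- factor(rep(c("lo", "hi"), length.out = nrow(st)))
  fit <- cox_fit(st, c("score", "grade"))
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_true(all(td$hazard_ratio > 0))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})
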