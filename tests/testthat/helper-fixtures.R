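# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small but well-powered synthetic bundle used across module tests.
small_bundle <- function() {
  cached("small_bundle", function() {
    simulate_bundle(sim_config(
      n_cohorts = 3, n_genes = 500, n_samples = 120, module_size = 30,
      n_negative = 8, rho = 0.6, seed = 2024L
    ), n_decoy_sets = 20)
  })
}

# Evaluate expr after set.seed (tests may freely disturb the RNG).
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Tiny expression cohort with known values.
toy_cohort <- function() {
  m <- rbind(
    DRV = c(1, 2, 3, 4, 5, 6),
    G1  = c(1.1, 2.2, 2.9, 4.3, 4.8, 6.1),
    G2  = c(6, 5, 4, 3, 2, 1),
    G3  = c(2, 2, 2, 2, 2, 2),
    G4  = c(0.3, 2.8, 1.7, 0.9, 2.4, 1.1)
  )
  colnames(m) <- paste0("S", 1:6)
  expression_cohort(m, "toy")
}

# Definition-level Pearson oracle: centred cross-products, no stats:: shortcuts.
pearson_oracle <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), n - 2))
}

# Step-up BH oracle computed from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    idx <- ord[i]
    prev <- min(prev, m * p[idx] / i)
    q[idx] <- prev
  }
  q
}

# Brute-force running-sum oracle: recomputes the prefix sums at every
# position from the definition, O(N * |S|).
es_oracle <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene %in% gene_set
  n <- nrow(ranked)
  nh <- sum(hit)
  nr <- sum(abs(ranked$metric[hit])^weight)
  running <- numeric(n)
  for (i in seq_len(n)) {
    p_hit <- sum(abs(ranked$metric[seq_len(i)][hit[seq_len(i)]])^weight) / nr
    p_miss <- sum(!hit[seq_len(i)]) / (n - nh)
    running[i] <- p_hit - p_miss
  }
  # maximal absolute deviation; an exact positive/negative tie is positive
  es <- if (max(running) >= -min(running)) max(running) else min(running)
  list(es = es, running = running)
}

# Product-limit oracle by direct tabulation.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

# Newton-Raphson maximum partial likelihood for one covariate, no ties.
cox_oracle_beta <- function(time, event, x, tol = 1e-10) {
  beta <- 0
  for (it in 1:50) {
    u <- 0; info <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(beta * x[risk])
      xb <- sum(w * x[risk]) / sum(w)
      x2b <- sum(w * x[risk]^2) / sum(w)
      u <- u + x[i] - xb
      info <- info + (x2b - xb^2)
    }
    step <- u / info
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
wilcox_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
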