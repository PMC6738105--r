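#' Score a metagene over a gene list
#'
#' Summarises a gene list into one scalar per sample. The default `"zmean"`
#' mode z-scores each gene across the cohort's samples and averages the
#' z-scores per sample (robust to platform scale differences between
#' cohorts); `"rawmean"` averages the log2 values directly. Listed genes
#' absent from the cohort are ignored (all absent is fatal); zero-variance
#' genes are dropped with a warning in `"zmean"` mode; missing values among
#' the listed genes are fatal.
#'
#' @param cohort an [expression_cohort()].
#' @param gene_list character vector of gene identifiers (matched
#'   case-insensitively).
#' @param mode `"zmean"` (default) or `"rawmean"`.
#' @return tibble (`cohort_id`, `sample_id`, `score`) of class
#'   `metagene_score`.
#' @export
metagene_score <- function(cohort, gene_list, mode = c("zmean", "rawmean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "expression_cohort"))
  idx <- which(norm_gene(cohort$genes) %in% norm_gene(gene_list))
  if (!length(idx)) abort("none of the listed genes is present in the cohort.")
  m <- cohort$values[idx, , drop = FALSE]
  if (anyNA(m)) abort("missing values among the listed genes; metagene scoring requires complete rows.")
  if (mode == "zmean") {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      warn(sprintf("%d zero-variance gene(s) dropped from the metagene.", sum(sds == 0)))
      m <- m[sds > 0, , drop = FALSE]
      if (!nrow(m)) abort("all listed genes have zero variance.")
      sds <- sds[sds > 0]
    }
    m <- (m - rowMeans(m)) / sds
  }
  out <- tibble(
    cohort_id = cohort$cohort_id, sample_id = cohort$samples,
    score = unname(colMeans(m))
  )
  class(out) <- c("metagene_score", class(out))
  out
}

#' Median dichotomisation
#'
#' Splits scores at their median; scores strictly above the median are
#' `"high"`, scores at or below it (ties included) are `"low"`.
#'
#' @param scores numeric vector.
#' @return factor with levels `low`, `high`, same length as `scores`.
#' @export
dichotomize_median <- function(scores) {
  if (any(!is.finite(scores))) abort("scores must be finite.")
  med <- median(scores)
  lab <- ifelse(scores > med, "high", "low")
  if (all(lab == "low")) warn("all scores at or below the median; single group.")
  factor(lab, levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin tidy interface over [survival::survfit()]: returns the product-limit
#' curve per group as a tibble. With only censored observations the curve is
#' flat at 1.
#'
#' @param data survival tibble with `time` and `event` columns.
#' @param group optional name of a grouping column.
#' @return tibble of class `km_curve`: `group` (when given), `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(data, group = NULL) {
  stopifnot(all(c("time", "event") %in% names(data)))
  if (any(data$time < 0)) abort("survival times must be non-negative.")
  fit <- if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  } else {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~", group))
    survival::survfit(f, data = data)
  }
  out <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  if (!is.null(fit$strata)) {
    out$group <- rep(sub("^[^=]*=", "", names(fit$strata)), fit$strata)
    out <- select(out, "group", dplyr::everything())
  }
  class(out) <- c("km_curve", class(out))
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank test (via [survival::survdiff()]): at each distinct
#' event time the observed-minus-expected count for one group is accumulated
#' with its hypergeometric variance; the statistic is chi-squared on
#' `k - 1` degrees of freedom.
#'
#' @param data survival tibble with `time`, `event` and the grouping column.
#' @param group name of the grouping column (>= 2 non-empty groups).
#' @return tibble: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group = "group") {
  stopifnot(all(c("time", "event", group) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2) abort("log-rank needs at least two non-empty groups.")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~", group))
  sd <- survival::survdiff(f, data = data)
  df <- length(sd$n) - 1
  tibble(chisq = sd$chisq, df = df, p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood via [survival::coxph()] with Breslow tie
#' handling by default (Efron available). Continuous covariates (e.g. a
#' metagene score) are used as-is; categorical covariates enter through
#' indicator coding. Monotone-likelihood/separation (a coefficient running
#' away) and non-convergence are detected and raised as errors.
#'
#' @param data survival tibble with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `cox_fit` wrapping the [survival::coxph()] fit;
#'   use [tidy()] / [glance()] to extract coefficient and model summaries.
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) abort(sprintf("covariate(s) not in data: %s.", toString(miss)))
  if (sum(data$event) < 1) abort("need at least one event.")
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) abort(sprintf("covariate '%s' is constant.", cv))
  }
  f <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        abort(paste("monotone likelihood / non-convergence:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(abs(stats::coef(fit)) > 20)) {
    abort("monotone likelihood suspected: a coefficient diverged.")
  }
  structure(list(fit = fit, covariates = covariates, ties = ties), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit: %s ties, covariates: %s>\n", x$ties, toString(x$covariates)))
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x a `cox_fit`.
#' @param ... unused.
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    term = rownames(co), estimate = co[, "coef"],
    hazard_ratio = co[, "exp(coef)"], std_error = co[, "se(coef)"],
    statistic = co[, "z"], p_value = co[, "Pr(>|z|)"]
  )
}

#' @rdname cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  f <- x$fit
  tibble(
    n = f$n, n_event = f$nevent,
    loglik_null = f$loglik[1], loglik = f$loglik[2],
    concordance = unname(f$concordance["concordance"])
  )
}
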