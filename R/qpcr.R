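#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target - Ct_ref) - (Ct_target_ctrl - Ct_ref_ctrl)` and the
#' relative quantity is `2^(-ddCt)`: one extra cycle of the normalised target
#' in the treated sample halves its relative expression. Assumes 100%
#' amplification efficiency, the method's own assumption. All arguments are
#' vectorised.
#'
#' @param ct_target,ct_ref target and reference (e.g. beta-actin) Ct in the
#'   sample of interest.
#' @param ct_target_ctrl,ct_ref_ctrl the same two Ct values in the calibrator
#'   (control) sample.
#' @return relative expression (control = 1).
#' @export
ddct <- function(ct_target, ct_ref, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target, ct_ref, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) abort("all Ct values must be finite.")
  ddct <- (ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' ChIP-qPCR percent of input
#'
#' The input Ct is first adjusted for the input dilution
#' (`Ct_input - log2(1 / input_fraction)` gives the Ct the undiluted input
#' would have), then enrichment is `100 * 2^(adjusted_input - Ct_IP)`.
#' Vectorised over Ct values.
#'
#' @param ct_ip immunoprecipitate Ct.
#' @param ct_input input-chromatin Ct.
#' @param input_fraction fraction of chromatin kept as input, in (0, 1\].
#' @return percent of input (100 = all input recovered).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (any(!is.finite(c(ct_ip, ct_input)))) abort("Ct values must be finite.")
  assert_scalar_number(input_fraction, "input_fraction", upper = 1)
  if (input_fraction <= 0) abort("`input_fraction` must be in (0, 1].")
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}

#' Relative quantification over a tidy Ct table
#'
#' Technical replicates are averaged on the Ct scale before transformation.
#' Each condition is quantified relative to `control`.
#'
#' @param ct_table tibble with columns `sample_id`, `condition`, `ct_target`,
#'   `ct_ref`.
#' @param control label of the calibrator condition.
#' @return tibble: `condition`, `mean_ct_target`, `mean_ct_ref`,
#'   `relative_expression`.
#' @export
qpcr_relative <- function(ct_table, control) {
  stopifnot(all(c("condition", "ct_target", "ct_ref") %in% names(ct_table)))
  means <- ct_table |>
    group_by(.data$condition) |>
    summarise(
      mean_ct_target = mean(.data$ct_target),
      mean_ct_ref = mean(.data$ct_ref), .groups = "drop"
    )
  if (!control %in% means$condition) abort(sprintf("control condition '%s' absent.", control))
  ctrl <- filter(means, .data$condition == control)
  means |>
    mutate(relative_expression = ddct(
      .data$mean_ct_target, .data$mean_ct_ref,
      ctrl$mean_ct_target, ctrl$mean_ct_ref
    ))
}
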