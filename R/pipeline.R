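#' Two-stage dataset of standardized test statistics
#'
#' Container for the per-hypothesis sufficient statistics of a two-stage
#' design: the standardized first- and second-stage means and the per-stage
#' sample sizes. In simulated data the truth labels and effect means are
#' carried along so that error and power counts can be formed; for real data
#' they are absent. `z2` may be `NA` for hypotheses without second-stage data
#' (it is required only for selected hypotheses at analysis time).
#'
#' @param z1 Standardized first-stage means (length m, finite).
#' @param z2 Standardized second-stage means (length m, `NA` allowed).
#' @param n1,n2 Per-stage sample sizes (positive; scalar, shared by all
#'   hypotheses).
#' @param is_alternative Optional logical truth labels (length m).
#' @param mu Optional per-hypothesis means (0 for nulls).
#' @param ids Optional hypothesis identifiers; default `"H1" ... "Hm"`.
#'
#' @return A list of class `"two_stage_dataset"` with the fields above plus
#'   `m` and the information fraction `w1 = n1/(n1+n2)`.
#' @export
two_stage_dataset <- function(z1, z2, n1, n2, is_alternative = NULL,
                              mu = NULL, ids = NULL) {
  m <- length(z1)
  stopifnot(is.numeric(z1), all(is.finite(z1)),
            is.numeric(z2), length(z2) == m,
            is.numeric(n1), length(n1) == 1L, n1 > 0,
            is.numeric(n2), length(n2) == 1L, n2 > 0)
  if (!is.null(is_alternative)) {
    stopifnot(is.logical(is_alternative), length(is_alternative) == m)
  }
  if (!is.null(mu)) stopifnot(is.numeric(mu), length(mu) == m)
  if (is.null(ids)) ids <- paste0("H", seq_len(m))
  stopifnot(length(ids) == m, !anyDuplicated(ids))
  structure(
    list(m = m, ids = as.character(ids), z1 = z1, z2 = z2, n1 = n1, n2 = n2,
         w1 = n1 / (n1 + n2), is_alternative = is_alternative, mu = mu),
    class = "two_stage_dataset"
  )
}

#' @export
print.two_stage_dataset <- function(x, ...) {
  cat(sprintf(
    "Two-stage dataset: m = %d hypotheses, n1 = %g, n2 = %g (w1 = %.3f)%s\n",
    x$m, x$n1, x$n2, x$w1,
    if (!is.null(x$is_alternative))
      sprintf(", %d alternatives", sum(x$is_alternative)) else ""))
  invisible(x)
}

new_final_analysis <- function(approach, data, selection, p, rejected, alpha) {
  R <- length(rejected)
  V <- S <- NA_integer_
  if (!is.null(data$is_alternative)) {
    S <- sum(data$is_alternative[rejected])
    V <- R - S
  }
  structure(
    list(approach = approach, alpha = alpha, m = data$m,
         final_p = p, rejected = rejected,
         R = R, V = V, S = S,
         m2 = selection$m2, gamma1_effective = selection$gamma1_effective,
         stopped = selection$stopped, selection = selection),
    class = "final_analysis"
  )
}

#' @export
print.final_analysis <- function(x, ...) {
  cat(sprintf("Two-stage %s analysis: m = %d, m2 = %d, R = %d%s%s\n",
              x$approach, x$m, x$m2, x$R,
              if (!is.na(x$V)) sprintf(" (V = %d, S = %d)", x$V, x$S) else "",
              if (x$stopped) ", stopped at interim" else ""))
  invisible(x)
}

check_stage2 <- function(data, selection) {
  miss <- selection$selected & !is.finite(data$z2)
  if (any(miss)) {
    stop(sprintf(
      "missing second-stage statistic for selected hypothesis: %s",
      paste(data$ids[miss], collapse = ", ")), call. = FALSE)
  }
}

#' Integrated two-stage analysis
#'
#' Runs the full integrated testing procedure: first-stage p-values, interim
#' selection by `rule`, sequential p-values for all m hypotheses (the
#' effective boundary of the rule for selected hypotheses, the first-stage
#' p-value for the rest), and the BH procedure at level `alpha` on all m
#' sequential p-values. Hypotheses not selected at the interim analysis can
#' still be rejected through their first-stage p-value. A stopped FDRS trial
#' returns zero rejections (BH at `alpha` rejects a subset of BH at
#' `alpha1 >= alpha` on the same p-values, which rejected nothing).
#'
#' @param data A [two_stage_dataset()].
#' @param rule A [selection_rule()].
#' @param alpha Overall FDR level.
#' @param settings Integration settings, see [quad_settings()].
#'
#' @return A `"final_analysis"` with the sequential p-values (length m),
#'   rejection indices and the counts R (and V, S when truth labels exist).
#' @export
run_integrated <- function(data, rule, alpha = 0.05,
                           settings = quad_settings()) {
  stopifnot(inherits(data, "two_stage_dataset"))
  p1 <- two_sided_p_from_z(data$z1)
  sel <- apply_selection(p1, rule)
  if (sel$stopped) {
    return(new_final_analysis("integrated", data, sel, p1, integer(0), alpha))
  }
  check_stage2(data, sel)
  z_pooled <- sqrt(data$w1) * data$z1 + sqrt(1 - data$w1) * data$z2
  p <- sequential_p_all(data$z1, z_pooled, data$w1, sel$gamma1_effective,
                        sel$selected, settings)
  bh <- bh_stepup(p, alpha)
  new_final_analysis("integrated", data, sel, p, bh$rejected, alpha)
}

#' Pilot two-stage analysis
#'
#' Final test on second-stage data only: the BH procedure is applied to the
#' two-sided second-stage p-values of the selected hypotheses. For the
#' FDR-threshold rule the improved nominal level `alpha/alpha1` (capped at 1)
#' is used, which still controls the FDR at `Pi0 * alpha` given the interim
#' selection at level `alpha1`; the other rules test at `alpha`. Non-selected
#' hypotheses can never be rejected.
#'
#' @inheritParams run_integrated
#'
#' @return A `"final_analysis"`; `final_p` holds the second-stage p-values of
#'   the `m2` selected hypotheses (named by hypothesis id).
#' @export
run_pilot <- function(data, rule, alpha = 0.05) {
  stopifnot(inherits(data, "two_stage_dataset"))
  p1 <- two_sided_p_from_z(data$z1)
  sel <- apply_selection(p1, rule)
  if (sel$stopped || sel$m2 == 0L) {
    return(new_final_analysis("pilot", data, sel, numeric(0), integer(0),
                              alpha))
  }
  check_stage2(data, sel)
  level <- if (rule$kind == "fdrs") min(alpha / rule$alpha1, 1) else alpha
  idx <- which(sel$selected)
  p2 <- two_sided_p_from_z(data$z2[idx])
  names(p2) <- data$ids[idx]
  bh <- bh_stepup(p2, level)
  new_final_analysis("pilot", data, sel, p2, idx[bh$rejected], alpha)
}

#' Single-stage baseline analysis
#'
#' BH procedure at level `alpha` on the two-sided p-values of a vector of
#' standardized means; the baseline a two-stage design is compared against
#' (with either the first-stage or the total sample size per hypothesis).
#'
#' @param z Standardized means, one per hypothesis.
#' @param alpha FDR level.
#' @param is_alternative Optional truth labels for V/S bookkeeping.
#'
#' @return A `"final_analysis"` with approach `"single_stage"`.
#' @export
run_single_stage <- function(z, alpha = 0.05, is_alternative = NULL) {
  p <- two_sided_p_from_z(z)
  bh <- bh_stepup(p, alpha)
  data <- list(m = length(z), is_alternative = is_alternative)
  sel <- new_interim_selection(rep(FALSE, length(z)), NA_real_, FALSE)
  new_final_analysis("single_stage", data, sel, p, bh$rejected, alpha)
}
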