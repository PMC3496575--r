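#' Interim selection rule
#'
#' Constructs and validates one of the three interim selection rules of a
#' two-stage screening design:
#' \describe{
#'   \item{`fixed_threshold`}{select every hypothesis with first-stage
#'     p-value at or below a pre-fixed boundary `gamma1`.}
#'   \item{`fns`}{fixed-number selection: select the `m2` hypotheses with the
#'     smallest first-stage p-values.}
#'   \item{`fdrs`}{FDR-threshold selection: select the rejections of the
#'     Benjamini-Hochberg procedure at an interim level `alpha1` larger than
#'     the overall level; if none is rejected the whole experiment stops for
#'     futility (probability \eqn{1 - \alpha_1} under the global null).}
#' }
#'
#' For `fdrs`, `ms` activates the modification that floors the effective
#' integrated-analysis boundary at the `ms`-smallest first-stage p-value,
#' repairing the FDR inflation seen when very few hypotheses are selected;
#' `ms = 6` controls the FDR across the simulated scenario battery and is the
#' default, `ms = 0` disables the floor.
#'
#' @param kind One of `"fixed_threshold"`, `"fns"`, `"fdrs"`.
#' @param gamma1 Selection boundary in `(0, 1)` (`fixed_threshold` only).
#' @param m2 Number of hypotheses to carry to stage 2 (`fns` only).
#' @param alpha1 Interim BH level in `(0, 1)` (`fdrs` only).
#' @param ms Non-negative integer floor parameter (`fdrs` only).
#' @param alpha Overall FDR level the rule will be used with; supplied so the
#'   `fdrs` requirement `alpha1 > alpha` can be checked at construction time.
#'
#' @return A list of class `"selection_rule"`.
#' @export
selection_rule <- function(kind = c("fixed_threshold", "fns", "fdrs"),
                           gamma1 = NULL, m2 = NULL, alpha1 = NULL, ms = 6L,
                           alpha = 0.05) {
  kind <- match.arg(kind)
  rule <- switch(kind,
    fixed_threshold = {
      if (is.null(gamma1) || !is.numeric(gamma1) || length(gamma1) != 1L ||
            gamma1 <= 0 || gamma1 >= 1) {
        stop("fixed_threshold rule needs `gamma1` in (0, 1)", call. = FALSE)
      }
      list(kind = kind, gamma1 = gamma1)
    },
    fns = {
      if (is.null(m2) || !is.numeric(m2) || length(m2) != 1L || m2 < 1 ||
            m2 != round(m2)) {
        stop("fns rule needs a positive integer `m2`", call. = FALSE)
      }
      list(kind = kind, m2 = as.integer(m2))
    },
    fdrs = {
      if (is.null(alpha1) || !is.numeric(alpha1) || length(alpha1) != 1L ||
            alpha1 <= 0 || alpha1 >= 1) {
        stop("fdrs rule needs `alpha1` in (0, 1)", call. = FALSE)
      }
      if (alpha1 <= alpha) {
        stop(sprintf(
          "fdrs requires an interim level above the overall level (alpha1 = %g <= alpha = %g)",
          alpha1, alpha), call. = FALSE)
      }
      if (!is.numeric(ms) || length(ms) != 1L || ms < 0 || ms != round(ms)) {
        stop("`ms` must be a non-negative integer", call. = FALSE)
      }
      list(kind = kind, alpha1 = alpha1, ms = as.integer(ms))
    })
  structure(rule, class = "selection_rule")
}

#' @export
print.selection_rule <- function(x, ...) {
  desc <- switch(x$kind,
    fixed_threshold = sprintf("fixed threshold gamma1 = %g", x$gamma1),
    fns = sprintf("fixed-number selection, m2 = %d", x$m2),
    fdrs = sprintf("FDR-threshold selection, alpha1 = %g, ms = %d",
                   x$alpha1, x$ms))
  cat("Interim selection rule:", desc, "\n")
  invisible(x)
}

new_interim_selection <- function(selected, gamma1_effective, stopped) {
  structure(
    list(selected = selected, m2 = sum(selected),
         gamma1_effective = gamma1_effective, stopped = stopped),
    class = "interim_selection"
  )
}

#' @export
print.interim_selection <- function(x, ...) {
  cat(sprintf(
    "Interim selection: m2 = %d of %d selected, gamma1_effective = %.4g%s\n",
    x$m2, length(x$selected), x$gamma1_effective,
    if (x$stopped) ", experiment stopped" else ""))
  invisible(x)
}

#' Selection by a pre-fixed p-value boundary
#'
#' Selects every hypothesis whose first-stage p-value is at most `gamma1`.
#' The number selected is random; an empty selection does not stop the design.
#'
#' @param p1 First-stage two-sided p-values.
#' @param gamma1 Selection boundary in `(0, 1)`.
#'
#' @return An `"interim_selection"`: logical mask `selected`, count `m2`,
#'   `gamma1_effective` (here the input boundary) and the `stopped` flag
#'   (always `FALSE` for this rule).
#' @export
select_fixed_threshold <- function(p1, gamma1) {
  stopifnot(is.numeric(p1), length(p1) > 0, all(p1 > 0), all(p1 <= 1))
  if (gamma1 <= 0 || gamma1 >= 1) {
    stop("`gamma1` must be in (0, 1)", call. = FALSE)
  }
  new_interim_selection(p1 <= gamma1, gamma1, stopped = FALSE)
}

#' Fixed-number selection (FNS)
#'
#' Selects exactly `m2` hypotheses with the smallest first-stage p-values;
#' boundary ties are broken by the stable hypothesis order so the count is
#' deterministic. The effective boundary for the integrated analysis is the
#' largest selected p-value \eqn{p_{(m_2)}}.
#'
#' @param p1 First-stage two-sided p-values.
#' @param m2 Number of hypotheses to select, between 1 and `length(p1)`.
#'
#' @return An `"interim_selection"` with `m2` selected hypotheses and
#'   `gamma1_effective = ` largest selected p-value.
#' @export
select_top_k <- function(p1, m2) {
  stopifnot(is.numeric(p1), length(p1) > 0, all(p1 > 0), all(p1 <= 1))
  m <- length(p1)
  if (!is.numeric(m2) || length(m2) != 1L || m2 < 1 || m2 > m ||
        m2 != round(m2)) {
    stop(sprintf("`m2` must be an integer in [1, %d]", m), call. = FALSE)
  }
  keep <- order(p1)[seq_len(m2)]   # order() is stable: ties by original index
  selected <- logical(m)
  selected[keep] <- TRUE
  new_interim_selection(selected, max(p1[keep]), stopped = FALSE)
}

#' FDR-threshold selection (FDRS)
#'
#' Selects the hypotheses rejected by the Benjamini-Hochberg procedure at the
#' interim level `alpha1`. If nothing is rejected the experiment stops for
#' futility. Otherwise the effective boundary for the integrated analysis is
#' \eqn{\gamma_1 = m_2 \alpha_1 / m}, floored (when `ms > 0`) at the
#' `ms`-smallest first-stage p-value. The floor only raises the boundary used
#' by the sequential p-value; it never enlarges the selection itself, so
#' hypotheses ranked between `m2 + 1` and `ms` still have no second-stage
#' data and keep their first-stage p-value.
#'
#' @param p1 First-stage two-sided p-values.
#' @param alpha1 Interim BH level in `(0, 1)`.
#' @param ms Non-negative integer; `0` disables the floor.
#'
#' @return An `"interim_selection"`; `stopped` is `TRUE` exactly when the
#'   interim BH procedure rejects nothing.
#' @export
select_fdrs <- function(p1, alpha1, ms = 6L) {
  stopifnot(is.numeric(p1), length(p1) > 0, all(p1 > 0), all(p1 <= 1))
  if (!is.numeric(alpha1) || length(alpha1) != 1L || alpha1 <= 0 || alpha1 >= 1) {
    stop("`alpha1` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(ms) || length(ms) != 1L || ms < 0 || ms != round(ms)) {
    stop("`ms` must be a non-negative integer", call. = FALSE)
  }
  m <- length(p1)
  bh <- bh_stepup(p1, alpha1)
  if (bh$d == 0L) {
    return(new_interim_selection(logical(m), gamma1_effective = NA_real_,
                                 stopped = TRUE))
  }
  selected <- logical(m)
  selected[bh$rejected] <- TRUE
  m2 <- sum(selected)
  gamma1 <- m2 * alpha1 / m
  if (ms > 0L) {
    gamma1 <- max(gamma1, sort(p1, partial = min(ms, m))[min(ms, m)])
  }
  new_interim_selection(selected, min(gamma1, 1), stopped = FALSE)
}

#' Apply a selection rule to first-stage p-values
#'
#' Dispatcher used by the analysis pipeline.
#'
#' @param p1 First-stage two-sided p-values.
#' @param rule A [selection_rule()].
#'
#' @return An `"interim_selection"`.
#' @export
apply_selection <- function(p1, rule) {
  stopifnot(inherits(rule, "selection_rule"))
  switch(rule$kind,
    fixed_threshold = select_fixed_threshold(p1, rule$gamma1),
    fns = select_top_k(p1, rule$m2),
    fdrs = select_fdrs(p1, rule$alpha1, rule$ms))
}
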