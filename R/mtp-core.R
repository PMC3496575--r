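#' Two-sided p-value of a standardized normal statistic
#'
#' Converts z-statistics (standardized means with known variance) into
#' two-sided p-values \eqn{p = 2(1 - \Phi(|z|))}.
#'
#' @param z Numeric vector of standardized test statistics. Must be finite.
#'
#' @return Numeric vector of p-values in `(0, 1]`. Values are floored at
#'   `1e-300` so that downstream quantile transforms (`qnorm`) stay finite.
#'
#' @examples
#' two_sided_p_from_z(0)          # 1
#' two_sided_p_from_z(1.959964)   # ~0.05
#' @export
two_sided_p_from_z <- function(z) {
  if (!is.numeric(z) || length(z) == 0L) {
    stop("`z` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(z))) {
    stop("`z` contains non-finite values", call. = FALSE)
  }
  pmax(2 * stats::pnorm(-abs(z)), 1e-300)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Applies the step-up multiple test that rejects all hypotheses with p-value
#' at or below \eqn{d\alpha/m}, where \eqn{d = \max\{i : p_{(i)} \le
#' i\alpha/m\}} (and \eqn{d = 0}, no rejections, if the set is empty).
#' Hypotheses tied at the rejection boundary are rejected together: the
#' rejection set is defined by the threshold, not by rank.
#'
#' @param p Numeric vector of p-values in `(0, 1]`, one per hypothesis.
#' @param alpha Nominal FDR level, a single number in `(0, 1)`.
#'
#' @return An object of class `"bh_result"`: a list with elements
#'   \describe{
#'     \item{d}{index of the largest ordered p-value passing its step
#'       threshold (0 if none),}
#'     \item{rejected}{integer indices of rejected hypotheses,}
#'     \item{threshold}{the rejection threshold \eqn{d\alpha/m} (0 if
#'       `d == 0`),}
#'     \item{alpha, m}{the inputs.}
#'   }
#'
#' @examples
#' bh_stepup(c(0.01, 0.02, 0.9), alpha = 0.05)   # rejects the two smallest
#' bh_stepup(c(0.04, 0.049, 0.05), alpha = 0.05) # step-up catch-up: all three
#' @export
bh_stepup <- function(p, alpha) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop("`p` must be a non-empty numeric p-value vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  m <- length(p)
  ord <- sort(p)
  pass <- which(ord <= seq_len(m) * alpha / m)
  d <- if (length(pass)) max(pass) else 0L
  threshold <- d * alpha / m
  rejected <- if (d > 0L) which(p <= threshold) else integer(0)
  structure(
    list(d = d, rejected = rejected, threshold = threshold,
         alpha = alpha, m = m),
    class = "bh_result"
  )
}

#' @export
print.bh_result <- function(x, ...) {
  cat(sprintf(
    "Benjamini-Hochberg step-up: m = %d, alpha = %g, d = %d, %d rejection(s)\n",
    x$m, x$alpha, x$d, length(x$rejected)))
  invisible(x)
}

#' t-test p-value for raw-data mode
#'
#' Two-sided t-test p-value used when per-observation data rather than
#' known-variance z-statistics are supplied: one-sample against 0 when `y` is
#' absent, two-sample with equal variances otherwise. Downstream sequential
#' p-value computations treat the implied \eqn{|z| = \Phi^{-1}(1 - p/2)} as
#' normal, i.e. the known-variance critical values are applied to the t-test
#' p-value.
#'
#' @param x Numeric vector of observations (first group).
#' @param y Optional numeric vector for the second group.
#'
#' @return A single two-sided p-value in `(0, 1]`.
#' @export
p_from_samples_tapprox <- function(x, y = NULL) {
  check_group <- function(v, label) {
    if (!is.numeric(v) || length(v) < 2L || any(!is.finite(v))) {
      stop(sprintf("%s must contain at least 2 finite observations", label),
           call. = FALSE)
    }
    if (stats::var(v) <= 0) {
      stop(sprintf("%s has zero variance", label), call. = FALSE)
    }
  }
  check_group(x, "`x`")
  if (is.null(y)) {
    ht <- stats::t.test(x, mu = 0)
  } else {
    check_group(y, "`y`")
    ht <- stats::t.test(x, y, var.equal = TRUE)
  }
  max(unname(ht$p.value), 1e-300)
}
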