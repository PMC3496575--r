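# Two-sided sequential p-values for a two-stage design with interim selection.
#
# For a hypothesis selected at the interim analysis (first-stage p-value
# p1 <= gamma1), the sequential p-value is the null probability
#   P( {|Z| >= |z|} and {|Z1| >= c_{1 - gamma1/2}} ),
# where Z1 is the standardized first-stage mean and Z the standardized overall
# mean of both stages. Under the null, (Z1, Z) is bivariate normal with
# correlation sqrt(w1), w1 = n1/(n1+n2), so conditionally on Z1 = x the pooled
# statistic is N(sqrt(w1) x, 1 - w1) and the probability is the sum of four
# one-dimensional normal integrals over the selection region |Z1| >= c.
# Non-selected hypotheses (p1 > gamma1) keep their first-stage p-value.

#' Numerical integration settings for sequential p-values
#'
#' @param abs_tol Absolute tolerance of the adaptive quadrature (reference
#'   path). Default `1e-10`, far below the Monte-Carlo resolution of any
#'   validation test.
#' @param tail_cut Truncation bound for the infinite integration limits; the
#'   standard normal density is below `1e-16` beyond `|z| = 8.5`.
#' @param nodes Number of Gauss-Legendre nodes of the vectorized batch path.
#'
#' @return A list of class `"quad_settings"`.
#' @export
quad_settings <- function(abs_tol = 1e-10, tail_cut = 8.5, nodes = 96L) {
  stopifnot(is.numeric(abs_tol), abs_tol > 0,
            is.numeric(tail_cut), tail_cut >= 8,
            is.numeric(nodes), nodes >= 16)
  structure(list(abs_tol = abs_tol, tail_cut = tail_cut,
                 nodes = as.integer(nodes)),
            class = "quad_settings")
}

#' Pooled two-stage test statistic
#'
#' Bundles the standardized first-stage mean, the standardized overall mean
#' of both stages, and the information fraction \eqn{w_1 = n_1/(n_1+n_2)}
#' (equivalently the squared correlation between the two; for non-normal
#' endpoints the correlation parameter of the asymptotic joint law may be
#' passed directly).
#'
#' @param z1 Standardized first-stage mean.
#' @param z2 Standardized second-stage mean (stage 2 only). Exactly one of
#'   `z2` and `z_pooled` must be given.
#' @param info_fraction First-stage information fraction in `(0, 1)`.
#' @param z_pooled Standardized overall mean; when omitted it is assembled as
#'   \eqn{\sqrt{w_1} z_1 + \sqrt{1-w_1} z_2}.
#'
#' @return A list of class `"pooled_statistic"` with elements `z1`,
#'   `z_pooled`, `info_fraction`.
#' @export
pooled_statistic <- function(z1, z2 = NULL, info_fraction, z_pooled = NULL) {
  stopifnot(is.numeric(z1), all(is.finite(z1)),
            is.numeric(info_fraction), length(info_fraction) == 1L,
            info_fraction > 0, info_fraction < 1)
  if (is.null(z_pooled) == is.null(z2)) {
    stop("supply exactly one of `z2` and `z_pooled`", call. = FALSE)
  }
  if (is.null(z_pooled)) {
    z_pooled <- sqrt(info_fraction) * z1 + sqrt(1 - info_fraction) * z2
  }
  stopifnot(is.numeric(z_pooled), all(is.finite(z_pooled)),
            length(z_pooled) == length(z1))
  structure(list(z1 = z1, z_pooled = z_pooled, info_fraction = info_fraction),
            class = "pooled_statistic")
}

# Gauss-Legendre nodes on [-1, 1], cached per order.
.gl_env <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_env[[key]])) {
    .gl_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gl_env[[key]]
}

# One tail of the selection region: integral over x in [lo, hi] of
#   [ P(Z >= |z|  | Z1 = x) + P(Z <= -|z| | Z1 = x) ] phi(x) dx
# with Z | Z1 = x ~ N(a, b^2), a = sqrt(w1) x, b = sqrt(1 - w1).
seq_p_integrand <- function(x, z_abs, w1, sign = 1) {
  a <- sign * sqrt(w1) * x
  b <- sqrt(1 - w1)
  (stats::pnorm((z_abs - a) / b, lower.tail = FALSE) +
     stats::pnorm((-z_abs - a) / b)) * stats::dnorm(x)
}

# Reference path: adaptive quadrature, one hypothesis at a time.
seq_p_quadrature <- function(z_abs, gamma1, w1, settings = quad_settings()) {
  cc <- stats::qnorm(1 - gamma1 / 2)
  upper <- max(settings$tail_cut, cc + 1)
  terms <- lapply(c(1, -1), function(s) {
    stats::integrate(seq_p_integrand, lower = cc, upper = upper,
                     z_abs = z_abs, w1 = w1, sign = s,
                     abs.tol = settings$abs_tol, rel.tol = settings$abs_tol,
                     stop.on.error = FALSE)
  })
  msgs <- vapply(terms, `[[`, "", "message")
  if (!all(msgs %in% c("OK", "roundoff error was detected"))) {
    stop(sprintf(
      "sequential p-value integration failed (z = %g, gamma1 = %g, w1 = %g): %s",
      z_abs, gamma1, w1, paste(unique(msgs), collapse = "; ")), call. = FALSE)
  }
  min(max(sum(vapply(terms, `[[`, 0, "value")), 1e-300), 1)
}

# Batch path: fixed-order Gauss-Legendre on [c, tail_cut], vectorized over
# hypotheses. The lower tail (-Inf, -c] is folded in by the sign symmetry of
# the integrand (substituting x -> -x flips the sign of a).
seq_p_batch <- function(z_abs, gamma1, w1, settings = quad_settings()) {
  if (!length(z_abs)) return(numeric(0))
  cc <- stats::qnorm(1 - gamma1 / 2)
  upper <- max(settings$tail_cut, cc + 1)
  gl <- gl_nodes(settings$nodes)
  half <- (upper - cc) / 2
  x <- cc + half * (gl$x + 1)
  wq <- gl$w * half * stats::dnorm(x)
  a <- sqrt(w1) * x
  b <- sqrt(1 - w1)
  up <- outer(z_abs, a, "-") / b    # (|z| - a)/b over hypotheses x nodes
  lo <- outer(-z_abs, a, "-") / b
  um <- outer(z_abs, -a, "-") / b   # mirrored tail, a -> -a
  lm <- outer(-z_abs, -a, "-") / b
  vals <- (stats::pnorm(up, lower.tail = FALSE) + stats::pnorm(lo) +
             stats::pnorm(um, lower.tail = FALSE) + stats::pnorm(lm)) %*% wq
  pmin(pmax(as.numeric(vals), 1e-300), 1)
}

#' Two-sided sequential p-value of one hypothesis
#'
#' Computes the sequential p-value of a two-stage design by the stage-wise
#' ordering of the sample space: if the first-stage p-value exceeds the
#' selection boundary `gamma1` it is returned unchanged; otherwise the joint
#' null probability of \{pooled statistic at least as extreme\} and
#' \{first-stage statistic inside the selection region\} is evaluated by
#' adaptive numerical integration.
#'
#' @param stat A [pooled_statistic()] holding scalar `z1`, `z_pooled` and the
#'   information fraction.
#' @param gamma1 Interim selection boundary for first-stage p-values, in
#'   `(0, 1)`.
#' @param settings Integration settings, see [quad_settings()].
#'
#' @return A single p-value in `(0, 1]`. Under a fixed `gamma1` the sequential
#'   p-value is uniformly distributed under the null hypothesis.
#' @export
sequential_p <- function(stat, gamma1, settings = quad_settings()) {
  stopifnot(inherits(stat, "pooled_statistic"),
            length(stat$z1) == 1L)
  if (!is.numeric(gamma1) || length(gamma1) != 1L || gamma1 <= 0 || gamma1 >= 1) {
    stop("`gamma1` must be a single number in (0, 1)", call. = FALSE)
  }
  p1 <- two_sided_p_from_z(stat$z1)
  if (p1 > gamma1) {
    return(p1)
  }
  seq_p_quadrature(abs(stat$z_pooled), gamma1, stat$info_fraction, settings)
}

#' Sequential p-values for a vector of hypotheses
#'
#' Vectorized form used by the analysis pipeline: selected hypotheses receive
#' the integrated sequential p-value at the common boundary `gamma1`;
#' non-selected hypotheses keep their first-stage two-sided p-value. The
#' selection mask is passed explicitly because data-dependent rules
#' (fixed-number and FDR-threshold selection with the m_s modification) may
#' raise the effective `gamma1` above the p-value of some non-selected
#' hypotheses.
#'
#' @param z1 Standardized first-stage means (length m).
#' @param z_pooled Standardized overall means (length m; needed only where
#'   `selected` is `TRUE`, may be `NA` elsewhere).
#' @param info_fraction First-stage information fraction in `(0, 1)`.
#' @param gamma1 Effective selection boundary in `(0, 1)`.
#' @param selected Logical mask of hypotheses selected for the second stage.
#' @param settings Integration settings, see [quad_settings()].
#' @param method `"batch"` (vectorized fixed-order Gauss-Legendre quadrature,
#'   default) or `"reference"` (per-hypothesis adaptive quadrature). The two
#'   agree to within `1e-8`.
#'
#' @return Numeric vector of p-values in `(0, 1]`, length m.
#' @export
sequential_p_all <- function(z1, z_pooled, info_fraction, gamma1, selected,
                             settings = quad_settings(),
                             method = c("batch", "reference")) {
  method <- match.arg(method)
  m <- length(z1)
  stopifnot(length(selected) == m, is.logical(selected))
  if (!is.numeric(gamma1) || length(gamma1) != 1L || gamma1 <= 0 || gamma1 > 1) {
    stop("`gamma1` must be a single number in (0, 1]", call. = FALSE)
  }
  p <- two_sided_p_from_z(z1)
  if (any(selected)) {
    zsel <- z_pooled[selected]
    if (any(!is.finite(zsel))) {
      stop("pooled statistic missing for a selected hypothesis", call. = FALSE)
    }
    p[selected] <- if (method == "batch") {
      seq_p_batch(abs(zsel), gamma1, info_fraction, settings)
    } else {
      vapply(abs(zsel), seq_p_quadrature, 0, gamma1 = gamma1,
             w1 = info_fraction, settings = settings)
    }
  }
  p
}

#' Monte-Carlo oracle for the sequential p-value
#'
#' Estimates \eqn{P(\{|Z| \ge z\} \cap \{|Z_1| \ge c_{1-\gamma_1/2}\})} under
#' the null by direct simulation of the bivariate normal pair
#' \eqn{(Z_1, Z)}, \eqn{Z = \sqrt{w_1} Z_1 + \sqrt{1-w_1} Z_2}. Used only to
#' validate the quadrature; it is never on the analysis path.
#'
#' @param z_abs Absolute pooled statistic (scalar).
#' @param gamma1 Selection boundary in `(0, 1)`.
#' @param info_fraction First-stage information fraction.
#' @param n_sim Number of simulated null pairs.
#'
#' @return A list with the estimate `p` and its binomial standard error `se`.
#' @export
sequential_p_mc <- function(z_abs, gamma1, info_fraction, n_sim = 1e6) {
  stopifnot(z_abs >= 0, gamma1 > 0, gamma1 < 1, n_sim >= 1e3)
  cc <- stats::qnorm(1 - gamma1 / 2)
  # blockwise to bound memory at large n_sim
  block <- 1e6
  hits <- 0
  done <- 0
  while (done < n_sim) {
    nb <- min(block, n_sim - done)
    zz1 <- stats::rnorm(nb)
    zz <- sqrt(info_fraction) * zz1 + sqrt(1 - info_fraction) * stats::rnorm(nb)
    hits <- hits + sum(abs(zz) >= z_abs & abs(zz1) >= cc)
    done <- done + nb
  }
  p <- hits / n_sim
  list(p = p, se = sqrt(p * (1 - p) / n_sim))
}
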