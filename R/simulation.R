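# Monte-Carlo engine: generates two-stage datasets of standardized test
# statistics under configurable correlation structures and estimates the
# realized FDR and the mean number of rejected alternatives.

#' Simulation scenario configuration
#'
#' Collects all design and simulation parameters of one scenario. Stage means
#' are simulated directly as standardized normals (the z-test depends on the
#' data only through them): a null hypothesis has standard normal stage
#' statistics, an alternative with per-observation mean `delta` (unit
#' variance) has stage means `delta * sqrt(n_k)` plus noise. The `m1 = m -
#' round(m * pi0)` alternative positions are re-randomized every run, which
#' matters under correlation.
#'
#' Correlation structures (shared by both stages, independent across stages,
#' unit diagonal):
#' \describe{
#'   \item{`independent`}{identity.}
#'   \item{`auto`}{autoregressive, \eqn{\rho^{|i-j|}}, by the stationary
#'     recursive construction.}
#'   \item{`block`}{compound symmetry `rho` within consecutive blocks of
#'     `block_size` hypotheses, independence across blocks.}
#'   \item{`equi`}{compound symmetry `rho` between all pairs, one-factor
#'     construction \eqn{z_i = \sqrt{\rho} W + \sqrt{1-\rho}\,\epsilon_i}.}
#' }
#'
#' @param m Number of hypotheses.
#' @param pi0 Proportion of true nulls in `[0, 1]`.
#' @param delta Per-observation standardized effect size of the alternatives.
#' @param n1,n2 Per-stage sample sizes per hypothesis.
#' @param alpha Overall FDR level.
#' @param rule A [selection_rule()].
#' @param correlation One of `"independent"`, `"auto"`, `"block"`, `"equi"`.
#' @param rho Correlation coefficient in `[0, 1)`; 0 reduces every structure
#'   to independence.
#' @param block_size Block length for the block structure.
#' @param n_runs Number of Monte-Carlo replicates.
#' @param seed Base seed; run `i` uses a seed derived from `(seed, i)` so
#'   runs are order-independent and individually reproducible.
#'
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(m = 1000L, pi0 = 0.95, delta = 1, n1 = 3, n2 = 9,
                            alpha = 0.05,
                            rule = selection_rule("fns", m2 = 10L),
                            correlation = c("independent", "auto", "block",
                                            "equi"),
                            rho = 0, block_size = 20L, n_runs = 1000L,
                            seed = 1L) {
  correlation <- match.arg(correlation)
  stopifnot(is.numeric(m), m >= 2, m == round(m),
            is.numeric(pi0), pi0 >= 0, pi0 <= 1,
            is.numeric(delta), is.finite(delta),
            is.numeric(n1), n1 > 0, is.numeric(n2), n2 > 0,
            is.numeric(alpha), alpha > 0, alpha < 1,
            inherits(rule, "selection_rule"),
            is.numeric(rho), rho >= 0, rho < 1,
            is.numeric(block_size), block_size >= 1,
            is.numeric(n_runs), n_runs >= 1,
            is.numeric(seed), seed == round(seed))
  m <- as.integer(m)
  m0 <- as.integer(round(m * pi0))
  structure(
    list(m = m, pi0 = pi0, m0 = m0, m1 = m - m0, delta = delta,
         n1 = n1, n2 = n2, alpha = alpha, rule = rule,
         correlation = correlation, rho = rho,
         block_size = as.integer(block_size),
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: m = %d, pi0 = %g (m1 = %d), delta = %g, n1 = %g, n2 = %g, alpha = %g\n",
    x$m, x$pi0, x$m1, x$delta, x$n1, x$n2, x$alpha))
  print(x$rule)
  cat(sprintf("  correlation = %s (rho = %g), n_runs = %d, seed = %d\n",
              x$correlation, x$rho, x$n_runs, x$seed))
  invisible(x)
}

# one stage of correlated standard normal noise
simulate_noise <- function(m, correlation, rho, block_size) {
  if (rho == 0 || correlation == "independent") {
    return(stats::rnorm(m))
  }
  switch(correlation,
    equi = sqrt(rho) * stats::rnorm(1) + sqrt(1 - rho) * stats::rnorm(m),
    block = {
      nb <- ceiling(m / block_size)
      w <- rep(stats::rnorm(nb), each = block_size)[seq_len(m)]
      sqrt(rho) * w + sqrt(1 - rho) * stats::rnorm(m)
    },
    auto = {
      eps <- stats::rnorm(m)
      as.numeric(stats::filter(c(eps[1], sqrt(1 - rho^2) * eps[-1]),
                               rho, method = "recursive"))
    })
}

run_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(run_index)) %% 2147483647)
}

#' Generate one simulated two-stage dataset
#'
#' Draws the standardized stage means of one Monte-Carlo replicate of a
#' scenario. Alternatives receive mean `delta * sqrt(n_k)` at stage k; their
#' positions among the m hypotheses are drawn uniformly at random each run.
#'
#' @param config A [scenario_config()].
#' @param run_index Replicate number; together with `config$seed` it
#'   determines the RNG stream.
#'
#' @return A [two_stage_dataset()] with truth labels and means filled in.
#' @export
generate_dataset <- function(config, run_index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(run_seed(config$seed, run_index))
  m <- config$m
  mu <- numeric(m)
  if (config$m1 > 0) {
    mu[sample.int(m, config$m1)] <- config$delta
  }
  z1 <- simulate_noise(m, config$correlation, config$rho, config$block_size) +
    mu * sqrt(config$n1)
  z2 <- simulate_noise(m, config$correlation, config$rho, config$block_size) +
    mu * sqrt(config$n2)
  two_stage_dataset(z1, z2, config$n1, config$n2,
                    is_alternative = mu != 0, mu = mu)
}

summarize_runs <- function(stats_mat, m1, n_runs) {
  fdp <- stats_mat["V", ] / pmax(stats_mat["R", ], 1)
  S <- stats_mat["S", ]
  se <- function(x) if (n_runs > 1) stats::sd(x) / sqrt(n_runs) else NA_real_
  list(fdr_hat = mean(fdp), fdr_se = se(fdp),
       mean_S = mean(S), s_se = se(S),
       mean_R = mean(stats_mat["R", ]),
       mean_m2 = mean(stats_mat["m2", ]),
       stop_rate = mean(stats_mat["stopped", ]),
       n_runs = n_runs, m1 = m1)
}

#' Run a simulation scenario
#'
#' Generates `config$n_runs` replicate datasets and runs the requested
#' two-stage analyses on each, accumulating the rejection counts. With
#' `approach = "both"` the integrated and pilot analyses are applied to the
#' same datasets (common random numbers), which makes their power difference
#' a paired estimate.
#'
#' @param config A [scenario_config()].
#' @param approach `"integrated"`, `"pilot"` or `"both"`.
#' @param settings Integration settings for the sequential p-values.
#' @param keep_runs If `TRUE`, attach the per-run count matrices.
#'
#' @return An object of class `"simulation_summary"`: per approach the
#'   Monte-Carlo estimates `fdr_hat` (mean of V/max(R,1)) and `mean_S` (mean
#'   rejected alternatives) with standard errors, plus `mean_m2`,
#'   `stop_rate`, and for `"both"` the paired percent improvement
#'   `100 * (mean_S_integrated / mean_S_pilot - 1)` with a delta-method SE.
#' @export
run_scenario <- function(config, approach = c("both", "integrated", "pilot"),
                         settings = quad_settings(), keep_runs = FALSE) {
  approach <- match.arg(approach)
  stopifnot(inherits(config, "scenario_config"))
  do_int <- approach %in% c("both", "integrated")
  do_pil <- approach %in% c("both", "pilot")
  n <- config$n_runs
  fields <- c("R", "V", "S", "m2", "stopped")
  res <- list(
    integrated = if (do_int) matrix(0, length(fields), n,
                                    dimnames = list(fields, NULL)),
    pilot = if (do_pil) matrix(0, length(fields), n,
                               dimnames = list(fields, NULL)))
  for (i in seq_len(n)) {
    data <- generate_dataset(config, i)
    if (do_int) {
      fa <- run_integrated(data, config$rule, config$alpha, settings)
      res$integrated[, i] <- c(fa$R, fa$V, fa$S, fa$m2, fa$stopped)
    }
    if (do_pil) {
      fa <- run_pilot(data, config$rule, config$alpha)
      res$pilot[, i] <- c(fa$R, fa$V, fa$S, fa$m2, fa$stopped)
    }
  }
  out <- list(config = config, approach = approach)
  if (do_int) out$integrated <- summarize_runs(res$integrated, config$m1, n)
  if (do_pil) out$pilot <- summarize_runs(res$pilot, config$m1, n)
  if (approach == "both") {
    si <- res$integrated["S", ]
    sp <- res$pilot["S", ]
    mi <- mean(si)
    mp <- mean(sp)
    out$improvement_pct <- if (mp > 0) 100 * (mi / mp - 1) else NA_real_
    out$improvement_se <- if (mp > 0 && n > 1) {
      # delta method for the ratio of paired means
      vr <- (stats::var(si) / mp^2 + mi^2 * stats::var(sp) / mp^4 -
               2 * mi * stats::cov(si, sp) / mp^3) / n
      100 * sqrt(max(vr, 0))
    } else NA_real_
  }
  if (keep_runs) out$runs <- res
  structure(out, class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  print(x$config)
  for (ap in c("integrated", "pilot")) {
    if (!is.null(x[[ap]])) {
      s <- x[[ap]]
      cat(sprintf(
        "  %-10s FDR = %.4f (se %.4f), mean S = %.2f (se %.2f), mean m2 = %.1f, stop rate = %.3f\n",
        ap, s$fdr_hat, s$fdr_se, s$mean_S, s$s_se, s$mean_m2, s$stop_rate))
    }
  }
  if (!is.null(x$improvement_pct)) {
    cat(sprintf("  integrated vs pilot improvement: %+.1f%% (se %.1f)\n",
                x$improvement_pct, x$improvement_se))
  }
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Convenience wrapper producing one summary row per scenario and approach.
#'
#' @param configs List of [scenario_config()] objects.
#' @param approach Passed to [run_scenario()].
#' @param settings Integration settings.
#'
#' @return A `data.frame` with the scenario parameters echoed and the
#'   Monte-Carlo summaries (`fdr_hat`, `fdr_se`, `mean_S`, `s_se`,
#'   `mean_m2`, `stop_rate`, and the paired `improvement_pct` on integrated
#'   rows when both approaches were run).
#' @export
run_grid <- function(configs, approach = "both", settings = quad_settings()) {
  stopifnot(length(configs) > 0)
  rows <- lapply(configs, function(cfg) {
    sm <- run_scenario(cfg, approach, settings)
    rule <- cfg$rule
    rule_params <- switch(rule$kind,
      fixed_threshold = sprintf("gamma1=%g", rule$gamma1),
      fns = sprintf("m2=%d", rule$m2),
      fdrs = sprintf("alpha1=%g,ms=%d", rule$alpha1, rule$ms))
    base <- data.frame(
      m = cfg$m, pi0 = cfg$pi0, delta = cfg$delta, n1 = cfg$n1, n2 = cfg$n2,
      alpha = cfg$alpha, rule = rule$kind, rule_params = rule_params,
      correlation = cfg$correlation, rho = cfg$rho, n_runs = cfg$n_runs,
      seed = cfg$seed, stringsAsFactors = FALSE)
    do.call(rbind, lapply(c("integrated", "pilot"), function(ap) {
      s <- sm[[ap]]
      if (is.null(s)) return(NULL)
      cbind(base, data.frame(
        approach = ap, fdr_hat = s$fdr_hat, fdr_se = s$fdr_se,
        mean_S = s$mean_S, s_se = s$s_se, mean_m2 = s$mean_m2,
        stop_rate = s$stop_rate,
        improvement_pct = if (ap == "integrated" &&
                                !is.null(sm$improvement_pct))
          sm$improvement_pct else NA_real_,
        stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
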