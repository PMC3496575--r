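# Run every test even when reproduction blocks fail.
options(testthat.progress.max_fails = 1000L)

# Brute-force BH oracle: test every candidate d from m down to 1 on the
# sorted p-values, then collect the rejection set from the threshold.
bh_brute_force <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  d <- 0L
  for (k in m:1) {
    if (ps[k] <= k * alpha / m) {
      d <- k
      break
    }
  }
  list(d = d, rejected = if (d > 0) which(p <= d * alpha / m) else integer(0))
}

# Small random p-value vectors that exercise ties and boundary cases.
random_p_vector <- function(n) {
  p <- switch(sample(3, 1),
              runif(n),
              rbeta(n, 0.3, 1),                # many small values
              round(runif(n), 2) + 1e-3)       # coarse grid -> frequent ties
  pmin(pmax(p, 1e-6), 1)
}

# Default scenario used by several pipeline tests.
test_scenario <- function(rule, ..., n_runs = 50, seed = 42) {
  scenario_config(m = 200L, pi0 = 0.9, delta = 1, n1 = 3, n2 = 9,
                  rule = rule, n_runs = n_runs, seed = seed, ...)
}
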