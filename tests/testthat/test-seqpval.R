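test_that("non-selected hypotheses keep their first-stage p-value", {
  stat <- pooled_statistic(z1 = 1, z2 = 2, info_fraction = 1 / 3)
  # p1 ~ 0.317 > gamma1 = 0.1, so the first-stage p-value passes through
  expect_equal(sequential_p(stat, gamma1 = 0.1), 2 * pnorm(-1))
})

test_that("as gamma1 approaches 1 the sequential p-value becomes the pooled fixed-sample p-value", {
  for (zp in c(0.5, 2, 3.5)) {
    stat <- pooled_statistic(z1 = 0.01, info_fraction = 1 / 3, z_pooled = zp)
    expect_equal(sequential_p(stat, gamma1 = 1 - 1e-12), 2 * pnorm(-zp),
                 tolerance = 1e-6)
  }
})

test_that("sequential p-values are sign-symmetric and in (0, 1]", {
  set.seed(5)
  for (i in 1:20) {
    z1 <- rnorm(1)
    zp <- rnorm(1, sd = 2)
    g <- runif(1, 0.01, 0.9)
    a <- sequential_p(pooled_statistic(z1 = z1, info_fraction = 0.3,
                                       z_pooled = zp), g)
    b <- sequential_p(pooled_statistic(z1 = -z1, info_fraction = 0.3,
                                       z_pooled = -zp), g)
    expect_equal(a, b)
    expect_gt(a, 0)
    expect_lte(a, 1)
  }
})

test_that("the sequential p-value decreases in the pooled statistic and never exceeds gamma1 when selected", {
  zs <- seq(0, 6, by = 0.25)
  for (g in c(0.05, 0.3)) {
    # z1 deep inside the selection region keeps every case on the
    # integrated branch
    p <- vapply(zs, function(z) {
      sequential_p(pooled_statistic(z1 = 10, info_fraction = 1 / 3,
                                    z_pooled = z), g)
    }, 0)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p <= g + 1e-12))   # joint event is inside the selection event
    expect_equal(p[1], g, tolerance = 1e-9)  # at z = 0 it is the whole selection event
  }
})

test_that("vectorized batch quadrature matches the adaptive reference path", {
  grid <- expand.grid(z = c(0, 0.7, 1.5, 2.5, 4, 6),
                      gamma1 = c(1e-4, 0.01, 0.1, 0.5, 0.9),
                      w1 = c(0.25, 1 / 3, 0.5))
  for (w1 in unique(grid$w1)) {
    for (g in unique(grid$gamma1)) {
      z <- grid$z[grid$w1 == w1 & grid$gamma1 == g]
      batch <- twostageFDR:::seq_p_batch(z, g, w1)
      ref <- vapply(z, twostageFDR:::seq_p_quadrature, 0, gamma1 = g, w1 = w1)
      expect_lt(max(abs(batch - ref)), 1e-8)
    }
  }
})

test_that("quadrature agrees with the frozen Monte-Carlo oracle fixture", {
  fixture <- read.delim(system.file("extdata", "seqp_oracle_fixture.tsv",
                                    package = "twostageFDR"))
  expect_gt(nrow(fixture), 20)
  for (i in seq_len(nrow(fixture))) {
    row <- fixture[i, ]
    p <- twostageFDR:::seq_p_quadrature(row$z_abs, row$gamma1, row$w1)
    expect_lt(abs(p - row$p_mc), 3 * row$mc_se)
    # the frozen quadrature column must still be what the code computes
    expect_equal(p, row$p_quad, tolerance = 1e-6)
  }
})

test_that("quadrature agrees with a live Monte-Carlo oracle", {
  set.seed(99)
  mc <- sequential_p_mc(2, 0.1, 1 / 3, n_sim = 1e6)
  p <- twostageFDR:::seq_p_quadrature(2, 0.1, 1 / 3)
  expect_lt(abs(p - mc$p), 3 * mc$se)
})

test_that("null sequential p-values under a fixed boundary are uniform", {
  set.seed(2718)
  m <- 1e4
  z1 <- rnorm(m)
  z2 <- rnorm(m)
  w1 <- 1 / 3
  zp <- sqrt(w1) * z1 + sqrt(1 - w1) * z2
  gamma1 <- 0.2
  p1 <- two_sided_p_from_z(z1)
  p <- sequential_p_all(z1, zp, w1, gamma1, selected = p1 <= gamma1)
  ks <- suppressWarnings(ks.test(p, "punif"))
  # 1% critical value of the Kolmogorov-Smirnov statistic at n = 1e4
  expect_lt(unname(ks$statistic), 1.628 / sqrt(m))
})

test_that("batch interface reduces to first-stage p-values and matches the scalar path", {
  set.seed(11)
  z1 <- rnorm(5)
  zp <- rnorm(5)
  none <- sequential_p_all(z1, zp, 1 / 3, 0.5, selected = rep(FALSE, 5))
  expect_equal(none, two_sided_p_from_z(z1))

  sel <- c(TRUE, rep(FALSE, 4))
  one <- sequential_p_all(z1, zp, 1 / 3, 0.5, selected = sel)
  expect_equal(one[1],
               twostageFDR:::seq_p_quadrature(abs(zp[1]), 0.5, 1 / 3),
               tolerance = 1e-8)
  expect_equal(one[-1], two_sided_p_from_z(z1)[-1])

  expect_error(sequential_p_all(z1, c(NA, zp[-1]), 1 / 3, 0.5, selected = sel),
               "missing")
  expect_error(sequential_p_all(z1, zp, 1 / 3, 0, selected = sel), "gamma1")
})
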