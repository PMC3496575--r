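test_that("generated stage statistics have the configured noncentrality", {
  cfg <- scenario_config(m = 10000L, pi0 = 0, delta = 1, n1 = 3, n2 = 9,
                         rule = selection_rule("fns", m2 = 10L), seed = 9)
  data <- generate_dataset(cfg, 1)
  expect_true(all(data$is_alternative))
  se1 <- 1 / sqrt(cfg$m)
  expect_lt(abs(mean(data$z1) - sqrt(3)), 3 * se1)
  expect_lt(abs(mean(data$z2) - sqrt(9)), 3 * se1)
  # pooled statistic assembles exactly from the stage means
  expect_equal(data$w1, 0.25)
})

test_that("correlation structures have the configured pairwise correlations", {
  draw <- function(correlation, rho, m = 3, reps = 3000) {
    cfg <- scenario_config(m = m, pi0 = 1, delta = 0, n1 = 3, n2 = 9,
                           rule = selection_rule("fns", m2 = 1L),
                           correlation = correlation, rho = rho, seed = 17)
    t(vapply(seq_len(reps), function(i) generate_dataset(cfg, i)$z1,
             numeric(m)))
  }
  se <- 1 / sqrt(3000)

  z <- draw("equi", 0.5)
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.5), 3 * se)
  expect_lt(abs(cor(z[, 1], z[, 3]) - 0.5), 3 * se)

  z <- draw("auto", 0.5)
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.5), 3 * se)
  expect_lt(abs(cor(z[, 1], z[, 3]) - 0.25), 3 * se)

  # adjacent hypotheses share a block of 20; hypotheses 1 and 25 do not
  z <- draw("block", 0.5, m = 25)
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.5), 3 * se)
  expect_lt(abs(cor(z[, 1], z[, 25])), 3 * se)

  # rho = 0 reduces every structure to independence
  z <- draw("equi", 0)
  expect_lt(abs(cor(z[, 1], z[, 2])), 3 * se)
})

test_that("scenarios are reproducible and runs are order-independent", {
  cfg <- test_scenario(selection_rule("fdrs", alpha1 = 0.3), n_runs = 10)
  a <- run_scenario(cfg, "both")
  b <- run_scenario(cfg, "both")
  expect_identical(a$integrated, b$integrated)
  expect_identical(a$pilot, b$pilot)
  d5 <- generate_dataset(cfg, 5)
  generate_dataset(cfg, 2)  # interleaved draw must not disturb run 5
  expect_identical(generate_dataset(cfg, 5)$z1, d5$z1)
})

test_that("a single-replicate scenario has undefined standard errors", {
  cfg <- test_scenario(selection_rule("fns", m2 = 5L), n_runs = 1)
  s <- run_scenario(cfg, "integrated")
  expect_identical(s$integrated$n_runs, 1L)
  expect_true(is.na(s$integrated$fdr_se))
  expect_true(is.na(s$integrated$s_se))
})

test_that("the FDRS stop rate under the global null matches 1 - alpha1", {
  cfg <- scenario_config(m = 200L, pi0 = 1, delta = 0, n1 = 3, n2 = 9,
                         rule = selection_rule("fdrs", alpha1 = 0.2),
                         n_runs = 2000L, seed = 23)
  s <- run_scenario(cfg, "integrated")
  se <- sqrt(0.8 * 0.2 / cfg$n_runs)
  expect_lt(abs(s$integrated$stop_rate - 0.8), 3 * se)
})

test_that("the data-dependent FNS boundary concentrates as m grows", {
  set.seed(29)
  sds <- vapply(c(500L, 2000L, 8000L), function(m) {
    cfg <- scenario_config(m = m, pi0 = 0.95, delta = 1, n1 = 3, n2 = 9,
                           rule = selection_rule("fns",
                                                 m2 = as.integer(0.01 * m)),
                           n_runs = 150L, seed = m)
    g <- vapply(seq_len(cfg$n_runs), function(i) {
      data <- generate_dataset(cfg, i)
      select_top_k(two_sided_p_from_z(data$z1), cfg$rule$m2)$gamma1_effective
    }, 0)
    sd(g)
  }, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("the fixed-threshold integrated design keeps its FDR below pi0 * alpha", {
  # the baseline design: fixed gamma1 makes the null sequential p-values
  # exactly uniform, so BH controls the FDR at pi0 * alpha under independence
  cfg <- scenario_config(m = 1000L, pi0 = 0.9, delta = 1, n1 = 3, n2 = 9,
                         rule = selection_rule("fixed_threshold",
                                               gamma1 = 0.1),
                         n_runs = 400L, seed = 53L)
  s <- run_scenario(cfg, "integrated")$integrated
  expect_lt(s$fdr_hat, 0.9 * cfg$alpha + 3 * s$fdr_se)
})

test_that("common random numbers reduce the standard error of the power difference", {
  cfg <- scenario_config(m = 500L, pi0 = 0.9, delta = 1, n1 = 3, n2 = 9,
                         rule = selection_rule("fns", m2 = 25L),
                         n_runs = 300L, seed = 37)
  s <- run_scenario(cfg, "both", keep_runs = TRUE)
  si <- s$runs$integrated["S", ]
  sp <- s$runs$pilot["S", ]
  n <- length(si)
  se_paired <- sd(si - sp) / sqrt(n)
  se_unpaired <- sqrt(var(si) / n + var(sp) / n)
  expect_lt(se_paired, se_unpaired)
  expect_gt(cor(si, sp), 0)
})

test_that("run_grid echoes the configuration and pairs the improvement column", {
  rule <- selection_rule("fns", m2 = 10L)
  cfgs <- list(test_scenario(rule, n_runs = 20),
               test_scenario(rule, n_runs = 20))
  tab <- run_grid(cfgs, "both")
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$mean_S[1], tab$mean_S[3])  # identical configs + seeds
  expect_identical(tab$improvement_pct[1], tab$improvement_pct[3])
  expect_true(all(is.na(tab$improvement_pct[tab$approach == "pilot"])))
  one <- run_grid(cfgs[1], "integrated")
  expect_identical(nrow(one), 1L)
})
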