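test_that("identical AICs across models yield t = 0 and no best model", {
  tab <- data.frame(M1 = c(10, 12, 14), M2 = c(10, 12, 14),
                    M3 = c(10, 12, 14))
  res <- population_best_model(tab)
  expect_true(all(res$comparisons$t == 0))
  expect_true(all(res$comparisons$p == 1))
  expect_false(res$best)
  expect_error(population_best_model(tab[1, ]), "at least 2")
  expect_error(population_best_model(tab, reference = "M7"), "not in table")
})

test_that("a value-modulated population penalizes the null model", {
  aics <- t(vapply(1:10, function(i) {
    act <- activity_frame(make_session(m1_truth(), seed = 900 + i),
                          "cue", "free")
    c(M1 = fit_model(act, "M1", label = "EVr+EVs-", n_restarts = 15,
                     seed = i)$aic,
      M9 = fit_model(act, "M9")$aic)
  }, numeric(2)))
  res <- population_best_model(as.data.frame(aics), reference = "M1")
  expect_lt(res$comparisons$mean_diff, 0)
  expect_lt(res$comparisons$p, 0.05)
  expect_true(res$best)
})

test_that("epoch proportion homogeneity uses a df = 2 chi-squared", {
  even <- epoch_proportions(c(20, 20, 20), 101)
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  typical <- epoch_proportions(c(28, 29, 24), 101)
  expect_equal(typical$df, 2)
  expect_gt(typical$p, 0.05)
  extreme <- epoch_proportions(c(30, 0, 0), 30)
  expect_lt(extreme$p, 0.001)
  expect_error(epoch_proportions(c(5, 5), 10), "length")
})

test_that("context attenuation pairs coefficients and detects weakening", {
  cf <- data.frame(EVr = rep(0.04, 5), EVs = rep(-0.05, 5))
  same <- context_attenuation(cf, cf)
  expect_equal(same$EVr$t, 0)
  expect_equal(same$EVs$p, 1)
  expect_error(context_attenuation(cf[1, ], cf[1, ]), "insufficient")
  set.seed(1)
  free <- data.frame(EVr = rnorm(40, 0.04, 0.005),
                     EVs = rnorm(40, -0.05, 0.005))
  forced <- free / 3 + matrix(rnorm(80, 0, 0.002), ncol = 2,
                              dimnames = list(NULL, c("EVr", "EVs")))
  res <- context_attenuation(free, forced)
  expect_gt(res$EVr$free_mean, res$EVr$forced_mean)
  expect_lt(res$EVr$p, 0.05)
  expect_lt(res$EVs$p, 0.05)
})

test_that("12-trial binning yields 3 forced and 4 free bins per activity", {
  ns <- make_session(m1_truth(), seed = 77,
                     behavior = behavior_params(abort_rate = 0))
  expect_message(b <- binned_coefficients(ns, "cue"), "dropped")
  expect_equal(nrow(b), 7)
  expect_equal(sum(b$context == "forced"), 3)
  expect_equal(sum(b$context == "free"), 4)
  expect_true(all(b$n_trials == 48))  # 12 trials x 4 blocks per bin
})

test_that("binned-coefficient population tests have the stacked layout", {
  binned <- do.call(rbind, lapply(1:6, function(i) {
    ns <- make_session(m1_truth(), seed = 80 + i,
                       behavior = behavior_params(abort_rate = 0))
    b <- suppressMessages(binned_coefficients(ns, "cue"))
    b$activity_id <- i
    b
  }))
  res <- binned_coefficient_tests(binned)
  # 6 activities x 3 bins x 2 coefficients in the forced ANOVA
  expect_equal(res$anova_forced$n, 36)
  expect_equal(res$anova_forced$df[1], 2)
  expect_equal(res$anova_free$df[1], 3)
  expect_equal(res$boundary_t$df, 11)  # 6 x 2 pairs
  # stationary coding: no bin effect expected within free choice
  expect_gt(res$anova_free$p, 0.01)
})

test_that("parameter dispersion flags spread differences across phases", {
  set.seed(2)
  same <- data.frame(phase = rep(c("forced", "free1", "free2"), each = 30),
                     rmax = rep(rnorm(30, 40, 5), 3),
                     beta = rep(rnorm(30, 20, 4), 3),
                     sigma = rep(rnorm(30, 60, 10), 3))
  res <- parameter_dispersion(same)
  expect_equal(res$sigma$brown_forsythe$F, 0, tolerance = 1e-10)
  expect_equal(res$beta$kruskal$statistic, 0, tolerance = 1e-10)
  wide <- same
  wide$sigma[wide$phase == "forced"] <-
    rnorm(30, 60, 50)  # 5x spread in the forced phase
  res2 <- parameter_dispersion(wide)
  expect_lt(res2$sigma$brown_forsythe$p, 0.05)
  const <- same
  const$beta[const$phase == "forced"] <- 7
  expect_true(is.na(parameter_dispersion(const)$beta$brown_forsythe$F))
})

test_that("fitted parameters correlate with observed max and baseline rates", {
  set.seed(3)
  n <- 40
  tab <- data.frame(rmax = runif(n, 15, 60), beta = runif(n, 10, 60),
                    sigma = runif(n, 40, 150))
  tab$max_rate <- tab$rmax * rnorm(n, 1, 0.1)
  tab$baseline_rate <- tab$rmax * tab$beta / tab$sigma + rnorm(n, 0, 1)
  res <- parameter_sanity(tab)
  expect_gt(res$max_rate$r, 0.6)
  expect_gt(res$baseline$r, 0.6)
  # negative beta rows leave the baseline relation with a message
  tab$beta[1:3] <- -5
  expect_message(res2 <- parameter_sanity(tab), "excluded")
  expect_equal(res2$baseline$n, n - 3)
  # constant baseline: degenerate, flagged
  tab$baseline_rate <- 10
  expect_true(is.na(suppressMessages(parameter_sanity(tab))$baseline$r))
})

test_that("equal-EV deviation isolates an LP3 rate bump", {
  lp <- lottery_pairs()
  act <- lp[rep(seq_len(nrow(lp)), each = 5), ]
  act$rate <- 10 + 0.04 * (act$ev_risky - act$ev_safe) +
    3 * (act$lp_index == 3)
  # independent oracle: per-block straight-line fit through the 5 condition
  # means, deviation of the observed LP3 mean from its zero-difference value
  oracle <- mean(vapply(1:4, function(b) {
    d <- act[act$block_id == b, ]
    m <- tapply(d$rate, d$lp_index, mean)
    vd <- tapply(d$ev_risky - d$ev_safe, d$lp_index, mean)
    cf <- coef(lm(m ~ vd))
    unname(m[3] - cf[1])
  }, numeric(1)))
  expect_equal(equal_ev_deviation(act), oracle, tolerance = 1e-8)
  expect_gt(equal_ev_deviation(act), 1)   # the bump survives the reference fit
  act$rate <- 10 + 0.04 * (act$ev_risky - act$ev_safe)
  expect_equal(equal_ev_deviation(act), 0, tolerance = 1e-8)
})

test_that("risk-attitude correlations split by coding type with guards", {
  set.seed(4)
  risky_pct <- runif(30, 20, 80)
  tab <- data.frame(
    label = rep(c("EVr+EVs-", "EVr-EVs+"), each = 15),
    risky_pct = risky_pct,
    deviation = c(0.1 * risky_pct[1:15] + rnorm(15, 0, 0.5),
                  -0.1 * risky_pct[16:30] + rnorm(15, 0, 0.5)))
  res <- risk_attitude_correlation(tab)
  expect_gt(res[["EVr+EVs-"]]$r, 0.5)
  expect_lt(res[["EVr-EVs+"]]$r, -0.5)
  flat <- data.frame(label = "EVr+EVs-", risky_pct = runif(5, 20, 80),
                     deviation = 0)
  expect_equal(risk_attitude_correlation(flat)[["EVr+EVs-"]]$r, 0)
  small <- flat[1:2, ]
  expect_match(risk_attitude_correlation(small)[["EVr+EVs-"]]$note, "fewer")
})
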