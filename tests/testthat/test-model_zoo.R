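cov1 <- function(ev1, ev2, ...) data.frame(ev1 = ev1, ev2 = ev2, ...)

test_that("model specs validate their parameter sets and counts", {
  expect_equal(model_n_params("M1"), 3)
  expect_equal(model_n_params("M9"), 1)
  expect_equal(model_n_params("M10"), 8)
  expect_equal(vapply(paste0("M", 11:13), model_n_params, numeric(1)),
               c(M11 = 4, M12 = 4, M13 = 4))
  expect_error(model_spec("M1", c(rmax = 40, beta = 20)), "exactly")
  expect_error(model_spec("M2", c(rmax = 40, beta = 20, sigma = 1)), "exactly")
  expect_error(model_spec("M99", c(b = 1)), "unknown model")
})

test_that("closed-form predictions match hand arithmetic", {
  m1 <- model_spec("M1", c(rmax = 40, beta = 20, sigma = 10))
  expect_equal(predict_rate(m1, cov1(120, 60)), 40 * 140 / 190)
  expect_equal(predict_rate(m1, cov1(0, 0)), 80)  # Rmax*beta/sigma baseline
  m2 <- model_spec("M2", c(rmax = 40, b = 10))
  expect_equal(predict_rate(m2, cov1(90, 90)), 30)
  m3 <- model_spec("M3", c(g = 0.4, b = 10))
  expect_equal(predict_rate(m3, cov1(90, 60)), 22)
  m4 <- model_spec("M4", c(rmax = 40, b = 10))
  expect_equal(predict_rate(m4, cov1(120, 60, v_min = 0, v_max = 240)), 30)
})

test_that("linear alternatives and the block-wise model use their covariates", {
  expect_equal(predict_rate(model_spec("M5", c(a = 0.1, b = 5)),
                            data.frame(evr = 120)), 17)
  expect_equal(predict_rate(model_spec("M6", c(a = 0.1, b = 5)),
                            data.frame(evs = 60)), 11)
  expect_equal(predict_rate(model_spec("M7", c(a = 0.1, b = 5)),
                            data.frame(ev_chosen = 90)), 14)
  expect_equal(predict_rate(model_spec("M8", c(a = 6, b = 8)),
                            data.frame(risky_cho = c(1, 0))), c(14, 8))
  expect_equal(predict_rate(model_spec("M9", c(b = 20)),
                            data.frame(x = 1:3)), rep(20, 3))
  m10 <- model_spec("M10", c(a1 = 0.1, a2 = 0.2, a3 = 0.3, a4 = 0.4,
                             b1 = 1, b2 = 2, b3 = 3, b4 = 4))
  expect_equal(predict_rate(m10, data.frame(evr = c(100, 100),
                                            block_id = c(1, 3))),
               c(11, 33))
})

test_that("model-family identities hold: nesting, translation, monotonicity", {
  ev <- expand.grid(ev1 = c(30, 60, 120, 240), ev2 = c(60, 120, 180))
  # M1 with beta = sigma = 0 collapses to M2 with b = 0
  m1 <- model_spec("M1", c(rmax = 35, beta = 0, sigma = 0))
  m2 <- model_spec("M2", c(rmax = 35, b = 0))
  expect_equal(predict_rate(m1, ev), predict_rate(m2, ev))
  # M3 is invariant to common value shifts
  m3 <- model_spec("M3", c(g = 0.3, b = 12))
  shifted <- data.frame(ev1 = ev$ev1 + 55, ev2 = ev$ev2 + 55)
  expect_equal(predict_rate(m3, ev), predict_rate(m3, shifted))
  # M1 with positive parameters: increasing in EV1, decreasing in EV2
  m1p <- model_spec("M1", c(rmax = 40, beta = 20, sigma = 50))
  expect_true(all(diff(predict_rate(
    m1p, data.frame(ev1 = seq(0, 300, 30), ev2 = 60))) > 0))
  expect_true(all(diff(predict_rate(
    m1p, data.frame(ev1 = 120, ev2 = seq(0, 300, 30)))) < 0))
  # M11 with a = 0 is exactly M1
  m11 <- model_spec("M11", c(rmax = 40, beta = 20, sigma = 50, a = 0))
  ev$context <- rep(c(1, 0), 6)
  expect_equal(predict_rate(m11, ev), predict_rate(m1p, ev))
})

test_that("range-normalization sensitivity scales inversely with block range", {
  m4 <- model_spec("M4", c(rmax = 40, b = 10))
  slope <- vapply(c(240, 360, 480, 600), function(vmax) {
    p <- predict_rate(m4, data.frame(ev1 = c(0, 60), v_min = 0, v_max = vmax))
    diff(p) / 60
  }, numeric(1))
  expect_equal(slope, 40 / c(240, 360, 480, 600))
})

test_that("degenerate denominators raise domain errors", {
  m1 <- model_spec("M1", c(rmax = 40, beta = 20, sigma = 0))
  expect_error(predict_rate(m1, cov1(0, 0)), "zero denominator")
  m2 <- model_spec("M2", c(rmax = 40, b = 10))
  expect_error(predict_rate(m2, cov1(0, 0)), "zero denominator")
  m4 <- model_spec("M4", c(rmax = 40, b = 10))
  expect_error(predict_rate(m4, cov1(60, 0, v_min = 10, v_max = 10)),
               "v_max > v_min")
})

test_that("EV1/EV2 assignment follows the coding type", {
  expect_equal(assign_ev1_ev2("EVr+EVs-", 90, 60), list(ev1 = 90, ev2 = 60))
  expect_equal(assign_ev1_ev2("EVr-EVs+", 90, 60), list(ev1 = 60, ev2 = 90))
  expect_equal(assign_ev1_ev2("EVr+EVs-", 0, 0), list(ev1 = 0, ev2 = 0))
  expect_error(assign_ev1_ev2("choice_only", 90, 60), "label")
  expect_error(assign_ev1_ev2("other", 90, 60), "label")
})

test_that("forced-choice value assumptions zero out the non-selectable option", {
  expect_equal(forced_choice_evs(150, 120, "risky", 1),
               list(evr = 150, evs = 120))
  expect_equal(forced_choice_evs(150, 120, "safe", 2),
               list(evr = 0, evs = 120))
  expect_equal(forced_choice_evs(150, 120, "risky", 2),
               list(evr = 150, evs = 0))
  expect_error(forced_choice_evs(150, 120, "risky", 2, context = "free"),
               "forced trials only")
  expect_error(forced_choice_evs(150, 120, "none", 2), "instructed")
  expect_error(forced_choice_evs(150, 120, "risky", 3), "assumption")
})
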