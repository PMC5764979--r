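# schedule-like frame holding one lottery pair many times, for law-of-large-
# numbers checks on the choice model
one_pair_schedule <- function(block, lp, n, context = "free") {
  d <- lottery_pairs()
  d <- d[d$block_id == block & d$lp_index == lp, ][rep(1, n), ]
  d$trial <- seq_len(n)
  d$context <- context
  d$instructed <- if (context == "forced") "risky" else "none"
  d$risky_side <- "left"
  d
}

test_that("behavior parameters are validated", {
  expect_s3_class(behavior_params(), "behavior_params")
  expect_error(behavior_params(inverse_temperature = -1))
  expect_error(behavior_params(abort_rate = 0.5))
  expect_error(behavior_params(rt_scale = 0))
})

test_that("softmax choice probabilities hit their analytic values", {
  # temperature zero: indifference everywhere
  beh0 <- simulate_behavior(one_pair_schedule(1, 5, 4000),
                            behavior_params(inverse_temperature = 0,
                                            abort_rate = 0), seed = 2)
  expect_equal(mean(beh0$choice == "risky"), 0.5, tolerance = 0.05)
  # LP5 of block 1: EVr 120 vs EVs 60 at 0.05/ul -> logistic(3) = 0.9526
  beh <- simulate_behavior(one_pair_schedule(1, 5, 4000),
                           behavior_params(inverse_temperature = 0.05,
                                           abort_rate = 0), seed = 3)
  expect_equal(mean(beh$choice == "risky"), plogis(3), tolerance = 0.02)
  # equal-EV pair with no risk bonus: indifference
  beh_eq <- simulate_behavior(one_pair_schedule(2, 3, 4000),
                              behavior_params(abort_rate = 0), seed = 4)
  expect_equal(mean(beh_eq$choice == "risky"), 0.5, tolerance = 0.05)
})

test_that("risky-choice rate rises monotonically with the value difference", {
  sched <- do.call(rbind, lapply(1:5, function(lp) one_pair_schedule(1, lp, 2000)))
  beh <- simulate_behavior(sched, behavior_params(abort_rate = 0), seed = 5)
  p <- tapply(beh$choice == "risky", beh$lp_index, mean)
  expect_true(all(diff(p) > 0))
})

test_that("forced trials follow the instruction and aborted ones do not", {
  sched <- build_trial_schedule(8)
  beh <- simulate_behavior(sched, behavior_params(abort_rate = 0.1), seed = 9)
  forced <- beh[beh$context == "forced", ]
  ok <- forced$aborted == 0L
  expect_true(all(forced$choice[ok] == forced$instructed[ok]))
  expect_true(all(forced$choice[!ok] != forced$instructed[!ok]))
  expect_true(all(beh$reward_ul[beh$rewarded == 1L] > 0))
  expect_true(all(beh$reward_ul[beh$aborted == 1L] == 0))
  expect_identical(beh$fb, beh$rewarded)
  # safe choices on clean trials always pay
  free_safe <- beh$context == "free" & beh$choice == "safe" & beh$aborted == 0L
  expect_true(all(beh$rewarded[free_safe] == 1L))
})

test_that("simulation is reproducible by seed", {
  sched <- build_trial_schedule(10)
  b1 <- simulate_behavior(sched, behavior_params(), seed = 11)
  b2 <- simulate_behavior(sched, behavior_params(), seed = 11)
  expect_identical(b1, b2)
  tru <- m1_truth()
  expect_identical(simulate_neuron(b1, tru, 12), simulate_neuron(b1, tru, 12))
  expect_false(identical(simulate_neuron(b1, tru, 12)$trials$rate_cue,
                         simulate_neuron(b1, tru, 13)$trials$rate_cue))
})

test_that("spike counts behave like Poisson draws around the model mean", {
  sched <- one_pair_schedule(1, 3, 10000)
  beh <- simulate_behavior(sched, behavior_params(abort_rate = 0), seed = 20)
  ns <- simulate_neuron(beh, ground_truth("M9", c(b = 20), "none"), seed = 21)
  expect_equal(mean(ns$trials$rate_cue), 20, tolerance = 0.5 / 20)
  # variance tracks the mean in a 1-s window
  expect_equal(var(ns$trials$rate_cue) / mean(ns$trials$rate_cue), 1,
               tolerance = 0.1)
})

test_that("baseline rate reflects the normalization zero-value output", {
  sched <- build_trial_schedule(30)
  beh <- simulate_behavior(sched, behavior_params(), seed = 31)
  base <- vapply(1:40, function(s) {
    simulate_neuron(beh, m1_truth(rmax = 40, beta = 20, sigma = 10),
                    seed = 100 + s)$baseline_rate
  }, numeric(1))
  expect_equal(mean(base), 80, tolerance = 0.05)  # Rmax*beta/sigma
})

test_that("M1-generated condition means are saturating, unlike a linear model", {
  spec <- model_spec("M1", c(rmax = 40, beta = 20, sigma = 30))
  act <- noise_free_activity(spec)
  m1 <- fit_model(act, "M1", label = "EVr+EVs-", n_restarts = 15, seed = 1)
  m5 <- fit_model(act, "M5")
  expect_lt(m1$sse, 1e-6)
  expect_gt(m5$sse, 1)
})

test_that("degenerate parameterizations that pin rates at the floor warn", {
  sched <- build_trial_schedule(33)
  beh <- simulate_behavior(sched, behavior_params(), seed = 34)
  tru <- ground_truth("M3", c(g = 0.001, b = -50), "EVr+EVs-")
  expect_warning(simulate_neuron(beh, tru, 35), "degenerate")
})

test_that("generate_dataset produces per-neuron sessions with a registry", {
  ds <- generate_dataset(3, function(i) m1_truth(), seed = 40)
  expect_length(ds, 3)
  expect_true(all(vapply(ds, function(s) nrow(s$trials), numeric(1)) == 344))
  reg <- attr(ds, "registry")
  expect_equal(reg$model_id, rep("M1", 3))
  expect_equal(reg$neuron_id, vapply(ds, `[[`, "", "neuron_id"))
  # sessions differ across neurons and are seed-reproducible
  expect_false(identical(ds[[1]]$trials$rate_cue, ds[[2]]$trials$rate_cue))
  ds2 <- generate_dataset(3, function(i) m1_truth(), seed = 40)
  expect_identical(ds[[1]]$trials, ds2[[1]]$trials)
})

test_that("behavior summaries report risky%, correct% and RT per pair", {
  sched <- build_trial_schedule(50)
  beh <- simulate_behavior(sched, behavior_params(abort_rate = 0), seed = 51)
  bs <- behavior_summary(beh)
  expect_equal(nrow(bs), 20)
  expect_true(all(bs$pct_correct == 100))
  expect_true(all(bs$mean_rt_ms > 0))
  # all-risky free choices give 100% risky everywhere
  beh_all <- beh
  beh_all$choice[beh_all$context == "free"] <- "risky"
  expect_true(all(behavior_summary(beh_all)$pct_risky == 100))
  # large-n check of the softmax percentage at LP5 of block 1
  big <- simulate_behavior(one_pair_schedule(1, 5, 10000),
                           behavior_params(abort_rate = 0), seed = 52)
  expect_equal(behavior_summary(big)$pct_risky[
    behavior_summary(big)$block_id == 1 &
      behavior_summary(big)$lp_index == 5], 95.3, tolerance = 1 / 95)
})
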