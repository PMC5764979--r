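# Shared fixtures, built in code at test time.

# One simulated neuron session: schedule + behavior + spiking.
make_session <- function(truth, seed = 1, behavior = behavior_params(),
                         neuron_id = "n1") {
  sched <- build_trial_schedule(seed)
  beh <- simulate_behavior(sched, behavior, seed + 1L)
  simulate_neuron(beh, truth, seed + 2L, neuron_id = neuron_id)
}

m1_truth <- function(rmax = 40, beta = 20, sigma = 60, ...) {
  ground_truth("M1", c(rmax = rmax, beta = beta, sigma = sigma),
               coding_type = "EVr+EVs-", ...)
}

# Noise-free activity frame over the 20 lottery pairs, rates generated by a
# model spec, n_per_pair free trials per pair.
noise_free_activity <- function(spec, label = "EVr+EVs-", n_per_pair = 10) {
  lp <- lottery_pairs()
  df <- lp[rep(seq_len(nrow(lp)), each = n_per_pair), ]
  df$context <- "free"
  df$aborted <- 0L
  df$trial <- 37L
  df$choice <- "safe"
  df$chosen_side <- "left"
  df$fb <- 1L
  df$rt_ms <- 200
  df$instructed <- "none"
  cov <- trial_covariates(df, label = label)
  cov$context_num <- 1L
  cov$pair <- paste0(cov$block_id, ".", cov$lp_index)
  cov$rate <- predict_rate(spec, cov)
  rownames(cov) <- NULL
  cov
}
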