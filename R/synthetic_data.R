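#' Behavioral simulation parameters
#'
#' Choice behavior on free trials follows a softmax on the expected-value
#' difference: P(risky) = logistic(inverse_temperature * (EVr + risk_bonus -
#' EVs)). The risky bonus encodes risk attitude (positive = risk seeking).
#' Reaction times are log-normal; aborts are Bernoulli per trial.
#'
#' @param inverse_temperature Softmax sensitivity, 1/ul (>= 0).
#' @param risk_bonus Additive value bonus for the risky option, ul.
#' @param abort_rate Per-trial abort probability, in [0, 0.2].
#' @param rt_location Median reaction time, ms.
#' @param rt_scale Log-scale sd of reaction times (> 0).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(inverse_temperature = 0.05, risk_bonus = 0,
                            abort_rate = 0.02, rt_location = 200,
                            rt_scale = 0.2) {
  stopifnot(inverse_temperature >= 0, abort_rate >= 0, abort_rate <= 0.2,
            rt_scale > 0, rt_location > 0)
  structure(list(inverse_temperature = inverse_temperature,
                 risk_bonus = risk_bonus, abort_rate = abort_rate,
                 rt_location = rt_location, rt_scale = rt_scale),
            class = "behavior_params")
}

#' Simulate choice behavior over a trial schedule
#'
#' Free trials choose the risky option with softmax probability; forced trials
#' follow the instruction (aborted forced trials are recorded as choices of the
#' non-instructed target). Risky choices are rewarded with probability 0.5,
#' safe choices with certainty; aborted trials pay nothing.
#'
#' @param schedule A `trial_schedule` from [build_trial_schedule()].
#' @param params A `behavior_params`.
#' @param seed Integer seed.
#' @return The schedule with added columns `choice` ("risky"/"safe"),
#'   `chosen_side`, `rewarded`, `reward_ul`, `fb` (= rewarded), `rt_ms`,
#'   `aborted`.
#' @export
simulate_behavior <- function(schedule, params, seed) {
  stopifnot(inherits(params, "behavior_params"))
  n <- nrow(schedule)
  with_seed(seed, {
    tr <- as.data.frame(schedule)
    p_risky <- stats::plogis(params$inverse_temperature *
                               (tr$ev_risky + params$risk_bonus - tr$ev_safe))
    free <- tr$context == "free"
    choice <- ifelse(free,
                     ifelse(stats::runif(n) < p_risky, "risky", "safe"),
                     tr$instructed)
    aborted <- as.integer(stats::runif(n) < params$abort_rate)
    # an aborted forced trial is a saccade to the non-matched target
    flip <- aborted == 1L & !free
    choice[flip] <- ifelse(tr$instructed[flip] == "risky", "safe", "risky")
    chosen_side <- ifelse(choice == "risky", tr$risky_side,
                          ifelse(tr$risky_side == "left", "right", "left"))
    win <- stats::runif(n) < ifelse(choice == "risky", 0.5, 1)
    rewarded <- as.integer(win & aborted == 0L)
    reward_ul <- ifelse(rewarded == 1L,
                        ifelse(choice == "risky", tr$risky_mag_ul, tr$safe_mag_ul),
                        0)
    tr$choice <- choice
    tr$chosen_side <- chosen_side
    tr$rewarded <- rewarded
    tr$reward_ul <- reward_ul
    tr$fb <- rewarded
    tr$rt_ms <- stats::rlnorm(n, meanlog = log(params$rt_location),
                              sdlog = params$rt_scale)
    tr$aborted <- aborted
    tr
  })
}

#' Ground truth for one simulated neuron
#'
#' @param model_id Generating model, "M1".."M13" (ignored for `coding_type`
#'   "choice_only" and "none").
#' @param params Named parameters. For value-coding types these must match the
#'   model (see [model_spec()]); for "choice_only", `c(a=, b=)` (rate = a *
#'   left-choice + b); for "none", `c(b=)`.
#' @param coding_type One of "EVr+EVs-", "EVr-EVs+", "choice_only", "none".
#' @param forced_attenuation Factor >= 1 applied on forced trials: beta and
#'   sigma are multiplied by it in the fractional models (M1, M11-M13), and
#'   the gain is divided by it in the linear models, weakening value
#'   modulation either way.
#' @param fb_coef Additive reward-feedback effect (spikes/s) in the feedback
#'   epoch.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(model_id, params, coding_type = "EVr+EVs-",
                         forced_attenuation = 1, fb_coef = 0) {
  coding_type <- match.arg(coding_type,
                           c("EVr+EVs-", "EVr-EVs+", "choice_only", "none"))
  stopifnot(forced_attenuation >= 1)
  params <- unlist(params)
  if (coding_type %in% c("EVr+EVs-", "EVr-EVs+")) {
    spec <- model_spec(model_id, params)  # validates
  } else if (coding_type == "choice_only") {
    stopifnot(setequal(names(params), c("a", "b")))
  } else {
    stopifnot(setequal(names(params), "b"))
  }
  structure(list(model_id = model_id, params = params,
                 coding_type = coding_type,
                 forced_attenuation = forced_attenuation, fb_coef = fb_coef),
            class = "ground_truth")
}

# Attenuate a parameter vector for forced trials: inflate beta/sigma where
# present, otherwise deflate the gain term(s).
.attenuate_params <- function(model_id, params, factor) {
  if (factor == 1) return(params)
  nm <- names(params)
  if (any(c("beta", "sigma") %in% nm)) {
    params[nm %in% c("beta", "sigma")] <- params[nm %in% c("beta", "sigma")] * factor
  } else if ("g" %in% nm) {
    params["g"] <- params["g"] / factor
  } else if ("rmax" %in% nm) {     # M2/M4: scale the value-driven component
    params["rmax"] <- params["rmax"] / factor
  } else {
    gains <- grepl("^a[0-9]*$", nm)
    params[gains] <- params[gains] / factor
  }
  params
}

#' Build the model covariate table from behavioral trial records
#'
#' @param trials Trial records from [simulate_behavior()] (or read back from
#'   disk); aborted trials are retained.
#' @param label Coding type used to assign `ev1`/`ev2`; `NULL` leaves them
#'   unset.
#' @return The trials with columns `ev1`, `ev2`, `ev_chosen`, `risky_cho`,
#'   `cho` (1 = left), `context_num` (1 = free), `percent_correct` (per
#'   lottery pair), `rt` (z-scored reaction time) appended.
#' @export
trial_covariates <- function(trials, label = NULL) {
  tr <- as.data.frame(trials)
  if (!is.null(label)) {
    ev <- assign_ev1_ev2(label, tr$ev_risky, tr$ev_safe)
    tr$ev1 <- ev$ev1
    tr$ev2 <- ev$ev2
  }
  tr$ev_chosen <- ifelse(tr$choice == "risky", tr$ev_risky, tr$ev_safe)
  tr$risky_cho <- as.integer(tr$choice == "risky")
  tr$cho <- as.integer(tr$chosen_side == "left")
  tr$context_num <- as.integer(tr$context == "free")
  pair <- interaction(tr$block_id, tr$lp_index, drop = FALSE)
  pc <- tapply(1 - tr$aborted, pair, mean) * 100
  tr$percent_correct <- as.numeric(pc[as.character(pair)])
  tr$rt <- as.numeric(scale(tr$rt_ms))
  tr
}

#' Simulate one neuron's epoch firing rates
#'
#' Per trial, the generating model's prediction (floored at 0.01 spikes/s)
#' gives the mean rate; the observed rate in each 1.0-s epoch (cue, saccade,
#' feedback) is an independent Poisson count. Forced trials use attenuated
#' parameters per the ground truth. The feedback-epoch mean adds
#' `fb_coef * Fb`. The baseline rate is a Poisson draw over a 0.6-s pre-cue
#' window around the model's zero-value output (Rmax*beta/sigma for the
#' fractional models, the intercept otherwise).
#'
#' @param trials Trial records from [simulate_behavior()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @param neuron_id Identifier stored in the session.
#' @return An object of class `neuron_session`: list with `neuron_id`,
#'   `ground_truth`, `trials` (with `rate_cue`, `rate_sac`, `rate_fb`
#'   columns), `baseline_rate`, `max_rate`.
#' @export
simulate_neuron <- function(trials, truth, seed, neuron_id = "n1") {
  stopifnot(inherits(truth, "ground_truth"))
  lab <- if (truth$coding_type %in% c("EVr+EVs-", "EVr-EVs+")) truth$coding_type else NULL
  cov <- trial_covariates(trials, label = lab)
  cov$context <- cov$context_num
  n <- nrow(cov)
  with_seed(seed, {
    mu <- switch(truth$coding_type,
      "choice_only" = truth$params["a"] * cov$cho + truth$params["b"],
      "none" = rep(truth$params["b"], n),
      {
        mu <- numeric(n)
        free <- cov$context_num == 1L
        spec_free <- model_spec(truth$model_id, truth$params)
        if (any(free)) mu[free] <- predict_rate(spec_free, cov[free, , drop = FALSE])
        if (any(!free)) {
          spec_forced <- model_spec(
            truth$model_id,
            .attenuate_params(truth$model_id, truth$params,
                              truth$forced_attenuation))
          mu[!free] <- predict_rate(spec_forced, cov[!free, , drop = FALSE])
        }
        mu
      })
    mu <- unname(mu)
    mu_fb <- mu + truth$fb_coef * cov$fb
    floor_hit <- mean(mu < 0.01)
    if (floor_hit > 0.5) {
      warning("degenerate parameterization: model prediction below the ",
              "0.01 spikes/s floor on ", round(100 * floor_hit),
              "% of trials")
    }
    mu <- pmax(mu, 0.01)
    mu_fb <- pmax(mu_fb, 0.01)
    tr <- as.data.frame(trials)
    tr$rate_cue <- stats::rpois(n, mu)
    tr$rate_sac <- stats::rpois(n, mu)
    tr$rate_fb <- stats::rpois(n, mu_fb)
    base <- if (truth$coding_type %in% c("EVr+EVs-", "EVr-EVs+") &&
                truth$model_id %in% c("M1", "M11", "M12", "M13")) {
      truth$params["rmax"] * truth$params["beta"] / truth$params["sigma"]
    } else {
      truth$params["b"]
    }
    baseline_rate <- stats::rpois(1L, max(0.6 * base, 0)) / 0.6
    structure(
      list(neuron_id = neuron_id, ground_truth = truth, trials = tr,
           baseline_rate = baseline_rate,
           max_rate = max(tr$rate_cue, tr$rate_sac, tr$rate_fb)),
      class = "neuron_session")
  })
}

#' Generate a population of simulated sessions
#'
#' Each neuron gets its own schedule, behavior and spiking, driven by
#' per-neuron seeds expanded from the master seed. The ground-truth registry
#' is attached as attribute `"registry"` for parameter-recovery tests.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param truth_sampler Function `(i) -> ground_truth` for neuron i.
#' @param behavior A `behavior_params`.
#' @param seed Master integer seed.
#' @return List of `neuron_session` objects with a registry attribute
#'   (data frame: neuron_id, model_id, coding_type).
#' @export
generate_dataset <- function(n_neurons, truth_sampler,
                             behavior = behavior_params(), seed = 1) {
  stopifnot(n_neurons >= 1)
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 1, 3 * n_neurons),
                                  ncol = 3))
  sessions <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    truth <- truth_sampler(i)
    sched <- build_trial_schedule(seeds[i, 1])
    beh <- simulate_behavior(sched, behavior, seeds[i, 2])
    sessions[[i]] <- simulate_neuron(beh, truth, seeds[i, 3],
                                     neuron_id = sprintf("n%03d", i))
  }
  registry <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(neuron_id = s$neuron_id, model_id = s$ground_truth$model_id,
               coding_type = s$ground_truth$coding_type)
  }))
  attr(sessions, "registry") <- registry
  sessions
}

#' Behavioral summary per lottery pair
#'
#' @param trials Trial records from [simulate_behavior()].
#' @return A 20-row data frame: `block_id`, `lp_index`, `pct_risky`
#'   (free non-aborted trials; NA for empty cells), `pct_correct`
#'   (non-aborted percentage over all trials of the pair), `mean_rt_ms`
#'   (non-aborted trials).
#' @export
behavior_summary <- function(trials) {
  tr <- as.data.frame(trials)
  grid <- lottery_pairs()[, c("block_id", "lp_index")]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- tr$block_id == grid$block_id[i] & tr$lp_index == grid$lp_index[i]
    fr <- sel & tr$context == "free" & tr$aborted == 0L
    ok <- sel & tr$aborted == 0L
    data.frame(
      block_id = grid$block_id[i], lp_index = grid$lp_index[i],
      pct_risky = if (any(fr)) 100 * mean(tr$choice[fr] == "risky") else NA_real_,
      pct_correct = if (any(sel)) 100 * mean(tr$aborted[sel] == 0L) else NA_real_,
      mean_rt_ms = if (any(ok)) mean(tr$rt_ms[ok]) else NA_real_)
  })
  do.call(rbind, out)
}
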