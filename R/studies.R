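#' Parameter-recovery study for the divisive normalization model
#'
#' Simulates a population of value-coding neurons with normalization
#' parameters drawn uniformly from realistic ranges (Rmax 10-60 spikes/s,
#' beta 10-100 ul, sigma 20-200 ul), fits the model to each neuron's
#' free-choice cue activity, and correlates true against fitted parameters.
#'
#' @param n_neurons Number of simulated neurons.
#' @param seed Master seed for truth draws, simulation and fitting.
#' @param n_restarts Restarts per fit.
#' @return List with `true` and `fitted` parameter tables, a `diverged` flag
#'   per neuron (ridge fits carry no interpretable estimate and are excluded
#'   from the correlations, with a message), `correlations` (named vector of
#'   Pearson r for rmax, beta, sigma) and `n_used`.
#' @export
recovery_study <- function(n_neurons = 50, seed = 1, n_restarts = 40) {
  true <- with_seed(seed, data.frame(
    rmax = stats::runif(n_neurons, 10, 60),
    beta = stats::runif(n_neurons, 10, 100),
    sigma = stats::runif(n_neurons, 20, 200)))
  sampler <- function(i) {
    ground_truth("M1", c(rmax = true$rmax[i], beta = true$beta[i],
                         sigma = true$sigma[i]), "EVr+EVs-")
  }
  ds <- generate_dataset(n_neurons, sampler,
                         behavior_params(abort_rate = 0), seed = seed + 1L)
  fits <- lapply(seq_along(ds), function(i) {
    suppressWarnings(
      fit_model(activity_frame(ds[[i]], "cue", "free"), "M1",
                label = "EVr+EVs-", n_restarts = n_restarts, seed = i))
  })
  fitted <- t(vapply(fits, `[[`, c(rmax = 0, beta = 0, sigma = 0), "params"))
  diverged <- vapply(fits, `[[`, logical(1), "diverged")
  if (any(diverged)) {
    message(sum(diverged), " neuron(s) with divergent (ridge) estimates ",
            "excluded from the recovery correlations")
  }
  ok <- !diverged
  list(true = true, fitted = as.data.frame(fitted), diverged = diverged,
       correlations = c(
         rmax = stats::cor(true$rmax[ok], fitted[ok, "rmax"]),
         beta = stats::cor(true$beta[ok], fitted[ok, "beta"]),
         sigma = stats::cor(true$sigma[ok], fitted[ok, "sigma"])),
       n_used = sum(ok))
}

#' Generating-model selection study
#'
#' Simulates activities from a known generating model, fits a competing model
#' set to each, and runs the population AIC-difference selection. Used to
#' check that the pipeline identifies the generating model and is not biased
#' toward the normalization form.
#'
#' @param truth_model "M1" (divisive normalization, Rmax 40, beta 20, sigma
#'   60) or "M3" (difference model, G 0.08, b 15).
#' @param n_activities Number of simulated activities (one cue-epoch activity
#'   per neuron).
#' @param seed Master seed.
#' @param models Model set fitted and compared.
#' @param n_restarts Restarts per nonlinear fit.
#' @return The [population_best_model()] result, plus the AIC table as
#'   attribute `"aic_table"`.
#' @export
model_selection_study <- function(truth_model = c("M1", "M3"),
                                  n_activities = 30, seed = 1,
                                  models = c("M1", "M2", "M3", "M4"),
                                  n_restarts = 30) {
  truth_model <- match.arg(truth_model)
  truth <- if (truth_model == "M1") {
    ground_truth("M1", c(rmax = 40, beta = 20, sigma = 60), "EVr+EVs-")
  } else {
    ground_truth("M3", c(g = 0.08, b = 15), "EVr+EVs-")
  }
  ds <- generate_dataset(n_activities, function(i) truth,
                         behavior_params(abort_rate = 0), seed = seed)
  aics <- t(vapply(seq_along(ds), function(i) {
    act <- activity_frame(ds[[i]], "cue", "free")
    vapply(models, function(m) {
      fit_model(act, m, label = "EVr+EVs-", n_restarts = n_restarts,
                seed = i)$aic
    }, numeric(1))
  }, stats::setNames(numeric(length(models)), models)))
  res <- population_best_model(as.data.frame(aics), reference = truth_model)
  attr(res, "aic_table") <- as.data.frame(aics)
  res
}

#' Free-vs-forced context attenuation study
#'
#' Simulates neurons whose forced-phase beta and sigma are inflated by
#' `attenuation` (weakening value modulation on forced trials), then runs the
#' three population analyses on all neuron-epoch activities: (i) paired
#' free-vs-forced comparison of |EVr| and |EVs| regression coefficients,
#' (ii) Brown-Forsythe dispersion of the fitted normalization parameters
#' across forced / first-half / second-half free phases (fits that only
#' reached the degenerate ridge are excluded, with a message), and (iii)
#' population model selection within forced trials (assumption 1).
#'
#' @param n_neurons Number of neurons; each contributes its cue, saccade and
#'   feedback epochs as activities (default 27, i.e. 81 activities).
#' @param seed Master seed.
#' @param attenuation Multiplicative beta/sigma inflation on forced trials.
#' @param n_restarts Restarts per nonlinear fit.
#' @return List with `attenuation` ([context_attenuation()] result),
#'   `dispersion` ([parameter_dispersion()] result), `forced_selection`
#'   ([population_best_model()] on forced-trial fits of M1-M4),
#'   `params` (the phase-wise parameter table) and `n_diverged`.
#' @export
attenuation_study <- function(n_neurons = 27, seed = 1, attenuation = 5,
                              n_restarts = 30) {
  true <- with_seed(seed, data.frame(
    rmax = stats::runif(n_neurons, 20, 50),
    beta = stats::runif(n_neurons, 10, 40),
    sigma = stats::runif(n_neurons, 40, 120)))
  sampler <- function(i) {
    ground_truth("M1", c(rmax = true$rmax[i], beta = true$beta[i],
                         sigma = true$sigma[i]), "EVr+EVs-",
                 forced_attenuation = attenuation)
  }
  ds <- generate_dataset(n_neurons, sampler,
                         behavior_params(abort_rate = 0), seed = seed + 1L)
  epochs <- c("cue", "saccade", "feedback")
  coef_free <- coef_forced <- NULL
  param_rows <- list()
  aic_forced <- NULL
  for (i in seq_along(ds)) {
    for (ep in epochs) {
      free <- activity_frame(ds[[i]], ep, "free")
      forced <- activity_frame(ds[[i]], ep, "forced")
      coef_free <- rbind(coef_free,
                         value_coefficients(free)[c("EVr", "EVs")])
      coef_forced <- rbind(coef_forced,
                           value_coefficients(forced)[c("EVr", "EVs")])
      ff <- suppressWarnings(
        fit_model(forced, "M1", label = "EVr+EVs-", n_restarts = n_restarts,
                  seed = i, context_scope = "forced_a1"))
      f1 <- suppressWarnings(
        fit_model(free[free$trial <= 61, ], "M1", label = "EVr+EVs-",
                  n_restarts = n_restarts, seed = i))
      f2 <- suppressWarnings(
        fit_model(free[free$trial > 61, ], "M1", label = "EVr+EVs-",
                  n_restarts = n_restarts, seed = i))
      param_rows[[length(param_rows) + 1L]] <- data.frame(
        phase = c("forced", "free1", "free2"),
        rbind(ff$params, f1$params, f2$params),
        diverged = c(ff$diverged, f1$diverged, f2$diverged))
      aic_forced <- rbind(aic_forced, vapply(
        c("M1", "M2", "M3", "M4"), function(m) {
          suppressWarnings(
            fit_model(forced, m, label = "EVr+EVs-",
                      n_restarts = n_restarts, seed = i,
                      context_scope = "forced_a1"))$aic
        }, numeric(1)))
    }
  }
  params <- do.call(rbind, param_rows)
  n_diverged <- sum(params$diverged)
  if (n_diverged) {
    message(n_diverged, " ridge (diverged) fits excluded from the ",
            "parameter-dispersion comparison")
  }
  list(attenuation = context_attenuation(coef_free, coef_forced),
       dispersion = parameter_dispersion(params[!params$diverged, ]),
       forced_selection = population_best_model(as.data.frame(aic_forced),
                                                reference = "M1"),
       params = params, n_diverged = n_diverged)
}
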