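#' Extract one neuron-epoch "activity" as a modeling frame
#'
#' The analysis unit is one neuron's firing in one task epoch. This builds the
#' covariate table (see [trial_covariates()]), drops aborted trials, filters
#' by context, and exposes the epoch's firing rate as column `rate`.
#'
#' @param session A `neuron_session`, or a data frame of trial records with
#'   rate columns.
#' @param epoch "cue", "saccade" or "feedback".
#' @param context "free", "forced" or "all".
#' @return Data frame with `rate` plus all model covariates.
#' @export
activity_frame <- function(session, epoch = c("cue", "saccade", "feedback"),
                           context = c("free", "forced", "all")) {
  epoch <- match.arg(epoch)
  context <- match.arg(context)
  tr <- if (inherits(session, "neuron_session")) session$trials else as.data.frame(session)
  cov <- trial_covariates(tr)
  cov$rate <- cov[[c(cue = "rate_cue", saccade = "rate_sac",
                     feedback = "rate_fb")[[epoch]]]]
  cov <- cov[cov$aborted == 0L, , drop = FALSE]
  if (context != "all") cov <- cov[cov$context == context, , drop = FALSE]
  cov$pair <- paste0(cov$block_id, ".", cov$lp_index)
  rownames(cov) <- NULL
  cov
}

# Models that are linear in their free parameters given the covariates; their
# least-squares optimum is computed exactly by OLS.
.linear_models <- c("M2", "M3", "M4", "M5", "M6", "M7", "M8", "M9", "M10")

# Design matrix (columns named after the parameters) for the linear models.
.linear_design <- function(model_id, df) {
  n <- nrow(df)
  one <- rep(1, n)
  switch(model_id,
    M2 = cbind(rmax = df$ev1 / (df$ev1 + df$ev2), b = one),
    M3 = cbind(g = df$ev1 - df$ev2, b = one),
    M4 = cbind(rmax = (df$ev1 - df$v_min) / (df$v_max - df$v_min), b = one),
    M5 = cbind(a = df$ev_risky, b = one),
    M6 = cbind(a = df$ev_safe, b = one),
    M7 = cbind(a = df$ev_chosen, b = one),
    M8 = cbind(a = df$risky_cho, b = one),
    M9 = cbind(b = one),
    M10 = {
      cols <- lapply(1:4, function(i) {
        ind <- as.numeric(df$block_id == i)
        m <- cbind(df$ev_risky * ind, ind)
        colnames(m) <- c(paste0("a", i), paste0("b", i))
        m
      })
      do.call(cbind, cols)
    },
    stop("no linear design for ", model_id))
}

# Residuals for the nonlinear (divisive-normalization family) models; returns
# a large penalty vector when the denominator degenerates so that restarts
# started in bad regions fail gracefully.
.frac_residuals <- function(p, df, model_id, y) {
  den <- p["sigma"] + df$ev1 + df$ev2
  if (any(!is.finite(den)) || any(abs(den) < 1e-8)) {
    return(rep(1e6, length(y)))
  }
  pred <- p["rmax"] * (p["beta"] + df$ev1) / den
  pred <- pred + switch(model_id,
    M1 = 0,
    M11 = p["a"] * df$context_num,
    M12 = p["a"] * df$percent_correct,
    M13 = p["a"] * df$rt)
  r <- y - pred
  if (any(!is.finite(r))) return(rep(1e6, length(y)))
  r
}

.random_start <- function(model_id, y) {
  s <- c(rmax = stats::runif(1, 0.5, 2) * max(max(y), 1),
         beta = stats::runif(1, 1, 600),
         sigma = stats::runif(1, 1, 600))
  if (model_id != "M1") {
    s <- c(s, a = switch(model_id,
                         M11 = stats::runif(1, -10, 10),
                         M12 = stats::runif(1, -0.2, 0.2),
                         M13 = stats::runif(1, -5, 5)))
  }
  s
}

# Multi-restart Levenberg-Marquardt for the fractional models.
#
# The fractional form has an unbounded ridge (rmax, sigma -> Inf at fixed
# rmax/sigma, where it degenerates to a line in EV1) whose SSE infimum is
# never attained; a restart that stops out there by ftol reports "converged"
# but its parameter magnitudes are artifacts of the stopping rule. Solutions
# with any |parameter| beyond 1e6 (far outside the task's rate/value scales)
# are therefore classed as diverged; the best interior solution is preferred,
# and only if every converged restart diverged is the ridge solution returned,
# flagged, with a warning.
.fit_nonlinear <- function(df, model_id, y, n_restarts, seed) {
  restart_seeds <- with_seed(seed, sample.int(2^31 - 1, n_restarts))
  best <- best_ridge <- NULL
  converged <- 0L
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, maxiter = 500)
  for (j in seq_len(n_restarts)) {
    start <- with_seed(restart_seeds[j], .random_start(model_id, y))
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = .frac_residuals, df = df,
                         model_id = model_id, y = y, control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    sol <- list(params = stats::setNames(as.numeric(res$par), names(res$par)),
                sse = res$deviance)
    if (res$info %in% 1:4 && max(abs(res$par)) <= 1e6) {
      converged <- converged + 1L
      if (is.null(best) || sol$sse < best$sse) best <- sol
    } else {
      # ridge walk: stopped by ftol at absurd magnitudes or by the iteration
      # cap while still climbing; either way no interior estimate exists
      if (is.null(best_ridge) || sol$sse < best_ridge$sse) best_ridge <- sol
    }
  }
  if (converged == 0L && is.null(best_ridge)) {
    stop("fit failure for ", model_id, ": none of ", n_restarts,
         " restarts completed (n = ", length(y), ", mean rate = ",
         round(mean(y), 2), ")")
  }
  if (converged < 10L && n_restarts >= 10L) {
    warning("only ", converged, " of ", n_restarts, " restarts converged for ",
            model_id)
  }
  if (is.null(best)) {
    warning(model_id, " fit did not attain an interior minimum; returning ",
            "the ridge solution (parameter magnitudes are not interpretable)")
    best <- best_ridge
    best$diverged <- TRUE
  } else {
    best$diverged <- FALSE
  }
  best$n_converged <- converged
  best
}

.fit_linear <- function(df, model_id, y) {
  x <- .linear_design(model_id, df)
  fit <- stats::lm.fit(x, y)
  params <- fit$coefficients
  params[is.na(params)] <- 0  # rank-deficient columns carry no signal
  list(params = params, sse = sum(fit$residuals^2), n_converged = NA_integer_,
       diverged = FALSE)
}

#' Fit one model to one activity by least squares
#'
#' Models nonlinear in their parameters (M1, M11-M13) are minimized by
#' Levenberg-Marquardt from `n_restarts` random starting points (Rmax uniform
#' on 0.5-2x the observed maximum rate; beta, sigma uniform on 1-600 ul);
#' the lowest-SSE converged solution is kept. Parameters are unbounded, so
#' negative fitted beta/sigma are possible. Models linear in their parameters
#' (M2-M10) are solved exactly by ordinary least squares. AIC uses the
#' package's Gaussian least-squares convention ([aic_ls()]).
#'
#' @param activity Data frame from [activity_frame()].
#' @param model_id "M1".."M13".
#' @param label Coding type used to assign EV1/EV2 ("EVr+EVs-"/"EVr-EVs+");
#'   required for M1-M4 and M11-M13.
#' @param n_restarts Number of random restarts for nonlinear models.
#' @param seed Integer master seed; expanded into per-restart seeds.
#' @param context_scope Bookkeeping tag stored in the result.
#' @return An object of class `model_fit`: `model_id`, `params`, `sse`, `n`,
#'   `k`, `aic`, `ve_trial`, `ve_mean` (percent), `predicted`,
#'   `n_restarts_converged`, `diverged` (TRUE when only ridge solutions were
#'   found, in which case the parameter magnitudes are not interpretable),
#'   `context_scope`, `seed`.
#' @export
fit_model <- function(activity, model_id, label = NULL, n_restarts = 100,
                      seed = 1, context_scope = "free") {
  df <- as.data.frame(activity)
  k <- model_n_params(model_id)
  if (nrow(df) < 2 * k) {
    stop("activity has ", nrow(df), " trials; need at least ", 2 * k,
         " for ", model_id)
  }
  needs_ev12 <- model_id %in% c("M1", "M2", "M3", "M4", "M11", "M12", "M13")
  if (needs_ev12) {
    if (is.null(label)) stop(model_id, " needs a coding label to assign EV1/EV2")
    ev <- assign_ev1_ev2(label, df$ev_risky, df$ev_safe)
    df$ev1 <- ev$ev1
    df$ev2 <- ev$ev2
  }
  y <- df$rate
  res <- if (model_id %in% .linear_models) {
    .fit_linear(df, model_id, y)
  } else {
    .fit_nonlinear(df, model_id, y, n_restarts, seed)
  }
  spec <- model_spec(model_id, res$params)
  df$context <- df$context_num
  predicted <- predict_rate(spec, df)
  structure(
    list(model_id = model_id, params = res$params, sse = res$sse,
         n = length(y), k = k, aic = aic_ls(res$sse, length(y), k),
         ve_trial = variance_explained(y, predicted, basis = "trial"),
         ve_mean = variance_explained(y, predicted, pair = df$pair,
                                      basis = "mean20"),
         predicted = predicted, label = label,
         n_restarts_converged = res$n_converged, diverged = res$diverged,
         context_scope = context_scope, seed = seed),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Model fit: ", x$model_id, " (", x$context_scope, ", n = ", x$n,
      ")\n", sep = "")
  cat("  params: ", paste(names(x$params), "=",
                          format(x$params, digits = 4), collapse = ", "),
      "\n", sep = "")
  cat("  SSE = ", format(x$sse, digits = 6), ", AIC = ",
      format(x$aic, digits = 6), "\n", sep = "")
  cat("  VE: trial ", format(x$ve_trial, digits = 3), "%, mean ",
      format(x$ve_mean, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Percent variance explained
#'
#' One minus the residual-to-total variance ratio, in percent. The trial basis
#' uses single-trial rates; the mean20 basis first averages observed and
#' predicted rates within each of the 20 lottery-pair conditions.
#'
#' @param observed,predicted Numeric vectors of rates.
#' @param pair Condition identifier per trial (required for `basis =
#'   "mean20"`).
#' @param basis "trial" or "mean20".
#' @return Percent variance explained (can be negative for bad models; at most
#'   100). `NA` when the total variance is zero.
#' @export
variance_explained <- function(observed, predicted, pair = NULL,
                               basis = c("trial", "mean20")) {
  basis <- match.arg(basis)
  if (basis == "mean20") {
    if (is.null(pair)) stop("`pair` is required for the mean20 basis")
    observed <- as.numeric(tapply(observed, pair, mean))
    predicted <- as.numeric(tapply(predicted, pair, mean))
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(NA_real_)
  100 * (1 - sum((observed - predicted)^2) / sst)
}

#' Two-fold stratified cross-validation of a model fit
#'
#' Trials are split in half at random within each of the 20 lottery pairs
#' (the larger half goes to training for odd counts); the model is fitted to
#' the training fold and mean20-basis variance explained is reported for both
#' folds using the training-fold parameters.
#'
#' @inheritParams fit_model
#' @param seed Controls both the split and the fitting restarts.
#' @return List with `ve_train`, `ve_test` (percent), `split_seed`, and the
#'   training `fit`.
#' @export
crossvalidate <- function(activity, model_id, label = NULL, n_restarts = 20,
                          seed = 1) {
  df <- as.data.frame(activity)
  counts <- table(df$pair)
  drop_pairs <- names(counts)[counts < 2L]
  if (length(drop_pairs)) {
    message("excluding pairs with < 2 trials: ",
            paste(drop_pairs, collapse = ", "))
    df <- df[!df$pair %in% drop_pairs, , drop = FALSE]
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(df)), df$pair), function(ix) {
      sample(ix, ceiling(length(ix) / 2))
    }), use.names = FALSE)
  })
  train <- df[idx_train, , drop = FALSE]
  test <- df[-idx_train, , drop = FALSE]
  fit <- fit_model(train, model_id, label = label, n_restarts = n_restarts,
                   seed = seed)
  spec <- model_spec(model_id, fit$params)
  if (!is.null(label) &&
      model_id %in% c("M1", "M2", "M3", "M4", "M11", "M12", "M13")) {
    ev <- assign_ev1_ev2(label, test$ev_risky, test$ev_safe)
    test$ev1 <- ev$ev1
    test$ev2 <- ev$ev2
  }
  test$context <- test$context_num
  pred_test <- predict_rate(spec, test)
  list(ve_train = fit$ve_mean,
       ve_test = variance_explained(test$rate, pred_test, pair = test$pair,
                                    basis = "mean20"),
       split_seed = seed, fit = fit)
}

#' Fit a model to forced-choice trials under a value-coding assumption
#'
#' @param session A `neuron_session` or trial-record data frame.
#' @param epoch Task epoch.
#' @param assumption 1 (both cued values encoded as on free trials) or 2 (the
#'   non-selectable option's value set to zero).
#' @inheritParams fit_model
#' @return A `model_fit` with `context_scope` "forced_a1" or "forced_a2".
#' @export
fit_forced <- function(session, model_id, label = NULL, assumption = 1,
                       epoch = "cue", n_restarts = 100, seed = 1) {
  df <- activity_frame(session, epoch = epoch, context = "forced")
  if (nrow(df) == 0L) stop("no forced trials present")
  ev <- forced_choice_evs(df$ev_risky, df$ev_safe, df$instructed, assumption)
  df$ev_risky <- ev$evr
  df$ev_safe <- ev$evs
  fit_model(df, model_id, label = label, n_restarts = n_restarts, seed = seed,
            context_scope = paste0("forced_a", assumption))
}
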