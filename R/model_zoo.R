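#' @name model_zoo
#' @title The thirteen candidate firing-rate models
#'
#' @description
#' Thirteen models of trial-by-trial firing rate are compared throughout the
#' package, addressed as "M1".."M13":
#' \describe{
#'   \item{M1 (divisive normalization, "advanced fractional")}{
#'     R = Rmax (beta + EV1) / (sigma + EV1 + EV2). Rmax is the maximal rate
#'     (spikes/s); beta (ul) sets the theoretical baseline Rmax*beta/sigma when
#'     both values are zero; sigma (ul) sets value sensitivity (large sigma =
#'     low sensitivity).}
#'   \item{M2 (simple fractional)}{R = Rmax EV1/(EV1 + EV2) + b.}
#'   \item{M3 (difference)}{R = G (EV1 - EV2) + b.}
#'   \item{M4 (range normalization)}{R = Rmax (EV1 - Vmin)/(Vmax - Vmin) + b,
#'     with Vmin/Vmax the block's smallest/largest possible reward.}
#'   \item{M5-M8 (linear alternatives)}{a*EVr + b, a*EVs + b, a*EVchosen + b,
#'     a*RiskyCho + b.}
#'   \item{M9 (null)}{R = b.}
#'   \item{M10 (block-wise linear)}{R = a_i EVr + b_i in payoff block i
#'     (8 parameters).}
#'   \item{M11-M13 (state-augmented normalization)}{the M1 form plus
#'     a*Context, a*PercentCorrect or a*RT, fitted jointly to free and forced
#'     trials.}
#' }
#' EV1/EV2 are the two option values after assignment by coding type (see
#' [assign_ev1_ev2()]). Predictions of the linear models are not clipped at
#' zero, and negative fitted beta/sigma are permitted during fitting.
NULL

.model_param_names <- list(
  M1 = c("rmax", "beta", "sigma"),
  M2 = c("rmax", "b"),
  M3 = c("g", "b"),
  M4 = c("rmax", "b"),
  M5 = c("a", "b"),
  M6 = c("a", "b"),
  M7 = c("a", "b"),
  M8 = c("a", "b"),
  M9 = "b",
  M10 = c(paste0("a", 1:4), paste0("b", 1:4)),
  M11 = c("rmax", "beta", "sigma", "a"),
  M12 = c("rmax", "beta", "sigma", "a"),
  M13 = c("rmax", "beta", "sigma", "a")
)

#' Model registry: parameter names and counts
#'
#' @param model_id Model identifier "M1".."M13".
#' @return `model_param_names()` returns the named parameter vector layout;
#'   `model_n_params()` the number of free parameters.
#' @export
model_param_names <- function(model_id) {
  p <- .model_param_names[[model_id]]
  if (is.null(p)) stop("unknown model id: ", model_id)
  p
}

#' @rdname model_param_names
#' @export
model_n_params <- function(model_id) length(model_param_names(model_id))

#' Construct a model specification
#'
#' @param model_id Model identifier "M1".."M13" (see [model_zoo]).
#' @param params Named numeric vector; names must match
#'   `model_param_names(model_id)` exactly.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("M1", c(rmax = 40, beta = 20, sigma = 10))
#' @export
model_spec <- function(model_id, params) {
  expected <- model_param_names(model_id)
  params <- unlist(params)
  if (!setequal(names(params), expected) || length(params) != length(expected)) {
    stop("params for ", model_id, " must be exactly {",
         paste(expected, collapse = ", "), "}")
  }
  structure(list(model_id = model_id, params = params[expected]),
            class = "model_spec")
}

#' Assign EV1/EV2 from the coding type
#'
#' Option 1 is the option whose value the neuron's firing increases with:
#' EVr+EVs- activities get (EV1, EV2) = (EVr, EVs); EVr-EVs+ activities the
#' reverse.
#'
#' @param label Coding type, `"EVr+EVs-"` or `"EVr-EVs+"`.
#' @param evr,evs Expected values of the risky and safe options (microliters).
#' @return A list with vectors `ev1` and `ev2`.
#' @export
assign_ev1_ev2 <- function(label, evr, evs) {
  if (!label %in% c("EVr+EVs-", "EVr-EVs+")) {
    stop("coding label must be 'EVr+EVs-' or 'EVr-EVs+', got: ", label)
  }
  if (label == "EVr+EVs-") list(ev1 = evr, ev2 = evs) else list(ev1 = evs, ev2 = evr)
}

#' Option values on forced-choice trials under the two coding assumptions
#'
#' On forced trials only the color-matched option can be rewarded. Under
#' assumption 1 neurons encode both cued values exactly as on free trials;
#' under assumption 2 the non-selectable option's value is set to zero.
#'
#' @param evr,evs Cued expected values (microliters); vectors.
#' @param instructed `"risky"` or `"safe"` per trial.
#' @param assumption 1 or 2.
#' @param context Optional per-trial context vector; any `"free"` entry is an
#'   error, since the assumptions only apply to forced trials.
#' @return A list with vectors `evr` and `evs` after the assumption is applied.
#' @export
forced_choice_evs <- function(evr, evs, instructed, assumption, context = NULL) {
  if (!assumption %in% c(1, 2)) stop("`assumption` must be 1 or 2")
  if (!is.null(context) && any(context != "forced")) {
    stop("forced_choice_evs applies to forced trials only")
  }
  if (any(!instructed %in% c("risky", "safe"))) {
    stop("`instructed` must be 'risky' or 'safe' on forced trials")
  }
  if (assumption == 1) return(list(evr = evr, evs = evs))
  list(evr = ifelse(instructed == "risky", evr, 0),
       evs = ifelse(instructed == "safe", evs, 0))
}

#' Predict firing rate from a model specification
#'
#' @param spec A `model_spec`.
#' @param cov Data frame of trial covariates. Required columns depend on the
#'   model: `ev1`, `ev2` (M1-M4, M11-M13); `evr` (M5, M10), `evs` (M6),
#'   `ev_chosen` (M7), `risky_cho` (M8); `v_min`, `v_max` (M4); `block_id`
#'   (M10); `context` 1/0 free/forced (M11); `percent_correct` (M12); `rt`
#'   (M13, z-scored reaction time).
#' @return Numeric vector of predicted rates (spikes/s); linear models may
#'   predict negative rates.
#' @examples
#' m1 <- model_spec("M1", c(rmax = 40, beta = 20, sigma = 10))
#' predict_rate(m1, data.frame(ev1 = 120, ev2 = 60))  # 40*140/190
#' @export
predict_rate <- function(spec, cov) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as.list(spec$params)
  id <- spec$model_id
  # accept the trial-record column names as covariate aliases
  if (is.null(cov$evr) && !is.null(cov$ev_risky)) cov$evr <- cov$ev_risky
  if (is.null(cov$evs) && !is.null(cov$ev_safe)) cov$evs <- cov$ev_safe
  if (is.character(cov$context)) cov$context <- as.integer(cov$context == "free")
  if (is.null(cov$context) && !is.null(cov$context_num)) {
    cov$context <- cov$context_num
  }
  frac <- function() {
    den <- p$sigma + cov$ev1 + cov$ev2
    if (any(den == 0)) {
      stop("zero denominator in normalization: sigma + EV1 + EV2 = 0 (sigma = ",
           p$sigma, ")")
    }
    p$rmax * (p$beta + cov$ev1) / den
  }
  switch(id,
    M1 = frac(),
    M2 = {
      den <- cov$ev1 + cov$ev2
      if (any(den == 0)) stop("zero denominator in simple fractional model: EV1 + EV2 = 0")
      p$rmax * cov$ev1 / den + p$b
    },
    M3 = p$g * (cov$ev1 - cov$ev2) + p$b,
    M4 = {
      rng <- cov$v_max - cov$v_min
      if (any(rng <= 0)) stop("range normalization requires v_max > v_min")
      p$rmax * (cov$ev1 - cov$v_min) / rng + p$b
    },
    M5 = p$a * cov$evr + p$b,
    M6 = p$a * cov$evs + p$b,
    M7 = p$a * cov$ev_chosen + p$b,
    M8 = p$a * cov$risky_cho + p$b,
    M9 = rep(p$b, nrow(cov)),
    M10 = {
      a <- unname(unlist(p[paste0("a", 1:4)])[cov$block_id])
      b <- unname(unlist(p[paste0("b", 1:4)])[cov$block_id])
      a * cov$evr + b
    },
    M11 = frac() + p$a * cov$context,
    M12 = frac() + p$a * cov$percent_correct,
    M13 = frac() + p$a * cov$rt,
    stop("unknown model id: ", id)
  )
}
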