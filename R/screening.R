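#' AIC from a log-likelihood
#'
#' AIC = -2 log L + 2k, with k the number of free parameters.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @return AIC (unitless).
#' @export
aic_from_loglik <- function(log_likelihood, k) {
  stopifnot(k >= 0)
  -2 * log_likelihood + 2 * k
}

#' Gaussian AIC for a least-squares fit
#'
#' The package's single AIC convention for least-squares fits: AIC =
#' n log(SSE/n) + 2k, the Gaussian profile log-likelihood with additive
#' constants dropped and k counting the regression/model coefficients only.
#' Differences between fits of the same data are invariant to the dropped
#' constants.
#'
#' @param sse Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of free parameters.
#' @return AIC (unitless).
#' @export
aic_ls <- function(sse, n, k) {
  stopifnot(n > 0, k >= 0, sse >= 0)
  n * log(sse / n) + 2 * k
}

# Candidate variable order is canonical and fixed; ties in AIC are broken by
# subset size, then lexicographically in this order.
.subset_order <- c("b0", "EVr", "EVs", "Fb", "Cho")

# All subsets of `vars` (including the empty set), sorted by (size, lex order).
.enumerate_subsets <- function(vars) {
  idx <- lapply(0:length(vars), function(k) {
    if (k == 0) return(list(character(0)))
    cols <- utils::combn(vars, k, simplify = FALSE)
    cols
  })
  subsets <- unlist(idx, recursive = FALSE)
  key <- vapply(subsets, function(s) {
    paste(sprintf("%02d", match(s, .subset_order)), collapse = "")
  }, character(1))
  subsets[order(lengths(subsets), key)]
}

# OLS fit of rate on a subset of named design columns; returns NULL for
# rank-deficient subsets.
.fit_subset <- function(y, design, subset) {
  n <- length(y)
  if (length(subset) == 0L) {
    return(list(coef = numeric(0), sse = sum(y^2), k = 0L))
  }
  x <- design[, subset, drop = FALSE]
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) return(NULL)
  fit <- qr.coef(qr_x, y)
  resid <- y - x %*% fit
  list(coef = stats::setNames(as.numeric(fit), subset),
       sse = sum(resid^2), k = length(subset))
}

.label_from_subset <- function(subset, coef) {
  has <- function(v) v %in% subset
  if (has("EVr") && has("EVs") && coef["EVr"] > 0 && coef["EVs"] < 0) {
    return("EVr+EVs-")
  }
  if (has("EVr") && has("EVs") && coef["EVr"] < 0 && coef["EVs"] > 0) {
    return("EVr-EVs+")
  }
  if (has("Cho") && !has("EVr") && !has("EVs") && !has("Fb")) {
    return("choice_only")
  }
  "other"
}

# Core exhaustive-AIC engine shared by screen_activity and screen_choice.
.screen <- function(activity, epoch, rate_col, include_cho) {
  tr <- as.data.frame(activity)
  if ("context" %in% names(tr)) tr <- tr[tr$context == "free", , drop = FALSE]
  if ("aborted" %in% names(tr)) tr <- tr[tr$aborted == 0L, , drop = FALSE]
  y <- tr[[rate_col]]
  if (length(unique(tr$ev_risky)) < 2L || length(unique(tr$ev_safe)) < 2L) {
    stop("screening requires variation in both EVr and EVs (>= 2 distinct values)")
  }
  vars <- c("b0", "EVr", "EVs")
  if (epoch == "feedback") vars <- c(vars, "Fb")
  if (include_cho) {
    if (length(unique(tr$chosen_side)) < 2L) {
      stop("choice screening requires both choice sides present")
    }
    vars <- c(vars, "Cho")
  }
  design <- cbind(b0 = rep(1, nrow(tr)), EVr = tr$ev_risky, EVs = tr$ev_safe)
  if (epoch == "feedback") design <- cbind(design, Fb = tr$fb)
  if (include_cho) {
    design <- cbind(design, Cho = as.integer(tr$chosen_side == "left"))
  }
  subsets <- .enumerate_subsets(vars)
  n <- length(y)
  rows <- list()
  best <- NULL
  skipped <- character(0)
  for (s in subsets) {
    fit <- .fit_subset(y, design, s)
    if (is.null(fit)) {
      skipped <- c(skipped, paste(s, collapse = "+"))
      next
    }
    a <- aic_ls(fit$sse, n, fit$k)
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(s, collapse = "+"), k = fit$k, sse = fit$sse, aic = a)
    if (is.null(best) || a < best$aic) {
      best <- list(subset = s, coef = fit$coef, aic = a, sse = fit$sse)
    }
  }
  if (length(skipped)) {
    message("skipped rank-deficient subsets: ", paste(skipped, collapse = ", "))
  }
  structure(
    list(epoch = epoch, selected_subset = best$subset,
         coefficients = best$coef, aic = best$aic, sse = best$sse,
         n = n, label = .label_from_subset(best$subset, best$coef),
         all_subsets = do.call(rbind, rows)),
    class = "screen_result")
}

#' Screen a neuron-epoch activity for relative-value coding
#'
#' Fits ordinary least squares for every subset of the candidate regressors
#' {b0, EVr, EVs} (plus Fb in the feedback epoch), including the empty and
#' intercept-only subsets, and selects the subset with minimal Gaussian AIC.
#' The activity is labeled "EVr+EVs-" when the selected subset contains both
#' expected values with a positive EVr and negative EVs coefficient,
#' "EVr-EVs+" for the mirror pattern, and "other" otherwise. Only non-aborted
#' free-choice trials are used.
#'
#' @param activity Data frame with the epoch rate column plus `ev_risky`,
#'   `ev_safe`, and (feedback epoch) `fb`; `context`/`aborted` columns are
#'   honored if present.
#' @param epoch "cue", "saccade" or "feedback".
#' @param rate_col Name of the firing-rate column; defaults to the epoch's
#'   simulated column (`rate_cue`, `rate_sac`, `rate_fb`).
#' @return A `screen_result`: selected subset, coefficients, AIC, label, and
#'   the full subset/AIC table.
#' @export
screen_activity <- function(activity, epoch = c("cue", "saccade", "feedback"),
                            rate_col = NULL) {
  epoch <- match.arg(epoch)
  if (is.null(rate_col)) {
    rate_col <- c(cue = "rate_cue", saccade = "rate_sac",
                  feedback = "rate_fb")[[epoch]]
  }
  .screen(activity, epoch, rate_col, include_cho = FALSE)
}

#' Screen for exclusive spatial-choice coding
#'
#' As [screen_activity()], with the left/right choice indicator Cho added to
#' the candidate set. The activity is labeled "choice_only" when the selected
#' subset contains Cho and none of EVr, EVs, Fb.
#'
#' @inheritParams screen_activity
#' @return A `screen_result`.
#' @export
screen_choice <- function(activity, epoch = c("cue", "saccade", "feedback"),
                          rate_col = NULL) {
  epoch <- match.arg(epoch)
  if (is.null(rate_col)) {
    rate_col <- c(cue = "rate_cue", saccade = "rate_sac",
                  feedback = "rate_fb")[[epoch]]
  }
  .screen(activity, epoch, rate_col, include_cho = TRUE)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Activity screening (", x$epoch, " epoch, n = ", x$n, ")\n", sep = "")
  cat("  selected: {", paste(x$selected_subset, collapse = ", "),
      "}  AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  if (length(x$coefficients)) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 4))
  }
  cat("  label: ", x$label, "\n", sep = "")
  invisible(x)
}
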