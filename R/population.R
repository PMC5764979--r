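#' Population-level model selection by AIC differences
#'
#' For a reference model M and each competitor Mj, computes the per-activity
#' AIC difference AIC(M) - AIC(Mj) and tests it against zero with a two-tailed
#' one-sample t-test. The reference is declared "best" when every mean
#' difference is negative and significant at `alpha`.
#'
#' @param aic_table Data frame or matrix, one row per activity, one column per
#'   model (named by model id), holding AIC values. Rows with missing values
#'   for a given comparison are dropped pairwise.
#' @param reference Reference model id (default "M1").
#' @param alpha Significance level for the "best model" call.
#' @return List with `comparisons` (data frame: model, mean_diff, t, df, p,
#'   n), `reference`, and `best` (logical).
#' @export
population_best_model <- function(aic_table, reference = "M1", alpha = 0.05) {
  aic_table <- as.data.frame(aic_table)
  if (nrow(aic_table) < 2L) stop("need at least 2 activities")
  if (!reference %in% names(aic_table)) {
    stop("reference model ", reference, " not in table")
  }
  competitors <- setdiff(names(aic_table), reference)
  rows <- lapply(competitors, function(m) {
    d <- aic_table[[reference]] - aic_table[[m]]
    keep <- is.finite(d)
    if (sum(!keep)) {
      message(sum(!keep), " activities dropped from ", reference, " vs ", m,
              " (missing fits)")
    }
    d <- d[keep]
    if (stats::sd(d) == 0) {
      # identical AICs on every activity: no evidence either way
      return(data.frame(model = m, mean_diff = mean(d), t = 0,
                        df = length(d) - 1L, p = 1, n = length(d)))
    }
    tt <- stats::t.test(d, mu = 0)
    data.frame(model = m, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(d))
  })
  comparisons <- do.call(rbind, rows)
  list(comparisons = comparisons, reference = reference,
       best = all(comparisons$mean_diff < 0 & comparisons$p < alpha))
}

#' Homogeneity of modulated-activity proportions across epochs
#'
#' Chi-squared test (df = 2) on the 2 x 3 table of modulated vs non-modulated
#' counts in the cue, saccade and feedback epochs. When any expected cell
#' count is zero the chi-squared statistic is undefined and Fisher's exact
#' test is reported instead (flagged in the result).
#'
#' @param modulated Integer vector of modulated counts per epoch (length 3).
#' @param total Integer vector of totals per epoch (length 3, or scalar).
#' @return List with `counts`, `proportions`, `statistic`, `df`, `p`,
#'   `method`.
#' @export
epoch_proportions <- function(modulated, total) {
  if (length(total) == 1L) total <- rep(total, length(modulated))
  stopifnot(length(modulated) == 3L, length(total) == 3L,
            all(modulated <= total))
  tab <- rbind(modulated = modulated, unmodulated = total - modulated)
  colnames(tab) <- c("cue", "saccade", "feedback")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ft <- stats::fisher.test(tab)
    return(list(counts = tab, proportions = modulated / total,
                statistic = NA_real_, df = NA_integer_, p = ft$p.value,
                method = "fisher (zero expected cell)"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(counts = tab, proportions = modulated / total,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, method = "chi-squared")
}

#' Free-choice regression coefficients of one activity
#'
#' Ordinary least-squares coefficients of rate on EVr and EVs (with
#' intercept; plus Fb in the feedback epoch), the full-model analogue of the
#' screening regression, used for free-vs-forced comparisons.
#'
#' @param activity Data frame from [activity_frame()].
#' @param epoch Task epoch (adds the Fb regressor for "feedback").
#' @return Named coefficient vector with elements `b0`, `EVr`, `EVs` (and
#'   `Fb`).
#' @export
value_coefficients <- function(activity, epoch = "cue") {
  df <- as.data.frame(activity)
  x <- cbind(b0 = 1, EVr = df$ev_risky, EVs = df$ev_safe)
  if (epoch == "feedback") x <- cbind(x, Fb = df$fb)
  fit <- stats::lm.fit(x, df$rate)
  stats::setNames(as.numeric(fit$coefficients), colnames(x))
}

#' Free-vs-forced attenuation of value coefficients
#'
#' Paired two-tailed t-tests on |b_EVr| and |b_EVs| between free and forced
#' choice trials across activities.
#'
#' @param coef_free,coef_forced Matrices/data frames with columns `EVr` and
#'   `EVs`, one row per activity, in matching order.
#' @return List with one entry per coefficient: mean +/- sem in each context
#'   and the paired t-test (t, df, p).
#' @export
context_attenuation <- function(coef_free, coef_forced) {
  coef_free <- as.data.frame(coef_free)
  coef_forced <- as.data.frame(coef_forced)
  stopifnot(nrow(coef_free) == nrow(coef_forced))
  if (nrow(coef_free) < 2L) stop("insufficient pairs: need >= 2 activities")
  out <- lapply(c("EVr", "EVs"), function(v) {
    a <- abs(coef_free[[v]])
    b <- abs(coef_forced[[v]])
    if (all(a == b)) {
      tt <- list(statistic = 0, parameter = length(a) - 1L, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    list(coefficient = v,
         free_mean = mean(a), free_sem = sem(a),
         forced_mean = mean(b), forced_sem = sem(b),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  })
  stats::setNames(out, c("EVr", "EVs"))
}

#' Per-bin value coefficients across the trial block
#'
#' Regression coefficients for EVr and EVs estimated in 12-trial bins from
#' the start of each payoff block (pooled across the four blocks by
#' within-block trial index): three forced bins (trials 1-36) and four free
#' bins (trials 37-84; trailing trials beyond the last full bin are dropped).
#'
#' @param session A `neuron_session` or trial-record data frame.
#' @param epoch Task epoch.
#' @param bin_size Trials per bin (default 12).
#' @return Data frame: `bin`, `context`, `n_trials`, `b_EVr`, `b_EVs`.
#' @export
binned_coefficients <- function(session, epoch = "cue", bin_size = 12) {
  df <- activity_frame(session, epoch = epoch, context = "all")
  df$bin <- ceiling(df$trial / bin_size)
  n_forced_bins <- 36 %/% bin_size
  n_bins_total <- 84 %/% bin_size   # drops the last 2 free trials
  dropped <- sum(df$bin > n_bins_total)
  if (dropped) {
    message(dropped, " trials beyond the last full bin dropped")
    df <- df[df$bin <= n_bins_total, , drop = FALSE]
  }
  out <- lapply(sort(unique(df$bin)), function(b) {
    d <- df[df$bin == b, , drop = FALSE]
    cf <- value_coefficients(d, epoch = epoch)
    data.frame(bin = b,
               context = if (b <= n_forced_bins) "forced" else "free",
               n_trials = nrow(d), b_EVr = cf[["EVr"]], b_EVs = cf[["EVs"]])
  })
  do.call(rbind, out)
}

#' Population tests on binned coefficients
#'
#' One-way ANOVA on |coefficient| across bins within each context (EVr and
#' EVs rows pooled, as in a per-activity x coefficient-type long table) and a
#' paired two-tailed t-test between the last forced bin and the first free
#' bin.
#'
#' @param binned Row-bound output of [binned_coefficients()] over many
#'   activities, with an `activity_id` column.
#' @return List with `anova_forced`, `anova_free` (F, df, p, n) and
#'   `boundary_t` (t, df, p, n).
#' @export
binned_coefficient_tests <- function(binned) {
  long <- rbind(
    data.frame(activity_id = binned$activity_id, bin = binned$bin,
               context = binned$context, coef = "EVr",
               value = abs(binned$b_EVr)),
    data.frame(activity_id = binned$activity_id, bin = binned$bin,
               context = binned$context, coef = "EVs",
               value = abs(binned$b_EVs)))
  one_way <- function(d) {
    fit <- stats::aov(value ~ factor(bin), data = d)
    s <- summary(fit)[[1]]
    list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
         p = s[["Pr(>F)"]][1], n = nrow(d))
  }
  last_forced <- max(binned$bin[binned$context == "forced"])
  first_free <- min(binned$bin[binned$context == "free"])
  a <- long[long$bin == last_forced, ]
  b <- long[long$bin == first_free, ]
  key <- function(d) paste(d$activity_id, d$coef)
  b <- b[match(key(a), key(b)), ]
  tt <- stats::t.test(a$value, b$value, paired = TRUE)
  list(anova_forced = one_way(long[long$context == "forced", ]),
       anova_free = one_way(long[long$context == "free", ]),
       boundary_t = list(t = unname(tt$statistic),
                         df = unname(tt$parameter), p = tt$p.value,
                         n = nrow(a)))
}

#' Dispersion of fitted parameters across task phases
#'
#' Brown-Forsythe test (median-centered Levene) for each normalization
#' parameter across the phases (forced, 1st half of free, 2nd half of free
#' trials), and Kruskal-Wallis tests across groups on the same columns.
#'
#' @param params Data frame with a `phase` (or `group`) column and one column
#'   per parameter (e.g. `rmax`, `beta`, `sigma`).
#' @param columns Parameter columns to test.
#' @return List per parameter with `brown_forsythe` (F, df, p) and
#'   `kruskal` (statistic, df, p); constant groups are flagged with NA
#'   statistics.
#' @export
parameter_dispersion <- function(params, columns = c("rmax", "beta", "sigma")) {
  df <- as.data.frame(params)
  gcol <- if ("phase" %in% names(df)) "phase" else "group"
  g <- factor(df[[gcol]])
  stopifnot(nlevels(g) >= 2L, all(table(g) >= 3L))
  out <- lapply(columns, function(v) {
    x <- df[[v]]
    const <- any(tapply(x, g, function(z) stats::sd(z) == 0))
    bf <- if (const) {
      list(F = NA_real_, df = NA, p = NA_real_,
           note = "constant group: statistic undefined")
    } else {
      lt <- car::leveneTest(x, g, center = stats::median)
      list(F = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
           p = lt[1, "Pr(>F)"])
    }
    kw <- stats::kruskal.test(x, g)
    list(parameter = v, brown_forsythe = bf,
         kruskal = list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p = kw$p.value))
  })
  stats::setNames(out, columns)
}

#' Sanity correlations of fitted normalization parameters
#'
#' Pearson correlations between (i) fitted Rmax and each activity's observed
#' maximal firing rate and (ii) the model's theoretical baseline
#' Rmax * beta / sigma and the observed pre-cue baseline rate. Rows with
#' negative fitted beta or sigma are excluded from the baseline relation (the
#' ratio is not a baseline there).
#'
#' @param table Data frame with columns `rmax`, `beta`, `sigma`, `max_rate`,
#'   `baseline_rate`.
#' @return List with `max_rate` and `baseline` entries (r, t, df, p, n);
#'   degenerate (zero-variance) relations return NA with a note.
#' @export
parameter_sanity <- function(table) {
  df <- as.data.frame(table)
  ct <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(r = NA_real_, t = NA_real_, df = NA, p = NA_real_,
                  n = length(x), note = "degenerate: zero variance or n < 3"))
    }
    h <- stats::cor.test(x, y)
    list(r = unname(h$estimate), t = unname(h$statistic),
         df = unname(h$parameter), p = h$p.value, n = length(x))
  }
  neg <- df$beta < 0 | df$sigma < 0
  if (any(neg)) {
    message(sum(neg), " activities with negative beta/sigma excluded from ",
            "the baseline relation")
  }
  ok <- df[!neg, , drop = FALSE]
  list(max_rate = ct(df$rmax, df$max_rate),
       baseline = ct(ok$rmax * ok$beta / ok$sigma, ok$baseline_rate))
}

#' Equal-expected-value activity deviation of one activity
#'
#' For each payoff block, the condition-mean rates of lottery pairs 1-5 are
#' regressed on the value difference EVr - EVs; the deviation is the mean
#' observed LP3 (equal-EV) rate minus the fit's prediction at zero value
#' difference, averaged over blocks. Positive deviations mean the neuron fires
#' more at the equal-EV pair than its value tuning predicts.
#'
#' @param activity Data frame from [activity_frame()] (free trials).
#' @return Deviation in spikes/s.
#' @export
equal_ev_deviation <- function(activity) {
  df <- as.data.frame(activity)
  devs <- vapply(sort(unique(df$block_id)), function(b) {
    d <- df[df$block_id == b, , drop = FALSE]
    m <- stats::aggregate(rate ~ lp_index, data = d, FUN = mean)
    vd <- stats::aggregate((ev_risky - ev_safe) ~ lp_index, data = d,
                           FUN = mean)
    names(vd)[2] <- "vdiff"
    m <- merge(m, vd, by = "lp_index")
    fit <- stats::lm(rate ~ vdiff, data = m)
    pred0 <- unname(stats::coef(fit)[1])   # prediction at EVr = EVs
    m$rate[m$lp_index == 3] - pred0
  }, numeric(1))
  mean(devs)
}

#' Correlation between risk attitude and equal-EV activity deviation
#'
#' Pearson correlation, per coding type, between each session's behavioral
#' risk attitude (percentage of risky choices on free trials) and the
#' neuron's equal-EV activity deviation (see [equal_ev_deviation()]).
#'
#' @param table Data frame with columns `label` ("EVr+EVs-"/"EVr-EVs+"),
#'   `deviation` and `risky_pct`, one row per activity/session.
#' @return Named list per coding type with (r, t, df, p, n); groups with
#'   fewer than 3 sessions or zero variance are flagged.
#' @export
risk_attitude_correlation <- function(table) {
  df <- as.data.frame(table)
  out <- lapply(c("EVr+EVs-", "EVr-EVs+"), function(lab) {
    d <- df[df$label == lab, , drop = FALSE]
    if (nrow(d) < 3L) {
      return(list(r = NA_real_, p = NA_real_, n = nrow(d),
                  note = "fewer than 3 sessions"))
    }
    if (stats::sd(d$deviation) == 0 || stats::sd(d$risky_pct) == 0) {
      return(list(r = 0, p = NA_real_, n = nrow(d),
                  note = "degenerate: zero variance"))
    }
    h <- stats::cor.test(d$deviation, d$risky_pct)
    list(r = unname(h$estimate), t = unname(h$statistic),
         df = unname(h$parameter), p = h$p.value, n = nrow(d))
  })
  stats::setNames(out, c("EVr+EVs-", "EVr-EVs+"))
}
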