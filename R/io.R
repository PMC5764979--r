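#' Write simulated sessions to delimited text
#'
#' One CSV row per trial (columns: neuron_id, block_id, trial, context,
#' lp_index, safe_mag_ul, risky_mag_ul, ev_risky, ev_safe, instructed,
#' risky_side, v_min, v_max, choice, chosen_side, rewarded, reward_ul, fb,
#' rt_ms, aborted, rate_cue, rate_sac, rate_fb). Numeric columns are written
#' at full double precision so that write-then-read is the identity. Ground
#' truth and per-session scalars go to a YAML sidecar `<path>.truth.yaml`.
#'
#' @param sessions List of `neuron_session` objects.
#' @param path Output CSV path.
#' @param truth_sidecar Write the ground-truth sidecar file?
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, truth_sidecar = TRUE) {
  cols <- c("neuron_id", "block_id", "trial", "context", "lp_index",
            "safe_mag_ul", "risky_mag_ul", "ev_safe", "ev_risky",
            "instructed", "risky_side", "v_min", "v_max", "choice",
            "chosen_side", "rewarded", "reward_ul", "fb", "rt_ms", "aborted",
            "rate_cue", "rate_sac", "rate_fb")
  tab <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    tr$neuron_id <- s$neuron_id
    tr[, cols]
  }))
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (truth_sidecar) {
    truth <- lapply(sessions, function(s) {
      gt <- s$ground_truth
      list(neuron_id = s$neuron_id, model_id = gt$model_id,
           coding_type = gt$coding_type,
           params = as.list(gt$params),
           forced_attenuation = gt$forced_attenuation, fb_coef = gt$fb_coef,
           baseline_rate = s$baseline_rate, max_rate = s$max_rate)
    })
    yaml::write_yaml(truth, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' Read sessions back from delimited text
#'
#' Columns are matched by name, so column order is free. Missing or extra
#' columns raise a schema error naming the offenders. If the ground-truth
#' sidecar written by [write_sessions()] is present it is restored; otherwise
#' sessions carry `ground_truth = NULL` and baseline/max rates are recomputed
#' from the stored rates where possible.
#'
#' @param path CSV path written by [write_sessions()].
#' @return List of `neuron_session` objects.
#' @export
read_sessions <- function(path) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop("parse error in ", path, ": ", conditionMessage(e))
                  })
  expected <- c("neuron_id", "block_id", "trial", "context", "lp_index",
                "safe_mag_ul", "risky_mag_ul", "ev_safe", "ev_risky",
                "instructed", "risky_side", "v_min", "v_max", "choice",
                "chosen_side", "rewarded", "reward_ul", "fb", "rt_ms",
                "aborted", "rate_cue", "rate_sac", "rate_fb")
  missing <- setdiff(expected, names(tab))
  extra <- setdiff(names(tab), expected)
  if (length(missing) || length(extra)) {
    stop("session schema mismatch; missing: {",
         paste(missing, collapse = ", "), "}, extra: {",
         paste(extra, collapse = ", "), "}")
  }
  sidecar <- paste0(path, ".truth.yaml")
  truth <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  truth_by_id <- if (!is.null(truth)) {
    stats::setNames(truth, vapply(truth, `[[`, "", "neuron_id"))
  } else NULL
  lapply(split(tab, tab$neuron_id)[unique(tab$neuron_id)], function(tr) {
    id <- tr$neuron_id[1]
    tr <- tr[order(match(tr$block_id, unique(tr$block_id)), tr$trial),
             setdiff(names(tr), "neuron_id")]
    rownames(tr) <- NULL
    gt <- NULL
    baseline <- NA_real_
    if (!is.null(truth_by_id) && id %in% names(truth_by_id)) {
      rec <- truth_by_id[[id]]
      gt <- ground_truth(rec$model_id, unlist(rec$params), rec$coding_type,
                         rec$forced_attenuation, rec$fb_coef)
      baseline <- rec$baseline_rate
    }
    structure(list(neuron_id = id, ground_truth = gt, trials = tr,
                   baseline_rate = baseline,
                   max_rate = max(tr$rate_cue, tr$rate_sac, tr$rate_fb)),
              class = "neuron_session")
  })
}

#' Pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param n_neurons Number of simulated neurons.
#' @param truth Named list: `model_id`, `params`, `coding_type`,
#'   `forced_attenuation`, `fb_coef` (single ground truth applied to every
#'   neuron unless `truth_sampler` is supplied to [run_pipeline()]).
#' @param behavior Named list of [behavior_params()] arguments.
#' @param models Model ids fitted in the fitting stage.
#' @param n_restarts Restarts per nonlinear fit.
#' @param epoch Task epoch analyzed.
#' @param out_dir Output directory for stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_neurons = 10,
                            truth = list(model_id = "M1",
                                         params = c(rmax = 40, beta = 20,
                                                    sigma = 60),
                                         coding_type = "EVr+EVs-",
                                         forced_attenuation = 1, fb_coef = 0),
                            behavior = list(), models = c("M1", "M2", "M3", "M4"),
                            n_restarts = 30, epoch = "cue",
                            out_dir = tempfile("valuenorm_run_")) {
  bad <- setdiff(models, names(.model_param_names))
  if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "))
  model_spec(truth$model_id, truth$params)  # validates before any compute
  structure(list(seed = seed, n_neurons = n_neurons, truth = truth,
                 behavior = behavior, models = models,
                 n_restarts = n_restarts, epoch = epoch, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$truth$params)) raw$truth$params <- unlist(raw$truth$params)
  do.call(pipeline_config, raw)
}

#' Run the full simulation-to-population pipeline
#'
#' Stages: (1) simulate sessions (schedules, behavior, spiking); (2) screen
#' every activity for relative-value coding; (3) fit the configured model set
#' to every relative-value activity on free trials; (4) population model
#' selection by AIC differences; (5) behavioral summary; (6) run manifest.
#' All tables are written as CSV under `config$out_dir`; reruns with the same
#' config reproduce the outputs bit-for-bit.
#'
#' @param config A `pipeline_config` (or path to a YAML config file).
#' @param truth_sampler Optional function `(i) -> ground_truth` overriding
#'   `config$truth`.
#' @return Invisibly, a list with the in-memory stage results (`sessions`,
#'   `screening`, `fits`, `aic_table`, `selection`, `behavior`,
#'   `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config, truth_sampler = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(truth_sampler)) {
    tt <- config$truth
    truth_sampler <- function(i) {
      ground_truth(tt$model_id, tt$params, tt$coding_type,
                   tt$forced_attenuation %||% 1, tt$fb_coef %||% 0)
    }
  }
  beh <- do.call(behavior_params, config$behavior)
  sessions <- generate_dataset(config$n_neurons, truth_sampler, beh,
                               seed = config$seed)
  write_sessions(sessions, file.path(config$out_dir, "sessions.csv"))

  screening <- do.call(rbind, lapply(sessions, function(s) {
    sc <- screen_activity(activity_frame(s, config$epoch, context = "free"),
                          epoch = config$epoch,
                          rate_col = "rate")
    data.frame(neuron_id = s$neuron_id, epoch = config$epoch,
               selected_subset = paste(sc$selected_subset, collapse = "+"),
               aic = sc$aic, label = sc$label)
  }))
  utils::write.csv(screening, file.path(config$out_dir, "screening.csv"),
                   row.names = FALSE)

  value_ids <- screening$neuron_id[screening$label %in%
                                     c("EVr+EVs-", "EVr-EVs+")]
  fits <- list()
  for (id in value_ids) {
    s <- sessions[[match(id, vapply(sessions, `[[`, "", "neuron_id"))]]
    lab <- screening$label[screening$neuron_id == id]
    act <- activity_frame(s, config$epoch, context = "free")
    for (m in config$models) {
      f <- fit_model(act, m, label = lab, n_restarts = config$n_restarts,
                     seed = config$seed)
      fits[[length(fits) + 1L]] <- data.frame(
        neuron_id = id, epoch = config$epoch, model_id = m,
        context_scope = f$context_scope,
        params = paste(names(f$params), round(f$params, 6), sep = "=",
                       collapse = ";"),
        sse = f$sse, aic = f$aic, ve_trial = f$ve_trial, ve_mean = f$ve_mean)
    }
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  if (!is.null(fits)) {
    utils::write.csv(fits, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
  }

  selection <- NULL
  if (!is.null(fits) && length(unique(fits$neuron_id)) >= 2L) {
    aic_table <- stats::reshape(
      fits[, c("neuron_id", "model_id", "aic")], direction = "wide",
      idvar = "neuron_id", timevar = "model_id")
    names(aic_table) <- sub("^aic\\.", "", names(aic_table))
    selection <- population_best_model(aic_table[, config$models,
                                                 drop = FALSE],
                                       reference = config$models[1])
    utils::write.csv(selection$comparisons,
                     file.path(config$out_dir, "population.csv"),
                     row.names = FALSE)
  } else {
    aic_table <- NULL
  }

  behavior <- do.call(rbind, lapply(sessions, function(s) {
    cbind(neuron_id = s$neuron_id, behavior_summary(s$trials))
  }))
  utils::write.csv(behavior, file.path(config$out_dir, "behavior.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = config$seed, n_neurons = config$n_neurons,
    models = config$models, n_restarts = config$n_restarts,
    epoch = config$epoch,
    n_value_coding = length(value_ids),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("valuenorm")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sessions = sessions, screening = screening, fits = fits,
                 aic_table = aic_table, selection = selection,
                 behavior = behavior, manifest = manifest,
                 out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
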