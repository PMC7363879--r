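# Workflow orchestration: generate a synthetic study, fit subjects, analyse
# gaze and model fit, and run the end-to-end parameter-recovery experiment.
# Each step reads a configuration (an R list or a YAML file), logs the seed
# and a configuration hash into its outputs, and writes plain-text artifacts
# (CSV + JSON) into an output directory.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

# small polynomial rolling hash of the deparsed configuration (stays within
# double precision), for provenance stamps
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) {
    h <- (h * 33 + b) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

check_config <- function(config, allowed) {
  bad <- setdiff(names(config), allowed)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  config
}

stamp <- function(config, seed) {
  list(seed = seed, config_hash = config_hash(config),
       package = "gaddm",
       version = as.character(utils::packageVersion("gaddm")))
}

#' Generate a synthetic study to disk
#'
#' Wraps [gen_study()]: writes `trials.csv`, `fixations.csv` and
#' `truth.json` (ground-truth parameters plus the seed and a config hash)
#' into `out_dir`.
#'
#' @param config A list (or YAML file path) of [generative_config()]
#'   arguments plus an optional `seed`.
#' @param out_dir Output directory (created if needed).
#' @return The [gen_study()] result, invisibly.
#' @export
run_generate <- function(config = list(), out_dir = "gaddm_out") {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  config$seed <- NULL
  check_config(config, names(formals(generative_config)))
  gc_args <- do.call(generative_config, config)
  study <- gen_study(gc_args, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(study$trials, file.path(out_dir, "trials.csv"))
  write_fixations(study$fixations, file.path(out_dir, "fixations.csv"))
  truth <- lapply(study$truth, function(x) {
    list(M = as.list(x$M), delta = as.list(x$delta),
         p_self_first = as.list(x$p_self_first))
  })
  jsonlite::write_json(c(list(meta = stamp(config, seed)), truth),
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(study)
}

#' Fit subjects from disk
#'
#' Reads `trials.csv`/`fixations.csv` from `data_dir`, screens subjects with
#' [exclusion_screen()], fits every kept subject with [addm()], and writes a
#' per-subject JSON summary (posterior means, R-hat, acceptance rate) plus a
#' CSV of posterior draws.
#'
#' @param config List or YAML path with optional keys `model`
#'   (`"gaze"`/`"static"`), `preset`, `seed`, `extend_gaze`.
#' @param data_dir Directory holding the input tables.
#' @param out_dir Output directory.
#' @return A named list of `"addm_fit"` objects, invisibly.
#' @export
run_fit <- function(config = list(), data_dir = "gaddm_out",
                    out_dir = file.path(data_dir, "fits")) {
  config <- read_config(config)
  check_config(config, c("model", "preset", "seed", "extend_gaze"))
  model <- config$model %||% "gaze"
  preset <- config$preset %||% "scaled_down"
  set.seed(config$seed %||% 1L)
  trials <- read_trials(file.path(data_dir, "trials.csv"))
  fixations <- if (model == "gaze") {
    read_fixations(file.path(data_dir, "fixations.csv"))
  } else NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- exclusion_screen(trials)
  write.csv(screen, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  fits <- list()
  for (s in screen$subject[screen$keep]) {
    tr <- trials[trials$subject == s, ]
    fx <- if (!is.null(fixations)) {
      fixations[fixations$subject == s, ]
    } else NULL
    fit <- addm(tr, fx, model = model, preset = preset,
                extend_gaze = isTRUE(config$extend_gaze))
    fits[[s]] <- fit
    jsonlite::write_json(list(
      meta = stamp(config, config$seed %||% 1L),
      subject = s, model = model, preset = preset,
      estimates = as.data.frame(fit$estimates),
      rhat = as.list(fit$rhat), converged = fit$converged,
      accept_rate = fit$accept_rate,
      n_migrations = fit$n_migrations,
      reset_chains = fit$reset_chains
    ), file.path(out_dir, paste0("fit_", s, ".json")), auto_unbox = TRUE,
    digits = NA)
    flat <- matrix(fit$draws, ncol = 16)
    colnames(flat) <- dimnames(fit$draws)[[3]]
    write.csv(flat, file.path(out_dir, paste0("draws_", s, ".csv")),
              row.names = FALSE)
  }
  invisible(fits)
}

#' Gaze and model-evaluation report
#'
#' Runs the gaze-occupancy cluster-permutation tests (bias within each
#' condition and the high-vs-low contrast), per-subject early gaze biases
#' with the Brown-Forsythe variance comparison, and (optionally) the
#' split-half cross-validation model comparison; writes CSV/JSON reports.
#'
#' @param config List or YAML path with optional keys `seed`, `n_perm`,
#'   `horizon_ms`, `run_cv`, `cv_preset`, `cv_n_sims`.
#' @param data_dir Directory holding `trials.csv` and `fixations.csv`.
#' @param out_dir Report directory.
#' @return A list with the cluster results, early-bias tables and (if run)
#'   the `"cv_result"`, invisibly.
#' @export
run_analyze <- function(config = list(), data_dir = "gaddm_out",
                        out_dir = file.path(data_dir, "report")) {
  config <- read_config(config)
  check_config(config, c("seed", "n_perm", "horizon_ms", "run_cv",
                         "cv_preset", "cv_n_sims"))
  set.seed(config$seed %||% 1L)
  n_perm <- config$n_perm %||% 1000
  horizon <- config$horizon_ms %||% 837
  trials <- read_trials(file.path(data_dir, "trials.csv"))
  fixations <- read_fixations(file.path(data_dir, "fixations.csv"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  occ_h <- occupancy(trials, fixations, "HIGH", horizon)
  occ_l <- occupancy(trials, fixations, "LOW", horizon)
  res <- list(
    bias_high = permutation_tmax(occ_h, contrast = "BIAS", n_perm = n_perm),
    bias_low = permutation_tmax(occ_l, contrast = "BIAS", n_perm = n_perm),
    condition = permutation_tmax(occ_h, occ_l, contrast = "CONDITION",
                                 n_perm = n_perm))
  for (nm in names(res)) {
    write.csv(res[[nm]]$clusters,
              file.path(out_dir, paste0("clusters_", nm, ".csv")),
              row.names = FALSE)
  }
  early_h <- early_gaze_bias_by_subject(trials, fixations, "HIGH")
  early_l <- early_gaze_bias_by_subject(trials, fixations, "LOW")
  bf <- brown_forsythe(list(high = early_h, low = early_l))
  early <- data.frame(subject = names(early_h), bias_high = early_h,
                      bias_low = early_l[names(early_h)])
  write.csv(early, file.path(out_dir, "early_gaze_bias.csv"),
            row.names = FALSE)
  out <- list(clusters = res, early_bias = early, brown_forsythe = bf)
  if (isTRUE(config$run_cv)) {
    cv <- split_half_cv(trials, fixations,
                        preset = config$cv_preset %||% "mini",
                        n_sims = config$cv_n_sims %||% 1000)
    write.csv(cv$per_subject, file.path(out_dir, "cv_per_subject.csv"),
              row.names = FALSE)
    out$cv <- cv
  }
  jsonlite::write_json(list(
    meta = stamp(config, config$seed %||% 1L),
    brown_forsythe = bf,
    cluster_counts = lapply(res, function(r) nrow(r$clusters)),
    cv_correlations = if (!is.null(out$cv)) out$cv$correlations else NULL
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a synthetic study, screens out response-invariant subjects
#' (the same more-than-90%-same-response rule applied before any model
#' fitting), fits the remaining subjects with the gaze model, and
#' correlates ground-truth with posterior-mean parameters across the fitted
#' subjects (pooling the two conditions).
#'
#' @param config List or YAML path: [generative_config()] keys plus `seed`,
#'   `preset` (default `"mini"`), `sampler` (named list of
#'   [sampler_settings()] overrides, e.g. `list(n_burn = 300)`), `screen`
#'   (apply the exclusion rule, default `TRUE`) and `n_fit` (fit at most
#'   this many kept subjects).
#' @param out_dir Optional directory for a JSON summary (`NULL` to skip).
#' @return A list with `truth`, `estimates` (per fitted subject x
#'   condition) and the named vector `recovery_r` of truth/estimate
#'   correlations per parameter.
#' @export
run_recovery <- function(config = list(), out_dir = NULL) {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  preset <- config$preset %||% "recovery"
  screen <- config$screen %||% TRUE
  n_fit <- config$n_fit %||% Inf
  settings <- do.call(sampler_settings,
                      c(list(preset = preset), config$sampler))
  config$seed <- NULL
  config$preset <- NULL
  config$screen <- NULL
  config$n_fit <- NULL
  config$sampler <- NULL
  check_config(config, names(formals(generative_config)))
  study <- gen_study(do.call(generative_config, config), seed = seed)
  keep <- if (screen) {
    sc <- exclusion_screen(study$trials)
    sc$subject[sc$keep]
  } else {
    unique(study$trials$subject)
  }
  keep <- head(keep, n_fit)
  truth <- truth_table(study)
  truth <- truth[truth$subject %in% keep, ]
  est_rows <- list()
  i0 <- 0L
  for (sid in unique(study$trials$subject)) {
    tr <- study$trials[study$trials$subject == sid, ]
    tls <- study$timelines[i0 + seq_len(nrow(tr))]
    i0 <- i0 + nrow(tr)
    if (!sid %in% keep) next
    fit <- addm(tr, model = "gaze", settings = settings, timelines = tls)
    for (cc in c("HIGH", "LOW")) {
      est_rows[[length(est_rows) + 1]] <- data.frame(
        subject = sid, condition = cc,
        t(fit$estimates[, cc]))
    }
  }
  est <- do.call(rbind, est_rows)
  recovery_r <- vapply(ADDM_PARAMS, function(p) {
    cor(truth[[p]], est[[p]])
  }, numeric(1))
  out <- list(truth = truth, estimates = est, recovery_r = recovery_r)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(truth, file.path(out_dir, "recovery_truth.csv"),
              row.names = FALSE)
    write.csv(est, file.path(out_dir, "recovery_estimates.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(meta = stamp(config, seed),
                              recovery_r = as.list(recovery_r)),
                         file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
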