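# File round-tripping (trajectory CSV + JSON sidecar, cue CSV, responses
# CSV, YAML run configuration) and the end-to-end pipeline.

#' Write / read a trajectory
#'
#' The trajectory goes to a long-format CSV (`trial_id, frame, dot_id, role,
#' x_deg, y_deg, heading_deg, override`); the trial spec and display
#' configuration go to a JSON sidecar (`<path>.json`) so the pair
#' round-trips losslessly.
#'
#' @param traj a `chase_trajectory`.
#' @param path CSV path; the sidecar is written next to it.
#' @param trial_id identifier stored in the CSV.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a list with `data` (the long data frame), `spec` and `config`.
#' @export
write_trajectory <- function(traj, path, trial_id = 1L) {
  utils::write.csv(as.data.frame(traj, trial_id = trial_id), path,
                   row.names = FALSE)
  sidecar <- list(spec = unclass(traj$spec), config = unclass(traj$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- utils::read.csv(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(trial_spec, sc$spec)
  config <- do.call(sim_config, sc$config)
  list(data = data, spec = spec, config = config)
}

#' Write a cue track alongside a trajectory
#'
#' Long-format CSV: `trial_id, frame, dot_id, cue_kind, value`.
#'
#' @param cues a `chase_cue_track`.
#' @param path CSV path.
#' @param trial_id identifier stored in the CSV.
#' @export
write_cue_track <- function(cues, path, trial_id = 1L) {
  nf <- nrow(cues$values); nd <- ncol(cues$values)
  utils::write.csv(data.frame(
    trial_id = trial_id,
    frame = rep(0:(nf - 1L), nd),
    dot_id = rep(seq_len(nd), each = nf),
    cue_kind = cues$kind,
    value = as.vector(cues$values)
  ), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' One document holding everything a full run needs: display constants,
#' generative model parameters, design sizes and the master seed, from which
#' every stage seed is derived deterministically.
#'
#' @param sim a [sim_config()].
#' @param params a [glmm_params()].
#' @param n_per_group participants per group.
#' @param n_present,n_absent test trials per subtlety per condition.
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), params = glmm_params(),
                       n_per_group = 24, n_present = 20, n_absent = 5,
                       seed = 1L) {
  structure(list(sim = sim, params = params, n_per_group = n_per_group,
                 n_present = n_present, n_absent = n_absent,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(sim = unclass(config$sim),
                        params = unclass(config$params),
                        n_per_group = config$n_per_group,
                        n_present = config$n_present,
                        n_absent = config$n_absent,
                        seed = config$seed), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(sim = do.call(sim_config, y$sim),
             params = do.call(glmm_params, y$params),
             n_per_group = y$n_per_group, n_present = y$n_present,
             n_absent = y$n_absent, seed = y$seed)
}

# stage seeds derived from the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) (seed * 7L + stage * 104729L) %% .Machine$integer.max

#' Run the full pipeline
#'
#' design -> cohort -> simulated responses -> random-intercept logistic fit
#' -> accuracy and d-prime summaries. All randomness flows from the master
#' seed; identical configurations give identical bundles. Outputs are
#' optionally written under `out_dir` (responses and summaries as CSV, the
#' fit's Wald table as JSON), stamped with the configuration hash and seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param fit if `FALSE`, stop after simulating responses.
#' @return list with `design`, `cohort`, `responses`, `fit`, `accuracy`,
#'   `dprime`, `override_counts` (constraint-override diagnostics are on the
#'   trajectory path; `NULL` here), `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, fit = TRUE) {
  n_participants <- 2L * config$n_per_group
  design <- build_design(n_participants, n_present = config$n_present,
                         n_absent = config$n_absent,
                         seed = .stage_seed(config$seed, 1L))
  cohort <- sample_cohort(config$n_per_group, config$params,
                          seed = .stage_seed(config$seed, 2L))
  responses <- simulate_study(design, cohort, config$params,
                              seed = .stage_seed(config$seed, 3L))
  fit_obj <- if (fit) fit_random_intercept_logistic(responses) else NULL
  acc <- accuracy_summary(responses)
  dp <- dprime_table(responses)

  tmp <- tempfile(fileext = ".yaml")
  write_run_config(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(responses, file.path(out_dir, "responses.csv"), row.names = FALSE)
    utils::write.csv(acc, file.path(out_dir, "accuracy_summary.csv"), row.names = FALSE)
    utils::write.csv(dp, file.path(out_dir, "dprime_summary.csv"), row.names = FALSE)
    if (fit) jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           fixed_effects = wald_table(fit_obj, warn_only = TRUE),
           sigma_u = fit_obj$sigma_u, converged = fit_obj$converged,
           n_obs = fit_obj$n_obs, n_participants = fit_obj$n_participants),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  list(design = design, cohort = cohort, responses = responses, fit = fit_obj,
       accuracy = acc, dprime = dp, config_hash = hash, seed = config$seed)
}

#' Constraint-override diagnostics for a set of trials
#'
#' Simulates each requested trial and counts, per trial, the frames on which
#' a constraint override replaced a dot's heading -- a diagnostic for how
#' often the wolf--sheep floor and the collision rule bite.
#'
#' @param specs list of [trial_spec()]s.
#' @param config a [sim_config()].
#' @return data frame `seed, subtlety, chase_present, n_override_frames,
#'   n_wolf_overrides`.
#' @export
override_counts <- function(specs, config = sim_config()) {
  do.call(rbind, lapply(specs, function(sp) {
    tr <- simulate_trial(sp, config)
    data.frame(seed = sp$seed, subtlety = sp$subtlety,
               chase_present = sp$chase_present,
               n_override_frames = sum(tr$override),
               n_wolf_overrides = sum(tr$override[, tr$wolf]))
  }))
}
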