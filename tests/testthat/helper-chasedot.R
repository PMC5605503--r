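# shared helpers for the chasedot test suite

# simulate a batch of trials and return the list
sim_batch <- function(n, subtlety, present = TRUE, condition = "baseline",
                      seed_base = 0L, config = sim_config()) {
  lapply(seq_len(n), function(k)
    simulate_trial(trial_spec(condition, subtlety, present, seed = seed_base + k),
                   config))
}

# minimum over frames of the wolf--sheep centre distance
min_wolf_sheep <- function(tr) min(dot_distance(tr, tr$wolf, tr$sheep))

# minimum over frames and visible pairs of the centre distance
min_pair_dist <- function(tr) {
  vis <- which(tr$visible)
  prs <- utils::combn(vis, 2)
  min(apply(prs, 2, function(p) min(dot_distance(tr, p[1], p[2]))))
}

# signed wolf heading deviations from the sheep bearing at clean chasing
# update events
wolf_update_devs <- function(tr) {
  u <- tr$updates[tr$updates$chasing & !tr$updates$override, ]
  signed_angle_diff(u$heading, u$bearing)
}

# signed heading changes of randomly moving dots at clean update events
# (excluding frame 0 where there is no previous update)
random_update_turns <- function(tr, roles = "distractor") {
  u <- tr$updates[tr$updates$role %in% roles & !tr$updates$override &
                    !tr$updates$chasing, ]
  signed_angle_diff(u$heading, u$prev_heading)
}

# minimal hand-built trajectory for closed-form observer checks
straight_chase_traj <- function(n_frames = 100, step = 0.1) {
  x <- cbind(wolf = (0:(n_frames - 1)) * step, sheep = rep(50, n_frames),
             d1 = rep(-10, n_frames), d2 = rep(-12, n_frames))
  y <- matrix(0, n_frames, 4); y[, 3] <- 5; y[, 4] <- -5
  structure(list(
    x = unname(x), y = y,
    heading = matrix(0, n_frames, 4),
    override = matrix(FALSE, n_frames, 4),
    roles = c("wolf", "sheep", "distractor", "distractor"),
    visible = rep(TRUE, 4), wolf = 1L, sheep = 2L,
    spec = trial_spec("baseline", 0, TRUE, seed = 1L),
    config = sim_config(),
    updates = data.frame()
  ), class = "chase_trajectory")
}

# simulate one full synthetic study and return the responses
quick_study <- function(n_per_group, params = glmm_params(), seed = 1L,
                        n_present = 20, n_absent = 5) {
  cohort <- sample_cohort(n_per_group, params, seed = seed)
  design <- build_design(2L * n_per_group, n_present = n_present,
                         n_absent = n_absent, seed = seed + 1L)
  simulate_study(design, cohort, params, seed = seed + 2L)
}

table1_truth <- c(-1.13, -0.39, 0.17, 0.23, -0.05, 0.66, 0.15, 0.01)

# hand-built responses: one participant-cell with given hit/false-alarm counts
make_cell <- function(hits, n_present, fas, n_absent, pid = "P01", group = "TD") {
  pres <- data.frame(chase_present = TRUE,
                     response_present = rep(c(TRUE, FALSE), c(hits, n_present - hits)))
  abs_ <- data.frame(chase_present = FALSE,
                     response_present = rep(c(TRUE, FALSE), c(fas, n_absent - fas)))
  out <- rbind(pres, abs_)
  out$participant_id <- pid; out$group <- group
  out$condition <- "baseline"; out$subtlety <- 45; out$age <- 14
  out$correct <- out$response_present == out$chase_present
  out
}
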