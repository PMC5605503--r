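#' Display and kinematics configuration
#'
#' Bundles all constants of the chase display: frame rate, trial duration,
#' dot speed and size, the heading-resampling window of the randomly moving
#' dots, the direction-update interval, the wolf--sheep minimum distance, the
#' chase-onset delay, and the arena geometry.
#'
#' Defaults reproduce the standard display: 60 Hz, 3000 ms trials, dots of
#' 1 degree moving at 14.5 degrees of visual angle per second, random
#' direction changes within a 120 degree window approximately every 170 ms,
#' a 5 degree wolf--sheep floor, and a 170 ms chase-onset delay. The arena is
#' a 48 x 30 degree rectangle (a 24-inch 16:10 monitor viewed at 57 cm) with
#' specular boundary reflection.
#'
#' @param frame_rate display refresh rate, Hz.
#' @param trial_duration trial length, ms.
#' @param dot_speed constant dot speed, degrees of visual angle per second.
#' @param dot_diameter dot size, degrees; also the minimum centre-to-centre
#'   separation allowed between any two dots.
#' @param random_window full width, degrees, of the uniform window from which
#'   randomly moving dots resample their heading.
#' @param direction_update_interval time between heading updates, ms.
#' @param wolf_sheep_min_dist minimum wolf--sheep centre distance, degrees.
#' @param chase_onset_delay time at the start of a trial during which the
#'   wolf moves like a random dot, ms.
#' @param arena_width,arena_height arena extent, degrees of visual angle.
#' @param boundary_mode `"reflect"` (specular heading reflection at walls) or
#'   `"resample"` (redraw a random heading until the step stays inside).
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config()
#' cfg$dot_speed / cfg$frame_rate  # per-frame step, degrees
#' @export
sim_config <- function(frame_rate = 60,
                       trial_duration = 3000,
                       dot_speed = 14.5,
                       dot_diameter = 1,
                       random_window = 120,
                       direction_update_interval = 170,
                       wolf_sheep_min_dist = 5,
                       chase_onset_delay = 170,
                       arena_width = 48,
                       arena_height = 30,
                       boundary_mode = c("reflect", "resample")) {
  boundary_mode <- match.arg(boundary_mode)
  cfg <- list(
    frame_rate = frame_rate, trial_duration = trial_duration,
    dot_speed = dot_speed, dot_diameter = dot_diameter,
    random_window = random_window,
    direction_update_interval = direction_update_interval,
    wolf_sheep_min_dist = wolf_sheep_min_dist,
    chase_onset_delay = chase_onset_delay,
    arena_width = arena_width, arena_height = arena_height,
    boundary_mode = boundary_mode
  )
  num <- cfg[setdiff(names(cfg), "boundary_mode")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))))
    stop("all numeric sim_config fields must be single positive finite numbers")
  cfg[names(num)] <- lapply(num, as.numeric)  # stable types across serialization
  if (cfg$random_window > 360) stop("random_window must not exceed 360 degrees")
  if (cfg$wolf_sheep_min_dist <= cfg$dot_diameter)
    stop("wolf_sheep_min_dist must exceed dot_diameter")
  structure(cfg, class = "sim_config")
}

#' Specification of a single trial
#'
#' @param condition `"baseline"`, `"social"` (gaze cues) or `"nonsocial"`
#'   (luminance cues).
#' @param subtlety chasing subtlety: the maximal angular deviation (degrees,
#'   half-window) of the wolf's heading from the bearing to its sheep.
#'   0 is perfect heat-seeking; the study used 15, 45 and 75.
#' @param chase_present logical; if `FALSE` the wolf chases a fifth,
#'   invisible sheep so the visible display contains no chase.
#' @param seed integer seed from which the whole trial is reproducible.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(condition = c("baseline", "social", "nonsocial"),
                       subtlety = 45, chase_present = TRUE, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(subtlety), length(subtlety) == 1L,
            subtlety >= 0, subtlety <= 180,
            is.logical(chase_present), length(chase_present) == 1L,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(condition = condition, subtlety = as.numeric(subtlety),
                 chase_present = chase_present, seed = as.integer(seed)),
            class = "trial_spec")
}

#' Fixed effects and random-intercept SD of the generative accuracy model
#'
#' Parameters of the random-intercept logistic model for trial-by-trial
#' detection accuracy. The linear predictor is
#' \deqn{\eta = \beta_0 + \beta_G G + \beta_A A + \beta_T T + \beta_S S +
#'       \beta_{soc} I_{soc} + \beta_{non} I_{non} + \beta_{GS} G S + u,}
#' with \eqn{G} group (TD = 0, ASD = 1), \eqn{A} age in years, \eqn{T} trial
#' type (chase-present = 1), \eqn{S} subtlety in degrees, condition dummies
#' against the baseline condition, and a participant intercept
#' \eqn{u \sim N(0, \sigma_u^2)}. `P(correct) = plogis(eta)`.
#'
#' Defaults are the published fixed-effect estimates of the paradigm's
#' reference fit; the random-intercept SD is not published and defaults
#' to 0.8 logits.
#'
#' @param beta_intercept,beta_group,beta_age,beta_trialtype,beta_subtlety,beta_social,beta_nonsocial,beta_group_x_subtlety
#'   fixed effects, logit units (subtlety terms per degree, age per year).
#' @param sigma_u SD of the participant random intercept, logits (>= 0).
#' @return An object of class `glmm_params`.
#' @export
glmm_params <- function(beta_intercept = -1.13,
                        beta_group = -0.39,
                        beta_age = 0.17,
                        beta_trialtype = 0.23,
                        beta_subtlety = -0.05,
                        beta_social = 0.66,
                        beta_nonsocial = 0.15,
                        beta_group_x_subtlety = 0.01,
                        sigma_u = 0.8) {
  stopifnot(sigma_u >= 0)
  structure(list(beta_intercept = beta_intercept, beta_group = beta_group,
                 beta_age = beta_age, beta_trialtype = beta_trialtype,
                 beta_subtlety = beta_subtlety, beta_social = beta_social,
                 beta_nonsocial = beta_nonsocial,
                 beta_group_x_subtlety = beta_group_x_subtlety,
                 sigma_u = sigma_u),
            class = "glmm_params")
}

# internal: frame counts derived from a config
.n_frames <- function(config) as.integer(round(config$trial_duration * config$frame_rate / 1000))
.delay_frames <- function(config) as.integer(round(config$chase_onset_delay * config$frame_rate / 1000))
.update_interval_frames <- function(config) {
  k <- as.integer(round(config$direction_update_interval * config$frame_rate / 1000))
  max(k, 1L)
}
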