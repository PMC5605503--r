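# Heuristic, trajectory-based observers: an item-by-item visual-search
# account of chase detection. Evidence for "dot i chases dot j" is scored
# from the motion (and optionally the cue) signals of the ordered pair; the
# observer responds "present" when the best pair's evidence clears a
# criterion.

#' Chase-evidence statistics for one ordered dot pair
#'
#' For the hypothesis that `pair[1]` (candidate wolf) chases `pair[2]`
#' (candidate sheep):
#' * `heading_alignment` -- mean over frames of the cosine of the angle
#'   between the candidate wolf's heading and its bearing to the candidate
#'   sheep (1 for perfect heat-seeking, ~0 for unrelated walkers);
#' * `proximity` -- the negative slope of the pair distance over time,
#'   normalised by the mean distance (chasing pairs close in);
#' * `cue_consistency` (when `cues` are given) -- gaze: mean cosine of
#'   (gaze - bearing to candidate sheep); luminance: magnitude-squared
#'   coherence of the two dots' tracks at the pair frequency (3 Hz).
#'
#' @param traj a `chase_trajectory`.
#' @param pair integer length-2: ordered (candidate wolf, candidate sheep)
#'   indices among the visible dots.
#' @param cues optional `chase_cue_track` from [eye_track()] or
#'   [color_track()].
#' @return named numeric vector `heading_alignment, proximity,
#'   cue_consistency` (the last `NA` without cues).
#' @export
chase_statistics <- function(traj, pair, cues = NULL) {
  stopifnot(inherits(traj, "chase_trajectory"), length(pair) == 2L)
  vis <- which(traj$visible)
  if (!all(pair %in% vis)) stop("invalid pair: both dots must be visible")
  w <- pair[1]; s <- pair[2]
  bear <- wrap_deg(atan2(traj$y[, s] - traj$y[, w],
                         traj$x[, s] - traj$x[, w]) * 180 / pi)
  alignment <- mean(cospi(signed_angle_diff(traj$heading[, w], bear) / 180))
  d <- dot_distance(traj, w, s)
  tt <- (seq_along(d) - 1) / traj$config$frame_rate
  slope <- stats::cov(tt, d) / stats::var(tt)
  proximity <- -slope / mean(d)
  cue <- NA_real_
  if (!is.null(cues)) {
    wc <- match(w, vis); sc <- match(s, vis)
    if (cues$kind == "gaze") {
      cue <- mean(cospi(signed_angle_diff(cues$values[, wc], bear) / 180))
    } else {
      cue <- .band_coherence(cues$values[, wc], cues$values[, sc],
                             freq = 3, frame_rate = traj$config$frame_rate)
    }
  }
  c(heading_alignment = alignment, proximity = proximity, cue_consistency = cue)
}

#' Heuristic observer parameters
#'
#' @param w_alignment,w_proximity,w_cue weights of the three pair statistics.
#' @param criterion decision criterion on the maximal pair score.
#' @param noise_sd SD of Gaussian decision noise (>= 0).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(w_alignment = 1, w_proximity = 0, w_cue = 0,
                            criterion = 0.5, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  structure(list(w_alignment = w_alignment, w_proximity = w_proximity,
                 w_cue = w_cue, criterion = criterion, noise_sd = noise_sd),
            class = "observer_params")
}

#' Evidence scores for all ordered visible pairs
#'
#' @param traj a `chase_trajectory`.
#' @param cues optional `chase_cue_track`.
#' @param params an [observer_params()].
#' @return data frame with one row per ordered visible pair: `wolf, sheep`,
#'   the three statistics and the weighted `score`.
#' @export
pair_scores <- function(traj, cues = NULL, params = observer_params()) {
  vis <- which(traj$visible)
  pairs <- expand.grid(wolf = vis, sheep = vis)
  pairs <- pairs[pairs$wolf != pairs$sheep, ]
  st <- t(apply(pairs, 1L, function(p) chase_statistics(traj, c(p[1], p[2]), cues)))
  cue <- ifelse(is.na(st[, "cue_consistency"]), 0, st[, "cue_consistency"])
  score <- params$w_alignment * st[, "heading_alignment"] +
    params$w_proximity * st[, "proximity"] + params$w_cue * cue
  cbind(pairs, as.data.frame(st), score = unname(score))
}

#' One trial's detection response from a heuristic observer
#'
#' Scores all 12 ordered visible pairs, adds Gaussian decision noise to the
#' maximum, and responds "present" when it exceeds the criterion. When
#' responding present, the quadrant of the best candidate sheep's final
#' position is reported (1 = upper right, counterclockwise).
#'
#' @inheritParams pair_scores
#' @return one-row data frame: `response_present, correct, quadrant,
#'   max_score`.
#' @export
heuristic_observer_response <- function(traj, cues = NULL,
                                        params = observer_params()) {
  sc <- pair_scores(traj, cues, params)
  best <- which.max(sc$score)
  evidence <- sc$score[best] +
    if (params$noise_sd > 0) stats::rnorm(1, 0, params$noise_sd) else 0
  present <- evidence > params$criterion
  quadrant <- NA_integer_
  if (present) {
    s <- sc$sheep[best]
    fx <- traj$x[nrow(traj$x), s]; fy <- traj$y[nrow(traj$y), s]
    quadrant <- if (fx >= 0 && fy >= 0) 1L else if (fx < 0 && fy >= 0) 2L
      else if (fx < 0 && fy < 0) 3L else 4L
  }
  data.frame(response_present = present,
             correct = present == traj$spec$chase_present,
             quadrant = quadrant, max_score = sc$score[best])
}
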