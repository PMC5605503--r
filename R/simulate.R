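# Trial simulator: random-walk distractors, a subtlety-constrained wolf,
# per-frame collision and wolf--sheep distance constraints, reflecting arena.

# one Euler step with pre-emptive specular reflection: if the straight step
# would exit the arena, the offending heading component is mirrored first, so
# every realised step has exactly length `step`.
.step_with_boundary <- function(x, y, heading, step, half_w, half_h, mode) {
  h <- heading
  dx <- step * cospi(h / 180); dy <- step * sinpi(h / 180)
  if (mode == "resample") {
    tries <- 0L
    while ((x + dx > half_w || x + dx < -half_w ||
            y + dy > half_h || y + dy < -half_h) && tries < 100L) {
      h <- stats::runif(1, 0, 360)
      dx <- step * cospi(h / 180); dy <- step * sinpi(h / 180)
      tries <- tries + 1L
    }
  }
  # reflect (also the terminal fallback for resample); each axis independently
  if (x + dx > half_w || x + dx < -half_w) {
    h <- wrap_deg(180 - h)
    dx <- step * cospi(h / 180)
  }
  if (y + dy > half_h || y + dy < -half_h) {
    h <- wrap_deg(-h)
    dy <- step * sinpi(h / 180)
  }
  c(x + dx, y + dy, h)
}

# constraint margins (distance minus threshold) of dot i at (nx, ny) against
# the reference positions `rx, ry` (other dots as of the moment i moves):
# dot_diameter against every other dot; the wolf--sheep floor against
# `partner_idx` (the sheep when the wolf moves, the wolf when the sheep
# moves -- the floor is a property of the pair, so both sides maintain it)
.margins <- function(nx, ny, i, rx, ry, partner_idx, cfg) {
  d <- sqrt((rx - nx)^2 + (ry - ny)^2)
  thr <- rep(cfg$dot_diameter, length(rx))
  if (!is.na(partner_idx)) thr[partner_idx] <- cfg$wolf_sheep_min_dist
  m <- d - thr
  m[i] <- Inf
  m
}

.violates <- function(nx, ny, i, rx, ry, partner_idx, cfg) {
  min(.margins(nx, ny, i, rx, ry, partner_idx, cfg)) < 0
}

# escape heading when both the sampled and the previous heading violate:
# steer directly away from the worst violator (the object with the smallest
# margin on the continuation position); if several objects violate at once
# and that direction still breaks a constraint, pick the direction
# maximising the minimum constraint margin at the next position
.escape_heading <- function(x, y, i, prev_heading, rx, ry, partner_idx,
                            step, hw, hh, mode, cfg) {
  cont <- .step_with_boundary(x, y, prev_heading, step, hw, hh, mode)
  j <- which.min(.margins(cont[1], cont[2], i, rx, ry, partner_idx, cfg))
  away <- bearing_deg(c(rx[j], ry[j]), c(x, y))
  s <- .step_with_boundary(x, y, away, step, hw, hh, mode)
  if (!.violates(s[1], s[2], i, rx, ry, partner_idx, cfg)) return(s)
  best <- s; best_m <- min(.margins(s[1], s[2], i, rx, ry, partner_idx, cfg))
  for (h in seq(0, 357, by = 3)) {
    cand <- .step_with_boundary(x, y, h, step, hw, hh, mode)
    m <- min(.margins(cand[1], cand[2], i, rx, ry, partner_idx, cfg))
    if (m > best_m) { best <- cand; best_m <- m }
  }
  best
}

#' Advance one dot by one frame
#'
#' Moves a dot along its heading by `speed / frame_rate` degrees, handling the
#' arena boundary according to `config$boundary_mode`. With `"reflect"`, a
#' step that would exit the arena mirrors the heading component at the wall
#' before moving, so the realised step always has exact length.
#'
#' @param state a dot state: list with `position` (length-2 numeric, degrees)
#'   and `heading` (degrees); other fields are carried through.
#' @param speed dot speed, degrees per second.
#' @param config a [sim_config()].
#' @return The updated state (same shape as `state`).
#' @export
advance_dot <- function(state, speed, config) {
  s <- .step_with_boundary(state$position[1], state$position[2], state$heading,
                           speed / config$frame_rate,
                           config$arena_width / 2, config$arena_height / 2,
                           config$boundary_mode)
  state$position <- s[1:2]
  state$heading <- s[3]
  state
}

#' Resolve movement constraints for a proposed heading
#'
#' Implements the display's two hard rules: no two dots may come closer than
#' `dot_diameter` (no hits or crossings), and the wolf--sheep pair may never
#' come within `wolf_sheep_min_dist` (both members of the pair maintain the
#' floor). If the proposed heading's next position
#' violates a rule the dot keeps its previous heading; if that also violates,
#' it steers directly away from the most-violated constraint's object (the
#' one whose margin at the continuation position is smallest).
#'
#' @param proposed_heading candidate heading, degrees.
#' @param dot the moving dot: list with `position`, `heading` and `role`
#'   (`"wolf"`, `"sheep"`, `"distractor"` or `"invisible_sheep"`).
#' @param others list of the other dots' states (same shape).
#' @param config a [sim_config()].
#' @return list with `heading` (degrees) and `override` (logical; `TRUE` when
#'   the proposed heading was replaced).
#' @export
resolve_constraints <- function(proposed_heading, dot, others, config) {
  rx <- vapply(others, function(o) o$position[1], numeric(1))
  ry <- vapply(others, function(o) o$position[2], numeric(1))
  roles <- vapply(others, function(o) o$role, character(1))
  partner <- if (identical(dot$role, "wolf")) {
    which(roles %in% c("sheep", "invisible_sheep"))[1]
  } else if (dot$role %in% c("sheep", "invisible_sheep")) {
    which(roles == "wolf")[1]
  } else NA_integer_
  if (is.na(partner)) partner <- NA_integer_
  step <- config$dot_speed / config$frame_rate
  x <- dot$position[1]; y <- dot$position[2]
  try_h <- function(h) {
    nx <- x + step * cospi(h / 180); ny <- y + step * sinpi(h / 180)
    !.violates(nx, ny, 0L, rx, ry, partner, config)
  }
  if (try_h(proposed_heading))
    return(list(heading = wrap_deg(proposed_heading), override = FALSE))
  if (try_h(dot$heading))
    return(list(heading = wrap_deg(dot$heading), override = TRUE))
  nx <- x + step * cospi(dot$heading / 180); ny <- y + step * sinpi(dot$heading / 180)
  j <- which.min(.margins(nx, ny, 0L, rx, ry, partner, config))
  away <- bearing_deg(c(rx[j], ry[j]), c(x, y))
  list(heading = away, override = TRUE)
}

#' Simulate one chase-detection trial
#'
#' Generates the full dot trajectory of one trial. Three (chase-present) or
#' four (chase-absent) visible dots move as correlated random walks: constant
#' speed, heading resampled within `random_window` at staggered update events
#' every `direction_update_interval` ms. The remaining visible dot is the
#' wolf: after the chase-onset delay its heading is resampled, at its update
#' events, uniformly within `subtlety` degrees of the bearing to its sheep --
#' a visible dot on chase-present trials, a fifth invisible dot on
#' chase-absent trials (the only difference between the two trial types).
#' Collision and wolf--sheep distance constraints are enforced every frame as
#' in [resolve_constraints()].
#'
#' The whole trial is reproducible from `spec$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [trial_spec()].
#' @param config a [sim_config()].
#' @return An object of class `chase_trajectory`: matrices `x`, `y`,
#'   `heading`, `override` (frames x dots, frame 0 in row 1), `roles`,
#'   `visible`, the `spec` and `config`, and `updates`, a data frame logging
#'   every heading-update event (frame, dot, role, previous/sampled/final
#'   heading, bearing to the sheep for chasing events, `chasing` and
#'   `override` flags).
#' @examples
#' tr <- simulate_trial(trial_spec("baseline", 15, TRUE, seed = 7))
#' nrow(tr$x)  # 180 frames at 60 Hz x 3000 ms
#' @export
simulate_trial <- function(spec, config = sim_config()) {
  stopifnot(inherits(spec, "trial_spec"), inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  roles <- if (spec$chase_present) {
    c("wolf", "sheep", "distractor", "distractor")
  } else {
    c("wolf", "distractor", "distractor", "distractor", "invisible_sheep")
  }
  n_dots <- length(roles)
  visible <- roles != "invisible_sheep"
  wolf <- 1L
  sheep <- which(roles %in% c("sheep", "invisible_sheep"))
  dist_idx <- which(roles == "distractor")
  move_order <- c(sheep, dist_idx, wolf)  # wolf last: it reacts to the moved sheep

  nf <- .n_frames(config)
  delay <- .delay_frames(config)
  interval <- .update_interval_frames(config)
  step <- config$dot_speed / config$frame_rate
  hw <- config$arena_width / 2; hh <- config$arena_height / 2

  # initial placement: uniform rejection sampling
  placed <- FALSE
  for (try in seq_len(10000L)) {
    px <- stats::runif(n_dots, -hw, hw)
    py <- stats::runif(n_dots, -hh, hh)
    dmat <- as.matrix(stats::dist(cbind(px, py)))
    diag(dmat) <- Inf
    if (min(dmat) >= config$dot_diameter && dmat[wolf, sheep] > config$wolf_sheep_min_dist) {
      placed <- TRUE; break
    }
  }
  if (!placed) stop("initialization error: could not place dots after 10000 retries")

  cur_h <- stats::runif(n_dots, 0, 360)
  phase <- sample.int(interval, n_dots, replace = TRUE) - 1L

  x <- matrix(NA_real_, nf, n_dots); y <- matrix(NA_real_, nf, n_dots)
  h <- matrix(NA_real_, nf, n_dots); ov <- matrix(FALSE, nf, n_dots)
  x[1, ] <- px; y[1, ] <- py; h[1, ] <- cur_h

  # update-event log
  cap <- n_dots * (nf %/% interval + 2L)
  up_frame <- integer(cap); up_dot <- integer(cap); up_prev <- numeric(cap)
  up_samp <- numeric(cap); up_final <- numeric(cap); up_bear <- numeric(cap)
  up_chase <- logical(cap); up_ov <- logical(cap); n_up <- 0L

  cx <- px; cy <- py
  for (t in seq_len(nf - 1L)) {
    rx <- cx; ry <- cy  # reference positions, refreshed as dots move
    for (i in move_order) {
      partner <- if (i == wolf) sheep else if (i == sheep) wolf else NA_integer_
      is_update <- (t %% interval) == phase[i]
      chasing <- is_update && i == wolf && t >= delay
      prev <- cur_h[i]
      bear <- NA_real_
      if (is_update) {
        if (chasing) {
          bear <- bearing_deg(c(rx[i], ry[i]), c(rx[sheep], ry[sheep]))
          sampled <- if (spec$subtlety == 0) bear else
            wrap_deg(bear + stats::runif(1, -spec$subtlety, spec$subtlety))
        } else {
          sampled <- wrap_deg(prev + stats::runif(1, -config$random_window / 2,
                                                  config$random_window / 2))
        }
      } else sampled <- prev

      # candidate headings in priority order; boundary handled per candidate
      chosen <- NULL; override <- FALSE
      s1 <- .step_with_boundary(rx[i], ry[i], sampled, step, hw, hh, config$boundary_mode)
      if (!.violates(s1[1], s1[2], i, rx, ry, partner, config)) {
        chosen <- s1
        override <- is_update && s1[3] != sampled  # boundary replaced a sampled heading
      } else if (is_update) {
        s2 <- .step_with_boundary(rx[i], ry[i], prev, step, hw, hh, config$boundary_mode)
        if (!.violates(s2[1], s2[2], i, rx, ry, partner, config)) {
          chosen <- s2; override <- TRUE
        }
      }
      if (is.null(chosen)) {  # constraint escape (see .escape_heading)
        chosen <- .escape_heading(rx[i], ry[i], i, prev, rx, ry, partner,
                                  step, hw, hh, config$boundary_mode, config)
        override <- TRUE
      }

      cx[i] <- chosen[1]; cy[i] <- chosen[2]; cur_h[i] <- chosen[3]
      rx[i] <- chosen[1]; ry[i] <- chosen[2]
      ov[t + 1L, i] <- override
      if (is_update) {
        n_up <- n_up + 1L
        up_frame[n_up] <- t; up_dot[n_up] <- i; up_prev[n_up] <- prev
        up_samp[n_up] <- sampled; up_final[n_up] <- cur_h[i]
        up_bear[n_up] <- bear; up_chase[n_up] <- chasing; up_ov[n_up] <- override
      }
    }
    x[t + 1L, ] <- cx; y[t + 1L, ] <- cy; h[t + 1L, ] <- cur_h
  }

  ix <- seq_len(n_up)
  updates <- data.frame(
    frame = up_frame[ix], dot = up_dot[ix], role = roles[up_dot[ix]],
    prev_heading = up_prev[ix], sampled_heading = up_samp[ix],
    heading = up_final[ix], bearing = up_bear[ix],
    chasing = up_chase[ix], override = up_ov[ix]
  )
  structure(list(x = x, y = y, heading = h, override = ov,
                 roles = roles, visible = visible,
                 wolf = wolf, sheep = sheep,
                 spec = spec, config = config, updates = updates),
            class = "chase_trajectory")
}

#' @export
print.chase_trajectory <- function(x, ...) {
  cat(sprintf("<chase_trajectory> %d frames, %d dots (%d visible), %s, subtlety %g, chase %s, seed %d\n",
              nrow(x$x), length(x$roles), sum(x$visible), x$spec$condition,
              x$spec$subtlety, if (x$spec$chase_present) "present" else "absent",
              x$spec$seed))
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x a `chase_trajectory`.
#' @param row.names,optional unused.
#' @param trial_id identifier written into the `trial_id` column.
#' @param ... unused.
#' @return data frame with columns `trial_id, frame, dot_id, role, x_deg,
#'   y_deg, heading_deg, override` (frame is 0-based).
#' @export
as.data.frame.chase_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                           trial_id = 1L, ...) {
  nf <- nrow(x$x); nd <- length(x$roles)
  data.frame(
    trial_id = trial_id,
    frame = rep(0:(nf - 1L), nd),
    dot_id = rep(seq_len(nd), each = nf),
    role = rep(x$roles, each = nf),
    x_deg = as.vector(x$x), y_deg = as.vector(x$y),
    heading_deg = as.vector(x$heading),
    override = as.vector(x$override)
  )
}

#' Pairwise distance series between two dots
#' @param traj a `chase_trajectory`.
#' @param i,j dot indices.
#' @return numeric vector, one distance per frame, degrees.
#' @keywords internal
#' @export
dot_distance <- function(traj, i, j) {
  sqrt((traj$x[, i] - traj$x[, j])^2 + (traj$y[, i] - traj$y[, j])^2)
}
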