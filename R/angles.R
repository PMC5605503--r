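#' Angle helpers (degrees, 0 = +x, counterclockwise)
#'
#' `wrap_deg()` wraps angles to \[0, 360); `signed_angle_diff()` returns the
#' signed difference `a - b` wrapped to (-180, 180]; `bearing_deg()` gives the
#' direction from one point to another.
#'
#' @param a,b angles in degrees.
#' @return degrees.
#' @keywords internal
#' @export
wrap_deg <- function(a) a %% 360

#' @rdname wrap_deg
#' @export
signed_angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname wrap_deg
#' @param from,to numeric length-2 points `(x, y)` in degrees of visual angle,
#'   or matrices with x/y columns.
#' @export
bearing_deg <- function(from, to) {
  if (is.matrix(from) || is.matrix(to)) {
    from <- rbind(from); to <- rbind(to)
    wrap_deg(atan2(to[, 2] - from[, 2], to[, 1] - from[, 1]) * 180 / pi)
  } else {
    wrap_deg(atan2(to[2] - from[2], to[1] - from[1]) * 180 / pi)
  }
}

#' Sample a heading for a randomly moving dot
#'
#' New headings are drawn uniformly within a window of full width `window`
#' centred on the previous heading, the rule that makes the distractor dots
#' move "haphazardly".
#'
#' @param prev_heading previous heading, degrees.
#' @param window full window width, degrees, in (0, 360].
#' @param n number of draws.
#' @return heading(s) in \[0, 360).
#' @examples
#' set.seed(1)
#' sample_random_heading(0, 120)  # within 60 degrees of 0
#' @export
sample_random_heading <- function(prev_heading, window, n = 1L) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window <= 0 || window > 360)
    stop("`window` must be a positive width of at most 360 degrees")
  wrap_deg(prev_heading + stats::runif(n, -window / 2, window / 2))
}

#' Sample the wolf's heading towards its sheep
#'
#' The chasing dot's heading is drawn uniformly within `subtlety` degrees on
#' either side of the instantaneous bearing to the sheep; the window is always
#' centred on the (moving) sheep. Subtlety 0 is perfect heat-seeking.
#'
#' @param wolf_pos,sheep_pos length-2 positions `(x, y)`, degrees.
#' @param subtlety half-window width, degrees, in \[0, 180\].
#' @param n number of draws.
#' @return heading(s) in \[0, 360).
#' @export
sample_wolf_heading <- function(wolf_pos, sheep_pos, subtlety, n = 1L) {
  stopifnot(subtlety >= 0, subtlety <= 180)
  if (all(wolf_pos == sheep_pos))
    stop("degenerate geometry: wolf and sheep positions coincide")
  b <- bearing_deg(wolf_pos, sheep_pos)
  if (subtlety == 0) return(rep(b, n))
  wrap_deg(b + stats::runif(n, -subtlety, subtlety))
}
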