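# Condition-specific cue signals: gaze orientation (social condition) and
# sinusoidal luminance modulation (non-social condition).

#' Gaze-orientation track for a social-condition trial
#'
#' Every visible dot carries eyes. On chase-present trials the wolf's eyes
#' point at the sheep's instantaneous position on every frame; all other dots
#' (and the wolf on chase-absent trials, where pointing at the invisible
#' sheep would betray trial type) gaze along their own heading.
#'
#' @param traj a `chase_trajectory` with `condition = "social"`.
#' @param wolf_gazes_invisible if `TRUE`, the wolf gazes at the invisible
#'   sheep on chase-absent trials instead of along its own heading.
#' @return A `chase_cue_track`: list with `kind = "gaze"`, `values` (frames x
#'   visible dots matrix of orientations in \[0, 360)) and `params`.
#' @export
eye_track <- function(traj, wolf_gazes_invisible = FALSE) {
  stopifnot(inherits(traj, "chase_trajectory"))
  if (traj$spec$condition != "social")
    stop("condition mismatch: eye_track requires a social-condition trial")
  vis <- which(traj$visible)
  g <- traj$heading[, vis, drop = FALSE]
  if (traj$spec$chase_present || wolf_gazes_invisible) {
    w <- traj$wolf; s <- traj$sheep
    g[, match(w, vis)] <- wrap_deg(atan2(traj$y[, s] - traj$y[, w],
                                         traj$x[, s] - traj$x[, w]) * 180 / pi)
  }
  g <- wrap_deg(g)
  structure(list(kind = "gaze", values = g,
                 params = list(wolf_gazes_invisible = wolf_gazes_invisible)),
            class = "chase_cue_track")
}

#' Luminance-modulation track for a non-social-condition trial
#'
#' Each visible dot's luminance follows
#' `L_i(t) = amplitude * sin(2 * pi * f_i * t + phi_i)` with `t` in seconds.
#' On chase-present trials the wolf and the sheep share the fast frequency
#' (3 Hz) while the two distractors modulate at 0.5 Hz; the two dots of each
#' same-frequency pair differ in phase by `phase_offset` (0.15 rad), and each
#' remaining dot gets an independent uniform phase. On chase-absent trials
#' the wolf plus one randomly chosen visible distractor carry 3 Hz (so
#' counting fast dots cannot reveal trial type); the others run at 0.5 Hz.
#'
#' Luminance is an abstract signal in \[-amplitude, amplitude\]; mapping to an
#' on-screen colour ramp is out of scope.
#'
#' @param traj a `chase_trajectory` with `condition = "nonsocial"`.
#' @param f_pair,f_distractor modulation frequencies, Hz.
#' @param phase_offset within-pair phase difference, radians.
#' @param amplitude peak luminance.
#' @param seed integer; defaults to a value derived from the trial seed so
#'   the track is reproducible alongside its trajectory.
#' @return A `chase_cue_track`: `kind = "luminance"`, `values` (frames x
#'   visible dots), `params` with per-dot `freq` and `phase`.
#' @export
color_track <- function(traj, f_pair = 3, f_distractor = 0.5,
                        phase_offset = 0.15, amplitude = 1, seed = NULL) {
  stopifnot(inherits(traj, "chase_trajectory"))
  if (traj$spec$condition != "nonsocial")
    stop("condition mismatch: color_track requires a nonsocial-condition trial")
  if (is.null(seed)) seed <- (traj$spec$seed + 9973L) %% .Machine$integer.max
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  vis <- which(traj$visible)
  nd <- length(vis)
  roles <- traj$roles[vis]
  wolf_col <- match(traj$wolf, vis)
  if (traj$spec$chase_present) {
    partner <- match(traj$sheep, vis)
  } else {
    partner <- sample(setdiff(which(roles == "distractor"), wolf_col), 1L)
  }
  freq <- rep(f_distractor, nd)
  freq[c(wolf_col, partner)] <- f_pair
  phase <- stats::runif(nd, 0, 2 * pi)
  phase[partner] <- phase[wolf_col] + phase_offset

  nf <- nrow(traj$x)
  tt <- (0:(nf - 1L)) / traj$config$frame_rate
  vals <- vapply(seq_len(nd),
                 function(i) amplitude * sin(2 * pi * freq[i] * tt + phase[i]),
                 numeric(nf))
  structure(list(kind = "luminance", values = vals,
                 params = list(freq = freq, phase = phase,
                               amplitude = amplitude, phase_offset = phase_offset,
                               pair = c(wolf_col, partner))),
            class = "chase_cue_track")
}

#' Dominant frequency of a sampled signal
#'
#' Peak of the discrete Fourier periodogram (excluding the DC bin). The
#' signal is zero-padded by `pad` before the transform so that frequencies
#' off the raw bin grid (a 3000 ms trial at 60 Hz has 1/3 Hz bins, so
#' 0.5 Hz falls between bins) are still located within a fine bin.
#'
#' @param values numeric signal, one sample per frame.
#' @param frame_rate sampling rate, Hz.
#' @param pad zero-padding factor (1 = raw bins).
#' @return Frequency of the periodogram maximum, Hz.
#' @export
dominant_frequency <- function(values, frame_rate, pad = 8L) {
  n <- length(values)
  m <- n * pad
  p <- Mod(stats::fft(c(values - mean(values), rep(0, m - n))))^2
  k <- 2:(m %/% 2 + 1)  # positive frequencies
  freqs <- (k - 1) * frame_rate / m
  freqs[which.max(p[k])]
}

# magnitude-squared coherence of two tracks at one frequency, estimated by
# averaging cross-spectra over `n_seg` non-overlapping segments (a single
# DFT bin has coherence 1 by construction).
.band_coherence <- function(a, b, freq, frame_rate, n_seg = 3L) {
  n <- length(a)
  seg <- n %/% n_seg
  k <- round(freq * seg / frame_rate) + 1L  # DFT bin of `freq` in a segment
  sxy <- 0 + 0i; sxx <- 0; syy <- 0
  for (s in seq_len(n_seg)) {
    ix <- ((s - 1L) * seg + 1L):(s * seg)
    fa <- stats::fft(a[ix] - mean(a[ix]))[k]
    fb <- stats::fft(b[ix] - mean(b[ix]))[k]
    sxy <- sxy + fa * Conj(fb)
    sxx <- sxx + Mod(fa)^2
    syy <- syy + Mod(fb)^2
  }
  if (sxx == 0 || syy == 0) return(0)
  Mod(sxy)^2 / (sxx * syy)
}
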