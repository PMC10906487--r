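#' Pixel-to-distance calibration
#'
#' Ratio of pixels to centimetres from a reference object of known length
#' (conventionally a 3 cm line drawn on the arena floor).
#'
#' @param px_length Measured length in pixels (> 0).
#' @param known_length_cm True length in cm (> 0, default 3).
#' @return Pixels per cm.
#' @examples
#' calibrate(30)  # 10 px per cm
#' @export
calibrate <- function(px_length, known_length_cm = 3) {
  if (px_length <= 0 || known_length_cm <= 0)
    stop("calibration lengths must be positive")
  px_length / known_length_cm
}

# centred finite differences, one-sided at the ends; x is a numeric vector
# sampled at uniform spacing dt
.diff_centered <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

.moving_average <- function(x, k) {
  if (k <= 1) return(x)
  f <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  f[is.na(f)] <- x[is.na(f)]   # ends keep the raw values
  f
}

#' C-start kinematics of one attempt
#'
#' Computes peak burst velocity and peak (tangential) acceleration over a
#' fixed analysis window following C-start onset -- conventionally 75 ms,
#' the span of stages 1 and 2 of the response. Coordinates are converted to
#' cm via the pixel calibration; per-frame speed comes from centred finite
#' differences of position (one-sided only at trajectory ends), and
#' acceleration from centred differences of speed. No smoothing is applied
#' by default; `smooth_window` > 1 applies a moving average to the
#' coordinates first.
#'
#' @param frames Data frame with columns `time_s`, `x_px`, `y_px`, at
#'   (nominally) uniform frame spacing.
#' @param fps Frame rate, frames s^-1.
#' @param pixels_per_cm Calibration ratio from [calibrate()].
#' @param onset_s C-start onset time (s); attempts lacking an onset cannot
#'   be analysed (pass `NA` to get an error) but still count towards
#'   responsiveness.
#' @param window_ms Analysis window length, ms (default 75).
#' @param body_length_cm Body length for BL s^-1 normalisation (optional).
#' @param smooth_window Moving-average width in frames (default 1 = none).
#' @return List: `u_max_cms`, `u_max_bls` (NA without `body_length_cm`),
#'   `a_max_ms2`, `t_umax_s`, `t_amax_s`, `n_frames_window`.
#' @export
analyze_cstart <- function(frames, fps, pixels_per_cm, onset_s,
                           window_ms = 75, body_length_cm = NULL,
                           smooth_window = 1) {
  stopifnot(is.data.frame(frames),
            all(c("time_s", "x_px", "y_px") %in% names(frames)))
  if (is.na(onset_s)) stop("attempt has no C-start onset annotation")
  if (pixels_per_cm <= 0) stop("pixels_per_cm must be positive")
  dt <- 1 / fps
  x_cm <- .moving_average(frames$x_px / pixels_per_cm, smooth_window)
  y_cm <- .moving_average(frames$y_px / pixels_per_cm, smooth_window)
  vx <- .diff_centered(x_cm, dt)
  vy <- .diff_centered(y_cm, dt)
  speed <- sqrt(vx^2 + vy^2)                 # cm s^-1
  accel <- .diff_centered(speed, dt)         # tangential, cm s^-2
  win_end <- onset_s + window_ms / 1000
  if (win_end > max(frames$time_s) + dt / 2)
    stop("analysis window extends beyond the trajectory")
  in_win <- frames$time_s >= onset_s & frames$time_s <= win_end + dt / 4
  if (sum(in_win) < 3) stop("fewer than 3 frames in the analysis window")
  iu <- which(in_win)[which.max(speed[in_win])]
  ia <- which(in_win)[which.max(abs(accel[in_win]))]
  list(u_max_cms = speed[iu],
       u_max_bls = if (is.null(body_length_cm)) NA_real_
                   else speed[iu] / body_length_cm,
       a_max_ms2 = abs(accel[ia]) / 100,
       t_umax_s = frames$time_s[iu], t_amax_s = frames$time_s[ia],
       n_frames_window = sum(in_win))
}

#' Select the best C-start attempt for a fish
#'
#' The reported per-fish values are the highest `u_max` across attempts and
#' the `a_max` of that same attempt (even when another attempt had a higher
#' acceleration). Ties go to the earliest attempt.
#'
#' @param attempts Data frame with columns `attempt_id`, `u_max_cms`,
#'   `a_max_ms2` (and optionally `u_max_bls`), one row per analysable
#'   attempt, in attempt order.
#' @return One-row data frame: the winning attempt, plus `best_attempt_id`.
#' @export
select_best <- function(attempts) {
  stopifnot(is.data.frame(attempts), nrow(attempts) >= 1,
            all(c("attempt_id", "u_max_cms", "a_max_ms2") %in%
                  names(attempts)))
  best <- which.max(attempts$u_max_cms)   # first max = earliest attempt
  out <- attempts[best, , drop = FALSE]
  out$best_attempt_id <- out$attempt_id
  rownames(out) <- NULL
  out
}

#' C-start responsiveness
#'
#' Percentage of startle attempts that elicited a C-start before physical
#' contact with the fish; contact-triggered C-starts count as
#' non-responses, so responsiveness reflects visual/mechanoacoustic rather
#' than tactile sensing.
#'
#' @param pre_contact_response Logical vector, one element per attempt.
#' @return Percentage in [0, 100].
#' @examples
#' score_responsiveness(c(TRUE, TRUE, FALSE, FALSE, FALSE))  # 40
#' @export
score_responsiveness <- function(pre_contact_response) {
  if (length(pre_contact_response) == 0)
    stop("responsiveness is undefined with zero attempts")
  100 * mean(as.logical(pre_contact_response))
}

#' Per-fish C-start results from a set of attempts
#'
#' Convenience wrapper that analyses every attempt with an onset
#' annotation, selects the best one, and scores responsiveness over all
#' attempts (including un-analysable ones).
#'
#' @param attempt_list List of attempts; each element a list with `frames`,
#'   `onset_s` (NA when no C-start was identified) and
#'   `pre_contact_response` (logical).
#' @param fps,pixels_per_cm,window_ms,body_length_cm,smooth_window Passed
#'   to [analyze_cstart()].
#' @param fish_id Identifier.
#' @return One-row data frame (`fish_id`, `u_max_cms`, `u_max_bls`,
#'   `a_max_ms2`, `responsiveness`, `best_attempt_id`, `n_attempts`,
#'   `n_analyzable`), or NULL kinematics columns (NA) when no attempt was
#'   analysable.
#' @export
cstart_results <- function(attempt_list, fps, pixels_per_cm,
                           window_ms = 75, body_length_cm = NULL,
                           smooth_window = 1, fish_id = NA_character_) {
  stopifnot(length(attempt_list) >= 1)
  resp <- score_responsiveness(
    vapply(attempt_list, function(a) isTRUE(a$pre_contact_response),
           logical(1)))
  rows <- list()
  for (i in seq_along(attempt_list)) {
    a <- attempt_list[[i]]
    if (is.null(a$onset_s) || is.na(a$onset_s)) next
    k <- analyze_cstart(a$frames, fps, pixels_per_cm, a$onset_s,
                        window_ms = window_ms,
                        body_length_cm = body_length_cm,
                        smooth_window = smooth_window)
    rows[[length(rows) + 1L]] <-
      data.frame(attempt_id = i, u_max_cms = k$u_max_cms,
                 u_max_bls = k$u_max_bls, a_max_ms2 = k$a_max_ms2)
  }
  if (!length(rows)) {
    return(data.frame(fish_id = fish_id, u_max_cms = NA_real_,
                      u_max_bls = NA_real_, a_max_ms2 = NA_real_,
                      responsiveness = resp, best_attempt_id = NA_integer_,
                      n_attempts = length(attempt_list), n_analyzable = 0L,
                      stringsAsFactors = FALSE))
  }
  best <- select_best(do.call(rbind, rows))
  data.frame(fish_id = fish_id, u_max_cms = best$u_max_cms,
             u_max_bls = best$u_max_bls, a_max_ms2 = best$a_max_ms2,
             responsiveness = resp, best_attempt_id = best$best_attempt_id,
             n_attempts = length(attempt_list), n_analyzable = length(rows),
             stringsAsFactors = FALSE)
}
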