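# Pure functions for the cosine activity model, time-of-day specialization,
# trait inheritance, and circular arithmetic. Angles are degrees throughout:
# one simulated day is 360 degrees (1 h = 15 degrees); conversion to radians
# happens only inside trig calls. `cospi()`/`sinpi()` keep values exact at
# the quarter-cycle points.

#' Wrap angles into [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped to `[0, 360)`.
#' @export
#' @examples
#' wrap_degrees(c(-10, 370, 180))
wrap_degrees <- function(x) {
  r <- x %% 360
  # a tiny negative angle rounds to exactly 360 under %%; keep [0, 360)
  r[r == 360] <- 0
  r
}

cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)

#' Instantaneous activity rate of the cosine rhythm
#'
#' The amount of movement over the day follows
#' \deqn{a(t) = \frac{M_{total}}{360^\circ}\,(1 + A \cos(t - \varphi))}
#' where `A` is the rhythm amplitude in \[0, 1\] and `phi` the phase angle of
#' peak activity. Total daily movement is fixed at `m_total` moves regardless
#' of the rhythm parameters.
#'
#' @param amplitude Rhythm amplitude in \[0, 1\] (0 = arrhythmic).
#' @param phase Phase angle of peak activity, degrees.
#' @param t Time of day, degrees (any real; wrapped internally).
#' @param m_total Total moves per day (default 20).
#' @return Moves per degree, non-negative for `amplitude <= 1`.
#' @export
#' @examples
#' activity_rate(0, 0, 120)        # flat profile: 20/360
#' activity_rate(1, 90, 90)        # peak doubles the flat rate
activity_rate <- function(amplitude, phase, t, m_total = 20) {
  (m_total / 360) * (1 + amplitude * cos_deg(t - phase))
}

#' Expected moves over a time interval
#'
#' Closed form of the integral of [activity_rate()] from `t0` to `t1`:
#' \deqn{m = \frac{M_{total}}{360^\circ}\left[(t_1 - t_0) +
#'   A\,\frac{180^\circ}{\pi}\,(\sin(t_1 - \varphi) - \sin(t_0 -
#'   \varphi))\right]}
#' Over any full day the integral equals `m_total` exactly.
#'
#' @inheritParams activity_rate
#' @param t0,t1 Interval endpoints in degrees; requires `t1 > t0` and
#'   `t1 - t0 <= 360`.
#' @return Expected (generally non-integer) number of moves, `>= 0` for
#'   `amplitude <= 1`.
#' @export
#' @examples
#' expected_moves(0.7, 123, 0, 360)   # always 20
#' expected_moves(0, 0, 0, 36)        # one of ten equal steps: 2
expected_moves <- function(amplitude, phase, t0, t1, m_total = 20) {
  if (any(t1 <= t0)) {
    stop("`t1` must be strictly greater than `t0`")
  }
  if (any(t1 - t0 > 360 + 1e-9)) {
    stop("interval length must not exceed 360 degrees")
  }
  (m_total / 360) *
    ((t1 - t0) + amplitude * (180 / pi) *
       (sin_deg(t1 - phase) - sin_deg(t0 - phase)))
}

#' Convert expected moves to whole moves with a fractional-credit carry
#'
#' Moves are realized deterministically by accumulating fractional credit and
#' taking the floor (floor-with-carry), so that the credit is conserved and
#' the realized daily total telescopes to the expected total. A `1e-9` snap
#' inside the floor protects exact-integer totals from float rounding.
#'
#' @param expected Expected moves for the interval (`>= 0`).
#' @param credit Carried fractional credit in `[0, 1)`.
#' @return List with integer `moves` and `credit` (the new carry in
#'   `[0, 1)`).
#' @export
#' @examples
#' realize_moves(1.7, 0.5)  # 2 moves, credit 0.2
realize_moves <- function(expected, credit = 0) {
  stopifnot(expected >= 0, credit >= 0, credit < 1)
  tot <- credit + expected
  moves <- floor(tot + 1e-9)
  new_credit <- tot - moves
  if (new_credit < 0) new_credit <- 0
  list(moves = as.integer(moves), credit = new_credit)
}

#' Energy gained from a resource under time-of-day specialization
#'
#' Specialization makes foraging more efficient at the circadian peak and
#' less efficient at the trough:
#' \deqn{E_{adj} = E_{orig}\,(1 + S \cos(t - \varphi))}
#' With `S = 0.2` an organism gains 20% more energy per resource at its peak
#' and 20% less at its trough; at `S = 0.75` the peak is seven times more
#' efficient than the trough. The specialization wave shares the activity
#' rhythm's phase angle.
#'
#' @param S Specialization value, `>= 0` (at most 1 keeps energy
#'   non-negative).
#' @param phase Organism phase angle, degrees.
#' @param t Time of day, degrees.
#' @param e_orig Baseline energy per resource (default 0.5).
#' @return Adjusted energy per consumed resource.
#' @export
#' @examples
#' resource_energy(0.2, 90, 90)    # 20% above baseline at the peak
resource_energy <- function(S, phase, t, e_orig = 0.5) {
  stopifnot(e_orig > 0, S >= 0)
  e_orig * (1 + S * cos_deg(t - phase))
}

#' Circular mean of angles
#'
#' Direction of the summed unit vectors, in degrees wrapped to `[0, 360)`.
#' When the resultant vector is shorter than `tol` (an antipodal tie) one of
#' the input angles is picked uniformly at random rather than raising an
#' error, because any deterministic choice would bias phase evolution.
#'
#' @param angles Non-empty numeric vector of degrees.
#' @param tol Resultant-length tolerance for the antipodal tie-break.
#' @return Mean direction in degrees.
#' @export
#' @examples
#' circular_mean(c(350, 10))  # 0, not 180
circular_mean <- function(angles, tol = 1e-9) {
  stopifnot(length(angles) >= 1)
  s <- sum(sin_deg(angles))
  c <- sum(cos_deg(angles))
  if (sqrt(s^2 + c^2) / length(angles) < tol) {
    return(wrap_degrees(angles[sample.int(length(angles), 1)]))
  }
  wrap_degrees(atan2(s, c) * 180 / pi)
}

#' Shortest angular distance between two phases
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Distance in degrees, in `[0, 180]`.
#' @export
#' @examples
#' circular_distance(350, 10)  # 20
circular_distance <- function(a, b) {
  d <- abs(wrap_degrees(a) - wrap_degrees(b))
  pmin(d, 360 - d)
}

#' Circular standard deviation in degrees
#'
#' \eqn{\sqrt{-2 \ln \bar R}} (in radians, reported in degrees), where
#' \eqn{\bar R} is the mean resultant length. For nearly uniform samples
#' \eqn{\bar R \to 0} and the statistic diverges; it is capped at the value
#' corresponding to \eqn{\bar R = 10^{-12}} (about 425.9 degrees).
#'
#' @param angles Numeric vector of degrees, length `>= 2`.
#' @return Circular SD in degrees.
#' @export
#' @examples
#' circular_sd(c(0, 90))  # sqrt(-2 log cos 45 deg) in degrees
circular_sd <- function(angles) {
  stopifnot(length(angles) >= 2)
  rbar <- sqrt(mean(cos_deg(angles))^2 + mean(sin_deg(angles))^2)
  rbar <- max(rbar, 1e-12)
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' Offspring rhythm traits from two parents
#'
#' The child's amplitude is the arithmetic mean of the parents' amplitudes
#' plus Normal(0, `amp_sd`) noise, clamped to \[0, 1\]; the child's phase is
#' the circular mean of the parents' phases plus Normal(0,
#' `phase_sd_frac` * 360 degrees) noise, wrapped to `[0, 360)`. Setting both
#' SDs to zero makes inheritance deterministic (no trait evolution). Uses
#' R's RNG stream.
#'
#' @param p1,p2 Parent trait lists with elements `amplitude` and `phase`.
#' @param amp_sd Amplitude mutation SD (0.04 in the evolving scenario
#'   presets; 0 here).
#' @param phase_sd_frac Phase mutation SD as a fraction of the full circle.
#' @return List with `amplitude` and `phase`.
#' @export
#' @examples
#' inherit_traits(list(amplitude = 0.4, phase = 350),
#'                list(amplitude = 0.6, phase = 10))
inherit_traits <- function(p1, p2, amp_sd = 0, phase_sd_frac = 0) {
  stopifnot(amp_sd >= 0, phase_sd_frac >= 0)
  amp <- (p1$amplitude + p2$amplitude) / 2
  if (amp_sd > 0) amp <- amp + stats::rnorm(1, 0, amp_sd)
  amp <- min(1, max(0, amp))
  ph <- circular_mean(c(p1$phase, p2$phase))
  if (phase_sd_frac > 0) ph <- ph + stats::rnorm(1, 0, phase_sd_frac * 360)
  list(amplitude = amp, phase = wrap_degrees(ph))
}
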