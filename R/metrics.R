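# Summary statistics over populations and trial records: mating-window
# overlap matrices, the cross-group mating (CGM) reproductive-isolation
# statistic, phase-difference trajectories, and event detection.

#' Mating-window overlap matrix
#'
#' Square matrix `M` with `M[i, j]` the mating-window overlap between the
#' phases of individuals `i` and `j`; symmetric with unit diagonal.
#'
#' @param phases Numeric vector of phase angles in degrees.
#' @param width Mating-window width in degrees.
#' @return An `n` x `n` numeric matrix with values in `[0, 1]`.
#' @export
#' @examples
#' overlap_matrix(c(0, 0, 180, 180))
overlap_matrix <- function(phases, width = 135) {
  stopifnot(length(phases) >= 1, width > 0, width <= 360)
  outer(phases, phases, function(a, b) mating_window_overlap(a, b, width))
}

#' Cross-group mating (CGM) statistic
#'
#' Measures reproductive segregation of a population of phase angles.
#' 2-means clustering (Lloyd's algorithm on the rows of the overlap matrix,
#' Euclidean metric, `nstart` seeded restarts, keeping the best
#' within-cluster sum of squares) splits the population into two clusters;
#' the CGM is the mean mating-window overlap across all between-cluster
#' pairs, i.e. the probability that a given mating would cross the split.
#' CGM 0 means complete reproductive isolation of the two groups; a
#' single-clump population gives CGM 1 regardless of the arbitrary split.
#'
#' @inheritParams overlap_matrix
#' @param seed Integer seed for the clustering restarts; by default taken
#'   from R's RNG stream.
#' @param nstart Number of random restarts (default 10).
#' @param iter_max Iteration cap per restart.
#' @param tol Centroid-shift convergence tolerance.
#' @return CGM in `[0, 1]`, or `NA` for fewer than two phases.
#' @export
#' @examples
#' cgm(c(rep(0, 6), rep(180, 6)), seed = 1)  # 0: fully isolated groups
cgm <- function(phases, width = 135, seed = NULL, nstart = 10,
                iter_max = 300, tol = 1e-6) {
  if (length(phases) < 2) return(NA_real_)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  cpp_cgm(as.numeric(phases), width, as.integer(seed),
          as.integer(nstart), as.integer(iter_max), tol)
}

#' Circular difference between two species' mean phases
#'
#' @param phases_a,phases_b Non-empty numeric vectors of degrees.
#' @return Degrees in `[0, 180]`.
#' @export
#' @examples
#' species_phase_difference(c(350, 10), c(80, 100))  # 90
species_phase_difference <- function(phases_a, phases_b) {
  stopifnot(length(phases_a) >= 1, length(phases_b) >= 1)
  circular_distance(circular_mean(phases_a), circular_mean(phases_b))
}

#' Per-day inter-species phase difference of a trial record
#'
#' @param record A [run_trial()] record of a two-species trial.
#' @return Numeric vector (one value per recorded day) of the circular
#'   distance between the two species' mean phase angles; `NA` on days where
#'   a species is extinct.
#' @export
phase_difference_series <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  daily <- record$daily
  a <- daily[daily$species == 1, ]
  b <- daily[daily$species == 2, ]
  if (nrow(b) == 0) stop("record has a single species")
  circular_distance(a$phase_mean, b$phase_mean)
}

#' First day a species' population reaches zero
#'
#' @param record A [run_trial()] record.
#' @return Named integer vector, one entry per species: the first recorded
#'   day with population 0, or `NA` if the species persists to the horizon.
#' @export
detect_exclusion <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  daily <- record$daily
  vapply(sort(unique(daily$species)), function(s) {
    d <- daily[daily$species == s, ]
    hit <- which(d$pop == 0)
    if (length(hit) == 0) NA_integer_ else as.integer(d$day[hit[1]])
  }, integer(1))
}

#' First day the CGM drops below a threshold (speciation day)
#'
#' @param record A [run_trial()] record from an assortative-mating scenario.
#' @param threshold CGM threshold (default 0.1).
#' @return The first recorded day with `CGM < threshold`, or `NA`.
#' @export
detect_speciation <- function(record, threshold = 0.1) {
  stopifnot(inherits(record, "trial_record"))
  daily <- record$daily
  d <- daily[daily$species == 1, ]
  hit <- which(!is.na(d$cgm) & d$cgm < threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(d$day[hit[1]])
}

#' Resource counts on the grid by time of day
#'
#' Snapshot of the total resources on the grid at each of the 10
#' step boundaries of every day. A deep trough at a shared activity peak
#' signals a strong time-resource gradient; an antiphase community flattens
#' the profile.
#'
#' @param record A [run_trial()] record.
#' @return A `(horizon + 1)` x 10 numeric matrix (row 0 is the initial
#'   state).
#' @export
resource_time_histogram <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  record$resources
}
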