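# Simulation configuration and the trial runner. The stateful engine (the
# 60-space resource grid, movement/foraging, metabolism, death, mating, and
# the 10-step-per-day scheduler) is compiled C++; a trial is fully
# determined by its (config, seed) pair through a single RNG stream.

#' Per-species configuration
#'
#' @param n0 Initial population size.
#' @param amplitude Initial rhythm amplitude in \[0, 1\].
#' @param phase Initial phase angle, degrees.
#' @param amp_sd Amplitude mutation SD (0 = amplitude fixed).
#' @param phase_sd_frac Phase mutation SD as a fraction of 360 degrees
#'   (0 = phase fixed).
#' @param S Specialization value (see [resource_energy()]).
#' @param k Target population fraction under stabilization (`NA` = filled in
#'   by [sim_config()] as an equal share).
#' @param init_phase_sd SD (degrees) of Normal initial phase spread around
#'   `phase`; 0 starts every organism at exactly `phase`.
#' @return A `species_config` list.
#' @export
species_config <- function(n0 = 75, amplitude = 0.5, phase = 0,
                           amp_sd = 0, phase_sd_frac = 0, S = 0, k = NA,
                           init_phase_sd = 0) {
  stopifnot(n0 >= 0, amplitude >= 0, amplitude <= 1,
            amp_sd >= 0, phase_sd_frac >= 0, S >= 0, init_phase_sd >= 0)
  structure(list(n0 = as.integer(n0), amplitude = amplitude,
                 phase = wrap_degrees(phase), amp_sd = amp_sd,
                 phase_sd_frac = phase_sd_frac, S = S, k = k,
                 init_phase_sd = init_phase_sd),
            class = "species_config")
}

#' Full simulation configuration
#'
#' World constants default to the standard experiment: a 60-space
#' environment receiving 600 resources per day in 10 equal steps, organisms
#' making 20 moves per day, spending 2 energy per day on movement and
#' metabolism, gaining 0.5 energy per resource, and dying at zero energy or
#' at 12 days of age. The baseline growth rate is 0.1 per day and the
#' mating window is 135 degrees (9 h).
#'
#' @param species List of [species_config()] objects (one or two species).
#' @param horizon_days Number of simulated days.
#' @param assortative Logical; phase-assortative mating (and daily CGM
#'   recording)?
#' @param stabilize Logical; stabilize populations around the target ratio?
#' @param n_spaces,resources_per_day,steps_per_day,m_total World constants.
#' @param daily_cost,e_orig,max_age,r,window_width,init_energy World
#'   constants (energy cost per day, baseline energy per resource, age
#'   limit in days, baseline growth rate per day, mating-window width in
#'   degrees, starting energy per organism).
#' @param poisson_births Logical (default `TRUE`): matings arrive as a
#'   constant-rate random stream, so the realized number per step is Poisson
#'   with the expected-progeny mean. `FALSE` uses a deterministic
#'   floor-with-carry birth ledger instead (same expectation, no demographic
#'   birth noise); see the methods vignette for why the stochastic stream is
#'   the default.
#' @param km_nstart,km_iter_max,km_tol 2-means settings for in-trial CGM.
#' @return A validated `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(list(species_config(amplitude = 1, phase = 0),
#'                        species_config(amplitude = 1, phase = 180)),
#'                   horizon_days = 50, stabilize = FALSE)
sim_config <- function(species, horizon_days = 2000, assortative = FALSE,
                       stabilize = TRUE, n_spaces = 60,
                       resources_per_day = 600, steps_per_day = 10,
                       m_total = 20, daily_cost = 2, e_orig = 0.5,
                       max_age = 12, r = 0.1, window_width = 135,
                       init_energy = 2, poisson_births = TRUE,
                       km_nstart = 10, km_iter_max = 300, km_tol = 1e-6) {
  if (inherits(species, "species_config")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, logical(1), "species_config")),
            horizon_days >= 1, n_spaces > 1, resources_per_day >= 0,
            steps_per_day >= 1, m_total > 0, daily_cost > 0, e_orig > 0,
            max_age >= 1, r >= 0, window_width > 0, window_width <= 360,
            init_energy > 0)
  ks <- vapply(species, function(s) s$k, numeric(1))
  if (all(is.na(ks))) {
    for (i in seq_along(species)) species[[i]]$k <- 1 / length(species)
  } else if (anyNA(ks)) {
    stop("either set `k` for every species or for none")
  }
  ks <- vapply(species, function(s) s$k, numeric(1))
  if (stabilize && abs(sum(ks) - 1) > 1e-8) {
    stop("target population fractions `k` must sum to 1 when stabilizing")
  }
  structure(list(
    species = species, horizon_days = as.integer(horizon_days),
    assortative = isTRUE(assortative), stabilize = isTRUE(stabilize),
    n_spaces = as.integer(n_spaces),
    resources_per_day = as.integer(resources_per_day),
    steps_per_day = as.integer(steps_per_day), m_total = m_total,
    daily_cost = daily_cost, e_orig = e_orig, max_age = as.integer(max_age),
    r = r, window_width = window_width, init_energy = init_energy,
    poisson_births = isTRUE(poisson_births),
    record_cgm = isTRUE(assortative), km_nstart = as.integer(km_nstart),
    km_iter_max = as.integer(km_iter_max), km_tol = km_tol
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d species, horizon %d days, %s mating, stabilization %s\n",
    length(x$species), x$horizon_days,
    if (x$assortative) "assortative" else "random",
    if (x$stabilize) "on" else "off"))
  for (i in seq_along(x$species)) {
    s <- x$species[[i]]
    cat(sprintf(
      "  species %d: n0=%d A=%.2f (sd %.3f) phi=%.0f (sd frac %.3f) S=%.2f k=%.2f\n",
      i, s$n0, s$amplitude, s$amp_sd, s$phase, s$phase_sd_frac, s$S, s$k))
  }
  invisible(x)
}

#' Run one simulated trial
#'
#' Advances the world for `horizon_days` days of 10 time steps each. Within
#' a step, in order: resources are added; each organism (in freshly shuffled
#' order) realizes its expected moves and forages; flat metabolism is
#' charged; energy-dead organisms are removed; matings occur (newborns join
#' at the end of the step); and at the day boundary ages increment and
#' age-dead organisms are removed before the daily record is taken.
#'
#' @param config A [sim_config()].
#' @param seed Integer trial seed; the same (config, seed) pair always
#'   reproduces the identical record.
#' @return A `trial_record` with elements `daily` (data frame: day, species,
#'   pop, mean_amplitude, phase_mean, phase_sd, cgm), `resources`
#'   (day x step grid-resource snapshots), `ledger` (per-day energy and
#'   resource accounting), `snapshot` (final per-organism states), `events`
#'   (`exclusion_day` per species and `speciation_day`), `config`, and
#'   `seed`. Day 0 is the initial state.
#' @export
#' @examples
#' cfg <- build_scenario("coexist_antiphase", horizon_days = 30)
#' rec <- run_trial(cfg, seed = 1)
#' tail(subset(rec$daily, species == 1))
run_trial <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  seed <- as.integer(seed)
  raw <- cpp_run_trial(unclass(config), seed)
  nsp <- length(config$species)
  nd <- config$horizon_days + 1
  daily <- data.frame(
    day = rep(0:(nd - 1), times = nsp),
    species = rep(seq_len(nsp), each = nd),
    pop = as.vector(raw$pop),
    mean_amplitude = as.vector(raw$mean_amplitude),
    phase_mean = as.vector(raw$phase_mean),
    phase_sd = as.vector(raw$phase_sd),
    cgm = rep(as.vector(raw$cgm), times = nsp)
  )
  daily <- daily[order(daily$day, daily$species), , drop = FALSE]
  rownames(daily) <- NULL
  rec <- structure(list(
    daily = daily,
    resources = raw$resources,
    ledger = data.frame(day = 0:(nd - 1), raw$ledger),
    snapshot = data.frame(raw$snapshot),
    grid = raw$grid,
    config = config,
    seed = seed
  ), class = "trial_record")
  rec$events <- list(exclusion_day = detect_exclusion(rec),
                     speciation_day = if (config$assortative)
                       detect_speciation(rec) else NA_integer_)
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  nd <- max(x$daily$day)
  fin <- x$daily[x$daily$day == nd, ]
  cat(sprintf("<trial_record> seed %d, %d days, %d species\n",
              x$seed, nd, length(unique(x$daily$species))))
  cat("  final populations:", paste(fin$pop, collapse = ", "), "\n")
  if (!all(is.na(fin$mean_amplitude))) {
    cat("  final mean amplitudes:",
        paste(round(fin$mean_amplitude, 3), collapse = ", "), "\n")
  }
  if (x$config$assortative) {
    cat(sprintf("  final CGM: %s; speciation day: %s\n",
                format(round(fin$cgm[1], 3)),
                format(x$events$speciation_day)))
  }
  ex <- x$events$exclusion_day
  if (any(!is.na(ex))) {
    cat("  exclusion day(s):",
        paste(sprintf("species %d: %s", seq_along(ex), format(ex)),
              collapse = "; "), "\n")
  }
  invisible(x)
}
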