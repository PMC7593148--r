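# Scenario presets reproducing the standard experiments, and seeded batch
# runners. Every preset fully determines a sim_config given a seed.

ratio_to_k <- function(ratio) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(
      as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || anyNA(parts) || any(parts <= 0)) {
      stop("ratio must look like \"2:1\"")
    }
  } else {
    stopifnot(is.numeric(ratio), length(ratio) == 2, all(ratio > 0))
    parts <- ratio
  }
  parts / sum(parts)
}

#' Build a preset scenario configuration
#'
#' Available presets:
#' \describe{
#'   \item{`exclusion_arrhythmic`}{Two arrhythmic species (amplitude 0),
#'     identical niches, no trait evolution, stabilization off: competitive
#'     exclusion.}
#'   \item{`exclusion_inphase`}{Two fully rhythmic species (amplitude 1) at
#'     the same phase, stabilization off: exclusion despite rhythmicity.}
#'   \item{`coexist_antiphase`}{Amplitude 1, phases 0 and 180 degrees,
#'     stabilization off: temporal niche partitioning allows coexistence.}
#'   \item{`character_displacement`}{Both species start at the same phase;
#'     phase evolves (SD fraction 0.04) with amplitude fixed at 1,
#'     stabilization on at 1:1: phases diverge to antiphase.}
#'   \item{`single_species`}{One species of 150 with both traits evolving
#'     (SDs 0.04) and specialization `S`: amplitude decays for small `S`,
#'     rises for large `S`.}
#'   \item{`two_species`}{Antiphase pair with evolving traits (SDs 0.04),
#'     specialization `S` for both, stabilization on at `ratio`: equilibrium
#'     amplitudes depend on relative population sizes.}
#'   \item{`speciation`}{One species of 150 under assortative mating
#'     (135-degree window), amplitude starting at 1, both traits evolving
#'     at the given SDs: the population may split into two reproductively
#'     isolated groups.}
#' }
#'
#' @param name Preset name (see Details).
#' @param ... Overrides forwarded to [sim_config()]; must be fully named
#'   (they follow `...` in the signature, so they are never partially
#'   matched).
#' @param S Specialization value for `single_species` / `two_species`
#'   (default 0.2, a small degree of specialization).
#' @param ratio Target population ratio for `two_species`, e.g. `"1:1"`,
#'   `"2:1"`, `"9:1"`.
#' @param phase_sd,amp_sd Mutation SDs for the `speciation` preset (phase SD
#'   as a fraction of 360 degrees).
#' @param horizon_days Trial length in days (default 2000).
#' @param init_amplitude Initial amplitude for the evolving-amplitude
#'   presets (default 0.5).
#' @return A [sim_config()].
#' @export
#' @examples
#' build_scenario("coexist_antiphase")
#' build_scenario("speciation", phase_sd = 0.05, amp_sd = 0.02)
build_scenario <- function(name, ..., S = 0.2, ratio = "1:1",
                           phase_sd = 0.05, amp_sd = 0.02,
                           horizon_days = 2000, init_amplitude = 0.5) {
  switch(
    name,
    exclusion_arrhythmic = sim_config(
      list(species_config(n0 = 75, amplitude = 0, phase = 0),
           species_config(n0 = 75, amplitude = 0, phase = 0)),
      horizon_days = horizon_days, stabilize = FALSE, ...),
    exclusion_inphase = sim_config(
      list(species_config(n0 = 75, amplitude = 1, phase = 0),
           species_config(n0 = 75, amplitude = 1, phase = 0)),
      horizon_days = horizon_days, stabilize = FALSE, ...),
    coexist_antiphase = sim_config(
      list(species_config(n0 = 75, amplitude = 1, phase = 0),
           species_config(n0 = 75, amplitude = 1, phase = 180)),
      horizon_days = horizon_days, stabilize = FALSE, ...),
    character_displacement = sim_config(
      list(species_config(n0 = 75, amplitude = 1, phase = 0,
                          phase_sd_frac = 0.04),
           species_config(n0 = 75, amplitude = 1, phase = 0,
                          phase_sd_frac = 0.04)),
      horizon_days = horizon_days, stabilize = TRUE, ...),
    single_species = sim_config(
      species_config(n0 = 150, amplitude = init_amplitude, phase = 180,
                     amp_sd = 0.04, phase_sd_frac = 0.04, S = S, k = 1),
      horizon_days = horizon_days, stabilize = TRUE, ...),
    two_species = {
      k <- ratio_to_k(ratio)
      sim_config(
        list(species_config(n0 = 75, amplitude = init_amplitude, phase = 0,
                            amp_sd = 0.04, phase_sd_frac = 0.04, S = S,
                            k = k[1]),
             species_config(n0 = 75, amplitude = init_amplitude,
                            phase = 180, amp_sd = 0.04,
                            phase_sd_frac = 0.04, S = S, k = k[2])),
        horizon_days = horizon_days, stabilize = TRUE, ...)
    },
    speciation = sim_config(
      species_config(n0 = 150, amplitude = 1, phase = 180, amp_sd = amp_sd,
                     phase_sd_frac = phase_sd, k = 1),
      horizon_days = horizon_days, stabilize = TRUE, assortative = TRUE,
      ...),
    stop(sprintf("unknown scenario preset '%s'", name))
  )
}

#' Run a batch of seeded trials
#'
#' Trial `i` uses seed `base_seed + i - 1`, so a batch is reproducible and
#' embarrassingly parallel by construction (results do not depend on how
#' trials are scheduled).
#'
#' @param config A [sim_config()], e.g. from [build_scenario()].
#' @param n_trials Number of independent trials.
#' @param base_seed Seed of the first trial.
#' @param keep_records Keep the full per-trial records (memory-heavy for
#'   long batches)?
#' @return A `batch_summary`: data frame `trials` with one row per trial
#'   (seed, final populations, survival, exclusion/speciation days, final
#'   mean amplitudes, mean phase difference over the last 200 recorded
#'   days), aggregate list `aggregates`, and optionally `records`.
#' @export
#' @examples
#' cfg <- build_scenario("exclusion_arrhythmic", horizon_days = 200)
#' run_batch(cfg, n_trials = 2, base_seed = 1)
run_batch <- function(config, n_trials, base_seed = 1,
                      keep_records = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_trials >= 1)
  nsp <- length(config$species)
  records <- if (keep_records) vector("list", n_trials) else NULL
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    rec <- run_trial(config, seed = base_seed + i - 1)
    nd <- max(rec$daily$day)
    fin <- rec$daily[rec$daily$day == nd, ]
    tail_days <- rec$daily$day > nd - 200
    row <- data.frame(trial = i, seed = rec$seed)
    for (s in seq_len(nsp)) {
      row[[paste0("final_pop_", s)]] <- fin$pop[fin$species == s]
      row[[paste0("final_amp_", s)]] <- fin$mean_amplitude[fin$species == s]
      row[[paste0("exclusion_day_", s)]] <- rec$events$exclusion_day[s]
      amp_tail <- rec$daily$mean_amplitude[tail_days & rec$daily$species == s]
      row[[paste0("tail_amp_", s)]] <- mean(amp_tail, na.rm = TRUE)
    }
    row$survived_all <- all(fin$pop > 0)
    row$speciation_day <- rec$events$speciation_day
    if (nsp == 2) {
      pd <- phase_difference_series(rec)
      row$tail_phase_diff <- mean(pd[rec$daily$day[rec$daily$species == 1] >
                                       nd - 200], na.rm = TRUE)
    }
    rows[[i]] <- row
    if (keep_records) records[[i]] <- rec
  }
  trials <- do.call(rbind, rows)
  aggregates <- list(
    n_trials = n_trials,
    fraction_survived_all = mean(trials$survived_all),
    fraction_excluded = mean(!trials$survived_all),
    fraction_speciated = mean(!is.na(trials$speciation_day)),
    median_exclusion_day = stats::median(
      suppressWarnings(apply(as.matrix(
        trials[grep("^exclusion_day_", names(trials))]), 1, min,
        na.rm = TRUE))[!trials$survived_all]),
    median_speciation_day = stats::median(trials$speciation_day,
                                          na.rm = TRUE)
  )
  structure(list(trials = trials, aggregates = aggregates,
                 records = records, config = config,
                 base_seed = base_seed),
            class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<batch_summary> %d trials (base seed %d)\n", a$n_trials,
              x$base_seed))
  cat(sprintf("  all species survived: %.0f%%; excluded: %.0f%%; speciated: %.0f%%\n",
              100 * a$fraction_survived_all, 100 * a$fraction_excluded,
              100 * a$fraction_speciated))
  invisible(x)
}

#' Generate a synthetic population for exercising the metrics layer
#'
#' Draws phases and amplitudes from mixtures of point masses and wrapped
#' normal components, with energies from a Gamma(shape 4, scale 0.5)
#' distribution (positive, mean 2 — one day's energy cost). Intended as a
#' reproducible fixture for unit tests of overlap/CGM statistics.
#'
#' @param n Number of organisms.
#' @param phase_spec Data frame with columns `weight`, `mean`, `sd`
#'   describing the phase mixture (degrees; `sd = 0` is a point mass).
#' @param amplitude_spec Same layout for amplitudes (clamped to \[0, 1\]).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `amplitude`, `phase`, `energy`,
#'   `age`.
#' @export
#' @examples
#' generate_fixture_population(
#'   20, phase_spec = data.frame(weight = c(1, 1), mean = c(0, 180), sd = 0),
#'   seed = 1)
generate_fixture_population <- function(n,
                                        phase_spec = data.frame(
                                          weight = 1, mean = 180, sd = 0),
                                        amplitude_spec = data.frame(
                                          weight = 1, mean = 1, sd = 0),
                                        seed = 1) {
  stopifnot(n >= 1,
            all(c("weight", "mean", "sd") %in% names(phase_spec)),
            all(c("weight", "mean", "sd") %in% names(amplitude_spec)))
  draw_mixture <- function(spec, n) {
    comp <- sample.int(nrow(spec), n, replace = TRUE,
                       prob = spec$weight / sum(spec$weight))
    stats::rnorm(n, spec$mean[comp], spec$sd[comp])
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  phases <- wrap_degrees(draw_mixture(phase_spec, n))
  amps <- pmin(1, pmax(0, draw_mixture(amplitude_spec, n)))
  data.frame(id = seq_len(n), amplitude = amps, phase = phases,
             energy = stats::rgamma(n, shape = 4, scale = 0.5),
             age = 0L)
}

# minimal local seed scoping (avoids a dependency for one helper)
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
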