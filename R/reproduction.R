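# Mate-pair selection, offspring energetics, and growth stabilization.
# Mating pressure is energy-proportional: the probability of being chosen as
# a parent is proportional to stored energy, so foraging success translates
# directly into reproductive fitness.

#' Population-ratio-stabilized growth rate
#'
#' When stabilization is on, the per-day growth rate is adjusted so a species
#' below its target share of the community reproduces more and one above it
#' reproduces less:
#' \deqn{r_{adj} = r \, k \, P_{total} / p}
#' where `k` is the species' target population fraction. At the target ratio
#' the adjustment is neutral (`r_adj = r`). With stabilization off the rate
#' is `r` unchanged; an extinct species (`p = 0`) gets rate 0.
#'
#' @param r Baseline per-day growth rate (default 0.1).
#' @param k Target population fraction of this species.
#' @param p Current population of this species.
#' @param p_total Total community population.
#' @param stabilize Logical; apply the ratio adjustment?
#' @return Adjusted per-day growth rate.
#' @export
#' @examples
#' adjusted_growth_rate(0.1, 0.5, 40, 100)  # below target: 0.125
adjusted_growth_rate <- function(r = 0.1, k, p, p_total, stabilize = TRUE) {
  if (p == 0) return(0)
  if (!stabilize) return(r)
  r * k * p_total / p
}

#' Expected progeny in one time step
#'
#' \deqn{N_{progeny} = p \, r_{adj} \, (t_1 - t_0)/360^\circ}
#' Summed over the 10 equal steps of a day this gives `p * r_adj`, i.e. a
#' 10% daily increase at the default rate if no animals died.
#'
#' @param p Current species population.
#' @param r_adj Adjusted per-day growth rate.
#' @param dt Step length in degrees (default 36, one tenth of a day).
#' @return Expected (generally fractional) number of births this step.
#' @export
#' @examples
#' expected_progeny(100, 0.1)  # 1 birth expected per step
expected_progeny <- function(p, r_adj, dt = 36) {
  p * r_adj * dt / 360
}

#' Mating-window overlap of two phase angles
#'
#' Each organism can mate only within a window of `width` degrees (9 h = 135
#' degrees by default) fixed relative to its phase angle. The probability of
#' two individuals mating is proportional to the overlap of their windows:
#' it is 1 at zero phase difference, decreases linearly, and reaches 0 at a
#' difference of `width` or more.
#'
#' @param phi1,phi2 Phase angles in degrees (vectorized).
#' @param width Mating-window width in degrees, in `(0, 360]`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
#' @examples
#' mating_window_overlap(0, 67.5)   # 0.5
#' mating_window_overlap(0, 180)    # 0: cannot mate
mating_window_overlap <- function(phi1, phi2, width = 135) {
  stopifnot(width > 0, width <= 360)
  pmax(0, width - circular_distance(phi1, phi2)) / width
}

#' Select mating pairs from a population
#'
#' The first parent is drawn with probability proportional to its energy.
#' Without assortative mating the partner is drawn energy-proportionally
#' among the rest; with assortative mating the partner weight is energy
#' times the mating-window overlap with the first parent, and if every
#' partner weight is zero a fresh first parent is drawn, up to 10 attempts,
#' after which the mating fails (the birth is forfeited). Shares the exact
#' code path used inside the simulation engine.
#'
#' @param population Data frame with numeric columns `energy` and `phase`.
#' @param assortative Logical; apply the mating-window filter?
#' @param width Mating-window width in degrees.
#' @param n Number of pairs to draw (with replacement across pairs).
#' @param seed Integer seed for the draw; by default taken from R's RNG
#'   stream.
#' @return An `n` x 2 integer matrix of row indices into `population`;
#'   a row of `NA`s marks a failed mating.
#' @export
#' @examples
#' pop <- data.frame(energy = c(9, 1), phase = c(0, 0))
#' select_pair(pop, n = 5, seed = 1)
select_pair <- function(population, assortative = FALSE, width = 135,
                        n = 1, seed = NULL) {
  stopifnot(is.data.frame(population),
            all(c("energy", "phase") %in% names(population)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  cpp_select_pairs(as.numeric(population$energy),
                   as.numeric(population$phase),
                   isTRUE(assortative), width, as.integer(n),
                   as.integer(seed))
}

#' Produce one offspring from a mating pair
#'
#' Each parent donates one third of its stored energy to the offspring, so
#' total energy is conserved exactly across the mating. Offspring traits
#' come from [inherit_traits()]; offspring start at age 0 with no carried
#' move credit.
#'
#' @param parent1,parent2 Lists (or one-row data frames) with `amplitude`,
#'   `phase`, and `energy`.
#' @param amp_sd,phase_sd_frac Mutation SDs passed to [inherit_traits()].
#' @return List with `offspring` (amplitude, phase, energy, age = 0,
#'   move_credit = 0) and `parent_energy` (the parents' retained energies).
#' @export
#' @examples
#' mate(list(amplitude = 1, phase = 0, energy = 6),
#'      list(amplitude = 1, phase = 0, energy = 3))
mate <- function(parent1, parent2, amp_sd = 0, phase_sd_frac = 0) {
  e1 <- parent1$energy
  e2 <- parent2$energy
  stopifnot(e1 > 0, e2 > 0)
  traits <- inherit_traits(parent1, parent2, amp_sd, phase_sd_frac)
  list(
    offspring = list(amplitude = traits$amplitude, phase = traits$phase,
                     energy = (e1 + e2) / 3, age = 0L, move_credit = 0),
    parent_energy = c(e1 * 2 / 3, e2 * 2 / 3)
  )
}
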