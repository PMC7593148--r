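# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms / clustering code paths.

# Composite-Simpson quadrature of the activity-rate integrand; error is
# O(h^4) so 2000 panels are far below 1e-9 on these smooth integrands.
quadrature_moves <- function(amplitude, phase, t0, t1, m_total = 20,
                             panels = 2000) {
  h <- (t1 - t0) / panels
  t <- t0 + h * (0:panels)
  f <- (m_total / 360) * (1 + amplitude * cos((t - phase) * pi / 180))
  w <- c(1, rep(c(4, 2), length.out = panels - 1), 1)
  sum(w * f) * h / 3
}

# Exhaustive 2-partition oracle for the cross-group mating statistic:
# the minimum mean cross-group overlap over all bipartitions (n <= ~14).
brute_force_cgm <- function(phases, width = 135) {
  n <- length(phases)
  M <- outer(phases, phases, function(a, b) {
    d <- abs((a %% 360) - (b %% 360))
    d <- pmin(d, 360 - d)
    pmax(0, width - d) / width
  })
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    in1 <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (all(in1) || !any(in1)) next
    best <- min(best, mean(M[in1, !in1]))
  }
  best
}

# Small two-species antiphase config used by several engine tests.
antiphase_config <- function(horizon_days = 100, stabilize = FALSE, ...) {
  sim_config(list(species_config(n0 = 75, amplitude = 1, phase = 0),
                  species_config(n0 = 75, amplitude = 1, phase = 180)),
             horizon_days = horizon_days, stabilize = stabilize, ...)
}

# Ledger identities that must hold for any trial record.
expect_conserved <- function(rec) {
  led <- rec$ledger
  expect_true(all(diff(led$grid_total) ==
                    (led$resources_added - led$resources_consumed)[-1]))
  de <- diff(led$total_energy) -
    (led$energy_gained - led$metabolic_cost - led$death_energy)[-1]
  expect_lt(max(abs(de)), 1e-8)
}
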