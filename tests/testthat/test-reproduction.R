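test_that("growth-rate stabilization pulls species toward their target", {
  expect_equal(adjusted_growth_rate(0.1, 0.5, 50, 100), 0.1)
  expect_equal(adjusted_growth_rate(0.1, 0.5, 40, 100), 0.125)
  expect_equal(adjusted_growth_rate(0.1, 1.0, 100, 100), 0.1)
  expect_equal(adjusted_growth_rate(0.1, 0.5, 0, 100), 0)
  expect_equal(adjusted_growth_rate(0.1, 0.9, 40, 100, stabilize = FALSE),
               0.1)
})

test_that("expected progeny telescopes to the daily growth rate", {
  expect_equal(expected_progeny(100, 0.1), 1)
  expect_equal(expected_progeny(0, 0.5), 0)
  # ten steps of a day sum to p * r_adj: 10% daily growth if none died
  expect_equal(sum(replicate(10, expected_progeny(100, 0.1, 36))), 10)
})

test_that("mating-window overlap is linear in phase difference", {
  expect_equal(mating_window_overlap(0, 0), 1)
  expect_equal(mating_window_overlap(0, 135), 0)
  expect_equal(mating_window_overlap(0, 67.5), 0.5)
  expect_equal(mating_window_overlap(0, 200), 0)  # beyond the window
  expect_equal(mating_window_overlap(350, 10), (135 - 20) / 135)
})

test_that("parents are chosen in proportion to stored energy", {
  pop <- data.frame(energy = c(9, 1), phase = c(0, 0))
  pairs <- select_pair(pop, n = 1e5, seed = 42)
  expect_equal(mean(pairs[, 1] == 1), 0.9, tolerance = 0.01)
  # second parent is always the other one here
  expect_true(all(pairs[, 1] != pairs[, 2]))
})

test_that("selection failures are reported, not raised", {
  # a single organism cannot mate
  one <- data.frame(energy = 5, phase = 0)
  expect_true(all(is.na(select_pair(one, n = 3, seed = 1))))
  # two organisms in antiphase cannot mate assortatively
  anti <- data.frame(energy = c(5, 5), phase = c(0, 180))
  expect_true(all(is.na(select_pair(anti, assortative = TRUE, n = 10,
                                    seed = 1))))
  # but they can without the window filter
  expect_false(anyNA(select_pair(anti, assortative = FALSE, n = 10,
                                 seed = 1)))
  # zero total energy fails
  zero <- data.frame(energy = c(0, 0), phase = c(0, 0))
  expect_true(all(is.na(select_pair(zero, n = 2, seed = 1))))
})

test_that("the assortative filter is inert when all overlaps are one", {
  # identical phases: overlap is exactly 1 for every pair, so assortative
  # pair statistics must match the plain energy-proportional rule
  pop <- data.frame(energy = c(4, 3, 2, 1), phase = rep(90, 4))
  pa <- select_pair(pop, assortative = TRUE, n = 4e4, seed = 7)
  pn <- select_pair(pop, assortative = FALSE, n = 4e4, seed = 7)
  fa <- tabulate(pa[, 1], 4) / nrow(pa)
  fn <- tabulate(pn[, 1], 4) / nrow(pn)
  expect_equal(fa, fn, tolerance = 0.02)
  expect_equal(fa, c(4, 3, 2, 1) / 10, tolerance = 0.02)
})

test_that("mating conserves energy exactly via the one-third donation", {
  res <- mate(list(amplitude = 1, phase = 0, energy = 6),
              list(amplitude = 1, phase = 0, energy = 3))
  expect_equal(res$offspring$energy, 3)
  expect_equal(res$parent_energy, c(4, 2))
  expect_equal(res$offspring$energy + sum(res$parent_energy), 9)
  expect_identical(res$offspring$age, 0L)
  expect_equal(res$offspring$move_credit, 0)
  # zero-SD inheritance passes traits through
  expect_equal(res$offspring$amplitude, 1)
  expect_equal(res$offspring$phase, 0)
})

test_that("1:1 stabilization keeps the species ratio near one half", {
  # antiphase pair, stabilization on: long-run share of species A in
  # [0.45, 0.55] for every trial
  cfg <- antiphase_config(horizon_days = 500, stabilize = TRUE)
  shares <- sapply(1:10, function(s) {
    rec <- run_trial(cfg, seed = 500 + s)
    d <- rec$daily[rec$daily$day > 100, ]
    pa <- d$pop[d$species == 1]
    pb <- d$pop[d$species == 2]
    mean(pa / (pa + pb))
  })
  expect_true(all(shares > 0.45 & shares < 0.55))
})

test_that("fixed traits stay fixed across generations", {
  # SDs = 0: the trait distribution is invariant (identical populations
  # stay identical) even as generations turn over
  cfg <- antiphase_config(horizon_days = 60, stabilize = TRUE)
  rec <- run_trial(cfg, seed = 8)
  snap <- rec$snapshot
  expect_true(all(snap$amplitude == 1))
  expect_true(all(snap$phase[snap$species == 1] == 0))
  expect_true(all(snap$phase[snap$species == 2] == 180))
})
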