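test_that("activity rate follows the cosine model", {
  # flat profile at zero amplitude, independent of phase and time
  expect_equal(activity_rate(0, 123, 45), 20 / 360)
  expect_equal(activity_rate(0, 0, 300), 20 / 360)
  # full-amplitude peak doubles the flat rate; trough is exactly zero
  expect_equal(activity_rate(1, 90, 90), 40 / 360)
  expect_identical(activity_rate(1, 90, 270), 0)
})

test_that("expected moves integrate the activity rate in closed form", {
  # any full day gives the fixed daily total of 20 moves
  set.seed(42)
  A <- runif(1e4)
  phi <- runif(1e4, 0, 360)
  expect_lt(max(abs(expected_moves(A, phi, 0, 360) - 20)), 1e-9)
  # arrhythmic step: one tenth of the day
  expect_equal(expected_moves(0, 0, 0, 36), 2)
  # symmetric interval around the peak, against Simpson quadrature
  m <- expected_moves(1, 0, -18, 18)
  expect_equal(m, quadrature_moves(1, 0, -18, 18, panels = 1e5),
               tolerance = 1e-9)
  expect_equal(m, 2 + (20 / 360) * (180 / pi) * 2 * sin(pi / 10),
               tolerance = 1e-12)
  expect_error(expected_moves(1, 0, 36, 36), "greater")
  expect_error(expected_moves(1, 0, 0, 400), "360")
})

test_that("closed form matches quadrature on random intervals", {
  set.seed(7)
  for (i in 1:200) {
    A <- runif(1)
    phi <- runif(1, 0, 360)
    t0 <- runif(1, -360, 360)
    t1 <- t0 + runif(1, 1, 360)
    expect_equal(expected_moves(A, phi, t0, t1),
                 quadrature_moves(A, phi, t0, t1), tolerance = 1e-6)
  }
})

test_that("move realization conserves fractional credit", {
  expect_identical(realize_moves(2, 0), list(moves = 2L, credit = 0))
  r <- realize_moves(1.7, 0.5)
  expect_identical(r$moves, 2L)
  expect_equal(r$credit, 0.2)
  # exact conservation away from integer boundaries
  set.seed(1)
  credit <- 0
  total <- 0
  for (i in 1:500) {
    e <- runif(1, 0, 5)
    r <- realize_moves(e, credit)
    expect_identical(r$moves + r$credit, credit + e)
    expect_gte(r$credit, 0)
    expect_lt(r$credit, 1)
    credit <- r$credit
  }
})

test_that("a day of realized moves telescopes to the daily total", {
  # ten consecutive steps from zero credit recover all 20 moves
  for (pars in list(c(1, 0), c(1, 90), c(0.3, 217), c(0, 0))) {
    credit <- 0
    total <- 0L
    for (s in 0:9) {
      m <- expected_moves(pars[1], pars[2], 36 * s, 36 * (s + 1))
      r <- realize_moves(m, credit)
      total <- total + r$moves
      credit <- r$credit
    }
    expect_identical(total, 20L)
    expect_lt(credit, 1e-9)
  }
  # from random starting credit the daily total is 20 +/- 1
  set.seed(11)
  for (i in 1:50) {
    credit <- runif(1)
    total <- 0L
    A <- runif(1); phi <- runif(1, 0, 360)
    for (s in 0:9) {
      r <- realize_moves(expected_moves(A, phi, 36 * s, 36 * (s + 1)),
                         credit)
      total <- total + r$moves
      credit <- r$credit
    }
    expect_true(total %in% 19:21)
  }
})

test_that("specialization scales resource energy around its baseline", {
  # 20% more at the peak when S = 0.2
  expect_equal(resource_energy(0.2, 90, 90), 0.6)
  expect_equal(resource_energy(0.2, 90, 270), 0.4)
  expect_equal(resource_energy(0, 0, 123), 0.5)
  # S = 0.75: peak is seven times the trough
  expect_equal(resource_energy(0.75, 0, 0) / resource_energy(0.75, 0, 180),
               7)
})

test_that("circular mean handles wrapping and ties", {
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(90, 90)), 90)
  expect_equal(circular_mean(c(0, 90)), 45)
  # rotation equivariance on random sets
  set.seed(3)
  for (i in 1:50) {
    x <- runif(8, 0, 360)
    rot <- runif(1, 0, 360)
    expect_lt(circular_distance(circular_mean(x + rot),
                                circular_mean(x) + rot), 1e-6)
  }
  # antipodal tie resolves to one of the inputs, never an error
  set.seed(4)
  got <- replicate(50, circular_mean(c(10, 190)))
  expect_true(all(got %in% c(10, 190)))
  expect_true(length(unique(got)) == 2)  # random, not a fixed pick
})

test_that("circular distance is the shorter arc", {
  expect_equal(circular_distance(0, 180), 180)
  expect_equal(circular_distance(350, 10), 20)
  expect_equal(circular_distance(90, 90), 0)
  expect_equal(circular_distance(-10, 10), 20)
})

test_that("circular SD matches the closed form and is capped", {
  expect_equal(circular_sd(c(45, 45, 45)), 0)
  expect_equal(circular_sd(c(0, 90)),
               sqrt(-2 * log(cos(pi / 4))) * 180 / pi)
  # near-uniform sample hits the documented ceiling
  expect_lte(circular_sd(seq(0, 359.9, by = 0.1)),
             sqrt(-2 * log(1e-12)) * 180 / pi)
})

test_that("trait inheritance averages, mutates, clamps and wraps", {
  p <- function(a, ph) list(amplitude = a, phase = ph)
  # zero SDs: deterministic midpoint / circular mean
  off <- inherit_traits(p(0.4, 350), p(0.6, 10))
  expect_equal(off$amplitude, 0.5)
  expect_equal(off$phase, 0)
  # identical parents are a fixed point
  off2 <- inherit_traits(p(0.7, 123), p(0.7, 123))
  expect_equal(off2$amplitude, 0.7)
  expect_equal(off2$phase, 123)
  # amplitude clamps at the boundary under mutation
  set.seed(5)
  amps <- replicate(200, inherit_traits(p(1, 0), p(1, 0),
                                        amp_sd = 0.04)$amplitude)
  expect_true(all(amps <= 1 & amps >= 0))
  expect_true(any(amps == 1))  # clamp, not redraw
  phs <- replicate(200, inherit_traits(p(1, 0), p(1, 0),
                                       phase_sd_frac = 0.04)$phase)
  expect_true(all(phs >= 0 & phs < 360))
})
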