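test_that("overlap matrix is symmetric with unit diagonal", {
  expect_equal(overlap_matrix(rep(42, 5)), matrix(1, 5, 5))
  # two antiphase blocks: within-group 1, cross-group 0
  M <- overlap_matrix(c(0, 0, 180, 180))
  expect_equal(M, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        c(0, 0, 1, 1), c(0, 0, 1, 1)))
  set.seed(10)
  ph <- runif(30, 0, 360)
  M <- overlap_matrix(ph)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 30))
  # entrywise agreement with the pairwise rule and with the engine's matrix
  expect_equal(M[3, ], mating_window_overlap(ph[3], ph))
  expect_equal(M, cpp_overlap_matrix(ph, 135))
})

test_that("CGM separates antiphase groups and unites single clumps", {
  set.seed(20)
  # complete reproductive isolation regardless of group sizes
  expect_equal(cgm(c(rep(0, 3), rep(180, 9)), seed = 1), 0)
  expect_equal(cgm(c(0, 180), seed = 1), 0)
  # one clump: all overlaps are 1 whatever the arbitrary split
  expect_equal(cgm(rep(77, 15), seed = 1), 1)
  expect_true(is.na(cgm(numeric(0))))
  expect_true(is.na(cgm(45)))
})

test_that("CGM is invariant to rotation and relabeling", {
  set.seed(21)
  ph <- c(rnorm(10, 0, 10), rnorm(8, 160, 10)) %% 360
  base <- cgm(ph, seed = 5)
  expect_gte(base, 0)
  expect_lte(base, 1)
  for (rot in c(37, 180, 301)) {
    expect_equal(cgm((ph + rot) %% 360, seed = 5), base, tolerance = 1e-12)
  }
  expect_equal(cgm(sample(ph), seed = 5), base, tolerance = 1e-12)
})

test_that("2-means CGM matches the exhaustive-partition oracle", {
  # clearly bimodal populations, n <= 12: the best 2-means split must
  # recover the minimum cross-group overlap over all bipartitions
  set.seed(22)
  for (i in 1:8) {
    n1 <- sample(3:8, 1)
    ph <- c(rnorm(n1, 0, 10), rnorm(12 - n1, 160, 10)) %% 360
    expect_equal(cgm(ph, seed = i), brute_force_cgm(ph), tolerance = 1e-9)
  }
})

test_that("CGM agrees with an independent k-means implementation", {
  set.seed(23)
  ph <- c(rnorm(40, 90, 12), rnorm(35, 260, 12)) %% 360
  M <- overlap_matrix(ph)
  km <- stats::kmeans(M, centers = 2, nstart = 10, iter.max = 300,
                      algorithm = "Lloyd")
  ref <- mean(M[km$cluster == 1, km$cluster == 2])
  expect_equal(cgm(ph, seed = 3), ref, tolerance = 1e-9)
})

test_that("species phase difference uses circular means", {
  expect_equal(species_phase_difference(c(10, 20), c(10, 20)), 0)
  expect_equal(species_phase_difference(rep(0, 5), rep(180, 5)), 180)
  expect_equal(species_phase_difference(c(350, 10), c(80, 100)), 90)
})

test_that("event detection reads the record time series", {
  fake <- structure(list(daily = data.frame(
    day = rep(0:4, each = 2), species = rep(1:2, 5),
    pop = c(10, 10, 8, 5, 6, 0, 5, 0, 4, 0),
    cgm = rep(c(0.67, 0.38, 0.2, 0.05, 0.02), each = 2)
  )), class = "trial_record")
  ex <- detect_exclusion(fake)
  expect_identical(ex, c(NA_integer_, 2L))
  expect_identical(detect_speciation(fake), 3L)
  expect_identical(detect_speciation(fake, threshold = 0.01), NA_integer_)
  expect_identical(detect_speciation(fake, threshold = 1), 0L)
})

test_that("resource histogram reflects the community's activity phase", {
  # two species at the same phase carve a trough at their shared peak;
  # antiphase species flatten the profile
  same <- sim_config(list(species_config(n0 = 75, amplitude = 1, phase = 180),
                          species_config(n0 = 75, amplitude = 1, phase = 180)),
                     horizon_days = 60, stabilize = TRUE)
  rec_s <- run_trial(same, seed = 3)
  h_s <- colMeans(resource_time_histogram(rec_s)[41:61, ])
  rec_a <- run_trial(antiphase_config(horizon_days = 60, stabilize = TRUE),
                     seed = 3)
  h_a <- colMeans(resource_time_histogram(rec_a)[41:61, ])
  # shared peak at 180 deg = step 5: in-phase profile dips there
  expect_lt(min(h_s[4:6]), min(h_s[c(1, 10)]))
  # relative range of the antiphase profile is much smaller
  range_rel <- function(h) (max(h) - min(h)) / mean(h)
  expect_lt(range_rel(h_a), range_rel(h_s))
})

test_that("organisms at the edges of the phase distribution gain more energy", {
  # stabilized focal species with phase spread 15 deg against a rival fixed
  # at the same mean phase: after a 50-day burn-in the outer phase deciles
  # hold more energy than the middle deciles (the time-resource gradient)
  cfg <- sim_config(list(
    species_config(n0 = 75, amplitude = 1, phase = 180,
                   init_phase_sd = 15, phase_sd_frac = 15 / 360),
    species_config(n0 = 75, amplitude = 1, phase = 180)),
    horizon_days = 50, stabilize = TRUE)
  diffs <- sapply(1:10, function(s) {
    rec <- run_trial(cfg, seed = 600 + s)
    snap <- rec$snapshot[rec$snapshot$species == 1, ]
    dev <- circular_distance(snap$phase, circular_mean(snap$phase))
    qs <- stats::quantile(dev, c(0.2, 0.8))
    mean(snap$energy[dev >= qs[2]]) - mean(snap$energy[dev <= qs[1]])
  })
  tt <- stats::t.test(diffs, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
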