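test_that("segmentation handles constant, square-wave and reduced cases", {
  t <- seq(0, 99)
  # constant below the enter threshold: one segment spanning the trace
  const <- distance_trace(t, rep(3, 100))
  segs <- segment_bound_states(const, 5, 10)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_ns, 0)
  expect_equal(segs$end_ns, 100)
  # noiseless square wave: segments equal the wave's low phases
  wave <- distance_trace(t, rep(rep(c(3, 12), each = 25), 2))
  segs_w <- segment_bound_states(wave, 5, 10)
  expect_equal(nrow(segs_w), 2L)
  expect_equal(segs_w$start_ns, c(0, 50))
  expect_equal(segs_w$end_ns, c(25, 75))
  # equal thresholds reduce to a single cutoff
  segs_1 <- segment_bound_states(wave, 7.5, 7.5)
  expect_equal(segs_1$start_ns, segs_w$start_ns)
  expect_equal(segs_1$end_ns, segs_w$end_ns)
  expect_error(segment_bound_states(distance_trace(t, rep(NaN, 100)), 5, 10),
               "NaN")
  expect_error(segment_bound_states(wave, 10, 5), "threshold_low")
})

test_that("short flickers are merged away by min_dwell", {
  t <- seq(0, 99)
  d <- rep(3, 100)
  d[50:51] <- 12 # a 2 ns excursion inside a long bound stretch
  tr <- distance_trace(t, d)
  expect_equal(nrow(segment_bound_states(tr, 5, 10)), 2L)
  merged <- segment_bound_states(tr, 5, 10, min_dwell = 5)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$end_ns - merged$start_ns, 100)
})

test_that("residence statistics summarize and censor segments", {
  t <- seq(0, 999)
  d <- rep(12, 1000)
  d[1:730] <- 3
  one <- segment_bound_states(distance_trace(t, d), 5, 10)
  expect_equal(residence_stats(one)$mean_ns, 730)
  # planted segments {100, 200, 300}
  d2 <- rep(12, 1000)
  d2[101:200] <- 3; d2[401:600] <- 3; d2[701:1000] <- 3
  segs <- segment_bound_states(distance_trace(t, d2), 5, 10)
  st <- residence_stats(segs)
  expect_equal(st$n_events, 3L)
  expect_equal(st$mean_ns, 200)
  expect_equal(st$median_ns, 200)
  expect_equal(st$total_bound_fraction, 0.6)
  # the last segment abuts the trace end and is censorable
  st_c <- residence_stats(segs, censor_last = TRUE)
  expect_equal(st_c$n_events, 2L)
  expect_equal(st_c$mean_ns, 150)
  # censoring the only segment yields an explicit empty result
  st_e <- residence_stats(segment_bound_states(distance_trace(t, rep(3, 1000)),
                                               5, 10), censor_last = TRUE)
  expect_equal(st_e$n_events, 0L)
  expect_true(is.na(st_e$mean_ns))
})

test_that("noiseless telegraph segmentation reproduces the planted dwells event-for-event", {
  tr <- simulate_distance_trace(40, 20, level_noise = 0, dt = 0.5,
                                duration = 3000, seed = 2)
  segs <- segment_bound_states(tr, 10, 20)
  # independent oracle: read the dwells straight off the level runs
  r <- rle(tr$distance_A == 5)
  starts <- c(0, cumsum(r$lengths))[which(r$values)] * 0.5
  lens <- r$lengths[r$values] * 0.5
  expect_equal(segs$start_ns, starts)
  expect_equal(segs$end_ns - segs$start_ns, lens)
})

test_that("hysteresis keeps the event count stable under moderate noise", {
  base <- simulate_distance_trace(40, 20, level_noise = 0, dt = 0.2,
                                  duration = 20000, seed = 8)
  clean <- segment_bound_states(base, 10, 20)
  noisy <- base
  noisy$distance_A <- base$distance_A +
    withr::with_seed(9, rnorm(nrow(base), 0, (20 - 10) / 6 * 0.9))
  noisy_segs <- segment_bound_states(distance_trace(noisy$t_ns,
                                                    noisy$distance_A), 10, 20)
  expect_lt(abs(nrow(noisy_segs) - nrow(clean)) / nrow(clean), 0.05)
})

test_that("dihedrals follow the IUPAC sign convention", {
  # planar trans chain
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # hand-derived perpendicular case and its mirror image
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), -90)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, -1)), 90)
  # cis
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
})

test_that("dihedrals are invariant under rigid motions", {
  withr::with_seed(11, {
    for (i in 1:20) {
      pts <- lapply(1:4, function(j) rnorm(3))
      ang <- tryCatch(do.call(dihedral, pts), error = function(e) NULL)
      if (is.null(ang)) next
      rot <- random_rotation()
      shift <- rnorm(3, 0, 10)
      moved <- lapply(pts, function(p) as.vector(rot %*% p) + shift)
      expect_equal(do.call(dihedral, moved), ang, tolerance = 1e-8)
    }
  })
})

test_that("circular means respect wrap-around", {
  expect_equal(circular_mean(c(170, -170)), 180)
  expect_equal(circular_mean(c(-90, -90, -90)), -90)
  withr::with_seed(12, {
    a <- runif(10, -180, 180)
    i <- sample(10, 3)
    b <- a; b[i] <- b[i] + 360
    expect_equal(circular_mean(b), circular_mean(a))
  })
  expect_error(circular_mean(c(0, 90, 180, -90)), "undefined")
  expect_error(circular_mean(numeric(0)), "non-empty")
})

test_that("circular means of concentrated angle samples find the mode", {
  angles <- withr::with_seed(13, rvonmises_deg(2000, -90, 50))
  expect_lt(abs(circular_mean(angles) - (-90)), 2)
})
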