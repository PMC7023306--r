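axis1k <- seq(0.4, 1.8, length.out = 1000)

test_that("EIM extraction equals a brute-force windowed sum", {
  # two species 0.5 Da apart with distinct per-bin intensities
  axis <- seq(0.8, 1.2, length.out = 200)
  i1 <- 1000 * exp(-(axis - 0.95)^2 / (2 * 0.01^2))
  i2 <- 400 * exp(-(axis - 1.05)^2 / (2 * 0.01^2))
  frames <- make_frames(axis, function(i) {
    data.frame(mz = c(609.15, 609.65), intensity = c(i1[i], i2[i]))
  })

  narrow <- extract_eim(frames, 609.15, tol = 0.01)
  expect_equal(narrow$intensity, i1, tolerance = 1e-12)
  # widening the tolerance to 1 Da merges both species per bin
  wide <- extract_eim(frames, 609.15, tol = 1)
  expect_equal(wide$intensity, i1 + i2, tolerance = 1e-12)
  # absent target -> all-zero trace
  zero <- extract_eim(frames, 999, tol = 0.01)
  expect_true(all(zero$intensity == 0))
})

test_that("BPM is the per-bin maximum and matches the EIM for one species", {
  axis <- seq(0.8, 1.2, length.out = 150)
  i1 <- 1000 * exp(-(axis - 0.95)^2 / (2 * 0.01^2))
  i2 <- 400 * exp(-(axis - 1.05)^2 / (2 * 0.01^2))
  two <- make_frames(axis, function(i) {
    data.frame(mz = c(609.15, 700.2), intensity = c(i1[i], i2[i]))
  })
  bpm <- extract_bpm(two)
  expect_equal(bpm$intensity, pmax(i1, i2), tolerance = 1e-12)

  one <- make_frames(axis, function(i) {
    data.frame(mz = 609.15, intensity = i1[i])
  })
  expect_equal(extract_bpm(one)$intensity,
               extract_eim(one, 609.15, 0.01)$intensity, tolerance = 1e-12)

  # empty bins give zero intensity
  gappy <- make_frames(axis, function(i) {
    if (i %% 2 == 0) NULL else data.frame(mz = 609.15, intensity = i1[i])
  })
  expect_true(all(extract_bpm(gappy)$intensity[seq(2, 150, 2)] == 0))
})

test_that("Savitzky-Golay smoothing reproduces polynomials and composes", {
  m <- gaussian_mobilogram(1.1, axis = axis1k)
  flat <- m
  flat$intensity <- rep(500, nrow(flat))
  expect_equal(smooth_mobilogram(flat)$intensity, flat$intensity,
               tolerance = 1e-9)

  spacing <- diff(axis1k)[1]
  center <- axis1k[500] + 0.3 * spacing  # off-grid centre, sigma = 4 bins
  g <- gaussian_mobilogram(center, sigma = 4 * spacing, axis = axis1k)
  sg <- smooth_mobilogram(g, window_mobility = 8 * spacing)
  shift <- abs(axis1k[which.max(sg$intensity)] - axis1k[which.max(g$intensity)])
  expect_lt(shift, 0.25 * spacing + 1e-12)
  # interior peak area preserved within 1%
  expect_lt(abs(sum(sg$intensity) - sum(g$intensity)) / sum(g$intensity), 0.01)

  two_cycles <- smooth_mobilogram(m, cycles = 2)
  twice <- smooth_mobilogram(smooth_mobilogram(m))
  expect_equal(two_cycles$intensity, twice$intensity, tolerance = 1e-12)

  expect_error(smooth_mobilogram(m, window_mobility = spacing / 10), "< 5")
})

test_that("peak picking finds isolated Gaussians at their true centres", {
  centers <- c(0.7, 1.0, 1.4)
  m <- gaussian_mobilogram(centers, sigma = 0.008,
                           heights = c(1000, 800, 600), axis = axis1k)
  pks <- pick_peaks(m)
  expect_equal(nrow(pks), 3L)
  spacing <- diff(axis1k)[1]
  expect_lt(max(abs(sort(pks$apex_pos) - centers)), spacing / 2)
  expect_true(all(pks$base_width >= pks$fwhm))
  # FWHM of a Gaussian is 2.3548 sigma
  expect_equal(pks$fwhm, rep(2.3548 * 0.008, 3), tolerance = 0.02)
})

test_that("relative intensity threshold suppresses minor peaks", {
  m <- gaussian_mobilogram(c(0.8, 1.3), sigma = 0.008,
                           heights = c(1000, 100), axis = axis1k)
  expect_equal(nrow(pick_peaks(m, rel_intensity_threshold = 15)), 1L)
  expect_equal(nrow(pick_peaks(m, rel_intensity_threshold = 5)), 2L)
})

test_that("valley depth controls merging of overlapping peaks", {
  # two Gaussians placed so the valley sits near 94% of the lower apex
  sigma <- 0.02
  sep <- 2.4 * sigma
  m <- gaussian_mobilogram(c(1.0, 1.0 + sep), sigma = sigma,
                           heights = c(1000, 950), axis = axis1k)
  y <- m$intensity
  i_mid <- which(axis1k >= 1.0 & axis1k <= 1.0 + sep)
  valley_ratio <- min(y[i_mid]) /
    min(max(y[axis1k < 1.0 + sep / 2]), max(y[axis1k > 1.0 + sep / 2]))
  expect_gt(valley_ratio, 0.90)
  expect_lt(valley_ratio, 0.96)
  merged <- pick_peaks(m, min_valley = 10)
  split <- pick_peaks(m, min_valley = 4)
  expect_equal(nrow(merged), 1L)
  expect_equal(nrow(split), 2L)
})

test_that("an all-zero mobilogram yields no peaks", {
  m <- gaussian_mobilogram(1.0, axis = axis1k)
  m$intensity <- rep(0, nrow(m))
  expect_equal(nrow(pick_peaks(m)), 0L)
})

test_that("smoothing creates no spurious local maxima above 1% of base", {
  set.seed(7)
  for (k in 1:3) {
    centers <- sort(runif(k, 0.6, 1.6))
    m <- gaussian_mobilogram(centers, sigma = 0.02,
                             heights = runif(k, 400, 1000), axis = axis1k)
    sm <- smooth_mobilogram(m)
    pks <- pick_peaks(sm, sensitivity = 99, rel_intensity_threshold = 1,
                      min_valley = 1)
    extra <- pks$height[!vapply(pks$apex_pos, function(p) {
      any(abs(p - centers) < 0.05)
    }, logical(1))]
    expect_true(all(extra < 0.01 * max(m$intensity)))
  }
})

test_that("peak purity equals the brute-force intensity ratio", {
  axis <- seq(0.9, 1.3, length.out = 300)
  target <- 609.15
  contam <- 612.40
  w <- exp(-(axis - 1.1)^2 / (2 * 0.01^2))
  frames <- make_frames(axis, function(i) {
    data.frame(mz = c(target, contam), intensity = c(80 * w[i], 20 * w[i]))
  })
  pk <- pick_peaks(smooth_mobilogram(extract_eim(frames, target, 0.01)))[1, ]
  expect_equal(as.numeric(peak_purity(frames, pk, target, 0.01)), 0.8,
               tolerance = 1e-9)

  pure <- make_frames(axis, function(i) {
    data.frame(mz = target, intensity = 80 * w[i])
  })
  expect_equal(as.numeric(peak_purity(pure, pk, target, 0.01)), 1)
  expect_equal(as.numeric(peak_purity(pure, pk, 999, 0.01)), 0)

  # zero ion current in the extent -> purity 0 with degenerate flag
  empty <- make_frames(axis, function(i) NULL)
  p <- peak_purity(empty, pk, target, 0.01)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
})

test_that("apex CCS recovers a planted rutin-like peak to < 0.05%", {
  ctx <- physics_context()
  mz <- species_mz(monoisotopic_mass("C27H30O16"), "[M-H]-")

  # identity axis: direct conversion
  sim <- simulate_frames(rutin_spec())
  got <- measure_ccs(sim$frames, mz, model = NULL, ctx = ctx)
  expect_lt(abs(got$apex_ccs - 231.05) / 231.05, 5e-4)

  # affine-distorted raw axis with a fitted calibration
  dist <- c(slope = 1.07, intercept = -0.03)
  sim2 <- simulate_frames(rutin_spec(distortion = dist))
  tab <- toy_calibrant_table()
  cal_run <- simulate_calibrant_run(tab, dist, ctx)
  model <- fit_calibration(measure_calibrant_raw(cal_run, tab), tab, ctx)
  got2 <- measure_ccs(sim2$frames, mz, model = model, ctx = ctx)
  expect_lt(abs(got2$apex_ccs - 231.05) / 231.05, 5e-4)
})

test_that("resolving power is apex over FWHM and scale-invariant", {
  expect_equal(tims_resolving_power(160, 4), 40)
  expect_equal(tims_resolving_power(160, 160 / 120), 120)

  m <- gaussian_mobilogram(1.1, sigma = 0.01, heights = 1000, axis = axis1k)
  m2 <- m
  m2$intensity <- m$intensity * 7.3
  p1 <- apex_ccs(pick_peaks(m)[1, ], NULL, 609.15)
  p2 <- apex_ccs(pick_peaks(m2)[1, ], NULL, 609.15)
  expect_equal(tims_resolving_power(p1), tims_resolving_power(p2),
               tolerance = 1e-12)
})
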