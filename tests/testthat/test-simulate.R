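test_that("generators are deterministic under a fixed seed", {
  spec <- rutin_spec(seed = 3L, noise = list(type = "additive", level = 0.01))
  a <- simulate_frames(spec)
  b <- simulate_frames(spec)
  expect_identical(a, b)
  spec2 <- spec
  spec2$seed <- 4L
  c <- simulate_frames(spec2)
  expect_false(identical(a$frames, c$frames))
  # the global RNG stream is not disturbed
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_frames(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the truth table is self-consistent through the physics", {
  spec <- rutin_spec()
  tt <- truth_table(spec)
  for (r in seq_len(nrow(tt))) {
    back <- inverse_k0_from_ccs(tt$true_ccs[r], tt$mz[r], spec$ctx)
    expect_lt(abs(back - tt$true_inv_k0[r]) / tt$true_inv_k0[r], 1e-12)
  }
})

test_that("a single noiseless species yields a Gaussian EIM at truth", {
  cmp <- compound_record("chrysin", "C15H10O4")
  spec <- simulation_spec(
    compounds = list(list(compound = cmp, species = "[M-H]-",
                          true_ccs = c("[M-H]-" = 156.14),
                          abundance = c("[M-H]-" = 1))),
    seed = 2L)
  sim <- simulate_frames(spec)
  eim <- extract_eim(sim$frames, sim$truth$mz[1], 0.01)
  spacing <- diff(eim$axis)[1]
  expect_lt(abs(eim$axis[which.max(eim$intensity)] - sim$truth$true_inv_k0[1]),
            spacing / 2 + 1e-12)
  # trace is the planted Gaussian (up to the support cut-off)
  expected <- 1e4 * exp(-(eim$axis - sim$truth$true_inv_k0[1])^2 /
                          (2 * spec$peak_sigma^2))
  expected[expected < 1e4 * 1e-6] <- 0
  expect_equal(eim$intensity, expected, tolerance = 1e-9)
})

test_that("an out-of-range species m/z is rejected", {
  cmp <- compound_record("tiny", monoisotopic_mass = 60)
  spec <- simulation_spec(
    compounds = list(list(compound = cmp, species = "[M-H]-",
                          true_ccs = c("[M-H]-" = 120),
                          abundance = c("[M-H]-" = 1))))
  expect_error(simulate_frames(spec, mass_range = c(100, 2000)),
               "outside mass range")
})

test_that("calibrant runs recover planted affine distortions", {
  ctx <- physics_context()
  tab <- toy_calibrant_table()

  run0 <- simulate_calibrant_run(tab, c(1, 0), ctx)
  m0 <- fit_calibration(measure_calibrant_raw(run0, tab), tab, ctx)
  expect_lt(abs(m0$slope - 1), 1e-9)
  expect_lt(abs(m0$intercept), 1e-9)

  run1 <- simulate_calibrant_run(tab, c(1.03, -0.01), ctx)
  m1 <- fit_calibration(measure_calibrant_raw(run1, tab), tab, ctx)
  expect_lt(abs(m1$slope - 1.03), 1e-9)
  expect_lt(abs(m1$intercept + 0.01), 1e-9)

  # intensity noise degrades the fit but only at the 1e-3 level
  run2 <- simulate_calibrant_run(tab, c(1.03, -0.01), ctx, seed = 8L,
                                 noise_level = 0.005)
  m2 <- fit_calibration(measure_calibrant_raw(run2, tab), tab, ctx)
  expect_lt(abs(m2$slope - 1.03), 1e-3)
})

test_that("replicate batches propagate the injected CCS jitter", {
  spec <- rutin_spec()
  batch0 <- simulate_replicate_batch(spec, n_replicates = 3,
                                     ccs_jitter_rsd = 0, seed = 5L)
  mz <- batch0$truth$mz[batch0$truth$species == "[M-H]-"]
  ccs0 <- vapply(batch0$replicates, function(r) {
    measure_ccs(r$frames, mz)$apex_ccs
  }, numeric(1))
  expect_equal(stats::sd(ccs0), 0, tolerance = 1e-9)

  batch1 <- simulate_replicate_batch(spec, n_replicates = 1,
                                     ccs_jitter_rsd = 0.1, seed = 5L)
  one <- build_library(list(replicate_set(
    rutin(), "[M-H]-",
    measure_ccs(batch1$replicates[[1]]$frames, mz)$apex_ccs)))
  expect_true(is.na(one[[1]]$ccs_by_reference[[1]]$sd))
})

test_that("matrix background leaves planted species nearly untouched", {
  spec <- rutin_spec()
  sim <- simulate_frames(spec)
  mz <- sim$truth$mz[sim$truth$species == "[M-H]-"]
  clean <- measure_ccs(sim$frames, mz)

  dense <- overlay_matrix_background(sim$frames, density = 200, seed = 6L)
  with_bg <- measure_ccs(dense, mz)
  expect_lt(percent_difference(clean$apex_ccs, with_bg$apex_ccs), 0.15)

  # density zero is the identity
  expect_identical(overlay_matrix_background(sim$frames, 0), sim$frames)
})

test_that("a direct mobility collision erodes purity", {
  spec <- rutin_spec()
  sim <- simulate_frames(spec)
  mz <- sim$truth$mz[sim$truth$species == "[M-H]-"]
  inv_k0 <- sim$truth$true_inv_k0[sim$truth$species == "[M-H]-"]
  # plant an interfering species right on top of the [M-H]- peak, slightly
  # offset in m/z so it shares the extent but not the EIM window
  axis <- sim$frames$raw_axis
  spectra <- sim$frames$spectra
  for (i in seq_along(axis)) {
    w <- exp(-(axis[i] - inv_k0)^2 / (2 * spec$peak_sigma^2))
    if (w < 1e-6) next
    spectra[[i]] <- rbind(spectra[[i]],
                          data.frame(mz = mz + 0.5, intensity = 3e4 * w))
  }
  collided <- frame_stack(axis, spectra)
  got <- measure_ccs(collided, mz)
  expect_lt(got$purity, 0.5)
  expect_gt(as.numeric(peak_purity(sim$frames,
                                   measure_ccs(sim$frames, mz), mz, 0.01)),
            0.6)
})

test_that("frame stacks round-trip through the JSON-lines format", {
  sim <- simulate_frames(rutin_spec())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_frames(sim$frames, path)
  back <- read_frames(path)
  expect_equal(back$raw_axis, sim$frames$raw_axis, tolerance = 1e-12)
  expect_identical(back$calibrated, sim$frames$calibrated)
  n <- vapply(sim$frames$spectra, nrow, integer(1))
  expect_identical(vapply(back$spectra, nrow, integer(1)), n)
  i <- which(n > 0)[1]
  expect_equal(back$spectra[[i]]$intensity, sim$frames$spectra[[i]]$intensity,
               tolerance = 1e-12)
})
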