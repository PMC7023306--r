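# Fixture builders and independent oracles shared across test files.

rutin <- function() {
  compound_record("rutin", "C27H30O16", compound_class = "flavonol glycoside",
                  retention_time = 12.5)
}

# mobilogram with Gaussian peaks planted at given centres (axis units)
gaussian_mobilogram <- function(centers, sigma = 0.01, heights = NULL,
                                axis = seq(0.4, 1.8, length.out = 1000)) {
  if (is.null(heights)) heights <- rep(1000, length(centers))
  y <- numeric(length(axis))
  for (k in seq_along(centers)) {
    y <- y + heights[k] * exp(-(axis - centers[k])^2 / (2 * sigma^2))
  }
  timsccs::extract_bpm(frame_stack(axis, lapply(y, function(v) {
    if (v <= 0) data.frame(mz = numeric(0), intensity = numeric(0))
    else data.frame(mz = 500, intensity = v)
  })))
}

# frame stack with per-bin centroid lists given as a function of bin index
make_frames <- function(axis, centroid_fn, calibrated = FALSE) {
  frame_stack(axis, lapply(seq_along(axis), centroid_fn),
              calibrated = calibrated)
}

# synthetic three-calibrant table in the tune-mix m/z range
toy_calibrant_table <- function(id = "toy") {
  reference_calibrant_table(id, mz = c(302, 602, 1034),
                            reference_ccs = c(153, 203, 255))
}

# one-compound, three-species rutin-like simulation spec
rutin_spec <- function(seed = 1L, noise = list(type = "none", level = 0),
                       distortion = c(slope = 1, intercept = 0),
                       sigma = 0.01) {
  simulation_spec(
    compounds = list(list(
      compound = rutin(),
      species = c("[M-H]-", "[M-3H]-", "[M-H+Na+HCO2]-"),
      true_ccs = c("[M-H]-" = 231.05, "[M-3H]-" = 220.0,
                   "[M-H+Na+HCO2]-" = 252.3),
      abundance = c("[M-H]-" = 1, "[M-3H]-" = 0.35, "[M-H+Na+HCO2]-" = 0.5)
    )),
    peak_sigma = sigma,
    noise = noise,
    calibration_distortion = distortion,
    seed = seed
  )
}

# Brute-force multinomial isotopologue oracle, independent of the package's
# iterative-convolution implementation: enumerates, per element, every
# placement of heavy isotopes up to the requested offset, multiplies the
# multinomial probabilities, and aggregates across elements by total offset.
oracle_isotope_ratios <- function(formula, n_iso = 4L) {
  counts <- timsccs::parse_formula(formula)
  abund <- list(
    H  = c(0.999885, 0.000115),
    C  = c(0.9893, 0.0107),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Na = 1, P = 1,
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  max_off <- n_iso - 1L
  per_element <- lapply(names(counts), function(el) {
    p <- abund[[el]]
    n <- counts[[el]]
    if (length(p) == 1L) return(c(1, rep(0, max_off)))
    heavy_offsets <- seq_along(p)[-1] - 1L   # offsets of the heavy isotopes
    grid <- expand.grid(lapply(heavy_offsets, function(o) 0:min(n, max_off)))
    out <- numeric(max_off + 1L)
    for (r in seq_len(nrow(grid))) {
      ks <- as.integer(grid[r, ])
      if (sum(ks) > n) next
      off <- sum(ks * heavy_offsets)
      if (off > max_off) next
      out[off + 1L] <- out[off + 1L] +
        stats::dmultinom(c(n - sum(ks), ks), prob = p)
    }
    out
  })
  # combine elements: product distribution over total offset
  total <- Reduce(function(a, b) {
    out <- numeric(max_off + 1L)
    for (i in 0:max_off) for (j in 0:(max_off - i)) {
      out[i + j + 1L] <- out[i + j + 1L] + a[i + 1L] * b[j + 1L]
    }
    out
  }, per_element)
  total / total[1]
}
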