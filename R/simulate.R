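# Synthetic frame-stack generator with machine-readable truth tables:
# planted Gaussian mobility peaks for adduct ions, calibrant runs under
# affine axis distortions, replicate batches with controlled CCS jitter, and
# dense matrix-background overlays.

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulation specification
#'
#' Defines a synthetic ion-mobility acquisition: which compounds and ion
#' species are present, their true CCS and abundances, the mobility axis, the
#' Gaussian mobility peak width, the noise model and an affine calibration
#' distortion mapping raw instrument readings to true 1/K0
#' (\code{inv_k0 = slope * raw + intercept}).
#'
#' @param compounds List of per-compound specs, each a list with elements
#'   \code{compound} (a [compound_record()]), \code{species} (character
#'   vector from [NEGATIVE_SPECIES]), \code{true_ccs} (named by species,
#'   square Angstroms) and \code{abundance} (named by species, arbitrary
#'   counts scale).
#' @param mobility_axis c(min, max, n_bins) in 1/K0; the default 0.4-1.8
#'   V s/cm^2 over 1000 bins matches a broad survey acquisition.
#' @param peak_sigma Gaussian mobility peak sigma in 1/K0 units. The default
#'   0.01 puts single-peak resolving power in the survey regime (about
#'   40-50 at mid-range mobility).
#' @param noise List: \code{type} "none" or "additive", and \code{level} as a
#'   fraction of the per-species base intensity.
#' @param calibration_distortion c(slope, intercept) of the raw -> 1/K0 map.
#' @param seed Integer RNG seed; all generators are deterministic given it.
#' @param ctx A [physics_context()].
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(compounds,
                            mobility_axis = c(0.4, 1.8, 1000),
                            peak_sigma = 0.01,
                            noise = list(type = "none", level = 0),
                            calibration_distortion = c(slope = 1, intercept = 0),
                            seed = 1L,
                            ctx = physics_context()) {
  stopifnot(mobility_axis[1] < mobility_axis[2], mobility_axis[3] >= 50,
            peak_sigma > 0)
  stopifnot(noise$type %in% c("none", "additive"))
  for (cs in compounds) {
    stopifnot(inherits(cs$compound, "compound_record"),
              all(cs$species %in% NEGATIVE_SPECIES),
              all(cs$species %in% names(cs$true_ccs)),
              all(cs$species %in% names(cs$abundance)),
              all(cs$true_ccs > 0), all(cs$abundance > 0))
  }
  structure(list(compounds = compounds, mobility_axis = mobility_axis,
                 peak_sigma = peak_sigma, noise = noise,
                 calibration_distortion = calibration_distortion,
                 seed = as.integer(seed), ctx = ctx),
            class = "simulation_spec")
}

#' Truth table of a simulation spec
#'
#' One row per (compound, species): theoretical m/z, true CCS, the true 1/K0
#' implied by the physics context, and the abundance. Internally consistent
#' with the Mason-Schamp conversion by construction.
#'
#' @param spec A [simulation_spec()].
#' @return Data frame with columns \code{compound}, \code{species},
#'   \code{mz}, \code{true_ccs}, \code{true_inv_k0}, \code{abundance}.
#' @export
truth_table <- function(spec) {
  rows <- list()
  for (cs in spec$compounds) {
    for (sp in cs$species) {
      mz <- species_mz(cs$compound$monoisotopic_mass, sp)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cs$compound$name, species = sp, mz = mz,
        true_ccs = cs$true_ccs[[sp]],
        true_inv_k0 = inverse_k0_from_ccs(cs$true_ccs[[sp]], mz, spec$ctx),
        abundance = cs$abundance[[sp]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# deprotonated-form isotope pattern of a compound/species, if a formula is known
.species_pattern <- function(compound, sp) {
  f <- compound$molecular_formula
  if (is.null(f)) {
    return(data.frame(mass = 0, relative_intensity = 1))
  }
  f <- switch(sp,
    "[M-3H]-" = { f["H"] <- f["H"] - 2L; f },
    "[2M-H]-" = f * 2L,
    "[M-H+HCO2H]-" = .add_formula(f, c(C = 1L, H = 2L, O = 2L)),
    "[M-H+Na+HCO2]-" = .add_formula(f, c(C = 1L, H = 1L, O = 2L, Na = 1L)),
    f)
  f["H"] <- f["H"] - 1L
  theoretical_isotope_pattern(f[f > 0])
}

#' Simulate a frame stack from a specification
#'
#' Each (compound, species) contributes a Gaussian mobility profile centred
#' at the raw axis position implied by its true CCS and the inverse of the
#' calibration distortion, carrying centroids at the species m/z with its
#' theoretical isotope pattern. Optional uniform additive noise perturbs the
#' centroid intensities. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @param base_intensity Intensity of an abundance-1 species apex (counts).
#' @param mass_range Allowed m/z window; a species m/z outside it is an error.
#' @return List with elements \code{frames} (a [frame_stack()], raw axis) and
#'   \code{truth} (the [truth_table()]).
#' @export
simulate_frames <- function(spec, base_intensity = 1e4,
                            mass_range = c(50, 2000)) {
  stopifnot(inherits(spec, "simulation_spec"))
  truth <- truth_table(spec)
  if (any(truth$mz < mass_range[1] | truth$mz > mass_range[2])) {
    bad <- truth[truth$mz < mass_range[1] | truth$mz > mass_range[2], ]
    stop(sprintf("species m/z %.4f (%s %s) outside mass range [%g, %g]",
                 bad$mz[1], bad$compound[1], bad$species[1],
                 mass_range[1], mass_range[2]), call. = FALSE)
  }
  a <- spec$calibration_distortion[[1]]
  b <- spec$calibration_distortion[[2]]
  inv_k0_axis <- seq(spec$mobility_axis[1], spec$mobility_axis[2],
                     length.out = spec$mobility_axis[3])
  raw_axis <- (inv_k0_axis - b) / a

  patterns <- list()
  for (cs in spec$compounds) {
    for (sp in cs$species) {
      patterns[[paste(cs$compound$name, sp)]] <- .species_pattern(cs$compound, sp)
    }
  }

  .with_seed(spec$seed, {
    spectra <- vector("list", length(inv_k0_axis))
    for (i in seq_along(inv_k0_axis)) {
      mzs <- numeric(0); ints <- numeric(0)
      for (r in seq_len(nrow(truth))) {
        w <- exp(-(inv_k0_axis[i] - truth$true_inv_k0[r])^2 /
                   (2 * spec$peak_sigma^2))
        if (w < 1e-6) next
        pat <- patterns[[paste(truth$compound[r], truth$species[r])]]
        iso_mz <- truth$mz[r] +
          (seq_len(nrow(pat)) - 1) * .ISOTOPOLOGUE_SPACING
        iso_int <- truth$abundance[r] * base_intensity * w *
          pat$relative_intensity
        mzs <- c(mzs, iso_mz); ints <- c(ints, iso_int)
      }
      if (spec$noise$type == "additive" && length(ints)) {
        ints <- ints + stats::runif(length(ints), 0,
                                    spec$noise$level * base_intensity)
      }
      spectra[[i]] <- data.frame(mz = mzs, intensity = ints)
    }
    list(frames = frame_stack(raw_axis, spectra, calibrated = FALSE),
         truth = truth)
  })
}

#' Simulate a tune-mix calibrant run
#'
#' Plants each calibrant ion of a reference table as a Gaussian mobility peak
#' at the raw position implied by its reference CCS and the inverse of the
#' given affine distortion, so that measuring the apexes and fitting
#' recovers the distortion.
#'
#' @param table A [reference_calibrant_table()].
#' @param distortion c(slope, intercept) of the raw -> 1/K0 map.
#' @param ctx A [physics_context()].
#' @param seed RNG seed (used only when \code{noise_level > 0}).
#' @param noise_level Additive intensity noise as a fraction of the apex.
#' @param mobility_axis,peak_sigma As in [simulation_spec()].
#' @return A [frame_stack()] on the raw axis.
#' @export
simulate_calibrant_run <- function(table, distortion = c(1, 0),
                                   ctx = physics_context(), seed = 1L,
                                   noise_level = 0,
                                   mobility_axis = c(0.4, 1.8, 1000),
                                   peak_sigma = 0.01) {
  stopifnot(inherits(table, "reference_calibrant_table"))
  a <- distortion[[1]]; b <- distortion[[2]]
  inv_k0_axis <- seq(mobility_axis[1], mobility_axis[2],
                     length.out = mobility_axis[3])
  raw_axis <- (inv_k0_axis - b) / a
  true_inv_k0 <- vapply(seq_len(nrow(table)), function(i) {
    ctx_i <- physics_context(ctx$drift_gas_molar_mass, ctx$temperature,
                             abs(table$charge[i]))
    inverse_k0_from_ccs(table$reference_ccs[i], table$mz[i], ctx_i)
  }, numeric(1))
  .with_seed(seed, {
    spectra <- lapply(seq_along(inv_k0_axis), function(i) {
      w <- exp(-(inv_k0_axis[i] - true_inv_k0)^2 / (2 * peak_sigma^2))
      keep <- w >= 1e-6
      ints <- 1e4 * w[keep]
      if (noise_level > 0 && length(ints)) {
        ints <- ints + stats::runif(length(ints), 0, noise_level * 1e4)
      }
      data.frame(mz = table$mz[keep], intensity = ints)
    })
    frame_stack(raw_axis, spectra, calibrated = FALSE)
  })
}

#' Measure calibrant raw apex positions from a calibrant run
#'
#' Extracts the EIM of each calibrant m/z, smooths it, picks peaks and
#' returns the raw apex reading of the most intense peak per calibrant,
#' paired by table row for [fit_calibration()].
#'
#' @param frames A calibrant-run [frame_stack()].
#' @param table The [reference_calibrant_table()] that was planted.
#' @param tol EIM m/z tolerance in Da.
#' @param smooth Apply Savitzky-Golay smoothing before picking.
#' @return Numeric vector of raw apex readings, one per table row.
#' @export
measure_calibrant_raw <- function(frames, table, tol = 0.01, smooth = TRUE) {
  vapply(seq_len(nrow(table)), function(i) {
    eim <- extract_eim(frames, table$mz[i], tol)
    eim_s <- if (smooth) smooth_mobilogram(eim) else eim
    pks <- pick_peaks(eim_s, refine_apex = FALSE)
    if (!nrow(pks)) stop("no mobility peak found for calibrant m/z ",
                         table$mz[i], call. = FALSE)
    # refine on the unsmoothed trace: exact for noiseless Gaussian profiles
    .refine_apex(eim$axis, eim$intensity,
                 pks$apex_idx[which.max(pks$height)])
  }, numeric(1))
}

#' Simulate a replicate batch with controlled CCS jitter
#'
#' Generates \code{n_replicates} runs of the same spec whose true CCS values
#' are independently jittered with the stated relative standard deviation, so
#' the full pipeline should recover per-compound RSDs near the injected
#' value. Triplicates with 0.1 percent jitter emulate routine TIMS
#' reproducibility.
#'
#' @param spec A [simulation_spec()].
#' @param n_replicates Number of replicate runs (default 3).
#' @param ccs_jitter_rsd Relative standard deviation of the true CCS in
#'   percent (default 0.1).
#' @param seed RNG seed for the jitter and per-replicate noise.
#' @return List with \code{replicates} (list of [simulate_frames()] results)
#'   and \code{truth} (the unjittered [truth_table()]).
#' @export
simulate_replicate_batch <- function(spec, n_replicates = 3L,
                                     ccs_jitter_rsd = 0.1, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"), ccs_jitter_rsd >= 0,
            n_replicates >= 1)
  base_truth <- truth_table(spec)
  .with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      jittered <- spec
      jittered$seed <- spec$seed + r
      jittered$compounds <- lapply(spec$compounds, function(cs) {
        cs$true_ccs <- cs$true_ccs *
          (1 + stats::rnorm(length(cs$true_ccs)) * ccs_jitter_rsd / 100)
        cs
      })
      simulate_frames(jittered)
    })
    list(replicates = reps, truth = base_truth)
  })
}

#' Overlay a dense matrix background onto a frame stack
#'
#' Adds random background mobility features (Gaussian in mobility, uniform in
#' m/z, log-uniform in intensity) emulating a complex plant-extract matrix.
#' Planted truth species are left untouched; the overlay tests whether
#' recovered CCS values shift in the presence of matrix.
#'
#' @param frames A [frame_stack()].
#' @param density Background features per 1/K0 unit (0 returns the input
#'   unchanged).
#' @param seed RNG seed.
#' @param mz_range m/z window for background centroids.
#' @param intensity_range Log10 intensity bounds of background apexes.
#' @param peak_sigma Mobility sigma of background features (axis units).
#' @return The augmented [frame_stack()].
#' @export
overlay_matrix_background <- function(frames, density, seed = 1L,
                                      mz_range = c(100, 1500),
                                      intensity_range = c(2, 4),
                                      peak_sigma = 0.01) {
  stopifnot(inherits(frames, "frame_stack"), density >= 0)
  if (density == 0) return(frames)
  span <- abs(diff(range(frames$raw_axis)))
  n_feat <- max(1L, round(density * span))
  .with_seed(seed, {
    feat_pos <- stats::runif(n_feat, min(frames$raw_axis), max(frames$raw_axis))
    feat_mz <- stats::runif(n_feat, mz_range[1], mz_range[2])
    feat_int <- 10^stats::runif(n_feat, intensity_range[1], intensity_range[2])
    spectra <- frames$spectra
    for (i in seq_along(frames$raw_axis)) {
      w <- exp(-(frames$raw_axis[i] - feat_pos)^2 / (2 * peak_sigma^2))
      keep <- w >= 1e-6
      if (!any(keep)) next
      spectra[[i]] <- rbind(spectra[[i]],
                            data.frame(mz = feat_mz[keep],
                                       intensity = feat_int[keep] * w[keep]))
    }
    frame_stack(frames$raw_axis, spectra, calibrated = frames$calibrated)
  })
}

#' Measure the CCS of a species in a frame stack
#'
#' The per-compound processing pipeline in one call: extract the EIM at the
#' target m/z, smooth it, pick mobility peaks, select the highest-purity
#' peak, and convert its apex through the calibration to CCS.
#'
#' @param frames A [frame_stack()].
#' @param target_mz Species m/z.
#' @param model A [fit_calibration()] result, or NULL when the frame axis is
#'   already calibrated 1/K0.
#' @param ctx A [physics_context()].
#' @param tol EIM m/z tolerance in Da.
#' @param ... Passed to [pick_peaks()].
#' @return One peak row (see [apex_ccs()]) with a \code{purity} column, or
#'   NULL when no peak is found.
#' @export
measure_ccs <- function(frames, target_mz, model = NULL,
                        ctx = physics_context(), tol = 0.01, ...) {
  eim_raw <- extract_eim(frames, target_mz, tol)
  eim <- smooth_mobilogram(eim_raw)
  pks <- pick_peaks(eim, refine_apex = FALSE, ...)
  if (!nrow(pks)) return(NULL)
  # peak detection on the smoothed trace, apex refinement on the raw one
  pks$apex_pos <- vapply(pks$apex_idx, function(i) {
    .refine_apex(eim_raw$axis, eim_raw$intensity, i)
  }, numeric(1))
  pks$purity <- vapply(seq_len(nrow(pks)), function(i) {
    as.numeric(peak_purity(frames, pks[i, ], target_mz, tol))
  }, numeric(1))
  best <- pks[order(-pks$purity, -pks$height)[1], ]
  apex_ccs(best, model, target_mz, ctx)
}
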