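# Frame stacks, EIM/BPM mobilograms, Savitzky-Golay smoothing, valley-based
# peak picking, purity, and apex CCS.

#' Frame stack
#'
#' A stack of per-mobility-bin centroided mass spectra, the raw input to all
#' mobilogram processing. The mobility axis may hold raw instrument readings
#' (before calibration) or calibrated 1/K0 values, flagged by
#' \code{calibrated}.
#'
#' @param raw_axis Strictly monotonic vector of mobility readings, one per bin.
#' @param spectra List (same length) of data frames with columns \code{mz}
#'   and \code{intensity}; empty bins may be NULL or zero-row frames.
#' @param calibrated Logical; TRUE when the axis is already in 1/K0 units.
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(raw_axis, spectra, calibrated = FALSE) {
  stopifnot(length(raw_axis) == length(spectra))
  d <- diff(raw_axis)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("mobility axis must be strictly monotonic", call. = FALSE)
  }
  spectra <- lapply(spectra, function(s) {
    if (is.null(s)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
    stopifnot(all(c("mz", "intensity") %in% names(s)))
    if (any(s$intensity < 0)) stop("negative centroid intensity", call. = FALSE)
    s[, c("mz", "intensity")]
  })
  structure(list(raw_axis = raw_axis, spectra = spectra,
                 calibrated = isTRUE(calibrated)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  n_cent <- sum(vapply(x$spectra, nrow, integer(1)))
  cat(sprintf("frame_stack: %d mobility bins [%.4f, %.4f] (%s), %d centroids\n",
              length(x$raw_axis), min(x$raw_axis), max(x$raw_axis),
              if (x$calibrated) "1/K0" else "raw", n_cent))
  invisible(x)
}

#' Write / read a frame stack as JSON lines
#'
#' One frame per line: \code{{"axis": r, "mz": [...], "intensity": [...]}}.
#' First line is a header object with the \code{calibrated} flag.
#'
#' @param frames A [frame_stack()].
#' @param file Path.
#' @return \code{write_frames}: invisibly the path; \code{read_frames}: a
#'   [frame_stack()].
#' @export
write_frames <- function(frames, file) {
  stopifnot(inherits(frames, "frame_stack"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(type = "frame_stack",
                                   calibrated = frames$calibrated),
                              auto_unbox = TRUE), con)
  for (i in seq_along(frames$raw_axis)) {
    s <- frames$spectra[[i]]
    writeLines(jsonlite::toJSON(
      list(axis = frames$raw_axis[i], mz = s$mz, intensity = s$intensity),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(file)
}

#' @rdname write_frames
#' @export
read_frames <- function(file) {
  lines <- readLines(file)
  hdr <- jsonlite::fromJSON(lines[1])
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  frame_stack(
    raw_axis = vapply(recs, function(r) r$axis, numeric(1)),
    spectra = lapply(recs, function(r) {
      data.frame(mz = as.numeric(unlist(r$mz)),
                 intensity = as.numeric(unlist(r$intensity)))
    }),
    calibrated = isTRUE(hdr$calibrated)
  )
}

.new_mobilogram <- function(axis, intensity, kind, target_mz = NA_real_,
                            tol = NA_real_) {
  structure(data.frame(axis = axis, intensity = intensity),
            kind = kind, target_mz = target_mz, tol = tol,
            class = c("mobilogram", "data.frame"))
}

#' Extract an ion mobilogram (EIM)
#'
#' Per-bin intensity is the sum of centroid intensities whose m/z lies within
#' the tolerance of the target; the mobility axis is copied from the frames.
#'
#' @param frames A [frame_stack()].
#' @param target_mz Target m/z in Da/e.
#' @param tol Tolerance; absolute Da by default, parts-per-million when
#'   \code{ppm = TRUE}.
#' @param ppm Interpret \code{tol} in ppm.
#' @return A \code{mobilogram} data frame (columns \code{axis},
#'   \code{intensity}) with attributes \code{kind}, \code{target_mz},
#'   \code{tol}.
#' @export
extract_eim <- function(frames, target_mz, tol = 0.01, ppm = FALSE) {
  stopifnot(inherits(frames, "frame_stack"), tol > 0)
  tol_da <- if (ppm) target_mz * tol * 1e-6 else tol
  intensity <- vapply(frames$spectra, function(s) {
    if (!nrow(s)) return(0)
    sum(s$intensity[abs(s$mz - target_mz) <= tol_da])
  }, numeric(1))
  .new_mobilogram(frames$raw_axis, intensity, "EIM", target_mz, tol_da)
}

#' Extract the base peak mobilogram (BPM)
#'
#' Per-bin intensity is the maximum centroid intensity in that bin across all
#' m/z, so the trace contains every adduct and aggregate species.
#'
#' @param frames A [frame_stack()].
#' @return A \code{mobilogram} of kind \code{"BPM"}.
#' @export
extract_bpm <- function(frames) {
  stopifnot(inherits(frames, "frame_stack"))
  intensity <- vapply(frames$spectra, function(s) {
    if (!nrow(s)) return(0)
    max(s$intensity)
  }, numeric(1))
  .new_mobilogram(frames$raw_axis, intensity, "BPM")
}

#' Savitzky-Golay smoothing of a mobilogram
#'
#' The window is specified as a mobility width and converted to the nearest
#' odd point count not below \code{window_mobility / bin-spacing} (minimum 5
#' points; a 0.005 V s/cm^2 window at 0.0005 spacing gives 11 points). The
#' trace is reflect-padded at the edges so interior peak areas are preserved.
#'
#' @param m A \code{mobilogram}.
#' @param window_mobility Smoothing window width in the axis units
#'   (default 0.005 V s/cm^2).
#' @param cycles Number of smoothing passes.
#' @param poly_order Polynomial order of the filter.
#' @return The smoothed \code{mobilogram}.
#' @export
smooth_mobilogram <- function(m, window_mobility = 0.005, cycles = 1L,
                              poly_order = 2L) {
  stopifnot(inherits(m, "mobilogram"), cycles >= 1)
  spacing <- mean(diff(m$axis))
  n <- ceiling(window_mobility / spacing)
  if (n %% 2 == 0) n <- n + 1
  if (n < 5) {
    stop(sprintf(
      "smoothing window of %.4g converts to %d points (< 5) at bin spacing %.4g",
      window_mobility, n, spacing), call. = FALSE)
  }
  y <- m$intensity
  half <- (n - 1) / 2
  for (i in seq_len(cycles)) {
    padded <- c(rev(y[2:(half + 1)]), y, rev(y[(length(y) - half):(length(y) - 1)]))
    sm <- signal::sgolayfilt(padded, p = poly_order, n = n)
    y <- sm[(half + 1):(half + length(y))]
  }
  out <- m
  out$intensity <- pmax(y, 0)
  out
}

# Sub-bin apex refinement by a parabola through the log-intensities of the
# apex bin and its neighbours. Exact for a noiseless Gaussian profile (whose
# log is quadratic); falls back to the bin centre at trace edges or when a
# bracketing intensity is nonpositive.
.refine_apex <- function(axis, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(axis[i])
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  if (y0 <= 0 || y1 <= 0 || y2 <= 0) return(axis[i])
  l0 <- log(y0); l1 <- log(y1); l2 <- log(y2)
  denom <- l0 - 2 * l1 + l2
  if (denom >= 0) return(axis[i])
  delta <- 0.5 * (l0 - l2) / denom
  if (abs(delta) > 1) return(axis[i])
  axis[i] + delta * (axis[i + 1L] - axis[i])
}

# Half-height width of the local maximum at index `apex` within [lo, hi],
# by linear interpolation of the 50% crossings.
.fwhm_at <- function(axis, y, apex, lo, hi) {
  half <- y[apex] / 2
  left <- NA_real_
  for (i in seq(apex, lo + 1L, by = -1L)) {
    if (y[i - 1L] <= half && y[i] > half) {
      f <- (half - y[i - 1L]) / (y[i] - y[i - 1L])
      left <- axis[i - 1L] + f * (axis[i] - axis[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (apex < hi) {
    for (i in seq(apex, hi - 1L)) {
      if (y[i + 1L] <= half && y[i] > half) {
        f <- (y[i] - half) / (y[i] - y[i + 1L])
        right <- axis[i] + f * (axis[i + 1L] - axis[i])
        break
      }
    }
  }
  # one-sided fallback for peaks truncated by the region boundary
  if (is.na(left) && is.na(right)) return(NA_real_)
  apex_x <- axis[apex]
  if (is.na(left)) left <- apex_x - (right - apex_x)
  if (is.na(right)) right <- apex_x + (apex_x - left)
  right - left
}

#' Pick mobility peaks
#'
#' Local maxima above the detection floor are found; the floor is
#' \code{(100 - sensitivity)\%} of the base-peak intensity (so sensitivity 97
#' detects down to 3\% of the maximum). Adjacent maxima are merged unless the
#' valley between them drops by at least \code{min_valley}\% of the lower
#' apex. Only peaks whose apex reaches \code{rel_intensity_threshold}\% of
#' the base peak are reported. The half-height width (FWHM) is measured by
#' linear interpolation and the 4-sigma base width derived from it assuming a
#' locally Gaussian shape (FWHM x 4 / 2.3548).
#'
#' @param m A \code{mobilogram} (smoothed or raw).
#' @param sensitivity Detection sensitivity in percent (default 97).
#' @param rel_intensity_threshold Minimum apex height as percent of the base
#'   peak (default 15).
#' @param min_valley Minimum valley depth between two peaks, as percent of
#'   the lower apex (default 10).
#' @param refine_apex Refine apex positions to sub-bin precision by a
#'   parabolic fit to the log-intensities around the apex bin — exact for a
#'   noiseless Gaussian peak (default TRUE).
#' @return A data frame of class \code{mobility_peaks} with one row per peak:
#'   \code{apex_idx}, \code{apex_pos} (axis units), \code{height},
#'   \code{fwhm}, \code{base_width} (axis units, 4-sigma), \code{area}.
#' @export
pick_peaks <- function(m, sensitivity = 97, rel_intensity_threshold = 15,
                       min_valley = 10, refine_apex = TRUE) {
  stopifnot(inherits(m, "mobilogram"),
            sensitivity > 0, sensitivity <= 100,
            rel_intensity_threshold > 0, rel_intensity_threshold <= 100,
            min_valley > 0, min_valley <= 100)
  y <- m$intensity
  axis <- m$axis
  empty <- structure(
    data.frame(apex_idx = integer(0), apex_pos = numeric(0),
               height = numeric(0), fwhm = numeric(0),
               base_width = numeric(0), area = numeric(0)),
    class = c("mobility_peaks", "data.frame"))
  base <- max(y)
  if (base <= 0) return(empty)
  floor_level <- (100 - sensitivity) / 100 * base

  n <- length(y)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    # plateau-tolerant local maximum: strictly above one neighbour, not below either
    is_max[i] <- y[i] > floor_level && y[i] >= l && y[i] >= r && (y[i] > l || y[i] > r)
  }
  apexes <- which(is_max)
  # collapse plateau runs to their centre
  if (length(apexes) > 1) {
    runs <- split(apexes, cumsum(c(1, diff(apexes) != 1)))
    apexes <- vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1))
  }
  if (!length(apexes)) return(empty)

  # valley-based merging: keep the higher apex of any pair whose separating
  # valley does not drop by >= min_valley% of the lower apex
  repeat {
    if (length(apexes) < 2) break
    merged <- FALSE
    for (j in seq_len(length(apexes) - 1L)) {
      a <- apexes[j]; b <- apexes[j + 1L]
      valley <- min(y[a:b])
      lower <- min(y[a], y[b])
      if (valley > (1 - min_valley / 100) * lower) {
        drop_idx <- if (y[a] >= y[b]) j + 1L else j
        apexes <- apexes[-drop_idx]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  keep <- y[apexes] >= rel_intensity_threshold / 100 * base
  apexes <- apexes[keep]
  if (!length(apexes)) return(empty)

  # region boundaries at the deepest valley between retained apexes
  bounds <- c(1L, vapply(seq_len(length(apexes) - 1L), function(j) {
    a <- apexes[j]; b <- apexes[j + 1L]
    a + which.min(y[a:b]) - 1L
  }, integer(1)), n)

  rows <- lapply(seq_along(apexes), function(j) {
    lo <- bounds[j]; hi <- bounds[j + 1L]
    apex <- apexes[j]
    fw <- .fwhm_at(axis, y, apex, lo, hi)
    seg <- lo:hi
    area <- sum(diff(axis[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    pos <- if (refine_apex) .refine_apex(axis, y, apex) else axis[apex]
    data.frame(apex_idx = apex, apex_pos = pos, height = y[apex],
               fwhm = fw, base_width = fw * 4 / 2.3548, area = area)
  })
  structure(do.call(rbind, rows),
            class = c("mobility_peaks", "data.frame"))
}

# mobility extent (lo, hi) of a peak at the 4-sigma base width
.peak_extent <- function(peak) {
  c(peak$apex_pos - peak$base_width / 2, peak$apex_pos + peak$base_width / 2)
}

#' Spectral purity of a mobility peak
#'
#' Fraction of the total centroid ion current within the peak's 4-sigma
#' mobility extent that falls within the m/z tolerance of the target species.
#' A pure peak (single ion species) has purity 1.
#'
#' @param frames The [frame_stack()] the peak was picked from.
#' @param peak One row of a [pick_peaks()] result.
#' @param target_mz Target species m/z.
#' @param tol Absolute m/z tolerance in Da.
#' @return Purity in [0, 1]. When the extent holds no ion current at all the
#'   value is 0 with attribute \code{degenerate = TRUE}.
#' @export
peak_purity <- function(frames, peak, target_mz, tol = 0.01) {
  stopifnot(inherits(frames, "frame_stack"))
  ext <- .peak_extent(peak)
  in_ext <- frames$raw_axis >= ext[1] & frames$raw_axis <= ext[2]
  total <- 0
  target <- 0
  for (s in frames$spectra[in_ext]) {
    if (!nrow(s)) next
    total <- total + sum(s$intensity)
    target <- target + sum(s$intensity[abs(s$mz - target_mz) <= tol])
  }
  if (total <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  target / total
}

#' Apex CCS of a picked mobility peak
#'
#' Converts a peak's apex position to CCS: raw apex -> calibrated 1/K0
#' (via [apply_calibration()], skipped when the frame axis is already
#' calibrated) -> CCS (via [ccs_from_inverse_k0()]). Widths are converted to
#' CCS units with the same affine/proportional maps.
#'
#' @param peak One row (or several rows) of a [pick_peaks()] result.
#' @param model A [fit_calibration()] result, or NULL when the peak's axis is
#'   already calibrated 1/K0.
#' @param mz Ion m/z used for the Mason-Schamp conversion.
#' @param ctx A [physics_context()].
#' @return The peak row(s) with added columns \code{apex_inv_k0},
#'   \code{apex_ccs}, \code{fwhm_ccs}, \code{base_width_ccs}.
#' @export
apex_ccs <- function(peak, model = NULL, mz, ctx = physics_context()) {
  if (is.null(model)) {
    inv_k0 <- peak$apex_pos
    slope <- 1
  } else {
    inv_k0 <- as.numeric(apply_calibration(model, peak$apex_pos))
    slope <- model$slope
  }
  k <- .ms_factor(mz, ctx)
  peak$apex_inv_k0 <- inv_k0
  peak$apex_ccs <- k * inv_k0
  peak$fwhm_ccs <- k * abs(slope) * peak$fwhm
  peak$base_width_ccs <- k * abs(slope) * peak$base_width
  peak
}

#' TIMS resolving power of a peak
#'
#' Single-peak resolving power R = apex CCS / FWHM(CCS), identical to the
#' value computed in mobility units. Survey-mode acquisition sits near R = 40
#' and narrow-range long-ramp acquisition above 100.
#'
#' @param peak Peak row(s) carrying \code{apex_ccs} and \code{fwhm_ccs}
#'   (see [apex_ccs()]), or a numeric apex value.
#' @param fwhm FWHM, required when \code{peak} is numeric.
#' @return Dimensionless resolving power.
#' @export
tims_resolving_power <- function(peak, fwhm = NULL) {
  if (is.numeric(peak)) {
    stopifnot(!is.null(fwhm), all(fwhm > 0))
    return(peak / fwhm)
  }
  stopifnot(all(peak$fwhm_ccs > 0))
  peak$apex_ccs / peak$fwhm_ccs
}
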