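# Negative-mode ion species m/z rules, theoretical isotope patterns, and
# m/z + pattern + purity based annotation of mobility peaks.

#' Theoretical m/z of a negative-mode ion species
#'
#' Deprotonation subtracts a proton (the electron stays with the ion). The
#' oxidised species \code{[M-3H]-} is modelled as loss of two hydrogen atoms
#' followed by deprotonation; \code{[2M-H]-} is the deprotonated dimer; the
#' adduct species add neutral formic acid or sodium formate to the
#' deprotonated ion. For rutin (M = 610.15338 Da) this places
#' \code{[M-H]-} at 609.146, \code{[M-3H]-} at 607.130 and
#' \code{[M-H+Na+HCO2]-} at 677.134.
#'
#' @param monoisotopic_mass Neutral monoisotopic mass M in Da (vectorised).
#' @param species One of [NEGATIVE_SPECIES].
#' @return m/z in Da/e.
#' @examples
#' species_mz(monoisotopic_mass("C27H30O16"), "[M-H]-")
#' @export
species_mz <- function(monoisotopic_mass, species) {
  stopifnot(all(monoisotopic_mass > 0))
  M <- monoisotopic_mass
  switch(species,
    "[M-H]-" = M - .PROTON_MASS,
    "[M-3H]-" = M - 2 * .MONO_MASS[["H"]] - .PROTON_MASS,
    "[2M-H]-" = 2 * M - .PROTON_MASS,
    "[M-H+HCO2H]-" = M - .PROTON_MASS + .FORMIC_ACID,
    "[M-H+Na+HCO2]-" = M - .PROTON_MASS + .SODIUM_FORMATE,
    stop("unknown ion species: ", species, call. = FALSE)
  )
}

#' Theoretical isotope pattern of a molecular formula
#'
#' Computes the isotopologue distribution by iterative convolution of the
#' per-element isotope distributions over nominal mass offsets (unit-mass
#' aggregation, appropriate at TOF resolution), truncates to the first
#' \code{n_isotopologues} bins and normalises the base (monoisotopic) peak to
#' 1. Supported elements: C, H, N, O, S, Na, P.
#'
#' @param formula Formula string or named element-count vector.
#' @param n_isotopologues Number of isotopologue bins to keep (default 4).
#' @return An object of class \code{isotope_pattern}: a data frame with
#'   columns \code{mass} (Da, strictly increasing) and
#'   \code{relative_intensity} (base = 1).
#' @examples
#' theoretical_isotope_pattern("C6H12O6")
#' @export
theoretical_isotope_pattern <- function(formula, n_isotopologues = 4L) {
  counts <- parse_formula(formula)
  stopifnot(n_isotopologues >= 1)
  dist <- 1  # probability over offsets 0, 1, 2, ...
  for (el in names(counts)) {
    per_atom <- .ISOTOPE_ABUNDANCE[[el]]
    el_dist <- 1
    for (k in seq_len(counts[[el]])) {
      el_dist <- .convolve_trunc(el_dist, per_atom, n_isotopologues)
    }
    dist <- .convolve_trunc(dist, el_dist, n_isotopologues)
  }
  if (length(dist) < n_isotopologues) {
    dist <- c(dist, rep(0, n_isotopologues - length(dist)))
  }
  rel <- dist / dist[1]
  keep <- rel > 0
  m0 <- sum(.MONO_MASS[names(counts)] * counts)
  masses <- m0 + (seq_len(n_isotopologues) - 1) * .ISOTOPOLOGUE_SPACING
  structure(
    data.frame(mass = masses[keep], relative_intensity = rel[keep]),
    class = c("isotope_pattern", "data.frame")
  )
}

.convolve_trunc <- function(a, b, n) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(la + lb - 1L, n))
  for (i in seq_len(la)) {
    jmax <- min(lb, n - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Isotope pattern from a list of (mass, intensity) peaks
#'
#' Normalises to the base peak and orders by mass, for use as an observed
#' pattern in [pattern_deviation()].
#'
#' @param mass Peak masses in Da.
#' @param intensity Peak intensities (any scale).
#' @return An \code{isotope_pattern}.
#' @export
isotope_pattern <- function(mass, intensity) {
  stopifnot(length(mass) == length(intensity), all(intensity > 0))
  o <- order(mass)
  structure(
    data.frame(mass = mass[o], relative_intensity = intensity[o] / intensity[o][1]),
    class = c("isotope_pattern", "data.frame")
  )
}

#' Isotope pattern deviation score
#'
#' Root-mean-square deviation of the base-normalised isotopologue intensities
#' over the first min(n) bins of the two patterns, scaled by 1000. Zero means
#' a perfect match; lower is better. Symmetric in its arguments.
#'
#' @param observed,theoretical \code{isotope_pattern} objects (base-normalised).
#' @return Nonnegative score.
#' @export
pattern_deviation <- function(observed, theoretical) {
  if (!nrow(observed) || !nrow(theoretical)) {
    stop("patterns must be nonempty", call. = FALSE)
  }
  n <- min(nrow(observed), nrow(theoretical))
  a <- observed$relative_intensity[seq_len(n)]
  b <- theoretical$relative_intensity[seq_len(n)]
  1000 * sqrt(mean((a - b)^2))
}

# observed isotopologue pattern of a species over a peak's mobility extent
.observed_pattern <- function(frames, peak, mz0, tol, n_iso = 4L) {
  ext <- .peak_extent(peak)
  in_ext <- frames$raw_axis >= ext[1] & frames$raw_axis <= ext[2]
  sums <- numeric(n_iso)
  for (s in frames$spectra[in_ext]) {
    if (!nrow(s)) next
    for (k in seq_len(n_iso)) {
      target <- mz0 + (k - 1) * .ISOTOPOLOGUE_SPACING
      sums[k] <- sums[k] + sum(s$intensity[abs(s$mz - target) <= tol])
    }
  }
  if (sums[1] <= 0) return(NULL)
  keep <- sums > 0
  isotope_pattern(mz0 + (which(keep) - 1) * .ISOTOPOLOGUE_SPACING, sums[keep])
}

#' Annotate mobility peaks with ion species
#'
#' For each supported negative-mode species of a compound, computes the
#' theoretical m/z and assigns it to a picked mobility peak when (a) the most
#' intense centroid in the peak's 4-sigma extent lies within the m/z
#' tolerance of the species, (b) the observed isotopologue pattern deviates
#' from the theoretical one by no more than \code{pattern_ceiling}, and
#' (c) among several candidate peaks for the same species the one with the
#' highest spectral purity wins (the apex height breaks remaining ties).
#' Peaks matching no species are labelled \code{"unknown"}. No species is
#' ever assigned to two peaks.
#'
#' @param peaks A [pick_peaks()] result.
#' @param frames The [frame_stack()] the peaks came from.
#' @param compound A [compound_record()].
#' @param tol Absolute m/z tolerance in Da (default 0.01).
#' @param pattern_ceiling Maximum allowed [pattern_deviation()] (default 50).
#' @return The peaks data frame with added columns \code{species},
#'   \code{species_mz}, \code{purity}, \code{pattern_score}.
#' @export
annotate_peaks <- function(peaks, frames, compound, tol = 0.01,
                           pattern_ceiling = 50) {
  stopifnot(inherits(frames, "frame_stack"),
            inherits(compound, "compound_record"))
  peaks$species <- rep("unknown", nrow(peaks))
  peaks$species_mz <- NA_real_
  peaks$purity <- NA_real_
  peaks$pattern_score <- NA_real_
  if (!nrow(peaks)) return(peaks)

  M <- compound$monoisotopic_mass
  assigned <- rep(FALSE, nrow(peaks))
  for (sp in NEGATIVE_SPECIES) {
    mz0 <- species_mz(M, sp)
    theo <- if (!is.null(compound$molecular_formula)) {
      f <- compound$molecular_formula
      f <- switch(sp,
        "[M-3H]-" = { f["H"] <- f["H"] - 2L; f },
        "[2M-H]-" = f * 2L,
        "[M-H+HCO2H]-" = .add_formula(f, c(C = 1L, H = 2L, O = 2L)),
        "[M-H+Na+HCO2]-" = .add_formula(f, c(C = 1L, H = 1L, O = 2L, Na = 1L)),
        f)
      f["H"] <- f["H"] - 1L  # deprotonation
      theoretical_isotope_pattern(f[f > 0])
    } else NULL

    cand <- integer(0)
    purity <- numeric(0)
    score <- numeric(0)
    for (i in seq_len(nrow(peaks))) {
      if (assigned[i]) next
      pk <- peaks[i, ]
      ext <- .peak_extent(pk)
      in_ext <- frames$raw_axis >= ext[1] & frames$raw_axis <= ext[2]
      cents <- do.call(rbind, frames$spectra[in_ext])
      if (is.null(cents) || !nrow(cents)) next
      base_mz <- cents$mz[which.max(cents$intensity)]
      if (abs(base_mz - mz0) > tol) next           # (a) dominance
      obs <- .observed_pattern(frames, pk, mz0, tol)
      if (is.null(obs)) next
      sc <- if (is.null(theo)) 0 else pattern_deviation(obs, theo)
      if (sc > pattern_ceiling) next               # (b) pattern agreement
      cand <- c(cand, i)
      purity <- c(purity, as.numeric(peak_purity(frames, pk, mz0, tol)))
      score <- c(score, sc)
    }
    if (!length(cand)) next
    best <- cand[order(-purity, -peaks$height[cand])][1]  # (c) highest purity
    peaks$species[best] <- sp
    peaks$species_mz[best] <- mz0
    peaks$purity[best] <- purity[match(best, cand)]
    peaks$pattern_score[best] <- score[match(best, cand)]
    assigned[best] <- TRUE
  }
  peaks
}

.add_formula <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out
}
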