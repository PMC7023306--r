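# Replicate aggregation into CCS library entries and percent-difference
# comparison of measurement sets / libraries.

#' Replicate measurement set
#'
#' CCS values for one (compound, ion species) pair under one calibration
#' reference, one value per analysis.
#'
#' @param compound A [compound_record()].
#' @param species Ion species label (see [NEGATIVE_SPECIES]).
#' @param ccs_values Positive CCS values in square Angstroms.
#' @param reference_table_id Calibration reference id the values were
#'   computed under.
#' @return An object of class \code{replicate_set}.
#' @export
replicate_set <- function(compound, species, ccs_values,
                          reference_table_id = "vendor_default") {
  stopifnot(inherits(compound, "compound_record"), length(ccs_values) >= 1)
  if (any(ccs_values <= 0)) stop("CCS values must be positive", call. = FALSE)
  if (!species %in% c(NEGATIVE_SPECIES, "unknown")) {
    stop("unknown ion species: ", species, call. = FALSE)
  }
  structure(list(compound = compound, species = species,
                 ccs_values = ccs_values,
                 reference_table_id = reference_table_id),
            class = "replicate_set")
}

#' Aggregate replicate CCS values
#'
#' Mean, sample standard deviation (n - 1 denominator) and RSD
#' (100 sd / mean) of a replicate set. A single value yields the mean with SD
#' and RSD flagged undefined (NA).
#'
#' @param x A [replicate_set()] or a numeric vector of positive values.
#' @return An [aggregate_stats()].
#' @examples
#' aggregate_replicates(c(231.0, 231.2, 231.4))  # sd 0.2, rsd 0.0865%
#' @export
aggregate_replicates <- function(x) {
  v <- if (inherits(x, "replicate_set")) x$ccs_values else x
  if (any(v <= 0)) stop("values must be positive", call. = FALSE)
  if (length(v) == 1L) return(aggregate_stats(v, NA_real_, 1L))
  aggregate_stats(mean(v), stats::sd(v), length(v))
}

#' Percent difference between two values
#'
#' \code{100 |a - b| / d}, with the denominator \code{d} being the first
#' value (the reference or library side, the default), the second value, or
#' their mean. Only the mean convention is symmetric under swapping the
#' arguments.
#'
#' @param a,b Positive values (vectorised).
#' @param denominator One of \code{"first"}, \code{"second"}, \code{"mean"}.
#' @return Percent difference(s), nonnegative.
#' @export
percent_difference <- function(a, b, denominator = c("first", "second", "mean")) {
  denominator <- match.arg(denominator)
  stopifnot(all(a > 0), all(b > 0))
  d <- switch(denominator, first = a, second = b, mean = (a + b) / 2)
  100 * abs(a - b) / d
}

#' Build a CCS library from replicate sets
#'
#' Groups replicate sets by (compound, species), aggregates each group's
#' values per calibration reference, and emits one [ccs_library_entry()] per
#' group. Deprotonated-molecule entries whose RSD exceeds \code{qc_rsd_max}
#' percent are QC-flagged: routine TIMS triplicates reproduce CCS to about
#' 0.1\% RSD, and values beyond about 0.35\% sit outside that regime.
#'
#' @param sets List of [replicate_set()] objects. Sets sharing (compound,
#'   species) but differing in reference id land in one entry with one
#'   [aggregate_stats()] per reference.
#' @param rt_map Optional named vector of retention times (minutes) keyed by
#'   compound name.
#' @param metadata An [instrument_metadata()] attached to each entry.
#' @param qc_rsd_max QC threshold on the \code{[M-H]-} RSD in percent
#'   (default 0.35).
#' @return List of [ccs_library_entry()] objects.
#' @export
build_library <- function(sets, rt_map = NULL,
                          metadata = instrument_metadata(),
                          qc_rsd_max = 0.35) {
  stopifnot(all(vapply(sets, inherits, logical(1), "replicate_set")))
  key <- vapply(sets, function(s) paste(s$compound$name, s$species, sep = "\r"),
                character(1))
  lapply(unique(key), function(k) {
    group <- sets[key == k]
    first <- group[[1]]
    masses <- vapply(group, function(s) s$compound$monoisotopic_mass, numeric(1))
    if (max(masses) - min(masses) > 1e-9) {
      stop("conflicting compound metadata for ", first$compound$name,
           call. = FALSE)
    }
    by_ref <- lapply(group, aggregate_replicates)
    names(by_ref) <- vapply(group, function(s) s$reference_table_id, character(1))
    if (anyDuplicated(names(by_ref))) {
      stop("duplicate reference table for ", first$compound$name, " ",
           first$species, call. = FALSE)
    }
    rt <- if (!is.null(rt_map) && first$compound$name %in% names(rt_map)) {
      rt_map[[first$compound$name]]
    } else first$compound$retention_time
    rsds <- vapply(by_ref, function(st) st$rsd_percent, numeric(1))
    qc <- first$species == "[M-H]-" && any(!is.na(rsds) & rsds > qc_rsd_max)
    ccs_library_entry(
      first$compound,
      ion_species_annotation(first$species,
                             species_mz(first$compound$monoisotopic_mass,
                                        first$species)),
      by_ref,
      retention_time = if (is.null(rt)) NA_real_ else rt,
      n_replicates = max(vapply(by_ref, function(st) st$n, integer(1))),
      qc_flag = qc
    )
  })
}

#' Compare two measurement sets by percent difference
#'
#' Joins two sets of (identifier, CCS) measurements on their identifier and
#' reports the per-item percent difference plus its mean/SD summary; this is
#' the computation behind matrix-effect and cross-library comparisons.
#'
#' @param a,b Data frames with an identifier column and a \code{ccs} column,
#'   or named numeric vectors of CCS keyed by identifier. Side \code{a} is
#'   the reference side for the \code{"first"} denominator convention.
#' @param join_on Identifier column name when data frames are supplied
#'   (default \code{"compound"}).
#' @param denominator Passed to [percent_difference()].
#' @return An object of class \code{comparison_report}: list with
#'   \code{per_item} (data frame: identifier, value_a, value_b,
#'   percent_difference), \code{summary} ([aggregate_stats()] of the percent
#'   differences) and \code{unmatched} (identifiers present on one side only).
#' @export
compare_measurement_sets <- function(a, b, join_on = "compound",
                                     denominator = "first") {
  as_named <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) return(x)
    stopifnot(is.data.frame(x), join_on %in% names(x), "ccs" %in% names(x))
    stats::setNames(x$ccs, x[[join_on]])
  }
  va <- as_named(a); vb <- as_named(b)
  if (anyDuplicated(names(va)) || anyDuplicated(names(vb))) {
    stop("join keys must be unique on each side", call. = FALSE)
  }
  common <- intersect(names(va), names(vb))
  if (!length(common)) stop("no common identifiers to compare", call. = FALSE)
  pd <- percent_difference(unname(va[common]), unname(vb[common]),
                           denominator = denominator)
  structure(
    list(per_item = data.frame(identifier = common,
                               value_a = unname(va[common]),
                               value_b = unname(vb[common]),
                               percent_difference = pd,
                               stringsAsFactors = FALSE),
         summary = aggregate_stats(mean(pd),
                                   if (length(pd) > 1) stats::sd(pd) else NA_real_,
                                   length(pd)),
         unmatched = c(setdiff(names(va), common), setdiff(names(vb), common))),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d matched item(s)\n", nrow(x$per_item)))
  print(x$per_item, row.names = FALSE)
  cat(sprintf("mean %% difference %.5f%%", x$summary$mean))
  if (!is.na(x$summary$sd)) cat(sprintf(" (sd %.5f)", x$summary$sd))
  cat("\n")
  if (length(x$unmatched)) {
    cat("unmatched:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
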