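# Domain types shared across the package and the flat-file CCS library
# format: a greppable TSV with a '#key=value' metadata header.

#' Negative-mode ion species supported by the library
#'
#' The deprotonated molecule, its dimer, the oxidised deprotonated ion, the
#' formic acid adduct and the sodium formate adduct, in ASCII notation.
#'
#' @format Character vector of species labels.
#' @export
NEGATIVE_SPECIES <- c("[M-H]-", "[2M-H]-", "[M-3H]-",
                      "[M-H+HCO2H]-", "[M-H+Na+HCO2]-")

#' Compound record
#'
#' @param name Compound name.
#' @param molecular_formula Formula string or named element-count vector;
#'   optional if \code{monoisotopic_mass} is given.
#' @param monoisotopic_mass Monoisotopic mass in Da; computed from the
#'   formula when omitted. When both are supplied they must agree within
#'   0.001 Da.
#' @param compound_class Free-text class tag (e.g. "flavone", "flavanone").
#' @param retention_time Retention time in minutes (optional).
#' @return An object of class \code{compound_record}.
#' @examples
#' compound_record("rutin", "C27H30O16", compound_class = "flavonol glycoside")
#' @export
compound_record <- function(name, molecular_formula = NULL,
                            monoisotopic_mass = NULL,
                            compound_class = NA_character_,
                            retention_time = NA_real_) {
  stopifnot(is.character(name), nzchar(name))
  counts <- if (!is.null(molecular_formula)) parse_formula(molecular_formula)
  if (is.null(monoisotopic_mass)) {
    if (is.null(counts)) stop("need molecular_formula or monoisotopic_mass",
                              call. = FALSE)
    monoisotopic_mass <- sum(.MONO_MASS[names(counts)] * counts)
  } else if (!is.null(counts)) {
    from_formula <- sum(.MONO_MASS[names(counts)] * counts)
    if (abs(from_formula - monoisotopic_mass) > 0.001) {
      stop(sprintf(
        "monoisotopic_mass %.5f disagrees with formula mass %.5f (> 0.001 Da)",
        monoisotopic_mass, from_formula), call. = FALSE)
    }
  }
  if (monoisotopic_mass <= 0) stop("monoisotopic_mass must be positive",
                                   call. = FALSE)
  structure(
    list(name = name, molecular_formula = counts,
         monoisotopic_mass = monoisotopic_mass,
         compound_class = compound_class,
         retention_time = retention_time),
    class = "compound_record"
  )
}

#' @export
print.compound_record <- function(x, ...) {
  f <- if (is.null(x$molecular_formula)) "" else
    paste0(" (", paste0(names(x$molecular_formula), x$molecular_formula,
                        collapse = ""), ")")
  cat(sprintf("%s%s, M = %.5f Da\n", x$name, f, x$monoisotopic_mass))
  invisible(x)
}

#' Ion species annotation
#'
#' @param species One of [NEGATIVE_SPECIES] or \code{"unknown"}.
#' @param mz Observed or theoretical m/z of the species.
#' @param charge Signed charge; -1 for all shipped negative-mode species.
#' @param purity Fraction of ion current in the peak's mobility extent
#'   attributable to this species, in [0, 1] (optional).
#' @return An object of class \code{ion_species_annotation}.
#' @export
ion_species_annotation <- function(species, mz, charge = -1L, purity = NA_real_) {
  if (!species %in% c(NEGATIVE_SPECIES, "unknown")) {
    stop("unknown ion species: ", species, call. = FALSE)
  }
  if (charge == 0) stop("charge must be nonzero", call. = FALSE)
  if (!is.na(purity) && (purity < 0 || purity > 1)) {
    stop("purity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(species = species, charge = as.integer(charge),
                 mz = mz, purity = purity),
            class = "ion_species_annotation")
}

#' Instrument metadata
#'
#' Records the user-controllable TIMS acquisition parameters recommended for
#' ion-mobility CCS reporting, so a library file is self-describing.
#'
#' @param drift_gas_composition Named fractions summing to 1 (default
#'   membrane-generated gas: 99.4\% N2, 0.6\% O2).
#' @param gas_temperature Gas temperature in K.
#' @param tunnel_in_pressure,tunnel_out_pressure TIMS tunnel pressures in mbar.
#' @param mobility_range 1/K0 acquisition range (min, max) in V s/cm^2.
#' @param ramp_time TIMS ramp time in ms.
#' @param icc_target Ion charge control target (ion count).
#' @param polarity \code{"negative"} or \code{"positive"}.
#' @return An object of class \code{instrument_metadata}.
#' @export
instrument_metadata <- function(drift_gas_composition = c(N2 = 0.994, O2 = 0.006),
                                gas_temperature = 305,
                                tunnel_in_pressure = 2.50,
                                tunnel_out_pressure = 0.74,
                                mobility_range = c(0.4, 1.8),
                                ramp_time = 90,
                                icc_target = 5e6,
                                polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (abs(sum(drift_gas_composition) - 1) > 1e-6) {
    stop("drift gas composition fractions must sum to 1", call. = FALSE)
  }
  if (mobility_range[1] >= mobility_range[2]) {
    stop("mobility_range min must be below max", call. = FALSE)
  }
  structure(
    list(drift_gas_composition = drift_gas_composition,
         gas_temperature = gas_temperature,
         tunnel_in_pressure = tunnel_in_pressure,
         tunnel_out_pressure = tunnel_out_pressure,
         mobility_range = mobility_range,
         ramp_time = ramp_time,
         icc_target = icc_target,
         polarity = polarity),
    class = "instrument_metadata"
  )
}

#' Aggregate replicate statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative standard
#' deviation of a replicate set. With a single replicate the SD and RSD are
#' undefined and stored as NA.
#'
#' @param mean Mean value.
#' @param sd Sample standard deviation (NA when n = 1).
#' @param n Number of replicates.
#' @return An object of class \code{aggregate_stats} with fields
#'   \code{mean}, \code{sd}, \code{rsd_percent}, \code{n}.
#' @seealso [aggregate_replicates()] to compute these from raw values.
#' @export
aggregate_stats <- function(mean, sd = NA_real_, n = 1L) {
  stopifnot(n >= 1)
  if (!is.na(sd) && sd < 0) stop("sd must be nonnegative", call. = FALSE)
  rsd <- if (is.na(sd) || mean == 0) NA_real_ else 100 * sd / mean
  structure(list(mean = mean, sd = sd, rsd_percent = rsd, n = as.integer(n)),
            class = "aggregate_stats")
}

#' CCS library entry
#'
#' One compound/ion-species pair with its aggregated CCS under one or more
#' calibration references.
#'
#' @param compound A [compound_record()].
#' @param species An [ion_species_annotation()].
#' @param ccs_by_reference Named list (by calibration-reference table id) of
#'   [aggregate_stats()], all with positive means.
#' @param retention_time Retention time in minutes (optional).
#' @param n_replicates Number of replicate analyses behind the entry.
#' @param qc_flag Logical; TRUE when the entry failed a reproducibility check.
#' @return An object of class \code{ccs_library_entry}.
#' @export
ccs_library_entry <- function(compound, species, ccs_by_reference,
                              retention_time = NA_real_, n_replicates = 1L,
                              qc_flag = FALSE) {
  stopifnot(inherits(compound, "compound_record"),
            inherits(species, "ion_species_annotation"),
            is.list(ccs_by_reference), length(ccs_by_reference) >= 1,
            !is.null(names(ccs_by_reference)))
  for (id in names(ccs_by_reference)) {
    st <- ccs_by_reference[[id]]
    if (!inherits(st, "aggregate_stats")) {
      stop("ccs_by_reference entries must be aggregate_stats", call. = FALSE)
    }
    if (!is.finite(st$mean) || st$mean <= 0) {
      stop("ccs mean must be positive (reference ", id, ")", call. = FALSE)
    }
    if (st$n < 1) stop("n_replicates must be >= 1", call. = FALSE)
  }
  structure(
    list(compound = compound, species = species,
         ccs_by_reference = ccs_by_reference,
         retention_time = retention_time,
         n_replicates = as.integer(n_replicates),
         qc_flag = isTRUE(qc_flag)),
    class = "ccs_library_entry"
  )
}

.LIB_COLUMNS <- c("compound", "formula", "monoisotopic_mass", "compound_class",
                  "rt_min", "species", "charge", "mz", "reference_table",
                  "ccs_mean", "ccs_sd", "ccs_rsd_percent", "n_replicates",
                  "qc_flag")

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.12f", x))

.formula_string <- function(counts) {
  if (is.null(counts)) return("")
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Write a CCS library to a TSV file
#'
#' Emits '#key=value' metadata header lines (drift gas composition,
#' temperature, pressures, ramp time, mobility range, calibration reference
#' ids) followed by a tab-separated table with one row per
#' (compound, species, reference-table) combination. Numeric values are
#' serialised with 12 decimal places so write -> read round trips reproduce
#' every field within 1e-9.
#'
#' @param entries List of [ccs_library_entry()] objects.
#' @param metadata An [instrument_metadata()].
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
write_library <- function(entries, metadata, file) {
  stopifnot(inherits(metadata, "instrument_metadata"))
  report <- validate_library(entries)
  if (nrow(report)) {
    bad <- report[report$severity == "error", , drop = FALSE]
    if (nrow(bad)) {
      stop("invalid library entry ", bad$entry[1], ": ", bad$field[1], " — ",
           bad$message[1], call. = FALSE)
    }
  }
  ref_ids <- unique(unlist(lapply(entries, function(e) names(e$ccs_by_reference))))
  gas <- paste(sprintf("%s:%.4f", names(metadata$drift_gas_composition),
                       metadata$drift_gas_composition), collapse = ",")
  header <- c(
    sprintf("#drift_gas_composition=%s", gas),
    sprintf("#gas_temperature_K=%.2f", metadata$gas_temperature),
    sprintf("#tunnel_in_pressure_mbar=%.2f", metadata$tunnel_in_pressure),
    sprintf("#tunnel_out_pressure_mbar=%.2f", metadata$tunnel_out_pressure),
    sprintf("#mobility_range=%.4f,%.4f", metadata$mobility_range[1],
            metadata$mobility_range[2]),
    sprintf("#ramp_time_ms=%.1f", metadata$ramp_time),
    sprintf("#icc_target=%g", metadata$icc_target),
    sprintf("#polarity=%s", metadata$polarity),
    sprintf("#calibration_references=%s", paste(ref_ids, collapse = ","))
  )
  rows <- character(0)
  for (e in entries) {
    for (id in names(e$ccs_by_reference)) {
      st <- e$ccs_by_reference[[id]]
      rows <- c(rows, paste(
        e$compound$name,
        .formula_string(e$compound$molecular_formula),
        .fmt_num(e$compound$monoisotopic_mass),
        ifelse(is.na(e$compound$compound_class), "NA", e$compound$compound_class),
        .fmt_num(e$retention_time),
        e$species$species,
        e$species$charge,
        .fmt_num(e$species$mz),
        id,
        .fmt_num(st$mean),
        .fmt_num(st$sd),
        .fmt_num(st$rsd_percent),
        st$n,
        ifelse(e$qc_flag, "TRUE", "FALSE"),
        sep = "\t"))
    }
  }
  writeLines(c(header, paste(.LIB_COLUMNS, collapse = "\t"), rows), file)
  invisible(file)
}

.parse_num <- function(x, what, row) {
  out <- suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  bad <- which(!is.na(x) & x != "NA" & is.na(out))
  if (length(bad)) {
    stop(sprintf("malformed numeric in column '%s', data row %d: '%s'",
                 what, row[bad[1]], x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read a CCS library TSV file
#'
#' Parses a file in the format produced by [write_library()]. Unknown
#' '#key=value' header keys are preserved as free-form annotations.
#'
#' @param file Path to a library TSV.
#' @return A list with elements \code{entries} (list of
#'   [ccs_library_entry()]), \code{metadata} ([instrument_metadata()]) and
#'   \code{annotations} (named character vector of unrecognised header keys).
#' @export
read_library <- function(file) {
  lines <- readLines(file)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys

  known <- c("drift_gas_composition", "gas_temperature_K",
             "tunnel_in_pressure_mbar", "tunnel_out_pressure_mbar",
             "mobility_range", "ramp_time_ms", "icc_target", "polarity",
             "calibration_references")
  gas <- if ("drift_gas_composition" %in% keys) {
    parts <- strsplit(strsplit(vals[["drift_gas_composition"]], ",")[[1]], ":")
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1))
  } else c(N2 = 0.994, O2 = 0.006)
  mr <- if ("mobility_range" %in% keys) {
    as.numeric(strsplit(vals[["mobility_range"]], ",")[[1]])
  } else c(0.4, 1.8)
  getv <- function(k, default) if (k %in% keys) vals[[k]] else default
  metadata <- instrument_metadata(
    drift_gas_composition = gas,
    gas_temperature = as.numeric(getv("gas_temperature_K", "305")),
    tunnel_in_pressure = as.numeric(getv("tunnel_in_pressure_mbar", "2.5")),
    tunnel_out_pressure = as.numeric(getv("tunnel_out_pressure_mbar", "0.74")),
    mobility_range = mr,
    ramp_time = as.numeric(getv("ramp_time_ms", "90")),
    icc_target = as.numeric(getv("icc_target", "5e6")),
    polarity = getv("polarity", "negative")
  )
  annotations <- vals[setdiff(keys, known)]

  if (!length(body) || all(!nzchar(body))) {
    return(list(entries = list(), metadata = metadata,
                annotations = annotations))
  }
  cols <- strsplit(body[1], "\t")[[1]]
  miss <- setdiff(.LIB_COLUMNS, cols)
  if (length(miss)) {
    stop("library file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) {
    return(list(entries = list(), metadata = metadata,
                annotations = annotations))
  }
  cells <- strsplit(data_lines, "\t")
  d <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(d) <- cols
  rowidx <- seq_len(nrow(d))
  d$monoisotopic_mass <- .parse_num(d$monoisotopic_mass, "monoisotopic_mass", rowidx)
  d$rt_min <- .parse_num(d$rt_min, "rt_min", rowidx)
  d$charge <- as.integer(.parse_num(d$charge, "charge", rowidx))
  d$mz <- .parse_num(d$mz, "mz", rowidx)
  d$ccs_mean <- .parse_num(d$ccs_mean, "ccs_mean", rowidx)
  d$ccs_sd <- .parse_num(d$ccs_sd, "ccs_sd", rowidx)
  d$ccs_rsd_percent <- .parse_num(d$ccs_rsd_percent, "ccs_rsd_percent", rowidx)
  d$n_replicates <- as.integer(.parse_num(d$n_replicates, "n_replicates", rowidx))

  key <- paste(d$compound, d$species, sep = "\r")
  entries <- lapply(unique(key), function(k) {
    rows <- d[key == k, , drop = FALSE]
    r1 <- rows[1, ]
    comp <- compound_record(
      r1$compound,
      molecular_formula = if (nzchar(r1$formula)) r1$formula else NULL,
      monoisotopic_mass = r1$monoisotopic_mass,
      compound_class = if (r1$compound_class == "NA") NA_character_
                       else r1$compound_class,
      retention_time = r1$rt_min
    )
    sp <- ion_species_annotation(r1$species, r1$mz, r1$charge)
    by_ref <- lapply(seq_len(nrow(rows)), function(i) {
      # enforce rsd = 100*sd/mean on read
      aggregate_stats(rows$ccs_mean[i], rows$ccs_sd[i], rows$n_replicates[i])
    })
    names(by_ref) <- rows$reference_table
    ccs_library_entry(comp, sp, by_ref, retention_time = r1$rt_min,
                      n_replicates = r1$n_replicates,
                      qc_flag = identical(r1$qc_flag, "TRUE"))
  })
  list(entries = entries, metadata = metadata, annotations = annotations)
}

#' Validate a set of CCS library entries
#'
#' Report-only check of entry invariants: positive CCS means, nonnegative
#' SDs, RSD consistency (rsd = 100 sd / mean within 1e-9 relative), replicate
#' counts, and duplicate (compound, species, reference) rows.
#'
#' @param entries List of [ccs_library_entry()] objects.
#' @return A data frame with columns \code{entry}, \code{field},
#'   \code{severity} ("error" or "warning") and \code{message}; zero rows iff
#'   every invariant holds.
#' @export
validate_library <- function(entries) {
  out <- list()
  add <- function(entry, field, severity, message) {
    out[[length(out) + 1L]] <<- data.frame(
      entry = entry, field = field, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  keys <- character(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    label <- paste0(e$compound$name, " ", e$species$species)
    if (e$compound$monoisotopic_mass <= 0) {
      add(label, "monoisotopic_mass", "error", "must be positive")
    }
    for (id in names(e$ccs_by_reference)) {
      st <- e$ccs_by_reference[[id]]
      if (!is.finite(st$mean) || st$mean <= 0) {
        add(label, "ccs_mean", "error",
            paste0("nonpositive CCS mean under reference ", id))
      }
      if (!is.na(st$sd) && st$sd < 0) {
        add(label, "ccs_sd", "error", "negative SD")
      }
      if (!is.na(st$sd) && !is.na(st$rsd_percent) && st$mean > 0) {
        expect <- 100 * st$sd / st$mean
        denom <- max(abs(expect), 1)
        if (abs(st$rsd_percent - expect) / denom > 1e-9) {
          add(label, "ccs_rsd_percent", "error",
              sprintf("rsd %.6f%% inconsistent with 100*sd/mean = %.6f%%",
                      st$rsd_percent, expect))
        }
      }
      if (st$n < 1) add(label, "n_replicates", "error", "must be >= 1")
      k <- paste(e$compound$name, e$species$species, id, sep = "\r")
      if (k %in% keys) {
        add(label, "duplicate", "warning",
            paste0("duplicate (compound, species, reference) row under ", id))
      }
      keys <- c(keys, k)
    }
  }
  if (!length(out)) {
    return(data.frame(entry = character(0), field = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
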