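# Mason-Schamp mobility <-> CCS conversion and linear TIMS calibration.

# SI constants
.ELEMENTARY_CHARGE <- 1.602176634e-19   # C
.BOLTZMANN <- 1.380649e-23              # J/K
.LOSCHMIDT <- 2.6867801e25              # m^-3, gas number density at 273.15 K, 101325 Pa
.AMU_KG <- 1.66053906660e-27            # kg per Da

#' Mobility physics context
#'
#' Bundles the physical parameters entering the Mason-Schamp relation:
#' drift-gas molar mass, effective gas temperature and ion charge number.
#' Reference CCS values for TIMS are defined for nitrogen drift gas, so the
#' default molar mass is that of N2; the trace oxygen present in
#' membrane-generated drying gas is recorded in instrument metadata but does
#' not enter the reduced mass.
#'
#' @param drift_gas_molar_mass Drift gas molar mass in Da (default 28.0134, N2).
#' @param temperature Effective gas temperature in K (default 305).
#' @param charge_number Absolute ion charge number, a positive integer.
#' @return An object of class \code{physics_context}.
#' @examples
#' ctx <- physics_context()
#' ccs_from_inverse_k0(1.10, 609.14611, ctx)
#' @export
physics_context <- function(drift_gas_molar_mass = 28.0134,
                            temperature = 305,
                            charge_number = 1L) {
  stopifnot(drift_gas_molar_mass > 0, temperature > 0, charge_number >= 1)
  structure(
    list(drift_gas_molar_mass = drift_gas_molar_mass,
         temperature = temperature,
         charge_number = as.integer(charge_number)),
    class = "physics_context"
  )
}

# Proportionality constant between CCS (A^2) and 1/K0 (V s/cm^2) at fixed
# m/z, z and context: Omega = .ms_factor(mz, ctx) * inv_k0.
.ms_factor <- function(mz, ctx) {
  z <- ctx$charge_number
  m_ion <- mz * z                           # Da
  mu <- m_ion * ctx$drift_gas_molar_mass /
    (m_ion + ctx$drift_gas_molar_mass) * .AMU_KG  # kg
  # inv_k0 given in V s/cm^2 -> V s/m^2 is *1e4; result m^2 -> A^2 is *1e20
  (3 * z * .ELEMENTARY_CHARGE) / (16 * .LOSCHMIDT) *
    sqrt(2 * pi / (mu * .BOLTZMANN * ctx$temperature)) * 1e4 * 1e20
}

#' Convert inverse reduced mobility to collision cross section
#'
#' Applies the Mason-Schamp relation
#' \deqn{\Omega = \frac{3 z e}{16 N_0} \sqrt{\frac{2\pi}{\mu k_B T}} \frac{1}{K_0}}
#' with \eqn{\mu} the reduced mass of the ion (from m/z and charge) and the
#' drift gas. At fixed m/z, charge and context, CCS is strictly proportional
#' to 1/K0.
#'
#' @param inv_k0 Inverse reduced mobility in V s/cm^2 (vectorised).
#' @param mz Ion m/z in Da/e.
#' @param ctx A [physics_context()].
#' @return CCS in square Angstroms.
#' @seealso [inverse_k0_from_ccs()] for the exact algebraic inverse.
#' @export
ccs_from_inverse_k0 <- function(inv_k0, mz, ctx = physics_context()) {
  if (any(inv_k0 <= 0) || any(mz <= 0)) {
    stop("inv_k0 and mz must be positive", call. = FALSE)
  }
  .ms_factor(mz, ctx) * inv_k0
}

#' Convert collision cross section to inverse reduced mobility
#'
#' Exact algebraic inverse of [ccs_from_inverse_k0()].
#'
#' @param ccs CCS in square Angstroms (vectorised).
#' @inheritParams ccs_from_inverse_k0
#' @return Inverse reduced mobility in V s/cm^2.
#' @export
inverse_k0_from_ccs <- function(ccs, mz, ctx = physics_context()) {
  if (any(ccs <= 0) || any(mz <= 0)) {
    stop("ccs and mz must be positive", call. = FALSE)
  }
  ccs / .ms_factor(mz, ctx)
}

#' Reference calibrant table
#'
#' A table of tune-mix calibrant ions (m/z, charge, reference CCS) under a
#' named calibration reference, e.g. the vendor default list or the more
#' recent community consensus list. At least three rows are required for the
#' table to be usable in a linear TIMS calibration fit.
#'
#' @param table_id Identifier for the calibration reference list.
#' @param mz Calibrant m/z values.
#' @param charge Signed charges (defaults to -1 for negative mode).
#' @param reference_ccs Reference CCS values in square Angstroms.
#' @return A data frame of class \code{reference_calibrant_table}.
#' @export
reference_calibrant_table <- function(table_id, mz, reference_ccs,
                                      charge = rep(-1L, length(mz))) {
  stopifnot(length(mz) == length(reference_ccs),
            length(mz) == length(charge))
  if (any(reference_ccs <= 0)) stop("reference_ccs must be positive", call. = FALSE)
  structure(
    data.frame(mz = mz, charge = as.integer(charge),
               reference_ccs = reference_ccs),
    table_id = as.character(table_id),
    class = c("reference_calibrant_table", "data.frame")
  )
}

#' Read a reference calibrant table from TSV
#'
#' Expects columns \code{table_id}, \code{mz}, \code{charge},
#' \code{reference_ccs}.
#'
#' @param file Path to a TSV file.
#' @return A [reference_calibrant_table()].
#' @export
read_calibrant_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("table_id", "mz", "charge", "reference_ccs")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  reference_calibrant_table(d$table_id[1], d$mz, d$reference_ccs, d$charge)
}

#' Fit a linear TIMS calibration
#'
#' Ordinary least squares fit of reference inverse reduced mobility (derived
#' from the calibrants' reference CCS through the Mason-Schamp relation)
#' against raw instrument mobility readings, paired by index. At least three
#' calibration points are required. The fitted model maps raw readings to
#' 1/K0 by a single affine evaluation, so analyte values are interpolated
#' between calibrants.
#'
#' @param measured_raw Raw instrument mobility readings, one per calibrant row.
#' @param table A [reference_calibrant_table()].
#' @param ctx A [physics_context()].
#' @return An object of class \code{tims_calibration} with elements
#'   \code{slope}, \code{intercept}, \code{n_points}, \code{residuals},
#'   \code{max_abs_residual}, \code{reference_table_id} and the calibrant
#'   \code{raw_span} used to flag extrapolation.
#' @export
fit_calibration <- function(measured_raw, table, ctx = physics_context()) {
  stopifnot(inherits(table, "reference_calibrant_table"))
  if (length(measured_raw) != nrow(table)) {
    stop("measured_raw must pair 1:1 with calibrant table rows", call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("calibration requires at least 3 calibrant points", call. = FALSE)
  }
  if (stats::var(measured_raw) <= .Machine$double.eps) {
    stop("singular calibration fit: no variance in raw readings", call. = FALSE)
  }
  ref_ctx <- physics_context(ctx$drift_gas_molar_mass, ctx$temperature, 1L)
  ref_inv_k0 <- vapply(seq_len(nrow(table)), function(i) {
    ctx_i <- physics_context(ctx$drift_gas_molar_mass, ctx$temperature,
                             abs(table$charge[i]))
    inverse_k0_from_ccs(table$reference_ccs[i], table$mz[i], ctx_i)
  }, numeric(1))
  fit <- stats::lm(ref_inv_k0 ~ measured_raw)
  res <- stats::residuals(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n_points = length(measured_raw),
         residuals = unname(res),
         max_abs_residual = max(abs(res)),
         reference_table_id = attr(table, "table_id"),
         raw_span = range(measured_raw),
         ref_inv_k0 = ref_inv_k0),
    class = "tims_calibration"
  )
}

#' @export
print.tims_calibration <- function(x, ...) {
  cat("Linear TIMS calibration (", x$reference_table_id, ")\n", sep = "")
  cat(sprintf("  1/K0 = %.8f * raw + %.8f\n", x$slope, x$intercept))
  cat(sprintf("  %d calibrants, max |residual| %.3e V s/cm^2\n",
              x$n_points, x$max_abs_residual))
  invisible(x)
}

#' Apply a TIMS calibration to raw mobility readings
#'
#' Evaluates \code{inv_k0 = slope * raw + intercept}. Readings outside the
#' span of the calibrants used in the fit are still converted but flagged as
#' extrapolated in the \code{"extrapolated"} attribute of the result.
#'
#' @param model A [fit_calibration()] result.
#' @param raw Raw mobility readings (vectorised).
#' @return Numeric vector of 1/K0 values with a logical attribute
#'   \code{"extrapolated"}.
#' @export
apply_calibration <- function(model, raw) {
  stopifnot(inherits(model, "tims_calibration"))
  out <- model$slope * raw + model$intercept
  attr(out, "extrapolated") <- raw < model$raw_span[1] | raw > model$raw_span[2]
  out
}

#' CCS of one raw reading under two calibration references
#'
#' Fits independent linear calibrations against two reference calibrant
#' tables (sharing the same raw calibrant readings) and reports the CCS of
#' the analyte reading under each, keyed by table id. Libraries built this
#' way carry CCS under both the vendor default and the community consensus
#' reference, which differ slightly.
#'
#' @param raw Raw mobility reading(s) of the analyte.
#' @param mz Analyte m/z.
#' @param calibrant_raw Raw readings of the calibrant ions, paired by index
#'   with the rows of each table.
#' @param tables List of two [reference_calibrant_table()] objects.
#' @param ctx A [physics_context()].
#' @return Named list (by table id) of CCS values.
#' @export
dual_reference_ccs <- function(raw, mz, calibrant_raw, tables,
                               ctx = physics_context()) {
  stopifnot(length(tables) == 2L)
  out <- lapply(tables, function(tab) {
    model <- fit_calibration(calibrant_raw, tab, ctx)
    inv_k0 <- apply_calibration(model, raw)
    ccs_from_inverse_k0(as.numeric(inv_k0), mz, ctx)
  })
  names(out) <- vapply(tables, attr, character(1), "table_id")
  out
}
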