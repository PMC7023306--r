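# Atomic masses (CODATA/IUPAC monoisotopic values) and isotope abundances.
# Proton mass is the physical proton (electron retained on deprotonation),
# which is what places deprotonated rutin at nominal m/z 609.

.MONO_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  P  = 30.97376151,
  S  = 31.97207069
)

.PROTON_MASS <- 1.00727646688

# Mass difference between successive isotopologue bins (13C - 12C).
.ISOTOPOLOGUE_SPACING <- 1.0033548378

# neutral mass deltas built from the monoisotopic atom masses
.FORMIC_ACID <- 2 * .MONO_MASS[["H"]] + .MONO_MASS[["C"]] + 2 * .MONO_MASS[["O"]]
.SODIUM_FORMATE <- .MONO_MASS[["H"]] + .MONO_MASS[["C"]] + 2 * .MONO_MASS[["O"]] +
  .MONO_MASS[["Na"]]

# Per-element isotope distributions as probabilities over nominal mass
# offsets 0, 1, 2, ... relative to the lightest isotope.
.ISOTOPE_ABUNDANCE <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Na = 1,
  P  = 1,
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Parse a molecular formula
#'
#' Converts a Hill-style formula string such as \code{"C27H30O16"} into a
#' named integer vector of element counts. Already-parsed named vectors are
#' returned unchanged (after validation).
#'
#' @param formula Formula string, or a named numeric vector of element counts.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C27H30O16")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(formula)) {
      stop("cannot parse formula: ", formula, call. = FALSE)
    }
    elem <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
    names(counts) <- elem
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.MONO_MASS))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  counts[counts > 0]
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or named element-count vector
#'   (see [parse_formula()]).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C27H30O16")  # rutin, 610.15338 Da
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.MONO_MASS[names(counts)] * counts)
}
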