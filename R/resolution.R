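# Peak capacity, multidimensional peak-capacity products, pairwise isomer
# resolution (Rpp) and the resolution matrix with threshold counting.

#' Chromatographic peak capacity
#'
#' P = 1 + t_g / mean(w): the total gradient time divided by the average
#' 4-sigma base peak width, plus one.
#'
#' @param gradient_time Total gradient time t_g in minutes.
#' @param peak_widths Vector of 4-sigma base peak widths in minutes.
#' @return Peak capacity (dimensionless).
#' @examples
#' peak_capacity(30, rep(0.1, 10))  # 301
#' @export
peak_capacity <- function(gradient_time, peak_widths) {
  stopifnot(gradient_time > 0, length(peak_widths) >= 1)
  if (any(peak_widths <= 0)) stop("peak widths must be positive", call. = FALSE)
  1 + gradient_time / mean(peak_widths)
}

#' Multidimensional peak capacity
#'
#' The peak capacity of a multidimensional separation is the product — not
#' the sum — of the capacities of its orthogonal dimensions. A UHPLC (about
#' 500) x TIMS (about 20) x QTOF (about 200,000) platform therefore reaches
#' about 2e9.
#'
#' @param capacities Vector of per-dimension peak capacities.
#' @return Product of the inputs.
#' @examples
#' multidim_peak_capacity(c(500, 20, 200000))  # 2e9
#' @export
multidim_peak_capacity <- function(capacities) {
  stopifnot(length(capacities) >= 1, all(capacities > 0))
  prod(capacities)
}

#' Pairwise peak-to-peak resolution
#'
#' Rpp = |delta CCS| / mean(W_CCS), with W the 4-sigma base widths; the same
#' number results in mobility units for peaks converted at the same m/z.
#' Rpp = 1 is baseline separation at 4 sigma, and about 0.5 is separation at
#' half height.
#'
#' @param apex_a,apex_b Apex positions (CCS in square Angstroms, or 1/K0).
#' @param width_a,width_b 4-sigma base widths in the same units.
#' @return Nonnegative resolution (vectorised).
#' @examples
#' rpp(160, 164, 4, 4)       # 1: baseline separation
#' rpp(200, 201, 2, 2)       # 0.5: half-height separation
#' @export
rpp <- function(apex_a, apex_b, width_a, width_b) {
  stopifnot(all(width_a > 0), all(width_b > 0))
  abs(apex_a - apex_b) / ((width_a + width_b) / 2)
}

#' Pairwise resolution matrix for an isomer group
#'
#' Evaluates [rpp()] for every unordered pair of group members (n members
#' give n(n-1)/2 pairs), counts pairs at or above each threshold, and assigns
#' colour classes: green for Rpp > 1, yellow for 0.5 < Rpp <= 1, white for
#' 0.25 < Rpp <= 0.5 and red for Rpp <= 0.25.
#'
#' @param members Data frame with columns \code{name}, \code{apex_ccs} and
#'   \code{base_width_ccs}; at least 2 rows.
#' @param thresholds Resolution thresholds to count pairs at
#'   (default 0.25, 0.5, 1).
#' @param group_id Label for the group.
#' @return An object of class \code{resolution_matrix}: list with
#'   \code{group_id}, \code{members}, the symmetric zero-diagonal \code{rpp}
#'   matrix, \code{pairs} (long-format data frame with colour class) and
#'   \code{counts} (named vector, pairs >= each threshold).
#' @export
isomer_matrix <- function(members, thresholds = c(0.25, 0.5, 1),
                          group_id = "isomer_group") {
  stopifnot(is.data.frame(members),
            all(c("name", "apex_ccs", "base_width_ccs") %in% names(members)))
  n <- nrow(members)
  if (n < 2) stop("an isomer group needs at least 2 members", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(members$name, members$name))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- rpp(members$apex_ccs[i], members$apex_ccs[j],
               members$base_width_ccs[i], members$base_width_ccs[j])
      m[i, j] <- m[j, i] <- r
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = members$name[i], b = members$name[j], rpp = r,
        class = if (r > 1) "green" else if (r > 0.5) "yellow"
                else if (r > 0.25) "white" else "red",
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  counts <- vapply(thresholds, function(th) sum(pairs$rpp >= th), numeric(1))
  names(counts) <- sprintf("rpp>=%g", thresholds)
  structure(list(group_id = group_id, members = members, rpp = m,
                 pairs = pairs, counts = counts),
            class = "resolution_matrix")
}

#' @export
print.resolution_matrix <- function(x, ...) {
  n <- nrow(x$members)
  cat(sprintf("resolution_matrix '%s': %d members, %d pairs\n",
              x$group_id, n, n * (n - 1) / 2))
  print(round(x$rpp, 3))
  cat("pairs at thresholds: ",
      paste(sprintf("%s: %d", names(x$counts), x$counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
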