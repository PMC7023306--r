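# Multi-criterion tiered annotation-quality matching of query features
# against a CCS library: accurate mass, retention time, isotope pattern,
# MS/MS similarity and CCS.

#' Annotation-quality tier thresholds
#'
#' Each matching criterion carries a (wide, narrow) threshold pair: meeting
#' the wide threshold earns the lower confidence tier, meeting the narrow one
#' the higher tier. Narrow is stricter than wide — smaller for the
#' difference-type criteria, larger for MS/MS similarity. CCS additionally
#' carries a separate high-confidence threshold: CCS matching within 2\% is
#' moderate confidence and within 0.3\% high confidence.
#'
#' @param mass_ppm Mass error thresholds in ppm (wide, narrow).
#' @param rt_min Retention-time error thresholds in minutes.
#' @param pattern_score Isotope [pattern_deviation()] score thresholds.
#' @param msms_cosine MS/MS cosine similarity thresholds (wide, narrow);
#'   narrow > wide on the similarity scale.
#' @param ccs_percent CCS percent-difference thresholds (default 5, 2).
#' @param high_confidence_ccs_percent High-confidence CCS threshold
#'   (default 0.3).
#' @return An object of class \code{aq_tiers}.
#' @export
aq_tiers <- function(mass_ppm = c(5, 2), rt_min = c(0.3, 0.1),
                     pattern_score = c(50, 20), msms_cosine = c(0.6, 0.8),
                     ccs_percent = c(5, 2), high_confidence_ccs_percent = 0.3) {
  stopifnot(mass_ppm[2] < mass_ppm[1], rt_min[2] < rt_min[1],
            pattern_score[2] < pattern_score[1],
            msms_cosine[2] > msms_cosine[1],
            ccs_percent[2] < ccs_percent[1],
            all(c(mass_ppm, rt_min, pattern_score, msms_cosine, ccs_percent,
                  high_confidence_ccs_percent) > 0))
  structure(list(mass_ppm = mass_ppm, rt_min = rt_min,
                 pattern_score = pattern_score, msms_cosine = msms_cosine,
                 ccs_percent = ccs_percent,
                 high_confidence_ccs_percent = high_confidence_ccs_percent),
            class = "aq_tiers")
}

#' Query feature
#'
#' A feature from a sample run to be matched against the library. All blocks
#' except the m/z are optional; absent criteria are simply not evaluated.
#'
#' @param mz Feature m/z in Da/e.
#' @param rt Retention time in minutes.
#' @param ccs Measured CCS in square Angstroms.
#' @param isotope_pattern An \code{isotope_pattern} (see [isotope_pattern()]).
#' @param msms Data frame of fragment peaks with columns \code{mz},
#'   \code{intensity}.
#' @return An object of class \code{query_feature}.
#' @export
query_feature <- function(mz, rt = NA_real_, ccs = NA_real_,
                          isotope_pattern = NULL, msms = NULL) {
  stopifnot(mz > 0)
  if (!is.null(msms)) {
    stopifnot(is.data.frame(msms), all(c("mz", "intensity") %in% names(msms)))
  }
  structure(list(mz = mz, rt = rt, ccs = ccs,
                 isotope_pattern = isotope_pattern, msms = msms),
            class = "query_feature")
}

#' CCS percent deviation of a query against a library value
#'
#' \code{100 |query - library| / library}; the library value is the reference
#' standard and serves as denominator.
#'
#' @param query_ccs,library_ccs Positive CCS values (vectorised).
#' @return Percent deviation.
#' @export
ccs_delta <- function(query_ccs, library_ccs) {
  stopifnot(all(query_ccs > 0), all(library_ccs > 0))
  100 * abs(query_ccs - library_ccs) / library_ccs
}

#' Cosine similarity of two MS/MS peak lists
#'
#' Fragment m/z values are binned on a shared grid of width \code{bin}; the
#' binned intensity vectors are compared by cosine similarity.
#'
#' @param a,b Data frames of fragment peaks (\code{mz}, \code{intensity}).
#' @param bin Bin width in Da (default 0.01).
#' @return Similarity in [0, 1].
#' @examples
#' a <- data.frame(mz = c(100, 200), intensity = c(1, 1))
#' b <- data.frame(mz = 100, intensity = 1)
#' msms_cosine(a, b)  # 1/sqrt(2)
#' @export
msms_cosine <- function(a, b, bin = 0.01) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  if (all(a$intensity == 0) || all(b$intensity == 0)) {
    stop("all-zero MS/MS intensities", call. = FALSE)
  }
  ka <- round(a$mz / bin)
  kb <- round(b$mz / bin)
  keys <- sort(unique(c(ka, kb)))
  va <- vapply(keys, function(k) sum(a$intensity[ka == k]), numeric(1))
  vb <- vapply(keys, function(k) sum(b$intensity[kb == k]), numeric(1))
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

.tier_of <- function(delta, wide, narrow, higher_is_better = FALSE) {
  if (is.na(delta)) return(NA_character_)
  if (higher_is_better) {
    if (delta >= narrow) "narrow" else if (delta >= wide) "wide" else "none"
  } else {
    if (delta <= narrow) "narrow" else if (delta <= wide) "wide" else "none"
  }
}

#' Annotation-quality score of one feature against one library entry
#'
#' Evaluates every criterion the feature supplies — mass error (ppm), RT
#' error (min), isotope-pattern deviation, MS/MS cosine and CCS percent
#' deviation — against the (wide, narrow) tier thresholds; criteria the
#' feature does not carry are marked not evaluated (NA). The CCS criterion
#' additionally sets a high-confidence flag when the deviation is within the
#' high-confidence threshold.
#'
#' @param feature A [query_feature()].
#' @param entry A [ccs_library_entry()].
#' @param tiers An [aq_tiers()].
#' @param reference_table_id Which calibration reference of the entry to
#'   match CCS against (default: the entry's first).
#' @return An object of class \code{aq_result}: list with \code{entry_id},
#'   per-criterion \code{delta} and \code{tier} vectors,
#'   \code{high_confidence_ccs}, \code{n_narrow}, \code{n_wide}.
#' @export
aq_score <- function(feature, entry, tiers = aq_tiers(),
                     reference_table_id = NULL) {
  stopifnot(inherits(feature, "query_feature"),
            inherits(entry, "ccs_library_entry"),
            inherits(tiers, "aq_tiers"))
  if (is.null(reference_table_id)) {
    reference_table_id <- names(entry$ccs_by_reference)[1]
  }
  if (!reference_table_id %in% names(entry$ccs_by_reference)) {
    stop("entry has no CCS under reference ", reference_table_id, call. = FALSE)
  }
  lib_mz <- entry$species$mz
  lib_rt <- entry$retention_time
  lib_ccs <- entry$ccs_by_reference[[reference_table_id]]$mean

  delta <- c(
    mass_ppm = abs(feature$mz - lib_mz) / lib_mz * 1e6,
    rt_min = if (is.na(feature$rt) || is.na(lib_rt)) NA_real_
             else abs(feature$rt - lib_rt),
    pattern_score = if (is.null(feature$isotope_pattern) ||
                        is.null(entry$compound$molecular_formula)) NA_real_
      else {
        f <- entry$compound$molecular_formula
        f["H"] <- f["H"] - 1L  # deprotonated form observed in negative mode
        pattern_deviation(feature$isotope_pattern,
                          theoretical_isotope_pattern(f[f > 0]))
      },
    msms_cosine = NA_real_,  # needs a library spectrum; see match_features
    ccs_percent = if (is.na(feature$ccs)) NA_real_
                  else ccs_delta(feature$ccs, lib_ccs)
  )
  tier <- c(
    mass_ppm = .tier_of(delta[["mass_ppm"]], tiers$mass_ppm[1], tiers$mass_ppm[2]),
    rt_min = .tier_of(delta[["rt_min"]], tiers$rt_min[1], tiers$rt_min[2]),
    pattern_score = .tier_of(delta[["pattern_score"]], tiers$pattern_score[1],
                             tiers$pattern_score[2]),
    msms_cosine = .tier_of(delta[["msms_cosine"]], tiers$msms_cosine[1],
                           tiers$msms_cosine[2], higher_is_better = TRUE),
    ccs_percent = .tier_of(delta[["ccs_percent"]], tiers$ccs_percent[1],
                           tiers$ccs_percent[2])
  )
  structure(
    list(entry_id = paste(entry$compound$name, entry$species$species),
         delta = delta, tier = tier,
         high_confidence_ccs = !is.na(delta[["ccs_percent"]]) &&
           delta[["ccs_percent"]] <= tiers$high_confidence_ccs_percent,
         n_narrow = sum(tier == "narrow", na.rm = TRUE),
         n_wide = sum(tier %in% c("wide", "narrow"), na.rm = TRUE)),
    class = "aq_result"
  )
}

#' @export
print.aq_result <- function(x, ...) {
  cat("AQ match vs", x$entry_id, "\n")
  for (k in names(x$delta)) {
    cat(sprintf("  %-14s delta %10.4g  tier %s\n", k, x$delta[[k]],
                if (is.na(x$tier[[k]])) "not evaluated" else x$tier[[k]]))
  }
  cat("  high-confidence CCS:", x$high_confidence_ccs, "\n")
  invisible(x)
}

#' Match query features against a CCS library
#'
#' Candidates are pre-filtered by the wide accurate-mass tier, scored with
#' [aq_score()], and ranked by decreasing count of narrow tiers, then
#' decreasing count of wide tiers, then ascending mass error, ascending CCS
#' deviation, and finally entry id — a deterministic ordinal ranking.
#'
#' @param features List of [query_feature()] objects.
#' @param library List of [ccs_library_entry()] objects.
#' @param tiers An [aq_tiers()].
#' @param top_k Number of ranked candidates to keep per feature (default 3).
#' @param reference_table_id Passed to [aq_score()].
#' @return List (one element per feature) of lists of \code{aq_result}
#'   objects, best first; an empty list when no entry passes the mass filter.
#' @export
match_features <- function(features, library, tiers = aq_tiers(), top_k = 3L,
                           reference_table_id = NULL) {
  stopifnot(length(library) >= 1)
  lapply(features, function(f) {
    results <- list()
    for (e in library) {
      ppm <- abs(f$mz - e$species$mz) / e$species$mz * 1e6
      if (ppm > tiers$mass_ppm[1]) next
      results[[length(results) + 1L]] <- aq_score(f, e, tiers,
                                                  reference_table_id)
    }
    if (!length(results)) return(list())
    key <- vapply(results, function(r) {
      sprintf("%05d|%05d|%018.9f|%018.9f|%s",
              99999L - r$n_narrow, 99999L - r$n_wide,
              r$delta[["mass_ppm"]],
              if (is.na(r$delta[["ccs_percent"]])) 999 else r$delta[["ccs_percent"]],
              r$entry_id)
    }, character(1))
    results[order(key)][seq_len(min(top_k, length(results)))]
  })
}
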