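lib_entry <- function(name, formula = NULL, mass = NULL, species = "[M-H]-",
                      ccs, rt = NA_real_, ref = "vendor_default") {
  comp <- compound_record(name, formula, monoisotopic_mass = mass,
                          retention_time = rt)
  by_ref <- list(aggregate_stats(ccs, 0.1, 3L))
  names(by_ref) <- ref
  ccs_library_entry(comp, ion_species_annotation(
    species, species_mz(comp$monoisotopic_mass, species)),
    by_ref, retention_time = rt, n_replicates = 3L)
}

test_that("CCS deltas map onto the moderate and high confidence tiers", {
  expect_equal(ccs_delta(231.05, 231.05), 0)
  d <- ccs_delta(232.37, 231.05)
  expect_equal(d, 100 * 1.32 / 231.05, tolerance = 1e-9)
  expect_lt(d, 2.0)   # inside the moderate tier
  expect_gt(d, 0.3)   # outside the high-confidence tier
  expect_gt(ccs_delta(236, 231.05), 2.0)
})

test_that("MS/MS cosine similarity matches closed forms", {
  a <- data.frame(mz = c(100, 200), intensity = c(1, 1))
  b <- data.frame(mz = 100, intensity = 1)
  expect_equal(msms_cosine(a, a), 1, tolerance = 1e-12)
  expect_equal(msms_cosine(a, b), 1 / sqrt(2), tolerance = 1e-12)
  disjoint <- data.frame(mz = c(300, 400), intensity = c(1, 2))
  expect_equal(msms_cosine(a, disjoint), 0)
  expect_error(msms_cosine(a, data.frame(mz = 1, intensity = 0)), "zero")
})

test_that("aq_score assigns per-criterion tiers and the CCS flag", {
  e <- lib_entry("rutin", "C27H30O16", ccs = 231.05, rt = 12.5)
  tiers <- aq_tiers()
  q_mz <- e$species$mz

  # delta CCS 1.5%: narrow CCS tier
  r1 <- aq_score(query_feature(q_mz, rt = 12.5, ccs = 231.05 * 1.015), e, tiers)
  expect_identical(unname(r1$tier[["ccs_percent"]]), "narrow")
  expect_false(r1$high_confidence_ccs)

  # delta CCS 4%: wide tier only
  r2 <- aq_score(query_feature(q_mz, ccs = 231.05 * 1.04), e, tiers)
  expect_identical(unname(r2$tier[["ccs_percent"]]), "wide")

  # delta CCS 0.2%: narrow and high confidence
  r3 <- aq_score(query_feature(q_mz, ccs = 231.05 * 1.002), e, tiers)
  expect_identical(unname(r3$tier[["ccs_percent"]]), "narrow")
  expect_true(r3$high_confidence_ccs)

  # absent criteria are not evaluated
  r4 <- aq_score(query_feature(q_mz), e, tiers)
  expect_true(is.na(r4$tier[["ccs_percent"]]))
  expect_true(is.na(r4$tier[["rt_min"]]))
  expect_identical(unname(r4$tier[["mass_ppm"]]), "narrow")
})

test_that("narrow tier always implies the wide condition", {
  e <- lib_entry("rutin", "C27H30O16", ccs = 231.05, rt = 12.5)
  tiers <- aq_tiers()
  set.seed(5)
  for (i in 1:50) {
    f <- query_feature(
      e$species$mz * (1 + runif(1, -1e-5, 1e-5)),
      rt = 12.5 + runif(1, -0.5, 0.5),
      ccs = 231.05 * (1 + runif(1, -0.08, 0.08)),
      isotope_pattern = theoretical_isotope_pattern("C27H29O16")
    )
    r <- aq_score(f, e, tiers)
    for (k in names(r$tier)) {
      if (!is.na(r$tier[[k]]) && r$tier[[k]] == "narrow") {
        wide_ok <- switch(k,
          mass_ppm = r$delta[[k]] <= tiers$mass_ppm[1],
          rt_min = r$delta[[k]] <= tiers$rt_min[1],
          pattern_score = r$delta[[k]] <= tiers$pattern_score[1],
          msms_cosine = r$delta[[k]] >= tiers$msms_cosine[1],
          ccs_percent = r$delta[[k]] <= tiers$ccs_percent[1])
        expect_true(wide_ok)
      }
    }
  }
})

test_that("an exact match ranks first with all evaluated tiers narrow", {
  lib <- list(
    lib_entry("rutin", "C27H30O16", ccs = 231.05, rt = 12.5),
    lib_entry("naringin", "C27H32O14", ccs = 215.92, rt = 10.1)
  )
  f <- query_feature(lib[[1]]$species$mz, rt = 12.5, ccs = 231.05)
  out <- match_features(list(f), lib)[[1]]
  expect_gte(length(out), 1L)
  expect_identical(out[[1]]$entry_id, "rutin [M-H]-")
  evaluated <- out[[1]]$tier[!is.na(out[[1]]$tier)]
  expect_true(all(evaluated == "narrow"))
})

test_that("CCS separates isobaric library entries", {
  # two isomers: same formula and m/z, CCS 3% apart
  iso_a <- lib_entry("2'-hydroxyflavone", "C15H10O3", ccs = 160.0)
  iso_b <- lib_entry("6-hydroxyflavone", "C15H10O3", ccs = 164.8)
  f <- query_feature(iso_a$species$mz, ccs = 160.1)
  out <- match_features(list(f), list(iso_b, iso_a))[[1]]
  expect_identical(out[[1]]$entry_id, "2'-hydroxyflavone [M-H]-")
  expect_identical(unname(out[[1]]$tier[["ccs_percent"]]), "narrow")
  # the CCS-inconsistent isomer keeps no narrow CCS tier
  other <- out[[which(vapply(out, function(r) r$entry_id, "") ==
                        "6-hydroxyflavone [M-H]-")]]
  expect_identical(unname(other$tier[["ccs_percent"]]), "wide")
})

test_that("mass prefilter and CCS tier reproduce a 40-of-151 census", {
  # 151 query features each matching a library entry by mass; exactly 40
  # also fall inside the wide CCS tier
  set.seed(9)
  n <- 151
  masses <- seq(200, 800, length.out = n)
  lib <- lapply(seq_len(n), function(i) {
    lib_entry(sprintf("cmp%03d", i), mass = masses[i], ccs = 150 + i / 4)
  })
  ccs_pass <- seq_len(n) <= 40
  feats <- lapply(seq_len(n), function(i) {
    lib_ccs <- 150 + i / 4
    query_feature(lib[[i]]$species$mz,
                  ccs = lib_ccs * (1 + if (ccs_pass[i]) 0.01 else 0.08))
  })
  res <- match_features(feats, lib)
  mass_matched <- sum(vapply(res, function(r) length(r) > 0, logical(1)))
  ccs_matched <- sum(vapply(res, function(r) {
    length(r) > 0 && !is.na(r[[1]]$tier[["ccs_percent"]]) &&
      r[[1]]$tier[["ccs_percent"]] %in% c("wide", "narrow")
  }, logical(1)))
  expect_equal(mass_matched, 151L)
  expect_equal(ccs_matched, 40L)
})

test_that("ranking is deterministic and monotone under loosened thresholds", {
  lib <- list(
    lib_entry("a", mass = 400.0000, ccs = 200),
    lib_entry("b", mass = 400.0004, ccs = 206),
    lib_entry("c", mass = 400.0008, ccs = 212)
  )
  f <- query_feature(species_mz(400.0000, "[M-H]-"), ccs = 200.2)
  r1 <- match_features(list(f), lib, top_k = 3)[[1]]
  r2 <- match_features(list(f), lib, top_k = 3)[[1]]
  expect_identical(vapply(r1, function(r) r$entry_id, ""),
                   vapply(r2, function(r) r$entry_id, ""))
  expect_identical(r1[[1]]$entry_id, "a [M-H]-")

  tight <- match_features(list(f), lib, aq_tiers(mass_ppm = c(1.5, 0.5)))[[1]]
  loose <- match_features(list(f), lib, aq_tiers(mass_ppm = c(5, 2)))[[1]]
  tight_ids <- vapply(tight, function(r) r$entry_id, "")
  loose_ids <- vapply(loose, function(r) r$entry_id, "")
  expect_true(all(tight_ids %in% loose_ids))
  expect_gte(length(loose_ids), length(tight_ids))
})
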