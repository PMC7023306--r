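Package: timsccs
Title: Collision Cross Section Libraries and Annotation Matching for
    Trapped Ion Mobility Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and using collision cross section (CCS)
    libraries from trapped ion mobility spectrometry (TIMS) measurements
    of plant natural products. Implements the Mason-Schamp conversion
    between reduced mobility and CCS, linear TIMS calibration against
    tune-mix calibrants under multiple reference tables, extracted and
    base-peak ion mobilogram construction with Savitzky-Golay smoothing
    and valley-based peak picking, negative-mode adduct annotation with
    theoretical isotope patterns, replicate aggregation into a TSV CCS
    library, multi-criterion tiered annotation-quality matching of query
    features against a library, pairwise isomer resolution and
    peak-capacity analysis, and a synthetic frame-stack generator with
    machine-readable truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
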