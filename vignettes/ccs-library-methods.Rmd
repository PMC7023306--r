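---
title: "CCS libraries for TIMS metabolomics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCS libraries for TIMS metabolomics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timsccs)
```

## The measurement model

Trapped ion mobility spectrometry holds ions stationary against a gas flow
with an electric field and elutes them by lowering the field; the elution
position is reported as the inverse reduced mobility 1/K₀ (V·s/cm²). The
quantity of analytical interest is the collision cross section Ω (Å²),
related to 1/K₀ by the Mason–Schamp equation

$$\Omega = \frac{3ze}{16N_0}\sqrt{\frac{2\pi}{\mu k_B T}}\cdot\frac{1}{K_0},$$

where $z$ is the charge number, $e$ the elementary charge, $N_0$ the gas
number density at standard conditions, $\mu$ the reduced mass of the ion and
the drift gas, $k_B$ Boltzmann's constant and $T$ the effective gas
temperature. At fixed m/z, charge and context, Ω is strictly proportional to
1/K₀, and `ccs_from_inverse_k0()` / `inverse_k0_from_ccs()` are exact
algebraic inverses — a property the test suite checks to below 1e-12
relative error.

Two conventions in this conversion deserve comment.

* **Temperature.** Reduced-mobility conventions differ between instruments
  and software, and the effective gas temperature inside a TIMS tunnel is
  not directly printed on any data file. We default to 305 K and expose it
  in `physics_context()`. Because TIMS CCS values are *calibrated* rather
  than first-principles quantities, any consistent temperature choice
  cancels between calibration and application; all round-trip and recovery
  properties asserted by the tests are temperature-independent.
* **Drift gas.** Reference CCS values are defined for nitrogen. Instruments
  fed by membrane nitrogen generators carry a small oxygen admixture
  (typically 0.6%); we record the composition in `instrument_metadata()` but
  use pure-N₂ molar mass (28.0134 Da) in the reduced mass, since that is
  what the reference tables assume.

## Calibration

TIMS mobility axes are calibrated against tune-mix calibrant ions with
agreed reference CCS values. `fit_calibration()` performs an ordinary
least-squares fit of reference 1/K₀ (derived from the reference CCS through
the Mason–Schamp relation) on raw instrument readings, paired by index, with
a minimum of three calibrants. Fitting in this direction makes
`apply_calibration()` a single affine evaluation, i.e. analyte readings are
interpolated between calibrants; readings outside the calibrant span are
converted but flagged as extrapolated. Whether a vendor's "linear fit" lives
in 1/K₀ space or in an internal voltage space is not documentable from the
outside; we fit in 1/K₀ space and validate by parameter recovery: for
noiseless synthetic calibrant runs under affine axis distortions with slope
in [0.8, 1.2] and intercept in [−0.1, 0.1], the fitted model recovers the
distortion to below 1e-9.

Because multiple reference CCS lists coexist for the common tune mixes
(vendor default vs newer community values), the library format stores one
aggregate per calibration reference per entry, and `dual_reference_ccs()`
computes both values from one raw reading. Both reference tables are
user-supplied configuration: no copyrighted vendor list ships with the
package, and all tests use synthetic tables.

## Mobilogram processing

`extract_eim()` sums centroid intensity within an m/z tolerance (default
±0.01 Da; ppm mode available) per mobility bin; `extract_bpm()` takes the
per-bin maximum across all m/z, so the base-peak trace shows every adduct
and aggregate at once.

Smoothing is single-cycle Savitzky–Golay with polynomial order 2. The
window is specified as a mobility width (default 0.005 V·s/cm²) and
converted to the nearest odd point count not below width/spacing, minimum
five points — at a typical 0.0005 V·s/cm² bin spacing that is 11 points.
Edges are reflect-padded.

Peak picking uses three percent-scale parameters chosen to mirror common
vendor semantics while remaining fully specified:

* **sensitivity** (default 97): the detection floor is
  (100 − sensitivity)% of the base-peak intensity, so higher sensitivity
  admits smaller peaks — monotone in the direction users expect of the
  opaque vendor parameter of the same name.
* **minimum peak valley** (default 10): two adjacent maxima remain separate
  peaks only if the valley between them drops by at least this percentage
  of the *lower* apex; the definition is scale-free.
* **relative intensity threshold** (default 15): only peaks reaching this
  percentage of the base peak are reported.

Widths are measured as the half-height width (FWHM) by linear interpolation
and converted to the 4σ base width via the Gaussian factor 4/2.3548, rather
than by baseline crossing — robust to noise floors and consistent with the
4σ convention used in the resolution algebra below. Apex positions are
refined to sub-bin precision with a parabola through the log-intensities of
the apex bin and its neighbours; for a Gaussian profile the log-trace is
exactly quadratic, so the refinement is exact on noiseless peaks. Without
it, half-bin quantisation on a 1000-bin axis alone would contribute about
0.06% CCS error, swamping the reproducibility scale of the measurement.

Spectral **purity** of a peak is the fraction of total centroid ion current
within its 4σ mobility extent that lies within the m/z tolerance of the
target species. Note that a perfectly pure compound still shows purity
around 0.7 when its isotopologue centroids (M+1, M+2, ...) are planted,
because only the monoisotopic window counts as "target"; purity is used for
*ranking* candidate peaks, where this constant factor is immaterial.

## Adduct annotation

The shipped negative-mode species set is [M−H]⁻, [2M−H]⁻, [M−3H]⁻,
[M−H+HCO2H]⁻ and [M−H+Na+HCO2]⁻. Deprotonation subtracts a proton mass
(1.00727646688 Da; the electron stays with the ion), and [M−3H]⁻ is modelled
as oxidation — loss of two hydrogen atoms — followed by deprotonation.
These conventions place the rutin species at m/z 609.146, 607.130 and
677.134, matching the nominal 609/607/677 pattern seen for catechol-bearing
flavonoid glycosides.

Isotope patterns are computed by iterative convolution of per-element
isotope distributions over nominal mass offsets (unit-mass aggregation,
appropriate at TOF resolution; fine structure is out of scope), and
pattern agreement is scored as 1000 × RMS deviation of the base-normalised
isotopologue intensities — an open, documented analogue of proprietary
pattern-match scores. A peak is annotated with a species when the most
intense centroid in its extent matches the species m/z, the pattern score
is below the ceiling (default 50), and — where several peaks compete for
the same species — it has the highest purity. Peaks matching nothing stay
`unknown`; mobilograms of real extracts frequently contain unexplained
peaks and no rule exists to name them.

## Library format and statistics

The library is a flat TSV with `#key=value` metadata header lines
(drift-gas composition, temperature, pressures, mobility range, ramp time,
calibration reference ids) followed by one row per (compound, species,
reference table). A flat file stays greppable and diff-able. Replicate
statistics use the sample (n−1) standard deviation, treating triplicates as
samples of a measurement population; RSD = 100·sd/mean is recomputed and
enforced on read. Numeric fields are serialised with 12 decimal places so a
write→read round trip reproduces every field within 1e-9 — printed reports
use the conventional 5-decimal percent style instead. Entries whose [M−H]⁻
RSD exceeds 0.35% are QC-flagged; routine TIMS triplicates sit near 0.1%
RSD and rarely beyond 0.35%, so a flag marks an entry as out of the
instrument's reproducibility regime rather than deleting it.

Percent differences between measurement sets default to the *first*
(reference/library) value as denominator; published tables rarely state
their convention, and recomputing their printed per-compound differences
from rounded CCS columns reproduces them only to a few thousandths of a
percent point, so the denominator is configurable (`first`, `second`,
`mean`) rather than guessed. Printed summary rows in the literature also
occasionally disagree with the mean of their own printed per-row values at
the 1e-2 percent-point level; we implement the plain mean.

## Matching and annotation quality

Each criterion — mass error (ppm), RT error (min), isotope pattern score,
MS/MS cosine, CCS percent deviation — carries a wide and a narrow
threshold; meeting the wide one earns the lower confidence tier, the
narrow one the higher tier. Defaults: mass 5/2 ppm, RT 0.3/0.1 min, pattern
50/20, MS/MS cosine 0.6/0.8, CCS 5%/2%. CCS additionally carries a separate
high-confidence flag at 0.3%. The 5%/2% display tiers and the 2.0%/0.3%
matching thresholds serve different purposes in practice (screening display
vs confident identification), so both are exposed rather than merged.
Candidates are pre-filtered by the wide mass tier and ranked ordinally —
count of narrow tiers, count of wide tiers, then ascending mass error,
ascending ΔCCS, entry id — because tier colours, not a weighted composite,
are what practitioners read; the ranking is deterministic and loosening any
threshold never removes a previously returned candidate.

## Resolution analysis

Peak capacity is implemented as $P = 1 + t_g/\bar w$ with $\bar w$ the mean
4σ base width — the standard gradient-time-over-average-width estimate —
and multidimensional capacity as the product over dimensions. Pairwise
isomer resolution is $R_{pp} = |\Delta\mathrm{CCS}| / \bar W_\mathrm{CCS}$
with the *mean* of the two 4σ widths; $R_{pp} = 1$ is baseline separation
at 4σ and about 0.5 is separation at half height. `isomer_matrix()`
evaluates all n(n−1)/2 unordered pairs, counts pairs at the 0.25 / 0.5 / 1
thresholds and assigns the conventional colour classes. Published isomer
matrices do not list their underlying CCS values as text, so exact
reproduction is impossible; instead the suite asserts the monotonicity that
makes those results meaningful — threshold counts never decrease, and
strictly increase, as resolving power grows from the survey (~40) to the
narrow-range (~117) regime. Whether such matrices used 4σ or FWHM widths is
likewise unstated; the width convention here is whatever the caller feeds
in, with the 4σ base width being what the pipeline produces.

## The synthetic-data generator

`simulate_frames()` plants each (compound, species) as a Gaussian profile
in 1/K₀ (peaks in TIMS are near-Gaussian, which is also what the 4σ
resolution algebra presumes) at the raw-axis position implied by its true
CCS and the inverse of an affine calibration distortion, carrying centroids
at the species m/z with the theoretical isotope pattern. Defaults: axis
0.4–1.8 V·s/cm² over 1000 bins (a broad survey acquisition range), peak
sigma 0.01 V·s/cm² (single-peak resolving power ≈ 45 at mid-range, the
survey regime), optional uniform additive intensity noise. Replicate
batches jitter the true CCS with a stated relative SD (default 0.1%, the
reproducibility scale of routine triplicates); matrix overlays add
background features uniform in mobility and log-uniform in intensity —
deliberately simple, since only CCS-shift robustness is asserted against
them. All generators are deterministic given their seed and emit a truth
table that is consistent with the physics module to 1e-12.

What the generator does *not* emulate: chromatographic peak shape and drift
in RT, detector saturation, space-charge CCS shifts, in-TIMS fragmentation,
profile-mode spectra, and correlated (non-uniform) noise. Passing the
recovery tests therefore demonstrates correctness of the *computations* —
calibration, conversion, peak measurement, aggregation — under controlled
conditions, not robustness to every artefact of real instrument data.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 1000-bin axes, batches of
up to 50 compounds × 3 replicates, and isomer groups of 7 — sizes chosen so
the full suite completes in well under a minute while every property is
exercised at the same parameter values the defaults document. Tolerances in
the tests come from the property being checked: machine-precision (1e-12)
for algebraic identities, 1e-9 for noiseless least-squares recovery, 0.05%
for end-to-end CCS recovery (sub-bin refinement makes this comfortable),
and sampling-error bands (e.g. mean recovered RSD in [0.05%, 0.15%] for an
injected 0.1% jitter across 50 triplicates, where the n = 3 sample SD is
biased low by the c₄ factor ≈ 0.886) for stochastic recoveries. Degenerate
inputs are contracts, not crashes: empty frame stacks give empty
mobilograms, all-zero traces give zero peaks, single replicates give
NA-flagged SDs, and zero ion current in a purity extent returns 0 with a
degenerate flag.
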