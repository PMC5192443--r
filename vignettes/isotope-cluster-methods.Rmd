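---
title: "Methods: isotope cluster prediction, detection and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope cluster prediction, detection and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoclustr)
```

## The problem

Every analyte in an LC-MS run produces not one feature but a short ladder of
coeluting *isotopologue features* — the isotope cluster — spaced by roughly
the ¹³C–¹²C mass difference of 1.003355 Da divided by the charge. Isotope
clusters carry the information needed to infer charge state and elemental
composition and to rank molecular formulas, but two things routinely go
wrong in practice. First, the heuristic region-of-interest (ROI) stage of
feature detectors tuned for specificity misses the weak higher isotope
peaks, so clusters come out truncated. Second, spacing-based grouping
confuses genuine clusters with overlapping clusters of coeluting isobars,
in-source hydrogen losses (1.008 Da below the molecular ion — almost the
isotope spacing) and detector-underestimated trailing peaks.

`isoclustr` addresses both: *targeted peak picking* re-examines the raw map
exactly where isotope peaks of already-detected features must lie, at a
deliberately relaxed signal-to-noise threshold; and *mass-specific
validation* checks each putative cluster's abundance ratios against what
molecular formulas of that mass can plausibly produce, splitting clusters
where the ratios are impossible.

## Theoretical isotope patterns

Patterns are computed by convolving per-element isotope distributions
(sparse mass/probability lists; intermediate terms below `1e-9` relative
probability are dropped, and terms more than `max_isotopes + 2` spacings
above the running monoisotopic mass are discarded since they can never
re-enter the reported window). Centroids closer than the FWHM implied by the
resolving power (FWHM = mass/R; default R = 10,000, where isotopic fine
structure is unresolved) are merged by intensity-weighted averaging.

Two conventions matter and are worth stating explicitly:

* **Intensity scale.** By default (`mass_weighted = TRUE`) a centroid's
  intensity is its *area* at constant resolving power: peak width grows
  proportionally with mass at fixed R, so with height-encoded abundances the
  integrated envelope area is abundance × mass. This is the convention under
  which the bundled reference intensities of the six worked-example
  substances reproduce to the printed precision; plain isotopologue
  probabilities are available with `mass_weighted = FALSE`.
* **Pruning reference.** The `prune_threshold` (default 0.01, in percent) is
  taken relative to the *monoisotopic* peak, not the base peak. The two
  differ only when the monoisotopic peak is not the most intense one — e.g.
  boron compounds, where ¹⁰B is the lighter but minor isotope — and the
  monoisotopic reference keeps the printed six-peak boron cluster stable.
* **Isotope window.** `max_isotopes = 5` keeps the monoisotopic peak plus at
  most five isotope peaks; without the cap, Cl₂-bearing compounds retain a
  seventh peak above 0.01% and the reference cluster sizes (4, 5, 6, 6, 6,
  6) would not be reproducible.

The bundled element table (`isotope_table()`) carries IUPAC/NIST
representative isotope masses and abundances for H, B, C, N, O, F, Na, Mg,
Si, P, S, Cl, K, Ca, Se, Br and I; abundances sum to one per element and
patterns conserve total probability to `1e-6` when pruning is disabled.

```{r}
theoretical_pattern("C4H7NO4")
```

## Targeted peak picking with predicted isotope ROIs

For each detected peak, one ROI is predicted per charge state z ≤ Z and
isotope number i ≤ I (defaults Z = 3, I = 5): the peak's retention-time
interval, and its m/z interval shifted by i·1.003355/z. All Z·I ROIs are
emitted; optional bounding-box merging of overlapping ROIs is available but
off by default, since the predicted positions are exactly where a picker
should look regardless of overlap. The ROI's retention-time interval is the
source peak's detected bounds, unpadded.

Targeted picking then runs at the relaxed threshold snthr′ = snthr·r/100
with r on the 5%-grid; the recommended operating point is r = 25, i.e.
snthr′ = 6.25 for the traditional snthr = 25. Matched control ("noise")
ROIs — centers drawn uniformly within the envelope of the predicted ROI
centers, widths drawn from 50-bin histograms of the detected peaks' relative
m/z widths and rt widths — quantify how many peaks relaxed picking would
find at random positions.

The bundled ROI examiner is deliberately lightweight: the extracted-ion
trace (maximum intensity per scan within the m/z window) supplies the apex;
the local noise level is the median intensity of centroids in the m/z
regions flanking the ROI (guard band 0.01 Da, width 0.2 Da, retention-time
span extended twofold) so that the peak's own chromatographic shoulders and
jittered centroids do not inflate the estimate; where the flanks are empty
the median of the off-peak trace is used, floored at one count. Peak
intensity is the trapezoidal area of the trace. The contribution this
package implements is *where to look*, not wavelet machinery — every
downstream function accepts externally produced peak tables, so a full
continuous-wavelet picker can be substituted for the examiner.

Merging of traditional and targeted tables drops an added peak when a
retained peak lies within max(mz·ppm/10⁶, abs) in m/z and rt_tol in
retention time; added peaks are also deduplicated against each other, since
several predicted ROIs (e.g. z = 1, i = 1 and z = 2, i = 2) can rediscover
the same feature.

## Cluster detection

Within a coeluting group, for each charge state, peak pairs are marked when
their spacing deviates from 1.003355/z by at most
max(mono_mz·Δm_ppm/10⁶, Δm_abs); the ppm term is referenced to the chain's
monoisotopic m/z, which is the reading that reproduces the printed minimal
relative mass errors of the worked examples. Putative clusters are maximal
gap-free chains of marked successive pairs. The production search is an
exact longest-path dynamic program over the successor graph — equivalent to
enumerating all chains and keeping the longest, which is what the method
prescribes — with deterministic tie-breaks: among successors permitting
equally long continuations, the one closest to the expected position, then
the more intense; among equal-length chains, the lower monoisotopic m/z,
then the smaller charge (the widest spacing). The largest cluster is
retained, its peaks removed, and the search repeated; retained clusters are
therefore peak-disjoint.

The default absolute tolerance is 0.01 Da. This is not cosmetic: spacings at
isotope peaks dominated by ³⁴S, ³⁷Cl or ¹⁰B/¹¹B deviate from the ¹³C spacing
by up to ~0.009 Da, and at 0.005 Da the sulfur-, chlorine- and
boron-containing reference clusters split exactly at those peaks.

## Mass-specific validation

A compound database is reduced to quantile tables: for every formula, the
theoretical pattern yields the ratio of the monoisotopic to the i-th isotope
peak (i = 1..5); compounds are grouped by exact mass into consecutive
half-open windows (sizes 10/25/50/100/250 Da; default 50) and per-window
p-quantiles are stored on a fixed 23-value grid. Database patterns are
computed *without* an abundance prune threshold: pruning at 0.01% would cap
every recordable ratio at 10⁴, exactly where the weakest printed reference
peaks sit, putting legitimate clusters on the table boundary. Compounds
whose pattern lacks the i-th peak are skipped for that index. Quantiles use
linear interpolation of order statistics (type 7); on sparse windows the
extreme p-values degenerate to the window minimum/maximum, which is
documented behaviour, not an error. Empty windows fall back to the nearest
populated window at lookup (logged), and masses beyond the last populated
window clamp to it, so validation never fails on a lookup.

Validation walks each putative cluster from the first isotope peak: the
observed ratio of monoisotopic to i-th abundance is bracketed by a noise
interval using both peaks' signal-to-noise estimates (noise n = a/sn;
r_min = max(a₁−n₁,0)/(a₂+n₂), r_max = (a₁+n₁)/max(a₂−n₂, ε)), and compared
with the window's 99% interval (p = 0.005 and 0.995) at the cluster's
monoisotopic mass (m/z × charge; the proton/electron mass is neglected
relative to the 50 Da windows). On non-overlap the cluster splits: a prefix
of at least two peaks is kept, a single-peak prefix (the hydrogen-loss case)
is released as an unannotated peak, and the suffix restarts as a new
putative cluster with the offending peak as monoisotopic, validated
recursively; a split-off single trailing peak (the underestimated-intensity
case) is likewise released. The kept prefix is final — it already passed its
checks. Peaks without a signal-to-noise estimate are assigned sn = ∞, the
strictest reading, and the noise model is intentionally simple: the
bracketing and monotone-leniency properties (wider intervals can only
reduce splits), not exact interval widths, carry the behaviour.

## The synthetic formula database

The bundled quantile tables (`default_quantile_tables()`) are prebuilt from
20,000 synthetic formulas spanning 50–1000 Da (seed 1), shipped as JSON.
The generator draws from five composition classes — lipid-like,
sugar/organic-acid-like, nucleotide-like (carbon-poor, phosphate- and
nitrogen-rich), peptide-like (sulfur-bearing) and halogenated/aromatic
(Cl/Br-bearing) — with elemental ratio ranges chosen to emulate a biological
compound database such as KEGG. The halogen and polyphosphate classes are
load-bearing: chlorinated compounds define the small monoisotopic-to-second
ratios (~1.5 for two chlorines) and nucleotide-like compounds the large
monoisotopic-to-first ratios of carbon-poor masses (~7.5 at 500–550 Da) that
real validation intervals must cover; a CHNOPS-only database would reject
every chlorinated cluster. Heteroatom propensities are tunable
(`element_weights`), e.g. `c(S = 0)` removes sulfur.

What the generator does *not* emulate: retention behaviour, adduct and
in-source fragment chemistry, isotopic fine structure, detector saturation
(the underestimated-peak scenario is constructed directly on peak tables),
and the true composition frequencies of any specific database. Passing
tests therefore demonstrate that the machinery behaves as specified under
realistic ratio diversity, not that any particular database's quantile
values are reproduced — those are database-version dependent by nature.

The raw-map simulator plants Gaussian elution profiles per isotopologue
(apex proportional to the theoretical pattern), centroid m/z jitter
(σ = 3×10⁻⁴ Da), and a uniform noise floor of random centroids, and returns
a ground-truth ledger with each isotopologue's true S/N (apex/noise level).
Everything is deterministic under a seed.

## Validating the worked example

With peaks carrying the instrument-style S/N estimate of 25 — the most
conservative value any peak passing traditional picking at snthr = 25 can
have, and the natural choice because the validation procedure is defined on
noise-bracketed ratios, not noise-free point ratios — the six bundled
reference clusters validate to the published outcome: five substances pass
unchanged and the boron compound autoinducer-2 loses its leading
monoisotopic peak, whose mono/first ratio of 0.244 lies an order of
magnitude below the lower 0.5% quantile near mass 192 for any plausible
biological formula (its surviving five peaks revalidate as a cluster). This
outcome is insensitive to the formula database: no CHNOPS/halogen
composition at that mass produces a monoisotopic peak four times weaker
than its first isotope peak.

```{r}
pk <- table1_spectrum(sn = 25)
cl <- find_putative_clusters(pk, Z = 3, abs_tol = 0.01)
v  <- validate_clusters(cl, peaks = pk)
tidy(v)
rejected_peaks(v)[, c("peak_id", "mz", "intensity")]
```

## Problem sizes and numerical choices

Defaults throughout: Z = 3, I = 5, snthr = 25, r = 25, Δm_abs = 0.01 Da,
Δm_ppm = 0, window size 50 Da, p = 0.005/0.995, Δm = 1.003355 Da stored once
and shared between ROI prediction and detection. The test suite exercises
the detection path against an exhaustive-enumeration oracle on ≤12-peak
spectra (100 random spectra), quantile tables against a hand-rolled
order-statistic oracle, peak merging against a quadratic deduplication
oracle, and the targeted-picking benchmark on twenty simulated maps of
three compounds each (monoisotopic S/N 100, first-isotope S/N 14–22,
straddling snthr′ = 6.25 and snthr = 25); the bundled tables use 20,000
compounds. These sizes were chosen so the whole suite runs in well under a
minute while every window and code path stays exercised.

Known limitations: the examiner is not a wavelet picker and underestimates
overlapping chromatographic peaks; charge assignment prefers the smallest
charge consistent with the spacing; validation compares only
monoisotopic-to-i-th ratios (as the method defines), so a distorted
intermediate peak with a plausible ratio to the monoisotopic peak is not
flagged; and quantile values from the synthetic database stand in for — but
do not reproduce — those of any curated compound database.
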