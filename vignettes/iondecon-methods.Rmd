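---
title: "Ion-ratio deconvolution of GC/MS chromatograms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-ratio deconvolution of GC/MS chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondecon)
```

## The problem

A scanning quadrupole GC/MS instrument produces, every fraction of a second,
a unit-mass spectrum over a fixed m/z window (here 50–350 at 12 scans/s).
Complex natural extracts — the package's motivating application is volatile
profiling of green and roasted coffee — contain hundreds of compounds, and
chromatography alone cannot separate all of them: many peaks are sums of two
or more coeluting components. `iondecon` identifies and quantifies target
compounds inside such composite peaks by *ion-ratio matching* and removes
each identified component by *mass-spectral subtraction*, so that the
remaining signal can itself be identified, until the residual is
indistinguishable from background.

## The identification criterion

A target compound is described by its reference spectrum, a retention time
(optionally a retention index), its **main ion** (the 100% ion, used for
quantification) and 2–5 **qualifier ions** with expected relative abundances
$R_i$ (qualifier intensity over main-ion intensity in the reference
spectrum). Four statistics must agree simultaneously before an
identification is accepted.

**Reduced ion intensities.** For scan $t$ with main-ion intensity $A_m(t)$
and qualifier intensities $A_i(t)$,

$$I_i(t) = \frac{A_i(t)}{R_i\,A_m(t)}.$$

A scan whose ion ratios match the reference exactly is *flat*: $I_i = 1$
for every qualifier. (The denominator placement is the only reading under
which a perfect match is flat at 1; `reduced_intensities()` implements it.)

**Average reduced-intensity deviation.** With $N$ qualifiers,

$$\Delta I(t) = \frac{\sum_{i<j} |I_i - I_j|}{N(N-1)/2},$$

the mean absolute pairwise difference; zero iff all reduced intensities are
equal. The acceptance rule is $\Delta I \le K + \Delta_0 / A_m$ with
$K = 0.20$ by default and $\Delta_0$ an additive noise allowance (three
times the baseline MAD of the TIC unless set explicitly).

**Scan-to-scan variance (SSV).** $\Delta E = \Delta I \cdot \log_{10} A_m$
weights the deviation by abundance, so that a given fractional ratio error
counts more when measured on a strong signal. The ceiling is
$\Delta E_{\max} = 7$, commensurate with abundances of $10^3$–$10^6$ counts
and $\Delta I \lesssim 2$ under a decadic logarithm; the package therefore
uses base 10. As a complementary, purely spectral view of scan-to-scan
constancy, `scan_distance_matrix()` exposes the pairwise cosine distances
between all scans of a region (scan 1 against 2, 3, …, n; scan 2 against
3, …, n; and so on); it is a diagnostic and takes no part in the pass/fail
decision.

**Q-value and Q-ratio.** The Q-value summarizes ion-ratio agreement across
the peak:

$$Q = \max\!\Big(0,\; 100 - \overline{100\,|R_i - r_i(t)|/R_i}\Big),$$

the mean running over qualifying scans and qualifier ions,
$r_i(t) = A_i(t)/A_m(t)$. The mean (rather than a sum) keeps $Q$ on the
0–100 scale on which the acceptance floor of 95 is stated; the main ion,
whose deviation is identically zero, is excluded so that it cannot dilute
the average. The Q-ratio check compares each qualifier's *mean* ratio
across the peak with $R_i$ and requires the worst fractional deviation to
be within ±20%.

`evaluate_target()` combines the four: the longest stretch of consecutive
qualifying scans (nonzero main ion, every $|I_i - 1| \le 0.20$,
$\Delta I$ within its allowance) must span at least 5 scans, the minimum
$\Delta E$ over that stretch must be at or below 7, and Q-value ≥ 95 and
Q-ratio ≤ 0.20 must hold over the stretch. All thresholds live in
`match_criteria()` and are user-adjustable.

```{r criteria, eval = FALSE}
match_criteria()  # K = 0.2, delta_e_max = 7, >= 5 consecutive scans,
                  # q_value_min = 95, q_ratio_tol = 0.2
```

## Deconvolution by iterative subtraction

`detect_peaks()` finds peak regions on the Savitzky–Golay-smoothed TIC:
apexes above `baseline + 3 × MAD`, regions extended to baseline return, and
two apexes are kept separate only when the valley between them drops below
half the smaller apex height above baseline — heavily fused peaks stay in
one region and are separated spectrally, not chromatographically.

Within a region, `deconvolve_peak()` iterates:

1. every library target whose retention time falls inside the region is
   evaluated against the current residual; those passing the full criterion
   are subtracted in descending Q-value order (ties: larger integrated
   main-ion area, then lexical id), the most confident assignment first;
2. if nothing passes, `select_invariant_scans()` looks for the 3–5
   consecutive scans whose spectra are most mutually constant (smallest
   mean pairwise cosine distance, every pairwise distance within a
   tolerance of 0.05, relaxed stepwise to 0.2 before falling back to the
   scans at the residual TIC apex). Their average — baseline-corrected and
   restricted to ions whose elution profiles co-elute with the base-peak
   ion — is matched against the library; a match of weighted-cosine ≥ 0.80
   is subtracted under the library spectrum, otherwise the averaged
   spectrum itself is registered as an unknown with a fresh numeric
   identifier and subtracted;
3. iteration stops when the smoothed residual TIC of the region is within
   `baseline + 3 × MAD` (`residual_is_background()`), when an iteration
   extracts nothing, or after 20 rounds.

Subtraction (`subtract_component()`) scales the component spectrum per
scan so its intensity at the anchor ion (the component's main ion) equals
the observed intensity there, and clips negative residuals at zero; before
clipping, subtracted + residual equals the original signal exactly.

Three numerical supports stabilize this loop on noisy, fused data:

* **Baseline correction.** An averaged residual spectrum carries the
  per-cell noise floor in all ~300 channels, which overwhelms the cosine
  geometry of a 5–25-ion spectrum. Before matching, the expected per-cell
  baseline is subtracted and ions consistent with the floor (within
  $2\sigma_{\text{cell}}/\sqrt{n_{\text{avg}}}$) are dropped.
* **Ion co-elution filter.** When the averaging window straddles two
  components, their ions peak at different scans. Ions whose smoothed
  profile apex lies more than 3 scans from the base-peak ion's apex (and
  whose profile correlation is below 0.95) are excluded, so the emitted
  spectrum belongs to the component owning the base peak and the second
  component survives in the residual for the next iteration.
* **Joint profile refinement.** Sequential anchor-ion subtraction is
  biased whenever components share ions. Once all component spectra of a
  region are known, the baseline-corrected region signal is decomposed per
  scan onto all spectra at once by linear least squares (negative profile
  values clipped), and abundances and per-component spectrum estimates are
  recomputed from that joint fit.

Each reported component carries `spectrum_est`, the average over its
qualifying window of the original signal minus the estimated contributions
of every *other* component — a data-derived spectrum that is meaningful
even when the subtraction used a library spectrum.

## Building a target library from heartcuts

In the two-dimensional acquisition mode, consecutive 1-minute windows of
first-column effluent are re-chromatographed on a second column of
different polarity; `build_library()` processes the resulting runs in
window order against a growing cumulative library, so components
transferred between adjacent cuts (flow- and concentration-driven
carryover) are recognized rather than re-registered. Duplicate suppression
merges a new component into an existing entry when its spectrum cosine is
at least 0.95 and its retention agrees within 10 index units (or 0.05 min
without a calibration), keeping the spectrum of the higher-abundance
occurrence. An unknown is registered only when it carries at least 5% of
its region's largest component abundance — smaller residuals are within
the scaling error of the preceding subtractions. Each stored target keeps
the averaged-invariant-scan spectrum of its best occurrence (a choice; an
instrument vendor might instead store a background-subtracted apex scan).

Identification levels follow common practice: a library match with
weighted-cosine score ≥ 0.80 and retention-index agreement within 30 units
is *tentative*; tentative plus an authentic reference standard (an input
flag, since no standard list ships with the package) is *positive*;
anything else stays *unknown* under its numeric identifier
(`classify_identification()`). All four thresholds (0.80, 30, 0.95, 10)
are conventional defaults, exposed as arguments. Retention indices use
van den Dool–Kratz linear interpolation on a C7–C30 n-alkane series
(`kovats_ri()`), with no extrapolation outside the calibrated span.

## Quantification and sample comparison

`quantify()` reports, per target, the deconvolved main-ion area over the
matched region divided by the internal standard's main-ion area, times a
nominal response scale (default $10^6$). The internal standard is
deuterated naphthalene (main ion m/z 136); its packaged reference spectrum
is synthetic (constructed, not measured) and so labelled. Targets failing
the criterion report 0.

The comparison layer (`detect()`, `venn_partition()`, `fold_change()`,
`count_fold_threshold()`, `comparison_report()`) operates on
compound × sample abundance tables. The default detection threshold is 0
(any nonzero value counts as present): the packaged coffee tables contain
printed values below the instrument's 5000-unit detection convention
(e.g. 4983), which shows that the 5000-unit rule was applied upstream of
tabulation; 5000 remains available as an argument. Fold changes are
reported as exact ratios plus a nearest-integer rounding (halves away from
zero), which reproduces every printed green-quality fold in the packaged
tables (179, 43, 38, 27, 23, 19, 14, 12; 13 and 12 in the opposite
direction). Compounds with a zero denominator are routed to "unique"
listings rather than fold lists. One published count over these tables —
65 compounds at 2-fold or greater in one roast-to-green direction — does
not reproduce from the printed values under any rounding convention we
enumerated (strict arithmetic gives 58); the computation is exposed but
that figure is not asserted, and the derived "40 common to both
directions" count is not asserted either.

## The synthetic-data generator

Because no instrument data are distributed with the source study,
validation rests on a seeded simulator with known ground truth
(`simulate_run()`, `simulate_heartcut_campaign()`, `random_spectrum()`).
It emulates: Gaussian elution profiles (width σ expressed in minutes);
unit-mass spectra of 5–25 ions with long-tailed intensity draws; a
constant baseline plus additive Gaussian noise per (scan, m/z) cell,
clipped at zero; 12 scans/s over m/z 50–350; an optional spiked internal
standard; and contiguous 1-minute heartcut windows with a seeded fraction
of compounds carried into the adjacent cut at a configurable abundance
ratio. Every generator is a pure function of its seed and configuration.

Signal-to-noise is stated on the TIC trace: a peak of "SNR 100" has apex
TIC equal to 100 times the standard deviation of the TIC noise
($\sqrt{n_{m/z}}$ times the per-cell noise sd). Test problem sizes are
runs of 1–1.2 min (720–864 scans × 301 channels), 2–7 coeluting compounds
per region, and campaigns of 3–6 cuts with 5–12 compounds — small enough
to run the whole validation suite in well under a minute while exercising
apex separations from 0.5σ upward.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: peak tailing and asymmetry, detector
saturation and column overload, heteroscedastic (signal-proportional)
noise, retention-time drift between runs, spectral skew across a peak, and
isotope structure. Real spectra also share fragment ions far more
systematically than random spectra do; the shared-ion stress the tests
apply is therefore optimistic for compound classes with near-identical
fragmentation (isomer families).

## Numerical choices and degenerate inputs

* Cosine distances are computed on dense unit-mass vectors; library search
  uses the mass-weighted variant ($w = m/z \cdot \sqrt{I}$).
* Ties in invariant-window selection prefer the larger window; ties in
  extraction order fall back to integrated area, then lexical id.
* A target whose retention time lies outside the searched span returns a
  not-found result (`passed = FALSE`, empty region), not an error;
  a scan with zero main-ion intensity is non-qualifying rather than
  erroneous at the region level, and an explicit error at the single-scan
  level (`reduced_intensities()`).
* Peak regions are clamped to at least 3 scans; iteration in
  `deconvolve_peak()` is capped at 20 rounds per region to guarantee
  termination.
* All file round-trips are exact for integer m/z and within $10^{-6}$
  relative for intensities.

## Known limitations

Two compounds without library spectra whose apexes lie closer than about
half a peak width have effectively identical elution profiles; no
spectrum-free method can split them, and the library builder registers one
blended entry (the validation oracle counts such clusters as one
resolvable component). Dense triple overlaps near that limit can
additionally leave one partial-blend entry. Trace unknowns below 5% of
their region's dominant component are suppressed as probable subtraction
shards and will be missed if genuine. Retention-time alignment across
runs, isotope-pattern modelling and high-resolution (accurate-mass) data
are out of scope.
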