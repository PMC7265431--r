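---
title: "The toffee data model: lattice compression, random access and 2D peak re-quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toffee data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toffer)
```

This vignette is the package's own account of the science it implements:
the model behind the format, the estimation and fitting algorithms, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not show
about real data.

## 1. The square-root lattice of a TOF analyser

A time-of-flight mass analyser measures ion arrival times at integer
multiples $i$ of a fixed sensor interval $\Delta t$, offset by $t'_0$.
Equating the electric potential energy $zU$ with the kinetic energy
$\tfrac12 m d^2/t^2$ over flight distance $d$ gives
$t_i \propto \sqrt{m/z}$, hence every observable m/z value lies on the
lattice

$$ m/z(i) \;=\; \bigl[\alpha\,(i + \gamma) + \beta\bigr]^2, \qquad
\alpha = \frac{\Delta t \sqrt{2U}}{d},\quad
\gamma = \Bigl\lceil \tfrac{t'_0}{\Delta t} \Bigr\rceil,\quad
\beta = \alpha\Bigl(\tfrac{t'_0}{\Delta t} - \gamma\Bigr). $$

`ims_from_instrument()` implements these relations;
`mz_from_index()` / `index_from_mz()` convert between the two spaces
(rounding half away from zero, stated explicitly because perturbed
inputs can produce half-step ties). Only $\alpha$ and the combined
offset $\alpha\gamma + \beta$ are identified from data; $\gamma$ is a
storage convention.

Because the instrument applies in-line calibration on top of routine lab
calibration, the coefficients drift slowly from scan to scan, and a
single per-run pair would not reproduce the data exactly. The format
therefore stores $\alpha, \beta$ per scan, their medians and a single
$\gamma$ per window.

## 2. Per-scan coefficient estimation

The reference data expose no coefficients, so they are estimated from
each scan's m/z vector (`estimate_scan_ims()`):

1. take successive differences of $\sqrt{m/z}$ — on a lattice every
   difference is an integer multiple of $\alpha$;
2. seed $\hat\alpha$ with the average of the near-minimal differences
   (adjacent profile samples);
3. **gap ladder**: a gap of $n$ steps can only be rounded to its integer
   count once $\hat\alpha$'s relative error is below $\approx 0.4/n$.
   The estimator therefore refines $\hat\alpha$ by regression through
   the origin on certified step counts, starting from single-step gaps
   and widening the certified range only as fast as the accumulated
   evidence allows ($\varepsilon = \eta/\sqrt{\sum n_k^2}$, with $\eta$
   the robust per-difference noise in step units). When no further
   widening is certified the remaining gaps are rounded best-effort;
4. assign cumulative integer indices and refine slope and intercept by
   least squares, iterating until the assignment is stable (at most 10
   rounds);
5. **lattice-reality guard**: a fit whose residuals approach half a step
   is rejected — any point set can be interpolated by a fine enough
   lattice, so lattice structure is only accepted when points sit far
   closer to the nodes than the step size (threshold 0.25 steps). This
   is what makes centroided input fail cleanly;
6. canonicalise to $\gamma = 0$, $\beta \in [0, \alpha)$ by folding
   whole multiples of $\alpha$ into the indices, which then approximate
   the absolute TOF sample index. The default acceptance residual is
   5 ppm, configurable.

Two consequences worth stating plainly. First, the absolute register
across a wide empty gap is identifiable only if the data contain
stepping-stone gaps; real profile scans (thousands of contiguous
samples) always do, and the package's estimation tests use
cluster-dense index sets for the same reason — isolated singletons
separated by thousands of steps genuinely under-determine the register,
and the estimator reports failure rather than guessing. Second, scans
with fewer than 3 distinct values cannot be estimated at all; on import
they inherit the nearest preceding estimable scan's coefficients.

## 3. The CSR store and the HDF5 layout

All non-zero samples of a window become integer triplets
(scan, m/z index, count) in compressed-sparse-row layout:
`retentionTimeIdx` holds one entry per scan — the *exclusive end offset*
of that scan's slice of `imsCoord` / `intensity` (no leading zero is
stored). Duplicate cells are summed at build time, zero counts dropped,
and coordinates are strictly increasing within a scan; `slice_scan()`
and the three extraction operations are binary searches over this
layout, which is semantically equivalent to an rtree for axis-aligned
queries without adding invariants.

On disk each window is one HDF5 group (`ms1`, `ms2-001`, … ordered by
ascending precursor centre, zero-padded to 3 digits) with the
coefficients as attributes/datasets and the three CSR datasets as
unsigned 32-bit, zlib level 6 (configurable). `metadataXML` is stored
as a UTF-8 string attribute: it is an mzML-style XML header, and the
package treats a printed integer type for it in earlier format
descriptions as an evident typo. The canonical layout is frozen in
`inst/extdata/toffee-manifest.txt` and checked byte-for-byte in the
tests.

Retention times are not stored per scan; the format keeps the linear
model `firstScanRetentionTimeOffset + scan * scanCycleTime`. On import
the cycle time is the median inter-scan interval, and inputs whose scan
times deviate from the linear model by more than 10% of the cycle time
raise a warning while the uniform model is still written — the one
place the representation is not faithful to arbitrary input. Intensity
values are rounded half-away-from-zero to integers with a warning beyond
1e-6 deviation, since TOF profile counts are integral at source.

## 4. What "lossless" means here

`export_run(import_run(S)) == S` for lattice-consistent spectra, over
non-zero samples: intensities and integer coordinates reproduce
**exactly**; reconstructed m/z values agree with the input to a few
units in the last place (measured ~1e-16–1e-15 relative, asserted at
1e-12). Bit-identity of the *coefficients* is not attainable in
general: the estimate is a least-squares fit to square roots that
already carry 1–2 ulp of round-off, so re-imported $\alpha,\beta$ match
the generating values to ~1e-12 relative rather than bitwise, and $\beta$
— the intercept extrapolated to index 0 from coordinates near $10^6$ —
amplifies ulp-level fit noise on data-poor scans to ~1e-9 √Da. The
round-trip tests compare integer fields exactly and coefficients at
those measured scales (1e-9 relative for $\alpha$, 1e-8 √Da for
$\beta$, estimable scans only).

## 5. Random access semantics

XIC bands are half-open `[mz_low, mz_high)` evaluated on reconstructed
m/z. Because coefficients differ per scan, the integer bounds of a band
may differ scan to scan; `extract_xic()` computes them from each scan's
own coefficients so the band is exact under drift, with
`use_median_ims = TRUE` as the documented fast approximation (good to
the few-ppm drift level; under the default drift of 1e-6 the
median-coefficient reconstruction deviates at most ~2 ppm, within the
5 ppm the field tolerates). Boundary indices are corrected against the
exact reconstruction predicate so they resolve identically to a
brute-force scan. All three extractors are pure views; the tests verify
them against brute-force triplet scans and against each other.

## 6. In-silico dilution series

Treating runs as triplets on a grid makes spike-in experiments a data
operation: `extract_foreground()` collects one peptide's raw samples
(MS1 precursor and MS2 fragment boxes, each covering the mono-isotope
and +1/+2 traces; apex = scan maximising the summed fragment XIC),
storing m/z rather than raw indices; `inject()` scales, re-grids onto
the *background* scan's own lattice (nearest index; deviation at most
half a step by construction), places at the nearest background scan to
the target retention time, and sums collisions. Scaled counts that
round to zero are dropped, emulating the instrument's lower limit of
detection — total intensity is otherwise conserved exactly, and the
injected peptide's apex XIC is linear in the dilution factor to within
integer rounding. The extraction box half-widths (30 s, 50 ppm) are
package defaults, configurable per query, as the reference material
does not state them. `label_detections()` scores a detection as a true
positive within 10 s of the injected retention time; with several
detections per peptide the nearest one claims the true positive,
within-threshold duplicates are redundant (not penalised), and
out-of-threshold detections count as false positives.

## 7. The analytic 2D peak model

Ion kinetic-energy spread makes a peptide peak approximately Gaussian in
m/z index space; the elution profile is left-skewed and is modelled as
log-normal in retention time:

$$ F_j = \frac{1}{t}\,\frac{a_j}{\sigma_t\sqrt{2\pi}}
\exp\!\left[-\frac{(\log t - \log t_0)^2}{2\sigma_t^2}
            -\frac{(m - m_{0,j})^2}{2\sigma_m^2}\right] + C_j, \qquad
C_j = c_j\,e^{-(m-m_{0,j})^2/(2\sigma_m^2)} $$

with the chemical-noise ridge $C_j$ included for MS1 fragments only
(the exponent uses $\sigma_m$; an inconsistent argument list in one
printed form of the model is resolved in favour of the formula). The
apex $t_0$ is shared across fragments — this is what lets the model
deconvolute co-eluting peaks — while $m_{0,j}$ is free per fragment to
absorb calibration offsets. Because the log-normal integrates to
$a_j$ over $t$, the fitted amplitude is the peak *area*, and
`requant_intensity = a_j`.

`fit_peak()` minimises $\sum_j \lVert F_j - I_j\rVert^2$ by bounded
Levenberg–Marquardt (trust-region-like damping via \pkg{minpack.lm})
with bounds $\sigma_t \in [10^{-3}, 2]$, $\sigma_m \in [0.1, 50]$,
$a_j, c_j \ge 0$, $t_0$ inside the raster's time range. Initial values
are deterministic moments of the raster ($t_0$ from the summed-fragment
apex, $m_{0,j}$ intensity-weighted means, spreads from second moments,
$a_j$ from apex $\times\, t_0 \sigma_t\sqrt{2\pi}$, $c_j = 0$); there
are no random restarts. Non-convergence raises a condition carrying the
best parameters and residual; all-zero rasters are rejected as
degenerate. Under the package's test conditions (1% apex-relative
Gaussian noise) the shared $t_0$ and the amplitudes are recovered well
within 2% and the spreads within 5%; noiseless rasters fit to
machine-level residual.

Cohort screening (`flag_outliers()`): spreads and locations are largely
systematic features of a run, so each feature ($\sigma_t$, $\sigma_m$,
and where available the retention-time and index offsets from their
expected values) gets a robust z-score (median/MAD); any feature beyond
the threshold (default 5) flags the fit. The rule and threshold are
package choices — no canonical rule exists for this step.

## 8. Peptide imaging

`render_peptide_image()` stacks one slice per ion (precursor from MS1,
fragments from the peptide's MS2 window), each with three channels at
isotope offsets $k \cdot \Delta_{13C-12C}/z$, $k = 0, 1, 2$
($\Delta_{13C-12C} = 1.0033548378$ Da). Fragment channels default to
charge 1 when the query does not specify fragment charges. Channels are
`extract_region()` views — exact counts, no normalisation — with a
default half-width of ±10 index steps; log-scaled 8-bit quantisation
happens only in the optional PNG export so the numeric rasters stay
exact.

## 9. The synthetic generator as study conditions

`synthetic_spec()` fixes the conditions every test runs under, chosen
once to emulate a small TripleTOF-like SWATH acquisition:

| parameter | default | rationale |
|---|---|---|
| isolation windows | 8 × 25 Da from 400 Da | small SWATH scheme |
| cycle time | 3.5 s | typical SWATH cycle |
| `base_alpha` | 4.07e-5 √Da/step | TOF spacing at m/z 400–900 |
| `base_beta` | 1.6e-5 √Da (∈ [0, α)) | canonical stored form |
| drift | 1e-6 fractional, smooth sinusoid per scan | stand-in for in-line calibration; the true drift magnitude is not published, so it is configurable and this value is an assumption |
| peptide apexes | 200–5000 counts | routine-intensity peptides |
| $\sigma_t$ | 0.03–0.07 (log-RT) | ~5–10 s elution widths |
| $\sigma_m$ | 1.5–3 index steps | TOF peak widths |
| isotope envelope | (1, 0.55, 0.22) | ~600 Da precursor-like |
| background noise | Poisson-placed 3-sample clusters, exponential counts (mean 5) | pragmatic, clearly non-physical stand-in |

Every sample lies exactly on its scan's lattice; peptide counts are the
analytic peak shape integerised (half-away) and zero-truncated; the
truth table accounts for every count, so total intensity is checkable
exactly. Noise clusters span 3 adjacent lattice points because a
detector reporting counts above threshold emits contiguous profile
points — isolated single samples would deny the estimator the adjacent
spacings it needs, a property of the emulation rather than a tuning
choice.

What passing tests on this generator show: the lattice arithmetic,
round trips, access semantics, conservation and recovery claims hold on
grid-consistent data with realistic sizes and drift. What they do not
show: behaviour on real chromatographic tailing, detector saturation,
centroided or Orbitrap data (out of scope), or real calibration-drift
profiles, none of which the generator attempts to model.

## 10. Problem sizes and determinism

The shipped tests and the acceptance script use runs of 4–40 cycles,
2–10 windows and 0–5 peptides — sizes chosen so the whole suite
exercises every code path in well under a minute while keeping every
check exact (oracle comparisons are equality, not tolerance, wherever
the quantity is integral). All randomness is seeded: the generator is
a pure function of its spec, `generate_peak_raster()` of its seed, and
the acceptance script derives every sub-seed from `--seed`.

## 11. Known limitations

* Orbitrap transfer functions and ion-mobility coordinates are out of
  scope; `IMSType` is stored to keep the file format forward-compatible.
* Per-scan retention times are not representable; jittered inputs are
  uniformised (with a warning).
* `estimate_scan_ims()` requires adjacent profile samples; sparse
  centroid-like scans fail by design.
* The dilution module constructs series and labels detections; scoring
  with a full peptide-centric search engine is outside the package.
* `fit_peak()` assumes one dominant peak per raster; heavily chimeric
  rasters rely solely on the shared-$t_0$ constraint for deconvolution.
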