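---
title: "Correlation-based mapping of visual-cortex proto-organization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based mapping of visual-cortex proto-organization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoconn)
```

## The problem this package addresses

Resting-state fMRI correlations can reveal the functional organization of
visual cortex even when visually evoked responses are weak or absent, as in
neonatal primates. The organizing observations are: (i) the same named area
in opposite hemispheres (a *homotopic* pair, e.g., left and right V1) shows
the strongest cross-hemisphere correlation; (ii) correlations fall off from
homotopic to adjacent to distal area pairs; (iii) the dorsal and ventral
quadrants of the early areas correlate preferentially with their
corresponding quadrant ("checkerboard" structure); (iv) correlations with V1
eccentricity bands recover a retinotopic eccentricity gradient across the
whole visual hierarchy; and (v) the area-by-area correlation network carries
a community and hierarchy structure that separates dorsal and ventral
processing streams. `protoconn` implements the full chain of analyses that
establish these observations, plus an instrumentation-noise null and the
Fourier analysis used for phase-encoded retinotopic and spatial-frequency
mapping, and couples them to a synthetic-data generator so that every stage
can be exercised and validated without scanner data.

## Temporal preprocessing of rest scans

`run_preprocess()` applies, per run: removal of the initial 5 TRs (scanner
onset transients); clipping of deviations beyond 2.5 SD of the voxel's run
mean; a zero-phase 4th-order Butterworth band-pass retaining 0.01–0.1 Hz
(applied forward–backward, so the effective magnitude response is the
squared Butterworth response); linear plus quadratic detrending; linear
regression of nuisance series (six motion parameters and their temporal
derivatives, a ventricle signal, a white-matter signal — the global mean
signal is deliberately *not* removed); and normalization of each voxel's run
to its mean. Two ordering points were genuinely open:

* **Trim first, normalize last.** Trimming before any statistic avoids
  onset transients contaminating means and SDs; normalizing last makes the
  final series dimensionless while leaving Pearson correlations unchanged
  (the step is affine per voxel and run). Because filtering and detrending
  leave a near-zero mean, the normalizer uses the voxel's pre-filter mean,
  captured after despiking, and returns `1 + x / m0`; voxels whose usable
  mean is below tolerance are flagged and excluded from seed averages.
* **Filtering versus nuisance regression order** is not determined by the
  method description; the default filters first, and
  `cfg$nuisance_before_filter = TRUE` switches the order.

The despike step clips to the threshold boundary rather than interpolating
a smooth replacement; clipping is simpler, monotone, and testable, and
differs from interpolation only at the clipped samples.

The mean is removed before the band-pass: DC lies outside the pass band
anyway, and filtering an offset series forward–backward would otherwise
inject a large baseline-proportional edge transient shared across voxels —
exactly the kind of spurious common signal the pipeline exists to avoid.

## Balanced seed correlations and the areal correlation profile

All seed analyses use 16 retinotopic areas per hemisphere. Because area
sizes differ, every mean signal is computed after subsampling each area
(without replacement) to the smallest area's voxel count; 100 subsample
iterations are drawn, correlations are computed per iteration, and the raw
(not Fisher-transformed) correlation coefficients are averaged across
iterations. When all areas happen to have equal size the subsample is the
identity and one iteration suffices.

The *areal correlation profile* is a second-order similarity: each seed
area's row of the within-hemisphere 16×16 matrix (self-correlation of 1
included, so the template prefers its own area) is correlated with each
contralateral voxel's 16-vector of area correlations. The result is masked
to voxels whose raw temporal correlation with the seed exceeds r = 0.15 —
the threshold that corresponds to t(1628) = 6.12 / t(1394) = 5.66 at
representative session lengths (`r_to_t()` reproduces these conversions). Pearson correlation is the default for the profile similarity
(matching the first-order analyses); Spearman is available via `method`.
Degrees of freedom are recorded as T − 2 over the concatenated retained
timepoints; trimming and filtering reduce the effective df in ways this
simple bookkeeping does not capture, so the recorded value is a
convention, not an inferential claim.

Pair groupings symmetrize over direction (left-A/right-B averaged with
left-B/right-A) before statistics. The cortical adjacency table that
distinguishes "adjacent" from "distal" pairs ships as an editable TSV
(`inst/extdata/area_adjacency.tsv`); which areas count as cortical
neighbors is an anatomical convention, so the table is versioned,
editable data rather than code.

## V1 eccentricity-band mapping

V1 is divided into 8 bands evenly spaced in cortical distance up to 10°.
Band-to-voxel correlation curves (balanced by subsampling to the smallest
band, 100 iterations) are fit with `A0 + A1·exp(−((x−B1)/C1)²)` over band
index x; the preferred band is B1. A voxel passes when the curve value at
the band nearest the peak reaches 0.15, and voxels are pre-selected by an
omnibus regression on the band means with F > 20. Fit initialization
(A0 = min, A1 = range, B1 = argmax, C1 = 2 bands) and bounds
(B1 ∈ [0.5, 8.5], C1 ∈ (0.3, 20]) prevent degenerate flat fits; these
choices are exposed rather than silent. Band index converts to degrees via
the band-center eccentricities of the parcellation, since even spacing in
cortical distance need not be even in degrees. `map_deviation()` compares
two per-voxel eccentricity maps by mean absolute deviation per area group,
excluding the seed area V1.

## Structure of the areal correlation network

The 16×16 matrix (symmetrized over direction) is converted to Euclidean
row-profile distances. Three views are computed:

* **Metric MDS under Kruskal's normalized stress-1**, minimized directly
  with BFGS from a classical-scaling start plus 20 random restarts (best
  kept, seed logged). This mirrors MATLAB's `mdscale` default criterion;
  `MASS::isoMDS` is *non-metric* and therefore not used.
* **Leading-eigenvector modularity** (Newman's spectral bisection with the
  generalized modularity matrix; refinement passes are deliberately
  omitted, so the plain algorithm is the default). Negative
  weights are clipped to zero by default, standard for correlation
  networks; `signed = TRUE` switches to signed modularity. The igraph
  implementation serves as an independent cross-check in the tests, never
  as the implementation.
* **Ward hierarchy** (`hclust` ward.D2, equivalent to MATLAB's Ward on
  Euclidean input) with the cophenetic correlation, a MATLAB-style
  inconsistency statistic (each link's height against the mean and SD of
  link heights within 2 levels below it; the depth is configurable), a cut
  at inconsistency 1.0, and an optimal leaf ordering computed by dynamic
  programming over subtree flips (minimizing summed adjacent-leaf
  dissimilarity).

A structural fact worth recording: for a *balanced* subtree whose root
merges two equal-height children, the inconsistency statistic is computed
from a 3-element height set and concentrates near 1.07–1.16 whenever the
root clearly exceeds its children — straddling the conventional 1.0 cutoff
regardless of noise level. A flat (equicorrelated) planted cluster of four
areas therefore yields an unstable cluster count. Real areal hierarchies
are not flat: their within-cluster merge heights are staggered. The
generator's `hierarchy_area_template()` reproduces that stagger (members
attach to the cluster core progressively more weakly), under which the
five-cluster cut is stable. This is a property of the inconsistency
statistic itself, not of this implementation — scipy's `inconsistent` and
`fcluster` reproduce the same values and the same splits, and are frozen
into the test suite as an oracle.

## Instrumentation-noise null

`simulate_noise_volume()` draws i.i.d. Gaussian noise per voxel-timepoint
and smooths each timepoint spatially with a Gaussian kernel of 3.5 mm FWHM
on the voxel coordinates, emulating the intrinsic spatial spread of the
fMRI signal with no neural structure. `run_null_pipeline()` passes such
data through the identical preprocessing and correlation path. Smoothing
cannot bridge the hemispheres (their blocks are separated by far more than
3·FWHM), so across-hemisphere null correlations are centered on zero with
approximately the Fisher 1/√(T−3) spread, while within-hemisphere
correlations acquire a spatial-proximity bias only — the control logic
that licenses the across-hemisphere analyses. Null magnitudes are often
quoted relative to real-data correlations; without reference recordings
such ratios are not computable, so the module reports absolute null
summaries. The expected voxel-pair correlation under
smoothing is computed exactly from the discrete, truncated, row-normalized
kernel (inner products of kernel rows) rather than from the continuous
Gaussian closed form, which is only approximate on a grid.

## Phase-encoded Fourier mapping

For each voxel the DFT of the mean-normalized series gives amplitude and
phase at the stimulus harmonic (e.g., 8 cycles per run of 40 s each);
phases are rotated backward by 2π·lag/period for a 4 s hemodynamic lag.
Significance is the F-ratio of power at the stimulus bin to mean power
across noise bins with (2, 2K) degrees of freedom. "All other frequencies"
leaves the exclusion set unstated; the default excludes DC, bins 1–2
(drift), the stimulus bin ± 1, and the 2f/3f harmonics, and the set is
configurable and recorded. Counterclockwise/expanding runs are negated
(mod 2π) and combined with clockwise/contracting runs by circular mean;
multiple runs are averaged in the complex domain. Decoding inverts the
linear phase-to-stimulus map; the spatial-frequency sweep decodes onto the
descending 8-step ladder (3, 2, 1, 0.8, 0.5, 0.4, 0.2, 0.1 cycles/degree)
interpolated on a log scale. Eccentricity and spatial-frequency paradigms
often insert 10 s blanks between cycles to separate foveal and peripheral
responses; the synthetic default omits blanks, and when data with blanks
are supplied, blank TRs are excised before the DFT and the cycle length
recomputed. Neither convention is privileged; both are available.

Block designs (20 s blocks, 20 s neutral gaps) are analyzed by OLS on
boxcars convolved with a MION (iron-oxide contrast) response kernel — a
sign-inverted, peak-normalized gamma variate t^8.6·e^(−t/0.547), a standard
shape for iron-oxide contrast in monkey fMRI; no single functional form is
canonical, so the kernel is config-overridable. Betas are scaled to percent signal change via per-run
mean normalization. Tuning-versus-eccentricity fits are unweighted lines
through the *bin means* (1° bins within the central 8°, bins under 5 voxels
dropped, areas with ≥ 2 unusable bins excluded); fitting bin means rather
than voxels compensates for the
uneven voxel distribution across eccentricity produced by cortical
magnification.

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions used throughout the tests and the acceptance script. Each
(hemisphere × area × quadrant × eccentricity-band) cell carries one latent
signal; a voxel inherits its cell's latent plus i.i.d. Gaussian noise —
the minimal model that matches every grouping the analyses use. The latent
correlation between two cells is the product of four factors:

| factor | default | meaning |
|---|---|---|
| area template | adjacent 0.5; nested communities 0.45 (five-group) / 0.30 (three-group); distal 0.10 | cortical neighborhood and stream structure |
| quadrant | ×0.6 when dorsal meets ventral | upper/lower-field segregation |
| eccentricity | exp(−Δband²/(2·1.5²)) | retinotopic gradient, width in bands |
| hemisphere | ×0.9 across hemispheres | homotopic (callosal) coupling |

The product matrix is projected to the nearest positive-semidefinite
correlation matrix by eigenvalue clipping. Latents and noise optionally
pass an AR(1) filter (coefficient 0.3) so band-pass filtering has a
realistic effect; rest-scan noise spectra vary across acquisitions, so
the AR(1) default is an assumption exposed in the configuration. Defaults were chosen once as plausible for neonatal rest
data — homotopic area-mean correlations near 0.7–0.8, adjacent near 0.4,
distal near 0.1, matching the qualitative ordering the analyses report —
and the default rest session is 2 runs × 150 TR at TR 2 s (≈ 5 min runs,
typical of 4–6 minute neonatal rest runs); recovery analyses
use a single 2000-TR run where the tests call for a long-T condition.
Eccentricity runs 0–10° linearly in cortical distance; cortical
magnification is deliberately not modeled, so band centers are evenly
spaced in degrees as well — analyses that convert bins to degrees use the
parcellation's band centers and remain correct under any monotone mapping.

What the generator does *not* emulate: hemodynamic nonlinearity,
physiological (cardiac/respiratory) noise, scanner drift beyond what
detrending removes, motion, eye movements, cortical-surface geometry, and
realistic voxel counts. Passing tests therefore show that the analysis
chain recovers planted structure of the kind the method assumes — they do
not certify performance on real scanner data.

## Problem sizes and numerical choices

The bundled demo configuration uses 16 voxels/area (512 voxels), 2 × 150
TR rest runs, 20 subsample iterations, and completes the full pipeline in
a few seconds; recovery-style analyses in the tests and acceptance script
use single 2000-TR runs and 20 seeds, chosen so the whole suite documents
the method's behavior at comfortably interactive scale. Numerical
tie-breaks and tolerances: PSD projection clips eigenvalues at 0 and
rescales to unit diagonal; the Cholesky draw adds 1e-10 jitter; MDS
treats coincident points with an epsilon guard; constant series produce
NaN correlations with a warning rather than an error; and the Gaussian
peak fit reports non-convergence explicitly (`converged = FALSE`) instead
of silently failing.

## Known limitations

Registration, surface reconstruction, spatial ICA, and eye-tracking are
out of scope; parcellations are inputs. The df bookkeeping after filtering
is conventional (T − 2). The inconsistency-cut cluster count is inherently
sensitive to balanced subtrees (see above). Real-data effect sizes (e.g.,
homotopic t(15) > 18, ANOVA F values, the 2.2°/2.0°/1.4° map deviations)
depend on recordings that are not publicly deposited and are not
reproduced here; the package reproduces the analytic threshold conversions
exactly and the structural findings as planted-recovery properties.
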