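---
title: "Quantifying RNA-peptide coacervate dynamics with coacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA-peptide coacervate dynamics with coacdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacdyn)
```

## Scope

Complex coacervates formed by ribozymal RNA and short cationic peptides
(oligoarginine, oligolysine, RGG/KGG repeats) are characterized by a small
set of quantitative readouts: molecular mobility from fluorescence recovery
after photobleaching (FRAP), droplet-scale rheology from coalescence
relaxation, RNA subdomain persistence from two-colour correlation, phase
boundaries from turbidity titrations, RNA partitioning from plate-reader
fluorescence, ribozyme activity from gel densitometry, and the chemical
environment (Mg^2+^ partitioning) from isothermal titration calorimetry
(ITC). `coacdyn` implements each of these analyses as a tested pipeline
stage, together with a synthetic-data generator that produces every input
with known ground truth, so the whole stack is verifiable without access to
raw microscopy or calorimetry archives.

## Image conventions

Frames are numeric matrices indexed (row, col) with 1-based pixel-centre
coordinates — the native R convention; positions reported by the
segmentation are therefore directly usable as matrix indices. All times are
seconds, lengths micrometres (converted from pixels only through the
`pixel_size` metadata attached at read time), and intensities arbitrary
units. TIFF is the only image format read or written: the writer quantizes
to 8/16-bit on the [0, 1] scale, and a value already on that grid
round-trips bit-exactly. Vendor metadata containers (CZI, ND2) are out of
scope; acquisition parameters come from the run configuration.

## Droplet segmentation and tracking

`segment_frame()` thresholds a frame, labels connected components, and
derives per-droplet descriptors from image moments: intensity-weighted
centroid, equivalent-disk radius $\sqrt{A/\pi}\,\cdot$ `pixel_size`, and
major/minor axes from the second-moment eigenvalues. Three threshold
policies are available:

* **otsu** (default) — parameter-free, appropriate for droplets of roughly
  uniform interior intensity;
* **quantile** — a fixed intensity quantile, for scenes with a known
  sparse foreground;
* **relative** — a fixed fraction (default 0.15) of the robust intensity
  range (0.1%–99.9% quantiles) above the floor. This exists because Otsu's
  bimodal assumption fails when droplets carry strong *interior* structure
  (e.g. two-colour domain patterns): the background class dominates the
  histogram and the threshold can land inside the droplet, splitting it.

All three are invariant to affine intensity transforms. Moment-based axis
estimates are accurate to ~2% for radii of 20 px and above and ~5% near
10 px; tests pin both bounds.

`track_droplets()` links centroids greedily to the nearest next-frame
centroid within `max_step` (default 2 um/frame — droplets in these
experiments are nearly static), with ties broken by smaller label index so
linking is deterministic. A next-frame droplet within `max_step` of two or
more track heads is interpreted as a coalescence: both parents terminate
and a new track starts carrying `merged_from`, which is exactly what the
fusion analysis consumes. No motion model is used; fast-moving droplets
would need one.

## FRAP

Four regions of interest are measured per frame: bleach region, whole
droplet, unbleached reference droplet, and background. Normalization is a
fixed pipeline: subtract background; divide bleach and whole-droplet traces
by the reference (cancelling acquisition photobleaching and any common
illumination drift); normalize each to its pre-bleach mean (20 frames by
default); divide bleach by whole droplet. The result is invariant to common
additive offsets and common multiplicative time-varying gains, which the
test suite asserts as a property.

The post-bleach curve is fitted to

$$f(t) = 1 - A\,e^{-(t - t_\mathrm{bleach})/\tau} + C,$$

with $A$ the bleach depth and $C$ the offset to complete recovery. $C$ is
free by default and fixed to 0 when the operator asserts that full recovery
was not observed (`fix_C = TRUE`), mirroring the reporting convention of
the underlying experiments. Initialization: $A$ from the first post-bleach
value, $\tau$ from the time to half recovery, $C = 0$. A curve whose
post-bleach amplitude is below 0.02 is flagged `amplitude_unidentifiable`
rather than fitted — $\tau$ is meaningless there.

The time constant converts to an apparent diffusion coefficient through the
experimentally calibrated half-time relation

$$D = \frac{0.88\, r^2}{4 \tau \ln 2},$$

with $r$ the bleach-region radius. The 0.88 prefactor is used verbatim; it
is an empirical constant of this relation, not derived here. Per-droplet
coefficients are averaged and reported with a t-based 95% confidence
interval.

`analyze_frap_movie()` runs the whole chain on a movie. The bleach frame is
detected as the sharpest frame-to-frame intensity drop of a droplet trace
relative to its pre-bleach level — a global minimum would be confounded by
slow acquisition photobleaching — and a fixed frame index can be supplied
instead when the protocol pins it. The bleached droplet is the one with the
largest drop, the reference the one with the smallest.

## Fusion rheology

Coalescing pairs relax to a sphere; the aspect ratio AR(t) = major/minor is
fitted to $A e^{-t/\tau} + c$, with $c$ the offset to a perfect sphere,
initialized at 1 and bounded away from absurdity; $|c - 1| \ge 0.2$ flags a
segmentation problem. The fit window starts at the first post-merge frame
and ends when AR < 1.05 (or the series ends) — beyond that point the signal
is indistinguishable from segmentation noise. Pre-fusion radii are taken
from the last frame before the merge.

The inverse capillary velocity $a = \eta/\gamma$ is the slope of
$\tau(r) = a\,r$ over events, with $r = \sqrt{r_1 r_2}$ the geometric
radius and the intercept fixed at 0. The closed form
$a = \sum \tau_i r_i / \sum r_i^2$ is verified in tests against a
brute-force grid minimizer; degenerate designs (all radii equal, single
event) reduce to the documented closed forms.

## Two-colour mixing

Per droplet and timepoint, the Pearson coefficient between the two
channels is computed **within the droplet mask only**: including background
pixels would inflate the correlation through the shared droplet/background
contrast regardless of interior mixing, which is exactly the artifact this
measurement must avoid. Across droplets the mean is reported with a t-based
95% CI computed on Fisher z-transformed coefficients (the coefficient is
bounded and skewed) and back-transformed. The time course is fitted with a
single exponential $\rho(t) = A e^{-t/\tau} + \rho_\infty$ as a guide.

The default droplet mask comes from segmenting the *time-averaged* summed
two-channel image with the relative threshold: averaging removes the
interior domain structure, and droplets are effectively static on the
30-minute sampling grid. For moving droplets, per-timepoint masks can be
passed explicitly.

## Turbidity, partitioning, stoichiometry

Absorbance at 500 nm converts to turbidity as
$100 - 10^{(2 - A)}$ (i.e. $100 - \%T$). Phase-boundary curves against the
amino-acid/nucleotide ratio are fitted with the exponentially modified
Gaussian

$$f(x) = A_1 \sigma\, e^{\sigma^2/(4\tau^2)}\, e^{-(x - x_0)/\tau}
  \left(1 + \operatorname{erf}\!\left(\frac{x - x_0}{\sigma}
  - \frac{\sigma}{2\tau}\right)\right),$$

whose sigmoidal rise (inflection $x_0$, width $\sigma$) captures
coacervation onset and whose exponential tail (constant $\tau$) captures
dissolution at peptide excess; the same form serves ICP-MS magnesium
content curves. In the slow-decay limit the shape reduces to an
erf-sigmoid with half-rise at $x_0$, which the tests use as an independent
oracle. Initialization: $x_0$ at the half-max rise, $\tau$ from the
peak-to-half-decay distance, $\sigma$ at a quarter of the rise width.

Partitioning and ligated-fraction curves are fitted with the Hill equation
$F_\mathrm{min} + (F_\mathrm{max} - F_\mathrm{min})/(1 + (F_\mathrm{half}/x)^n)$,
optionally weighting points by the reciprocal of their standard deviation
and constraining $F_\mathrm{min} = 0$ (the variant used for sequestration
curves). The Hill coefficient is bounded in [0.1, 50]; a fit pinned at a
bound is flagged rather than silently returned — the data then do not
constrain cooperativity.

Monomer stoichiometry reduces a species table to nucleotide and amino-acid
totals ($\sum c_i \ell_i$ per class). The default ligase mix — 5 uM of a
66-nt enzyme strand plus 6 uM of an 18-nt substrate — totals 438 uM
nucleotide; the strand lengths are chosen to satisfy exactly that total,
with the substrate length anchored at 18 nt by its non-base-pairing
same-length control (AC)~9~. A separate charge/nt ratio counts charged
monomers only. The combinatorial plausibility factor of a heteropeptide
(k cationic residues on an n-mer) is the exact falling factorial
$n(n-1)\cdots(n-k+1)$.

## ITC heat accounting

Injection series carry their schedule and cell/syringe metadata; the first
0.2 ul priming injection is discarded per protocol. The molar-ratio axis
uses the standard perfusion (overflow) cell model — each injection dilutes
the cell analyte and previously delivered titrant by $(1 - v/V)$ — a
convention choice that cancels in the matched-schedule comparisons below.
Units are arranged so no conversion constants appear:
uJ / (mM $\times$ ul) is exactly kJ/mol.

The total binding heat is the sum of blank-subtracted injection heats
normalized by moles of analyte monomer (nucleotide) in the cell.
Incomplete titrations are continued by refilling the syringe;
`stitch_refills()` concatenates parts with the cumulative accounting
carried across the seam and rejects out-of-order parts.

The magnesium-release comparison is pure enthalpy bookkeeping, with no
binding-isotherm model: $\Delta\Delta H = \Delta H_\mathrm{Pep-Mg} -
\Delta H_\mathrm{Pep+Mg}$, and under competitive replacement
$\Delta\Delta H = f \cdot \Delta H_\mathrm{Mg}$ with $f$ the release
fraction; $f \approx 1$ means the peptide displaces all RNA-bound Mg^2+^.
Uncertainties propagate first-order from replicate spread.

## The synthetic-data generator

Every stage has a generator that writes the same structures the analysis
consumes, with the ground truth serialized beside the data and all
randomness fixed by one seed. Design choices:

* **FRAP movies** encode the exponential recovery law directly — the bleach
  disk follows $1 - A e^{-(t - t_b)/\tau^*}$ with
  $\tau^* = 0.88 r^2/(4 D^* \ln 2)$ inverted from the diffusion relation,
  under a global photobleaching decay and Gaussian read noise. The pipeline
  under test is the normalization/fit stack, not the photophysics; a
  Brownian-dynamics mode would test a different thing. Defaults mirror the
  experimental acquisition: 200 ms frames over 3 min, 20 pre-bleach frames,
  1 um bleach radius. The idealized trace set returned alongside the movie
  takes the small-bleach-ROI limit, so its normalized curve is exactly the
  embedded exponential; in the rendered movie the bleach disk occupies a
  finite droplet fraction, which biases the whole-droplet normalization at
  second order — this is why trace-level recovery is tested at 1% and
  movie-level at 25%.
* **Fusion movies** merge two disks into an area-conserving ellipse whose
  aspect ratio relaxes as $1 + (AR_0 - 1)e^{-t/\tau^*}$,
  $\tau^* = a^* \sqrt{r_1 r_2}$; the trace-level generator draws radius
  pairs and emits noisy AR series for capillary-fit studies.
* **Mixing scenes** start from anti-correlated half-droplet domains and, in
  liquid mode, relax the inter-channel correlation exponentially toward the
  mixed state with time constant $\tau^*$ — the decay of the fundamental
  diffusive mode of the domain pattern, realized exactly by mixing
  orthonormal within-mask patterns at analytic weights (gel mode freezes
  the weights). This makes $\tau^*$ an exact ground truth rather than a
  byproduct of a blur schedule. Defaults: 9 timepoints every 30 min.
* **ITC experiment sets** generate per-injection heats as increments of a
  saturating coverage curve scaled so the designed totals hold, and build
  the $\pm$Mg pair so $\Delta\Delta H = f\,\Delta H_\mathrm{Mg}$ by
  construction (default $\Delta H_\mathrm{Mg} = -2.9$ kJ/mol nucleotide,
  39 x 1 ul injections).
* **Gel lanes** are Gaussian bands over a uniform background realizing a
  chosen ligated fraction.

What passing these tests shows — and does not. The generators share the
functional forms with the fitters, so parameter-recovery tests validate
the normalization chains, estimators, initializations and error handling,
not the adequacy of single-exponential recovery or EMG shapes for any
particular real dataset. Real data additionally contain model mismatch
(anomalous diffusion, non-spherical droplets, baseline drifts in ITC) that
these tests deliberately do not emulate.

## Numerical choices

All nonlinear fits use Levenberg-Marquardt (minpack.lm's `nls.lm`) with
box constraints, analytic-free numeric Jacobians, and `ftol` near machine
precision; the driver is called directly so that zero-residual (noiseless)
fits are handled cleanly. Covariances are moment-based,
$\hat\sigma^2 (J^\top J)^{-1}$, and degenerate exactly when residuals
vanish. Degenerate inputs are contracts, not accidents: flat FRAP curves
and spherical fusion tracks are flagged unidentifiable; monotone titration
data are flagged `no_peak`; constant channels yield a missing Pearson
coefficient; empty gel lanes yield a missing fraction with a warning.
Tie-breaks in tracking are by label index; all stochastic tests fix seeds.

Problem sizes in the shipped tests and acceptance script (3 diffusion
regimes x 10 movies at 64x64 px, 20 fusion events, 20 mixing scenes,
50-seed curve-fit Monte Carlo, 78-injection titrations) were chosen as the
smallest designs at which the Monte-Carlo error is comfortably inside each
stated tolerance.

## Known limitations

No watershed splitting of touching (non-fusing) droplets; no 3-D
segmentation; no reaction-diffusion FRAP models; no binding-isotherm
fitting ($K_d$, site models) for ITC; no Manders or spatial-autocorrelation
colocalization metrics; no molecular-weight calibration for gels. The
greedy tracker assumes near-static droplets between frames.
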