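# coacdyn

Quantitative analysis of RNA–peptide coacervate dynamics in R.

Complex coacervation — liquid–liquid phase separation of oppositely charged
polyelectrolytes — lets catalytic RNA (ribozymes) and short cationic
peptides (R₉, K₉, (RGG)ₙ, …) form membrane-free droplet compartments.
Whether such a droplet behaves as an RNA gel or a liquid, and whether it
retains the Mg²⁺ that ribozymes need, is decided by peptide sequence and
read out through a handful of quantitative assays. `coacdyn` implements
those assays as tested pipeline stages for researchers working on
condensate biophysics and origin-of-life protocell models:

* **Droplet image analysis** — segmentation (Otsu/quantile/relative
  thresholds), moment-based shape descriptors, greedy nearest-centroid
  tracking with explicit fusion (merge) handling.
* **FRAP** — four-ROI normalization (background, photobleaching reference,
  pre-bleach window, whole-droplet), recovery fit
  `f(t) = 1 − A·exp(−(t − t_bleach)/τ) + C`, and the apparent diffusion
  coefficient `D = 0.88 r² / (4 τ ln 2)` with t-based 95% CIs across
  droplets; whole-droplet (mask-based) FRAP for slow RNA recovery.
* **Fusion rheology** — aspect-ratio relaxation `A·exp(−t/τ) + c` per
  coalescence event and the inverse capillary velocity η/γ as the slope of
  `τ(r) = a·r` over the geometric radius `r = √(r₁r₂)`, intercept fixed
  at 0.
* **Two-colour mixing** — per-droplet Pearson correlation between channels
  (inside the droplet mask only), Fisher-z aggregated, with an exponential
  decay fit for the mixing time.
* **Titration curves** — absorbance→turbidity conversion
  `100 − 10^(2−A)`, exponentially-modified-Gaussian fits for phase
  boundaries (and ICP-MS Mg²⁺ curves), Hill fits for partitioning and
  activity curves, a.a./nt stoichiometry, and the combinatorial
  plausibility factor of heteropeptides.
* **ITC** — injection-heat series with perfusion-cell dilution accounting,
  blank subtraction, syringe-refill stitching, total heats in kJ/mol
  monomer, and the ΔΔH = ΔH_Pep−Mg − ΔH_Pep+Mg magnesium-release
  comparison.
* **Gel densitometry** — lane profiles, rolling-minimum background, ligated
  fraction I_P/(I_P + I_S1).
* **Synthetic data** — a generator for every stage (`sim_*`) with exact
  ground truth and seed-reproducible output, so the full stack is testable
  without microscope or calorimeter archives.

## Worked example

Simulate a FRAP movie with a known diffusion coefficient and analyse it
end-to-end (segmentation → ROI traces → normalization → fit → D):

```r
library(coacdyn)

sim <- sim_frap_movie(D_star = 0.1, seed = 1)   # ground truth: 0.1 um^2/s
res <- analyze_frap_movie(sim$stack, bleach_radius_um = 1)
res
#> <frap_analysis> bleach frame 21, tau = 3.011 s, D = 0.1054 um^2/s
res$fit
#> <frap_fit> A = 0.5494, tau = 3.011 s, C = -0.0003114
```

The bleach was placed after the 20 pre-bleach frames (frame 21 detected
automatically), the fitted recovery time constant is 3.0 s, and the
resulting apparent diffusion coefficient 0.105 µm²/s — within ~5% of the
embedded truth, the residual bias coming from the finite bleach-spot
fraction of the droplet. Averaging several droplets:

```r
D <- summarize_diffusion(vapply(1:5, function(s) {
  m <- sim_frap_movie(D_star = 0.1, seed = s)
  analyze_frap_movie(m$stack, bleach_radius_um = 1)$D
}, numeric(1)))
D
#> <diffusion_estimate> D = 0.1052 um^2/s, 95% CI [0.105, 0.1054], n = 5
```

Fusion rheology from ten synthetic coalescence events generated at an
inverse capillary velocity of 220 s/µm (the scale of gel-like
arginine-peptide droplets):

```r
se   <- sim_fusion_events(n_events = 10, a_star = 220, seed = 2)
taus <- vapply(se$events, function(e)
  coef(fit_relaxation(e$ar, e$time_s))[["tau"]], numeric(1))
cf <- capillary_velocity(data.frame(
  r_geo = vapply(se$events, function(e) sqrt(e$r1 * e$r2), numeric(1)),
  tau   = taus))
cf
#> <capillary_fit> inverse capillary velocity a = 218.8 s/um, 95% CI [217, 220.6], 10 event(s)
```

And the closed-form stages:

```r
turbidity_from_absorbance(c(0, 1, 2))
#> [1]  0 90 99
mixture_stoichiometry(r3c_standard_mix())$nt_uM   # 5 uM x 66 nt + 6 uM x 18 nt
#> [1] 438
combinatorial_factor(12, 4)                        # 12-mer with 4 cationic residues
#> [1] 11880
```

## Documentation

The methods vignette (`vignettes/coacervate-analytics.Rmd`) describes the
models, their assumptions, parameter defaults and units, what the
synthetic-data generator does and does not emulate, numerical choices, and
known limitations. Function-level documentation lives in the roxygen
comments in `R/`.
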