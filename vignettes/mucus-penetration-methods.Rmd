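---
title: "Quantifying bacterial penetration into mucus droplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial penetration into mucus droplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucotrace)
```

## The measurement problem

In ex vivo mucus-barrier assays, a droplet of purified intestinal mucus sits
in a shallow imaging chamber surrounded by a suspension of motile fluorescent
bacteria. Over two hours of time-lapse imaging, bacteria either penetrate the
droplet — visible as fluorescence spreading inward from the interface — or
are halted and aggregate at its periphery. `mucotrace` turns such image
stacks into two quantitative readouts:

1. **Penetration length `lambda_p`.** Around the annotated droplet boundary,
   the mean fluorescence intensity is computed on concentric rings spaced one
   pixel apart (each ring's sum divided by its number of in-bounds pixels).
   From the maximum of this radial profile, the interior portion is fitted
   with an exponential decay

   $$y(x) = A e^{-\lambda x} + B, \qquad x = r_{\mathrm{peak}} - r \ge 0,$$

   and the penetration length is $\lambda_p = 1/\lambda$: the characteristic
   distance over which the bacterial signal decays inward of its interfacial
   maximum. `A` is the decaying amplitude, `B` the interior plateau
   (background plus any uniformly distributed signal). The fit runs in
   physical units (micrometres), so `lambda_p` is calibration-independent.

2. **Normalized radial aggregation profile `P1`.** Frames are binarized with
   the Triangle (Zack) histogram threshold; connected components
   (8-connectivity) with area strictly greater than 27 µm² — roughly ten
   bacteria — count as aggregates. The droplet interior is divided into 10
   concentric annuli of equal radial step $\Delta r = r_{\mathrm{middle}}/10$
   and the exterior into annuli of the same step. Per annulus,
   $P^1 = (A_C / A_T)\,/\,\Delta r_{\mathrm{norm}}$ with $A_C$ the aggregate
   (white-pixel) area in the annulus, $A_T$ the in-bounds annulus area, and
   $\Delta r_{\mathrm{norm}} = \Delta r / R = 0.1$ the dimensionless step.
   A separate summary, the total exterior fraction, is the white-pixel
   fraction of the whole exterior region (all white pixels, not only
   size-filtered aggregates — deliberately, as that is how the summary
   measurement is defined; a filtered variant is available by passing a
   filtered mask).

## Reference geometry from the annotated boundary

Droplet boundaries are annotated manually as vertex polygons (CSV vertex
lists or ImageJ-dialect `.roi`). All circular reference geometry shares one
center, the polygon's area centroid:

* `r_inner`: radius of the largest centered circle inside the polygon
  (minimum centroid-to-edge distance);
* `r_outer`: radius of the smallest centered circle containing all vertices;
* `r_middle = (r_inner + r_outer)/2`, the boundary that splits interior from
  exterior;
* `R := r_middle`, the droplet radius used for the `r/R` axis.

A free-center maximal inscribed circle could be slightly larger, but rings,
annuli and the interior/exterior split must all be concentric for the radial
statistics to be consistent, so the common centroid is used throughout. Radial
ring assignment is `round(distance)` in pixels; annulus bins are half-open
`[k dr, (k+1) dr)` on the exact (un-rounded) distance. Partial fields of view
are first-class: every per-ring and per-annulus statistic uses in-bounds
pixels only, and exterior annuli are enumerated to the image edge.

## Preprocessing

Background removal follows the rolling-ball idea: the background is the
grayscale morphological opening of the frame with a disc of radius 50 px
(configurable), and is subtracted with clipping at zero. For synthetic frames
with flat illumination there is no background to remove and the step can be
disabled (`analysis_config(subtract_bg = FALSE)`). The Triangle threshold
uses 256 histogram bins over the observed intensity range; the far tail end
is the last non-empty bin on the side of the peak with the longer tail, and
distance ties break toward the peak (the lower threshold for dark-background
images, keeping faint aggregates). Foreground is strictly above the
threshold. Whether real frames should be binarized before or after background
subtraction is ambiguous; the pipeline binarizes the background-subtracted
frame and exposes the switch.

## Fit initialization, gates and degenerate inputs

The bounded Levenberg–Marquardt fit starts from `B0 = min(y)`,
`A0 = y(0) - B0`, `lambda0 = ln 2 / x_half` (first half-amplitude crossing),
with constraints `A >= 0`, `lambda > 0`, `B >= 0`. A fit is reported only
when all quality gates pass (`fit_ok`); otherwise `lambda_p` is undefined:

* at least 5 profile points inward of the peak (fewer is an error, not a
  failed fit);
* a decaying amplitude exists (`A0 > 0`);
* the optimizer converges with `lambda` off its lower bound;
* `r_squared >= 0.2`;
* `lambda_p` is at least the profile's radial spacing — a "decay" shorter
  than one ring is unresolvable and indicates a step artifact, which is
  exactly what inert-particle control scenes produce (particles pile up
  outside the boundary and the interior is flat).

The gates are package choices (the measurement procedure itself prescribes
none) and are configurable and logged. Peak location takes the argmax of the
profile up to `r_outer`, with ties broken toward the largest radius, since
the physical peak sits at the interface.

## The synthetic scene generator

The generator produces time-lapse stacks with fully known ground truth so
that every stage of the pipeline is verifiable without real data. It
emulates the *statistical image structure* the analysis assumes — not
bacterial dynamics (no run-and-tumble, chemotaxis or rheology). The expected
intensity at signed inward distance `s` from the boundary is

* exterior (`s < 0`): a suspension plateau
  `exterior_density * pixel_size^2 * per_bacterium_intensity` plus a
  half-Gaussian accumulation layer (amplitude `interface_peak_amplitude`,
  width 12 µm) whose maximum sits on the boundary and which extends outward
  only: bacteria that cannot cross the boundary pile up on its exterior
  side. Rendering the layer symmetric would double-count accumulation into
  the interior and contradict the pure-exponential interior model that the
  fit assumes.
* interior (`s > 0`): `B + A exp(-s / lambda_p(t))`.

With `shot_noise = TRUE` (default) the signal is realized as discrete
Poisson point emitters of intensity `per_bacterium_intensity` whose rate
reproduces that expectation — penetrating bacteria are sparse bright dots,
as in real images, so the 27 µm² filter removes them unless they clump.
With `shot_noise = FALSE` the deterministic expected field is rendered
(used by closed-form tests). Aggregates are filled discs with lognormal
areas; real aggregates are irregular, but area — the only quantity the
analysis uses — is exact for discs. Their radial placement law defines the
phenotypes: `exterior_peaked` concentrates discs just outside the middle
boundary, `interior_peaked` just inside with a tail reaching ~50% of the
radius. Frames end with optional Gaussian read noise and digitization to
integer counts in `[0, 65535]` (16-bit camera).

Defaults and their rationale:

* image 2048×2048 px at 1.3 µm/px (5X objective on a 6.5 µm sensor pitch),
  frames every 2 min — the reference acquisition; tests and the analysis
  scripts use 512×512 px at 2 µm/px with the droplet center near a corner,
  i.e. a quarter field of view of a full droplet, matching acquisitions that
  cover part of each droplet;
* droplet radius 916 µm, jittered per droplet with SD 96 µm in group
  generation — the observed droplet-size distribution;
* boundary perturbed by cosine modes (k = 2, 12 µm) and (k = 3, 8 µm),
  about 1.3–2.2% of the radius: droplets are roughly circular, and a small
  non-circularity exercises the inscribed/circumscribed logic;
* `lambda_p(t) = lambda_0 + (lambda_inf - lambda_0)(1 - e^{-t/tau})` with
  `lambda_0 = 5` µm and `tau = 40` min: penetration accumulates toward a
  plateau, positive and non-decreasing, with group differences emerging
  within ~20 min;
* phenotype presets: suckling-like `lambda_inf = 37` µm, exterior-peaked
  aggregates, accumulation-layer amplitude 600 counts; weaned-like
  `lambda_inf = 115` µm, interior-peaked aggregates, layer amplitude 150.
  The plateaus are the two phenotype group means at T = 120 min; the layer
  amplitudes encode that the low-penetration phenotype accumulates heavily
  at the interface while the high-penetration phenotype swims in.
* the neutral (non-preset) layer amplitude is 300 counts, comparable to the
  interior peak `A + B` (405): when the exterior layer dwarfs the interior
  peak, the profile maximum sits on the layer and the decay fit starts in
  the wrong regime — a real limitation of fit-from-the-maximum profiling,
  discussed below.

Per-stack seeds derive from the master seed by one step of a
linear-congruential map modulo `2^31 - 1` (`derive_seed`), so any single
stack of a generated experiment can be re-rendered in isolation; identical
parameters and seed give bit-identical stacks.

## Statistics

The unit of analysis is the biological sample: technical replicates are
averaged within sample before any cross-sample statistic, preventing
pseudo-replication. Group summaries report mean ± SEM across samples.

The Mann–Whitney test is exact for combined sample sizes up to 24: the
two-tailed p-value is computed by full enumeration of all
`choose(n1 + n2, n1)` group assignments as
`Pr(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)` — the reflection rule around
the null mean, not doubling of one tail, chosen because it is exactly
reproducible by enumeration (small-sample two-tailed conventions differ).
Ties use midranks. Larger samples fall back to the tie-corrected normal
approximation, flagged as such. Kruskal–Wallis (tie-corrected H,
chi-squared reference) serves as the omnibus test, and a two-sided Grubbs
test (`G = max|x_i - mean| / sd`, p from the standard t-based relation)
screens for single outliers within a group.

For curve-level comparisons the package provides a permutation test: max
|two-sample t| across the covariate grid, null by permuting sample-level
group labels (replicates travel with their sample), exhaustive when fewer
assignments exist than requested permutations. Mixed-model analyses
(LMM, type-III ANOVA, estimated marginal means with Tukey correction) are
deliberately out of scope: the exported long-format tables are shaped for
direct consumption by standard mixed-model tooling.

## Verification strategy and problem sizes

Every operation is tested against an independent oracle: radial profiling
against brute-force per-pixel binning; component labeling against a BFS
flood fill; the Triangle bin against an exhaustive point-line-distance scan;
the exact Mann–Whitney against a pair-counting enumeration over binary
assignments; Grubbs against the closed-form relation and a Monte Carlo null;
geometry against dense boundary sampling and convex line-distance formulas;
the renderer against its own closed form via azimuthal averaging.

Acceptance-level checks run at these sizes, chosen to probe the full
pipeline while keeping a test run in minutes on one CPU: parameter recovery
on 512×512 quarter-view scenes at `lambda_p` of 37 and 115 µm, 20 seeds each
(median relative error below 10%); end-to-end phenotype separation with 7
samples × 4 replicate droplets per group, measured at the T = 120 min frame,
over 20 harness seeds (exact Mann–Whitney p ≤ 0.05 and a higher
first-exterior-annulus `P1` in the suckling-like group in ≥ 95% of seeds);
Mann–Whitney type-I error at n = 7 vs 7 over 2000 null simulations
(within [0.03, 0.07]); byte-identical tables on repeated runs.

## Known limitations

* **What passing tests show.** The generator reproduces the radial
  statistical structure of the assay, not bacterial motion, mucus
  heterogeneity, uneven droplet rims, or aggregate irregularity. Passing
  recovery tests demonstrates the estimator chain is correct and robust for
  that structure; it does not certify accuracy on real droplets whose
  deviations from the model are larger.
* **Peak-ring contamination.** The ring containing the boundary mixes
  interior and exterior pixels; with a bright exterior accumulation layer
  this biases `lambda_p` downward (up to ~20% when the layer dwarfs the
  interior signal and the boundary is visibly non-circular). The bias is a
  property of fit-from-the-maximum radial profiling itself, at any
  resolution, and is resolution-dependent; the grid-equivariance test
  therefore isolates numerical robustness on layer-free scenes.
* **Circular geometry.** All statistics assume the annotated polygon is
  nearly circular; strongly lobed droplets violate the concentric-ring
  premise, and the centroid-outside-polygon guard only catches the extreme
  case.
* **Single channel.** Dual-color bead controls are handled by selecting one
  channel at read time; no spectral unmixing.
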