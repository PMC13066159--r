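# mucotrace

Quantifying how motile bacteria penetrate mucus droplets, from fluorescence
time-lapse imaging.

## The problem

The intestinal mucus layer is a selective barrier: depending on host state,
motile bacteria either swim deep into mucus or are halted at its surface and
cross-linked into aggregates. A tractable ex vivo readout places a droplet of
purified mucus in a shallow imaging chamber, surrounds it with a suspension
of fluorescent flagellated bacteria, and records a time-lapse of the
interface. `mucotrace` is for researchers running such assays: it converts
image stacks plus a manually annotated droplet boundary into tidy,
statistically analyzable tables of two readouts:

* the **penetration length** λ<sub>p</sub> — the radial intensity profile
  around the droplet is fitted from its interfacial maximum inward with

  *y*(*x*) = *A* e<sup>−λx</sup> + *B*,  λ<sub>p</sub> = 1/λ,

  where *x* is the inward distance (µm) from the profile peak. A short
  λ<sub>p</sub> means bacteria stay at the rim; a long one means they invade.
* the **normalized radial aggregation profile** P¹ — frames are binarized
  (Triangle threshold), connected components larger than 27 µm² (~10
  bacteria) count as aggregates, and per concentric annulus
  P¹ = (A<sub>C</sub>/A<sub>T</sub>) / Δr<sub>norm</sub>, with
  A<sub>C</sub> the aggregate area, A<sub>T</sub> the annulus area and
  Δr<sub>norm</sub> = 0.1 the annulus width in r/R units. P¹ locates where
  aggregated bacteria sit relative to the droplet boundary.

Because deposited imaging data are not required to exercise the method, the
package includes a synthetic scene generator with complete ground truth
(boundary polygon, true λ<sub>p</sub>(t), aggregate catalog) emulating two
phenotypes: a low-penetration, exterior-aggregating mode ("suckling-like",
λ<sub>p</sub> plateau 37 µm) and a high-penetration, interior-aggregating
mode ("weaned-like", plateau 115 µm). Exact small-sample statistics
(enumerated two-tailed Mann–Whitney, Kruskal–Wallis, Grubbs outlier test, a
curve permutation test) complete the chain from images to p-values.

## Worked example

Generate one suckling-like droplet scene (512×512 px at 2 µm/px, a quarter
field of view of a 916 µm droplet, measured at T = 120 min) and run the full
measurement chain on it:

```r
library(mucotrace)

p <- preset_suckling(image_shape = c(512L, 512L), pixel_size = 2,
                     droplet_center = c(20, 20), n_frames = 1L,
                     t_start = 120, seed = 7L)
sc  <- generate_scene(p)
res <- analyze_droplet(sc$stack,
                       boundary_annotation(sc$truth$boundary_polygon),
                       config = analysis_config(subtract_bg = FALSE))

res$lambda
#>   t_min lambda_p_um fit_ok r_squared r_peak_um        A        B
#> 1   120    28.30475   TRUE 0.9703206       920 600.3119 106.2372
round(sc$truth$lambda_p, 1)
#> [1] 35.4
head(res$aggregation[order(-res$aggregation$P1), ], 3)
#>    annulus     side r_over_R_mid A_C_um2 A_T_um2        P1
#> 11      10 exterior         1.05   20244  136500 1.4830769
#> 16      15 exterior         1.55      16     228 0.7017544
#> 12      11 exterior         1.15    5264   81660 0.6446241
round(res$exterior_fraction, 3)
#> [1] 0.216
```

Reading the output: the fitted penetration length is 28.3 µm against a
generator truth of 35.4 µm (the bright accumulation layer at the interface
biases single-droplet fits somewhat low; group medians recover the truth
within 10%). The aggregation profile peaks in the first exterior annulus
(r/R ≈ 1.05, P¹ = 1.48) — aggregates sit immediately outside the droplet
boundary, the signature of the low-penetration phenotype — and 21.6% of the
exterior region area is covered by bacterial signal.

## The analysis workflow

The `analysis/` scripts run the full study on synthetic data:

```sh
Rscript analysis/01_simulate.R   # two-group experiments (7x4 endpoint, 2x2 timecourse)
Rscript analysis/02_measure.R    # geometry, lambda_p, aggregation -> results/*.csv
Rscript analysis/03_stats.R      # group summaries, exact MW / KW / Grubbs / permutation
Rscript analysis/04_figures.R    # lambda_p(t) and P1-vs-r/R figures
```

`03_stats.R` prints, for the default seed: suckling 30.1 µm vs weaned
119.1 µm at T = 120 min, exact Mann–Whitney p = 5.8×10⁻⁴ (the smallest
two-tailed value attainable at n = 7 vs 7 under the reflection rule), and a
first-exterior-annulus P¹ of 1.45 (suckling) vs 0.69 (weaned).

Real data are analyzed the same way through a manifest: one row per droplet
(`file`, `boundary_file`, `group`, `sample`, `replicate`) passed to
`analyze_manifest()`, with boundaries as CSV vertex lists or ImageJ-dialect
`.roi` files and calibration (µm/px, min/frame) supplied at read time.

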