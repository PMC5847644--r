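# shgdir — local SHG emission directionality analysis

Second-harmonic generation (SHG) microscopy images fibrillar collagen
without labels, and the *direction* the harmonic is emitted carries
information that intensity alone does not: the forward-to-backward ratio at
the point of creation, F<sub>SHG</sub>/B<sub>SHG</sub>, is set by fibril
size and packing through phase matching,

> E<sub>2ω</sub> = κ E<sub>ω</sub>² · sinc(Δk·L/2),  sinc(x) = sin(x)/x,

so smaller phase mismatch Δk gives both brighter and more forward-directed
SHG. What a microscope measures, however, is the detected F/B after the
photons have propagated through scattering tissue — a depth-dependent blur
of the quantity of interest. `shgdir` implements the full analysis chain
used to recover and exploit the local creation ratio in ovarian tissue
(normal stroma, benign tumors, endometrioid, low-grade serous and
high-grade serous carcinoma), where collagen remodeling differs by tumor
type and, critically, so does its *heterogeneity*:

1. **Monte Carlo photon transport** (Rcpp core) through a homogeneous
   scattering slab — Henyey–Greenstein scattering, NA-limited detection
   with Snell refraction — builds a lookup table of measured F/B over a
   creation-ratio grid (1 to 19.9 in 0.3 steps, 64 values) × depth.
2. **Patch-wise extraction**: stacks are trimmed, desaturated, denoised and
   calibrated (isotropic-emitter F/B baseline); each optical section is
   tiled into 30×30-pixel patches (≈10 µm, spanning whole fiber
   structures); patch mean(F)/mean(B) is inverted through the table at the
   section's depth, yielding creation-ratio heat maps with validity flags.
3. **Heterogeneity and correlation statistics**: per-volume mean and SD of
   patch ratios; per-section Pearson correlation between the
   (self-normalized) heat map and SHG intensity; Welch t-tests between
   tissue groups; gray-level co-occurrence (GLCM) texture features as the
   negative control.
4. **Fiber morphology**: Otsu segmentation, skeleton + Euclidean-distance
   width estimation per fiber/bundle segment, group summaries.
5. **A synthetic five-class tissue generator** with known ground truth —
   class-specific fiber geometry, spatially coherent phase-mismatch
   domains calibrated so the ground-truth ratio moments equal the
   published cohort values (means 4.0/8.8/3.0/5.1/2.7, SDs
   2.0/3.9/1.7/3.5/1.7 for normal/benign/endometrioid/LGS/HGS), sinc-law
   intensities, transport-consistent F/B mixing and Poisson noise — so the
   whole pipeline is testable end-to-end without any external data.

The intended users are microscopists and image-analysis researchers who
want a transparent, tested reference implementation of directional SHG
analysis, or a simulation sandbox for patch-size, noise and inversion
design questions.

## Worked example

```r
library(shgdir)

optics   <- optical_properties()      # mu_s' = 2 mm^-1, g = 0.9, n = 1.4
geometry <- detection_geometry()      # 0.9 NA forward, 0.8 NA backward

lut <- build_lookup_table(optics, geometry,
         mc_config(photons_per_condition = 1e4, rng_seed = 1,
                   depth_grid = seq(0, 16, length.out = 9)))

config <- run_config(n_volumes_per_class = 2, shape = c(128, 128),
                     n_sections = 16, mean_counts = 200, seed = 1)
report <- run_full_analysis(config, table = lut)
report
```

prints (abridged):

```
Group mean F_SHG/B_SHG (Table-1 style):
        group mean_ratio mean_ratio_se within_volume_sd
       normal   3.691414   0.109004753        2.7777152
       benign   8.404747   0.162508021        3.4366159
 endometrioid   3.103245   0.009709334        1.1250197
          LGS   4.899612   0.097222824        2.8215176
          HGS   2.764986   0.003408314        0.9247763

Group heat-map/intensity Pearson r (Fig.-5 style):
        group    mean_r          se n_stacks
       normal 0.5547420 0.183091223        2
       benign 0.6835009 0.192977152        2
 endometrioid 0.4618144 0.005301960        2
          LGS 0.8634961 0.004672968        2
          HGS 0.8949641 0.030796839        2
```

Reading it: the pipeline recovered the configured class ordering of mean
creation ratios (benign > LGS > normal > endometrioid > HGS, the published
cohort ordering); benign and LGS show the widest within-volume spread
(most heterogeneous local F<sub>SHG</sub>/B<sub>SHG</sub>); and the
heat-map/intensity correlation is highest for the HGS-like class, whose
narrow mismatch and fiber-width distributions keep directionality and
brightness locked together. `write_report_csv(report, "out/")` exports
every table.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— Monte Carlo lookup-table build plus the reduced five-class synthetic
cohort analysis above — and writes its JSON result to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness (photon transport, fiber fields, mismatch domains, shot
noise) derives from `--seed`.
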