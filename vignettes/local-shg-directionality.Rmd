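---
title: "Local SHG emission directionality: models, parameters, and design choices"
author: "shgdir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local SHG emission directionality: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter and why their defaults are what
they are, what the synthetic-tissue generator does and does not emulate,
and the design decisions taken where the underlying methodology left
choices open.

## 1. The quantity of interest

Second-harmonic generation in fibrillar collagen is coherent: the ratio of
forward- to backward-emitted harmonic at the point of creation,
$F_{SHG}/B_{SHG}$ (the *creation ratio*), is governed by phase matching.
For an interaction length $L$ and wavevector mismatch $\Delta k$,

$$E_{2\omega} \;=\; \kappa\, E_\omega^2\,
  \frac{\sin(\Delta k L/2)}{\Delta k L/2},$$

so small $|\Delta k|$ (well-matched fibril size/packing relative to
$\lambda_{SHG}$) produces bright, strongly forward-directed SHG, while
large mismatch produces dim, more isotropic emission. `shg_field()` and
`shg_intensity()` implement this with the removable singularity handled
exactly ($\mathrm{sinc}(0)=1$).

The microscope does not observe the creation ratio. Photons created at
depth $z$ inside a scattering slab are redirected before reaching either
the condenser-side (forward) or objective-side (backward) detector, so the
*measured* F/B is a depth-dependent transformation of the creation ratio.
Undoing that transformation is the core of the package.

## 2. Photon transport model

`simulate_emission()` traces photons through a single homogeneous slab:

* **Geometry.** $z=0$ at the objective-side (backward) face, depths in µm
  increasing toward the condenser. Slab thickness defaults to 150 µm
  (vibratome-sectioned tissue is ~100–150 µm).
* **Launch.** A photon goes up with probability $r/(1+r)$ and down with
  $1/(1+r)$, uniformly in solid angle within a cone about $\pm z$. The
  default cone half-angle is the tissue-side image of the 0.8-NA
  excitation aperture, $\arcsin(0.8/n)$, by NA invariance across the
  interface. This choice makes the ballistic limit exact: with
  $\mu_s' = 0$ every launched photon stays inside both acceptance cones,
  so measured F/B equals the creation ratio at every depth. A water-side
  cone ($\arcsin(0.8/1.33)$) would clip the backward aperture whenever
  $n > 1.33$ and break that limit.
* **Scattering.** Henyey–Greenstein with anisotropy $g$ (default 0.9,
  typical of collagenous tissue); $\mu_s = \mu_s'/(1-g)$ with
  $\mu_s'$ in mm⁻¹ at 494 nm (default 2 mm⁻¹; per-tissue values are
  configurable). Absorption is negligible at this wavelength
  ($\mu_a \ll \mu_s$) and defaults to zero; when nonzero it is handled by
  weight attenuation, and weight is conserved exactly:
  collected_F + collected_B + escaped + absorbed = launched (no roulette).
* **Detection.** A photon exiting a face is collected if
  $n \sin\theta \le \mathrm{NA}$ of that face (Snell refraction folded
  into the acceptance test); defaults 0.9 NA forward, 0.8 NA backward.
* **Reproducibility.** The production core (C++) uses its own
  xoshiro256** generator; every (ratio, depth) grid node gets a stream
  derived deterministically from the root seed, so tables are
  bit-reproducible and independent of R's RNG state. A deliberately naive
  per-photon R loop, `simulate_emission_reference()`, written with a
  different scattering-frame algebra and driven by R's RNG, serves as an
  independent oracle; the suite checks agreement within combined Monte
  Carlo error on a panel of scattering conditions.

Default photon budget is $10^5$ per grid node (desk-scale); standard
errors are delta-method errors of the ratio of multinomial fractions,
including the $+2/n$ anticovariance term.

## 3. Lookup table and inversion

`build_lookup_table()` runs the forward model over the creation-ratio grid
1.0–19.9 in steps of 0.3 (64 values, the classical inversion grid) and a
depth grid (default 1-µm spacing, matching the section spacing). Measured
F/B must be nondecreasing in the creation ratio at each depth; a true
decrease marks an under-sampled simulation. Because a table makes on the
order of $10^3$ pairwise comparisons, the gate uses a 3-standard-error
floor with a multiplicity-adjusted threshold (expected false-alarm rate
about $10^{-3}$ per build) — a literal per-pair 3-SE rule would reject
roughly one healthy table in every few builds on noise alone.

**Inversion.** Transport is linear in the up/down launch components:
writing $A,B$ ($C,D$) for the forward (backward) collection probabilities
of up- and down-launched photons at a given depth,

$$\mathrm{F/B}(r) \;=\; \frac{A r + B}{C r + D}.$$

`invert_measured_fb()` therefore fits this four-parameter Möbius model to
the 64 grid nodes per depth (weighted total least squares) and inverts it
analytically. The fit pools the Monte Carlo noise of the whole grid; a
single-node piecewise-linear inversion carries the full node noise divided
by the local slope and, at the reduced table budget used in testing
($10^4$ photons/node), misses off-grid round trips by about twice the grid
resolution, while the pooled inversion recovers them within it. Nearest
depth row selection (1-µm grids make depth interpolation unnecessary),
clamping to the grid ends and the `ok`/`clamped_low`/`clamped_high` flags
are unchanged. Tables persist losslessly to hierarchical JSON
(`save_lut()`/`read_lut()`, 17 significant digits) and export to
long-format CSV via `as.data.frame()`.

## 4. Patch-wise extraction

`preprocess_stack()` drops the first and last 10 optical sections
(boundary effects; configurable), marks pixels at or above the saturation
threshold invalid in *both* channels (the channels are simultaneous views
of the same voxel), optionally applies a 3×3 median denoise identically to
both channels, and can subtract a known dark level (dark counts enter F
and B equally and drag low-signal ratios toward 1).
`apply_calibration()` divides the forward channel by the
isotropic-emitter F/B baseline so that an isotropic source reads F/B = 1;
being scalar, it commutes exactly with patch averaging.

`compute_patch_grid()` tiles each section into non-overlapping 30×30-pixel
patches from the top left (trailing margins discarded — this preserves
uniform patch statistics; 512 px → 17×17 patches with 2-px margins). The
patch statistic is mean(F)/mean(B) — the photon-count estimator, robust to
near-zero pixels — over valid pixels; a patch is valid when at least half
its pixels are valid, its backward mean is positive, and (optionally)
above a minimum signal level so that empty patches are not inverted.
Thirty pixels (≈10 µm) is the scale that spans whole fiber structures:
smaller patches are shot-noise-limited (`patch_size_sweep()` reproduces
the failure-fraction diagnostic), larger ones average away fiber-level
information toward the frame mean.

`extract_ratio_heatmaps()` then inverts each valid patch at its section's
depth, producing the creation-ratio heat-map stack with flags and
provenance (the lookup-table fingerprint).

## 5. The mismatch-to-directionality map

The qualitative physics fixes only monotonicity: zero mismatch gives the
most forward emission, large mismatch approaches isotropy. The default map
is the simplest form with those limits,

$$r(|\Delta k|) = 1 + (r_{max}-1)\,e^{-|\Delta k|/d},$$

with $r_{max}=19.9$ (the top of the inversion grid) and decay
$d = 0.5$ rad/µm. The decay sets the $\Delta k$ scale of the synthetic
world; 0.5 rad/µm places the five class-mean mismatches (≈0.4–1.5 rad/µm)
inside the principal sinc lobe for micrometre-scale interaction lengths,
where intensity and directionality fall together — the regime the
correlation analysis probes. The map is pluggable.

One consequence worth stating: calibrated against the published class
moments, the exponential map gives nearly equal mismatch dispersions for
the HGS-like and LGS-like classes (their *relative* ratio SDs are nearly
equal), so in this synthetic world the higher HGS heat-map/intensity
correlation is carried by the fiber-width channel — LGS width dispersion
(0.9 µm) scatters intensity through $L$ in the sinc argument, HGS width
dispersion (0.25 µm) does not — which is exactly the width-heterogeneity
contrast reported for these tissue classes.

## 6. The synthetic tissue generator

`default_profiles()` encodes five classes. Ground-truth ratio moments are
the published cohort values (means 4.0 / 8.8 / 3.0 / 5.1 / 2.7; SDs 2.0 /
3.9 / 1.7 / 3.5 / 1.7). Morphology follows the qualitative class
descriptions: normal is a loose isotropic mesh; benign dense with thick
bundles; endometrioid sparser with long straight aligned fibers; LGS a
tightly packed matrix of shorter fibers with the widest width dispersion;
HGS densely packed, aligned, wavy, with the narrowest width dispersion.
Fiber widths use the published class means (2.13–2.2 µm). Densities are
0.5–0.8, reflecting the collagen-dense stroma (>70% coverage) these
analyses target. A single default optics set serves all classes (per-class
bulk optics belong to prior literature and are configurable).

* **Fiber fields** (`generate_fiber_field()`): wavy line segments with
  disc cross-sections stamped at fractional centres (so rasterized width
  matches the analytic band convention), widths truncated-normal,
  orientations von Mises, placed until the target coverage; first-wins
  overlap so every pixel has one fiber id.
* **Mismatch field** (`assign_dk_and_ratio()`): $|\Delta k|$ is a folded
  Normal evaluated on *spatial domains* — one standard-normal draw per
  25-µm cell, read per pixel. Fibril size and packing vary between
  micrometre-scale domains, not independently per fiber: independent
  per-fiber draws would average out inside 30-px patches and could never
  realise patch-level SDs of 2–4. The domain field is redrawn every 8
  sections of depth (axial persistence ≈ 8 µm) while the fiber geometry
  persists with small lateral jitter; a single 2-D field replicated
  through a 64-µm stack would sample only ~12 independent domains per
  volume and make cohort statistics seed-unstable. The centre
  $\Delta k_c$ is solved on the realized draws so the pixel-weighted mean
  ratio hits the class mean within 0.1; the dispersion $\sigma_{\Delta k}$
  is a *class constant*, calibrated once against the population folded
  Normal (deterministic quadrature) so the population ratio SD hits the
  class SD (`calibrate_dk_sd()`); targets beyond what the bounded map can
  realise fall back to the widest attainable, with a warning.
* **Rendering** (`render_stack()`): per-pixel created intensity
  $\propto \mathrm{sinc}^2(\Delta k\, w/2)$ with the local fiber width as
  interaction length; the split into detected F and B uses the lookup
  table's measured F/B at (pixel ratio, section depth); the forward
  channel is multiplied by the calibration factor; counts are scaled so
  fiber pixels average `mean_counts` (default 200); background receives
  1% dark counts; independent Poisson noise per channel.

**What the generator does not emulate** — and hence what a green test does
not establish: coherent emission lobes and speckle; the microscope PSF
(fibers have hard edges); true 3-D fiber growth (geometry persists in
depth); per-class optical properties; instrument drift or registration
error; and any biological variation beyond the parameterized morphology
and mismatch statistics. Green end-to-end tests establish that the
*analysis chain* is self-consistent — transport inversion undoes transport
mixing, patch statistics recover configured moments and orderings — not
that real tissue obeys the generator's assumptions.

**Known attenuation.** Patch averaging mixes domains and background at
patch boundaries and the inversion clamps at the grid ends, attenuating
the recovered within-volume SD to roughly 70–95% of the configured
(pre-patch) value at the default geometry and pulling the recovered means
slightly low — by ~0.05 for the low-ratio classes up to ~0.3 for the
benign-like class (mean 8.8), whose patches mix the widest ratio range.
The class grouping of dispersions is preserved. The property suite
asserts exactly this (means within 2 SE or the 0.4 mixing bound; SDs
within the attenuated band; wide-dispersion classes above narrow ones).

## 7. Statistics

* `heterogeneity_summary()`: per-volume mean and SD of all valid patch
  ratios; groups summarised as mean ± SE across volumes — the Table-1
  structure (row 1: mean ratios; row 2: within-volume SDs).
* `section_pearson()`: patches of the heat map against patch-reduced
  forward-channel intensity, both min-max self-normalized per section.
  Pearson is invariant under positive affine maps, so self-normalization
  cannot change r — it is retained for fidelity and exported-map
  comparability, and the suite asserts the invariance as a regression
  guard. Sections with fewer than 3 valid patches or zero variance report
  missing. Patch-reduced intensity (not heat-map upsampling) is the
  implemented reading of the per-section comparison; clamped patches are
  included, invalid excluded.
* `stack_correlation()` / `group_correlations()`: per-section r averaged
  per stack; groups compared by two-sample t-tests on per-stack means —
  Welch by default (pooled available); groups with fewer than two stacks
  are skipped with a warning. No multiple-testing correction is applied
  across the pairwise comparisons, matching standard practice for this
  descriptive table.
* `glcm_features()`: 16 gray levels, equal-width bins over the finite
  range, symmetric co-occurrence matrix averaged over offsets
  (0,1),(1,0),(1,1),(1,−1); energy $\sum P^2$, entropy
  $-\sum P\log_2 P$ with $0\log 0 = 0$, homogeneity
  $\sum P/(1+|i-j|)$. A constant image is defined (energy 1, entropy 0),
  not an error. These are the intensity-texture negative control: they
  carry no sub-resolution fibril information.

## 8. Fiber morphology

`segment_fibers()` uses Otsu's threshold (256 bins) with small-object
removal; a constant image yields an empty mask. `extract_fiber_widths()`
thins the mask (Zhang–Suen), splits the skeleton where the circular
crossing number is ≥ 3 (a plain neighbour count misreads staircase corners
on diagonal lines), removes the branch pixels with their 8-neighbourhoods
(arms otherwise remain diagonally connected), and discards segments
shorter than 10 px (skeleton spurs). Per-segment width is
$2\,q_{0.6}(\mathrm{EDT}) - 0.5$ pixels along the centerline: the
upper-middle quantile of the exact Euclidean distance transform resists
both the staircase dips of shallow-angle skeletons (which bias the mean
and median low) and junction bulges in dense fields (which bias the
maximum high); the half-pixel term splits the boundary ambiguity between
the last foreground and first background pixel centre. Validated within
one pixel on rotated bars of widths 3–15 px across 0–90°, and the
generator→estimator loop recovers configured class means within 2 SE on
sparse (resolvable) fields. Connected structures report as fiber/bundle
segments — overlapping fibers are *not* separated, matching the
granularity of standard fiber-extraction tools; on dense fields the
reported widths are bundle widths by design.

## 9. Numerical choices and degenerate inputs

* Creation ratios clamp to [1, 19.9] with explicit flags; flag counts are
  conserved (ok + clamped_low + clamped_high + invalid = patches).
* Zero measured F/B (a patch with backward signal but no forward counts)
  clamps low rather than erroring; non-finite input errors.
* Zero-variance t-test groups report the limit (t = 0, p = 1 when means
  agree; infinite t, p = 0 when they differ) instead of erroring.
* Identical (config, seed) pairs reproduce tables, fields, stacks and
  reports bit-for-bit; cohort child seeds are derived deterministically
  and stay below 2³¹.
* Calibration tolerances: realized mean ratio within 0.1 of target
  (warning beyond); dispersion calibration to uniroot tolerance 1e-10 on
  a 4096-point quadrature.

## 10. Pipeline

`run_config()` + `run_full_analysis()` compose the stages — lookup table
(built if absent), per-volume generation, preprocessing (with dark
subtraction), calibration, heat-map extraction, heterogeneity,
correlations, fiber widths on the mid-stack section, GLCM — streaming
volume-by-volume so memory stays bounded, and return a report whose
tables `write_report_csv()` exports. The exported functions and this
vignette are the package's interface; the stages mirror what a
command-line wrapper would expose (`simulate-lut`, `generate-synthetic`,
`extract-fb`, `fiber-widths`, `analyze`) for anyone embedding the package
in a larger workflow.

## 11. Known limitations

* The slab is homogeneous: depth- or class-varying optical properties
  within a volume are out of scope (bulk-averaged properties are the
  stated assumption of the approach).
* Coherent SHG angular lobes are not modeled; the launch cone is a
  geometric surrogate whose half-angle is configurable.
* The mismatch→ratio map is heuristic; only its monotone shape is
  physically fixed, and the class-level mismatch dispersions it implies
  depend on its form (Section 5).
* Within-volume SD recovery is attenuated by patch averaging
  (Section 6); comparisons should be made on identically processed data.
* Fiber widths on dense fields are bundle widths; individual-fiber widths
  require resolvable (sparse) structures.
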