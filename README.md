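# npcflux

Analysis of two-colour 3D MINFLUX experiments on nucleocytoplasmic
transport. One colour channel images the nuclear pore complex (NPC)
scaffold through a blinking dye on the NUP96 rings; the other tracks a
transport receptor (an importin-class cargo) as it binds, traverses or
aborts passage through individual pores. `npcflux` turns the two
localization streams into:

- **per-pore scaffold fits** — a double-circle model (shared ring radius,
  cytoplasmic/nucleoplasmic ring spacing, centre) plus the eightfold
  symmetry phase of each pore, with aligned composite images and
  early/late stability diagnostics;
- **a registered coordinate frame** — gold-bead rigid xy alignment between
  channels and an axial scale calibrated from the ring spacing
  (51.5 nm reference / 76.8 nm raw = 0.67);
- **curated transport tracks** — photometric filtering (CFR/EFO/DCR),
  assignment to pores by the 400-nm-cube rule, transit detection at
  |z| ≤ 25 nm, classification into import / export / abortive import /
  abortive export, angular confinement and residence times;
- **diffusion mixture fits** — jump-step and R²/t histograms fitted
  jointly by seeded forward simulation with 1–3 species, each with its
  own localization precision and (for the mobile species) diffusion
  coefficient;
- **volume-corrected radial density maps** around aligned pores with
  annular zone summaries (centre / transport annulus / periphery).

A ground-truthed synthetic MINFLUX generator (blinking scaffold streams,
fiducials, cargo cohorts, full localization-error model: precision,
jiggle, sphere rotation, sample drift, variable timesteps) backs the test
suite and serves as the forward model of the fits.

## The core statistics

For pure diffusion the 3D jump distance R between successive
localizations at interval t follows
`p(R) ∝ R² exp(−R²/4Dt)` (per-axis variance 2Dt); the time-normalised
statistic `u = R²/t` is **independent of t** under pure diffusion but not
in the presence of localization error, whose contribution scales as 1/t.
Fitting the jump histogram and the u histogram *simultaneously* therefore
separates diffusion from precision — the package's mixture fit exploits
exactly this dichotomy, generating model curves by seeded simulation with
anisotropic precision (σx/σy = 0.93, σx/σz = 1.55) and the empirical
timestep distribution of the data.

## Worked example

```r
library(npcflux)
res <- run_pipeline(pipeline_config(out_dir = "npcflux-demo", seed = 7))
table(res$classification$class)
#> abortive_export abortive_import      background          export          import
#>               5               5              10              10              10
mean(res$pores$ring_spacing)
#> [1] 51.45376
```

The demo simulates a field of six pores and a forty-track cohort,
reconstructs every pore (mean fitted ring spacing 51.45 nm against a
51.5 nm ground truth), registers and filters the cargo channel, and
recovers the simulated transport classes exactly. The output directory
collects `pores.csv`, `tracks.csv`, `density.csv`, the composite z
profile, a stability table and a `run_log.json` holding the full
configuration and seeds; a rerun with the same seed is byte-identical.

Individual stages are exported directly, e.g.

```r
compute_z_scale(51.5, 76.8)          # 0.6705729  (0.67 at 2 dp)
fit <- fit_species_model(sample, n_species = 3, seed = 7)
```

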