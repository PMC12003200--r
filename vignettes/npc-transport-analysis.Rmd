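---
title: "Models and methods behind npcflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npcflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcflux)
```

# Scope

`npcflux` analyses two-colour 3D MINFLUX localization data of
nucleocytoplasmic transport: a scaffold channel in which a blinking dye
decorates the NUP96 rings of nuclear pore complexes (NPCs), and a cargo
channel in which a transport receptor is tracked as it interacts with and
traverses pores. The package covers the full desk-side analysis — scaffold
reconstruction, channel registration, track curation and classification,
jump-step diffusion analysis, and radial density mapping — together with a
ground-truthed synthetic data generator that stands in for raw microscope
exports (which are not publicly archived for this kind of experiment) and
doubles as the forward model for the mixture fits.

# The localization table

A MINFLUX localization is a row: emitter/track label (`trace_id`), time
(seconds), `x`, `y`, `z` (nm) and photometric quality attributes in kHz or
as ratios — EFO (emission frequency averaged over the offset positions of
the scan pattern), EFC (at the pattern centre), CFR = EFC/EFO (low values
indicate a well-centred single emitter) and DCR (spectral detector channel
ratio in [0, 1]). The package defines a plain-CSV dialect with exactly
these columns because vendor exports are proprietary; absent photometric
values are empty fields, never sentinel zeros, so that filters cannot
silently pass missing data. Strict validation (monotone time per trace,
CFR consistency with EFC/EFO at 1e-6 relative tolerance, DCR in [0, 1]) is
the default, with a non-strict mode that reports problems instead of
stopping.

Bursts — runs of consecutive localizations of one emitter — are split at
trace changes and at gaps longer than 3 ms, the interval after which the
scan head considers the fluorophore switched off. A gap of exactly 3 ms
does not split ("longer than" semantics).

# Scaffold reconstruction

Pores are found by single-linkage clustering in 3D with an 80 nm distance
cut-off and a minimum of 30 localizations. Pores in a field sit hundreds
of nanometres apart while one pore's localizations span ~130 nm, so any
cut between those scales works; single linkage was chosen because it needs
no density parameter and the membership tests pin its behaviour.

Each cluster is fit with a **double-circle model**: two congruent circles
of shared radius, parallel to the xy plane, centres on a common vertical
axis, separated by the ring spacing. The fit minimises the squared
residuals of (cylindrical radius − ring radius) and (|z − z0| − spacing/2).
Localizations are assigned to the upper or lower ring by the sign of
z − z0; the split is initialised at the count-weighted mean and iterated
to the balanced midpoint — a plain median would sit inside the fuller ring
of an unevenly sampled pore and bias the spacing low by several
nanometres. The xy centre uses an algebraic circle fit refined by
Gauss–Newton; outliers beyond 3 sigma of the residual distribution are
trimmed and the fit repeated. Clusters whose localizations occupy a single
plane are flagged degenerate (spacing unidentifiable) rather than forced.
Tilt is not fitted: the nuclear envelope at the bottom of the nucleus is
flat enough that pore tilts stay below ~10 degrees, and a tilted variant
would add two parameters the typical per-pore counts cannot support.

The **eightfold symmetry phase** reduces localization azimuths modulo 45
degrees and fits `offset + amplitude * cos(8(theta − phase))` to 3-degree
bins by least squares; the phase itself is taken from the unbinned
eightfold resultant, which is the bin-width→0 limit of the same least
squares and removes half-bin quantisation. A phase is flagged low
confidence when the amplitude is below twice its standard error — flat
azimuthal distributions then do not contribute a spurious rotation.
Aligned pores (translated to their centres, rotated by minus their phase)
are pooled into composite 2D histograms with 2 nm bins scaled to percent
of maximum.

**Precision from centroid deviations**: bursts with at least 20
localizations contribute per-axis deviations from their own centroid,
pooled with n−1 degrees of freedom per burst (removing the
sqrt((n−1)/n) shrinkage of deviations about a sample mean). This
estimator is deliberately naive: any slow motion of the emitter during a
burst — linkage error, scaffold breathing, residual drift — inflates it.
The jump-step analysis below provides the counter-estimate, and the
package reproduces the characteristic gap between the two on simulated
data (a 4.1 nm true precision reads as ~6.3 nm under nanometre-scale
diffusional drift of the dye centroid — an overestimate of roughly half).

An early/late split of each pore's localizations at the median timestamp
gives a per-pore displacement diagnostic for long acquisitions.

# Channel registration

The cargo channel is mapped onto the scaffold channel with gold-bead
fiducials measured in both channels. Repeated bead fixes are collapsed to
per-bead medians (robust to transient outliers), then a least-squares
orthogonal Procrustes fit in xy — rotation plus translation only, no
scale; a reflection-optimal solution is corrected to a proper rotation
and flagged. The z axis is treated separately: raw MINFLUX z is compressed
by the refractive-index mismatch between the aqueous sample and the oil
immersion, and the scale factor is calibrated from an independently
measured NPC ring spacing (astigmatism reference 51.5 nm against the raw
MINFLUX 76.8 nm, i.e. a factor of 0.67 at two decimals; the quotient is
kept at full precision internally and applied unrounded by default).
After scaling, the per-cell mean z deviation between channels (typically
5–14 nm) is subtracted; scale strictly precedes offset, and a dedicated
test asserts that order.

# Track curation and classification

Cargo localizations are filtered per point: CFR < 0.8, EFO inside a
window, DCR inside the cargo dye's spectral window. The DCR window
defaults to [0.3, 0.8]; the exact published cut is not stated, so the
window is configurable and every rejection is tallied in a log. A failing
point breaks the run and the surviving fragments are re-tested against
the minimum length of 5 consecutive localizations. Tracks whose median
EFO exceeds 1.7x the dataset median are flagged as double-dye (roughly
the 10–15% expected from under-labelling) but retained, since flagged
tracks carry genuine transport events.

Tracks are assigned to the pore whose 400-nm cube they enter, ties going
to the nearest centre at closest approach, and are transformed into the
pore frame (translated to the pore centre, rotated by minus the pore's
phase, cytoplasm at +z). A track transits when any point lies within
25 nm of the midplane (inclusive). Classification uses the same ±25 nm
compartment threshold: import runs from z > +25 to z < −25, export the
mirror; abortive import enters from the cytoplasmic side, never attains
z < 0 (the midplane is the empirical point of no return) and returns;
anything else is unclassified. One constant for transit and compartment
membership keeps the geometry coherent; the class definitions are
mirror-symmetric by construction and the suite asserts that negating z
swaps the labels exactly.

Angular confinement is quantified per track against the reference azimuth
of the in-pore localization nearest the midplane; pooled wrapped
differences get a zero-centred Gaussian width (bounded below at 0.5
degrees) plus a chi-square goodness flag that catches azimuthally uniform
data. Residence time sums the intervals between consecutive in-pore
points, so seven points at 2 ms spacing give 12 ms.

# Jump-step and R²/t analysis

For pure isotropic diffusion the displacement between successive
localizations follows, per bin of width b at distance R and timestep t
(per-axis variance 2Dt):

- 1D: `p(x) = 2b/sqrt(4*pi*D*t) * exp(-x^2/(4Dt))` (folded Gaussian),
- 2D: `p(r) = b*r/(2Dt) * exp(-r^2/(4Dt))`,
- 3D: `p(R) = b*R^2 / (sqrt(4*pi)*(Dt)^(3/2)) * exp(-R^2/(4Dt))`,

and mixtures of species are convex combinations of these. MINFLUX
timesteps are not constant — localizations below the photon minimum are
retried, so intervals are integer multiples of the base scan cycle — and
the change of variables u = R²/t gives time-independent forms, e.g. in
3D `p(u) = b*sqrt(u)/(4*sqrt(pi)*D^(3/2)) * exp(-u/(4D))` (u in nm²/ms
throughout; D converts as 1 µm²/s = 1000 nm²/ms). All binned
distributions are normalised, and a warning fires when the requested
range truncates more than 0.1% of the mass. The central diagnostic: u is
invariant to timestep mixing *only* under pure diffusion; localization
precision, jiggle and sphere-rotation error are time-independent offsets
whose contribution to R²/t scales as 1/t, so they break the invariance.
The suite asserts the dichotomy in both directions.

**Mixture fitting.** One to three species are fitted jointly to the jump
and u histograms. Model curves come from seeded forward simulation with
the same error model as the generator (anisotropic precision with the
fixed axis ratios sigma_x/sigma_y = 0.93 and sigma_x/sigma_z = 1.55,
timesteps resampled from the data), because with anisotropic noise and
variable timesteps no tractable closed form exists. Fixed per-species
seeds make the objective deterministic and act as common random numbers,
so the surface is smooth in the parameters. The objective is the
equal-weight sum of squared differences of normalised frequencies over
both histograms. Mixture weights enter linearly and are solved exactly at
every evaluation by a tiny active-set constrained least squares; the
remaining nonlinear parameters (per-species sigma_x and the mobile
species' D — species other than the last are pinned at D = 0 by default,
mirroring a bound/confined/mobile decomposition, with a `free_D` escape
hatch) are optimised by a coarse log-grid (cached per species) followed
by Nelder–Mead, then polished at four times the simulation size to
shrink Monte-Carlo bias in the optimum. Boundary-pinned parameters and
near-zero weights are flagged.

Identifiability deserves a note: with nearly constant timesteps the jump
variance 2Dt + 2σ² collapses D and σ onto a ridge and *no* estimator can
separate them. Separation comes entirely from timestep diversity, which
the retry mechanism provides in real acquisitions. The synthetic cargo
conditions therefore use a geometric-retry model with 0.55 ms base cycle
and retry probability 0.75 (mean interval ≈ 2.2 ms), consistent with the
arithmetic of a ~14 ms median residence over a median of 7 in-pore
points; under these conditions the three-species recovery tests pass with
margin, and they are also where the method is honest about its limits.

# Volume-corrected radial density maps

Pore-frame localizations are binned in (r, z) with 5 nm × 10 nm cells and
each count is divided by its annular shell volume `pi*(r_out² − r_in²)*Δz`,
so a uniform 3D density appears flat in r. Displays are scaled to percent
of maximum with optional clipping (peripheral-binding maps saturate at
60–70% because of hotspots above the pore); raw counts and densities are
always retained and total counts are conserved. Zone summaries average
the corrected density over |z| ≤ 15 nm in three annuli — centre (default
0–12 nm), transport annulus (12–33 nm, bracketing the ~23 nm transport
radius), periphery — with edges configurable because the published zone
boundaries are descriptive rather than numeric.

# The synthetic generator — what it emulates and what it does not

The generator produces: double-ring scaffold blinking streams (16 corner
sites per pore, Poisson burst counts, per-burst trace ids as acquisition
software assigns them, anisotropic localization noise); gold-bead
fiducial pairs with a known rigid transform, z scale and per-cell offset;
and cargo cohorts (import, export, abortive import/export, background)
whose transits run along a 23 nm annulus within one 45-degree lobe, with
decoy tracks carrying out-of-window DCR and a configurable double-dye
fraction. Jump trajectories implement per-axis diffusion variance 2Dt
(anisotropic triplets allowed, for the dye-centroid drift model),
precision, jiggle and sphere-rotation noise re-randomised every
localization, and an optional shared sample-drift random walk.

Defaults are the study conditions: ring spacing 51.5 nm, scaffold dye
sigma_x 4.1 nm (apparent 6.5/7.0/4.2 nm through the centroid estimator
under drift), cargo precision 8.2 nm, scaffold cycle 3.3 ms, cargo base
cycle 0.55 ms, transport annulus 23 nm, angular scatter 19 degrees. The
ring radius default of 53.5 nm is a structural convention for the NUP96
ring, not a measured constant of this pipeline. What the generator does
*not* emulate: photon-level PSF/donut physics, photophysics beyond
two-state blinking, motion blur within a single localization (subsumed
into the per-species sigma, as the fits assume), pore tilt, and the
dense molecular context of a real nucleus. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
error model, not robustness to every instrumental artefact.

# Numerical choices and limitations

- Histogram ranges default to the 99.8th percentile of the data with 30%
  headroom and ~60 bins; fits use the same bins for data and model.
- Simulation sizes in the shipped tests (e.g. 1 200 trajectories of 16
  localizations per fit dataset, 50 pores for scaffold recovery, 20 seeds
  per recovery median) were chosen so the whole suite runs comfortably on
  one CPU while leaving the recovery tolerances clear margins.
- The weight solver resolves degenerate (collinear) species histograms
  with a 1e-10 ridge; ties in model selection are broken toward fewer
  effective species via the boundary flags rather than automatically.
- Two-species data fitted with one species fails visibly on the u
  histogram (the goodness ordering is asserted, not a numeric threshold,
  because "fits much better" is qualitative).
- Known limitations: single-linkage clustering can chain pores closer
  than ~150 nm (not a regime of these fields); the double-circle model
  assumes untilted congruent rings; track re-identification across gaps
  is out of scope; and the mixture fit reports point estimates — bootstrap
  the seeds for uncertainty.

# A worked end-to-end run

```{r, eval = FALSE}
library(npcflux)
res <- run_pipeline(pipeline_config(out_dir = "npcflux-demo", seed = 7))
table(res$classification$class)
mean(res$pores$ring_spacing)
```

The demo simulates six pores and forty tracks, reconstructs the pores
(mean fitted ring spacing within a couple of nanometres of 51.5), and
classifies the cohort back to its ground truth; artefacts (pore table,
track table, density grid, run log with config and seeds) land in the
output directory.
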