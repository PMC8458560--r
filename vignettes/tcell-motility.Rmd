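---
title: "Models and methods: naive T cell motility and in-silico DC encounters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: naive T cell motility and in-silico DC encounters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellscan)
```

`tcellscan` reimplements, as a self-contained R workflow, the in-silico
arm of an intravital imaging study of naive T cell motility: summary
statistics of measured 3D tracks, a calibrated generator standing in for
undeposited measured data, synthesis of long tracks from short-track step
statistics, and an agent-based simulation of T cell encounters with
static dendritic cells (DCs) in a model lymph-node T cell zone. This
vignette documents the models, conventions and defaults, and what the
synthetic data do and do not establish.

## Track statistics

A track is a time-ordered sequence of 3D centroid positions, uniformly
sampled (default every 20 s, the usual two-photon frame interval, for
20 min). From the displacements \(d_s = p_{s+1} - p_s\) we compute:

* **step speeds** \(|d_s|/\Delta t\), reported in µm/min;
* **turning angles**, the angle between \(d_s\) and \(d_{s+1}\)
  (0° straight, 180° reversal);
* **plane angles**, the signed dihedral angle between the plane spanned
  by \((d_s, d_{s+1})\) and the plane spanned by \((d_{s+1}, d_{s+2})\),
  with the sign given by the right-hand rule about \(d_{s+1}\), in
  \((-180°, 180°]\). Plane angles capture how fast the local plane of
  motion rotates out of itself.

**Pauses.** The direction of a near-zero displacement is numerically
meaningless, so steps slower than 1 µm/min are treated as pauses: any
turning or plane angle touching a pause is undefined and excluded from
distributions and resampling pools (counts of exclusions are retained).
Plane angles at exactly collinear joints (cross product below a relative
tolerance of 1e-8) are likewise undefined. Useful symmetry checks, which
the test suite asserts: rigid motions and uniform scaling leave all
angles unchanged; time reversal preserves both turning and plane angles
(both plane normals *and* the rotation axis flip, so the signs cancel);
a mirror reflection flips chirality and negates plane angles.

**Motility coefficient (MC).** The field summarises dispersal by the mean
displacement \(\langle |p(t+\tau) - p(t)| \rangle\) plotted against
\(\sqrt{\tau}\). We average over all tracks and all start indices
(overlapping lags: standard practice, lower variance, at the price of
correlated curve points), fit a line through the origin by least squares
over a lag window, and report \(\mathrm{MC} = m^2/6\) in µm²/min. The
default window is \(\tau \in [2, 10]\) min: below ~2 min persistent walkers
are still ballistic and the √-law does not hold; 10 min keeps at least
half of a 20-min track's lags well estimated. Window and convention are
arguments of `motility()`. For calibration purposes note the Brownian
anchor: for isotropic diffusion with diffusivity \(D\), displacement is
Maxwell-distributed and \(\langle|r|\rangle = \sqrt{16 D \tau/\pi}\), so
the recovered MC is \(8D/(3\pi)\); the test suite verifies this to 5% on
simulated Brownian cohorts. MC conventions differ between studies — a
point we return to under *Limitations*.

The `motility()` fit is the package's central summary object: per-track
mean speeds, the cohort mean with its SEM (track = unit of replication),
a 12 × 15° turning-angle histogram, the displacement curve and the MC,
with `print`, `summary`, `coef` and `plot` methods.

## The synthetic measured-like cohort

No raw tracks ship with the package, so a generator
(`cohort_spec()` / `generate_cohort()`) emulates the measured cohorts'
statistical structure. The model is a heterogeneous correlated random
walk chosen as the *minimal* parameterisation reproducing the published
summary statistics it is calibrated to:

* each track draws a base speed from
  Normal(`mean_speed`, `between_track_speed_sd`), truncated at zero —
  between-cell speed heterogeneity;
* each step draws its speed from a lognormal around the base with CV
  `within_track_speed_cv`;
* each new direction is a von Mises–Fisher draw about the previous
  direction with concentration
  \(\kappa = \kappa_0 (1 + \beta\, v/\bar v)\): faster steps are
  straighter, the negative speed–turning-angle coupling seen in vivo.

Defaults: 60 tracks (a typical imaging-field yield) of 20 min at 20 s;
`between_track_speed_sd` = 3 µm/min (gives a cohort-mean SEM of ~0.3–0.4
µm/min at typical cohort sizes, matching the precision with which such
speeds are reported); `within_track_speed_cv` = 0.35 (step speeds of
lymphocytes fluctuate strongly within a track); `beta` = 1 (a moderate,
shared coupling — calibration absorbs its interplay with
\(\kappa_0\)). These were fixed once as field-realistic choices; they are
deliberately not per-genotype dials.

**Calibration.** `calibrate_to_targets()` sets `mean_speed` directly (the
generator is unbiased for the cohort mean track speed) and solves for
\(\kappa_0\) by bisection so the generated cohort's MC matches the target;
MC is monotone increasing in \(\kappa_0\) at fixed speed, bracketed below
by the isotropic walk and above by near-ballistic motion, and targets
outside that range raise an error naming the bound. The shipped presets
`cohort_preset("WT")` (13.2 µm/min, 64 µm²/min → \(\kappa_0 = 2.625\)) and
`cohort_preset("ITK")` (11.9 µm/min, 36 µm²/min → \(\kappa_0 = 1.71875\))
were produced by one such calibration run (1000-track cohorts, 1%
tolerance) and are frozen in code so downstream analyses never re-run it;
the test suite checks that fresh preset cohorts recover both targets
(speed within 2%, MC within 10% at a few hundred tracks).

**What the generator does not emulate:** imaging artifacts (drift, track
fusion/fission, z-anisotropy), tissue boundaries, pausing behaviour
(generated speeds are lognormal and essentially never fall under the
1 µm/min pause threshold), and any within-track behavioural switching
(confined vs. directed phases). Consequently, passing tests establish
that the *pipeline* recovers what it is fed, not that real T cells follow
a von Mises–Fisher walk. In particular, the two genotype presets differ
only in speed and persistence; if real Itk-deficient cells instead
achieve their low MC through pausing or phase switching at
WT-like turning angles, encounter outcomes can differ from simulations
built on this generator (see *Limitations*).

## Long-track synthesis by step remixing

Encounter simulations need 8-h tracks; measurements are 20 min. Long
tracks are built from measured short ones in three steps
(`synthesize_tracks()`):

1. **Joint triplet pool** (`build_step_pool()`). Because speed, turning
   angle and plane angle are coupled within a step, we resample them
   *jointly*: the pool holds (speed, turning angle, plane angle) triplets
   taken from the same measured step, with provenance. A step qualifies
   only if all three components are defined at its entry joint — which
   requires two prior displacements (so steps 3, 4, … of each track) and
   excludes pauses and collinear joints. Drawing 1440 steps per 8-h track
   from a pool of a few thousand makes sampling with replacement
   unavoidable, and it is used.
2. **Roughness-matching exchange** (`remix_exchange()`). A freshly
   resampled sequence is temporally white; real tracks are smooth. The
   targets are the measured cohort's mean squared differences of
   consecutive step speeds and of consecutive turning angles (pooled
   within tracks, never across track boundaries). The algorithm proposes
   swapping two random positions and keeps the swap only if it strictly
   decreases the objective
   \(\sum_k \max(0, R_k - T_k)/\max(T_k, \varepsilon)\) over
   \(k \in \{\text{speed}, \text{turn}\}\) — a formalisation of "more
   similar to the measured means" that decreases monotonically to the
   stopping rule *both roughnesses at or below their targets*. Ties are
   rejected; a sequence already below both targets is returned unchanged;
   failure to converge within `max_proposals` (default 2·10⁵) is an
   error, not a silent degradation. Roughness deltas are updated locally
   (only pairs adjacent to the swapped positions change) and the
   bookkeeping is pinned against full recomputation in tests. Pooled
   cohort roughness (not per-source-track roughness) is the target: the
   synthetic track has no single source track.
3. **3D reconstruction** (`reconstruct_track()`). The triplet sequence is
   geometrically completed: the initial direction is uniform on the
   sphere and the initial plane normal uniform orthogonal to it (no
   orientation bias before arena placement); each triplet then rotates
   the plane normal about the current direction by its plane angle,
   rotates the direction about the new normal by its turning angle, and
   advances by speed·Δt. Re-deriving the angle sequences from the
   reconstructed positions reproduces the inputs to 10⁻⁶ (round-trip
   test); the moving frame is re-orthonormalised every step because
   rounding errors otherwise feed back through the rotation axes and
   grow exponentially over 1440-step tracks. The exchange and
   reconstruction inner loops are implemented in C++ (Rcpp), driven by
   R's RNG so runs remain seed-reproducible.

Exchange moves permute the sampled multiset, so synthesis preserves the
pool's marginal distributions exactly; tests additionally check that
synthesized 8-h cohorts keep the measured cohort's MC within 15%.

## The encounter simulation

`arena_config()` defaults encode the study conditions: a 1-mm-diameter
spherical T cell zone; DCs static and uniform in the ball (radius
\(R U^{1/3}\) times a uniform direction; a rejection sampler is kept as a
distributional cross-check); 100 tracks chosen at random per replicate,
each given an independent uniform (Haar) rotation and a starting position
drawn from an isotropic Normal with SD 150 µm about the centre; 8 h at
20-s steps; 50 replicates with fresh DC placement and track selection.

**Contact rule.** A cell whose position comes within 15 µm of any DC is
in stable contact and is frozen at that position for the remainder of the
run ("freeze-on-contact"); its first-contact time is recorded. The
contact threshold is *within* 15 µm — a proximity of at least 15 µm would
make nearly every position a contact. Distance is tested at every step
against actual DC distance regardless of momentary zone membership (DCs
exist only inside the zone, so this differs from an inside-only rule just
within one contact radius of the boundary; testing actual distance is the
simpler, chosen rule). The contact fraction's denominator is all 100
cells, not only those currently in zone. Runs with 10⁴ DCs use a
uniform-grid spatial hash (cell size = contact radius, 27-neighbourhood
query) whose results are pinned to the brute-force all-pairs oracle in
tests; 50-DC runs use vectorised brute force.

**Residency.** Every step whose (possibly frozen) position lies inside
the zone counts as residency, including steps after re-entry. For
calibration-style runs with DCs absent, `residence_half_life()` fits
\(f(t) = f_0 e^{-\lambda t}\) to the mean fraction of cells inside the
zone by least squares on the log-fraction and reports \(\ln 2/\lambda\)
in hours; extrapolation beyond the simulated 8 h is expected, and a
non-decaying curve reports an infinite half-life. The published
calibration this mirrors describes an 11-h average half-life; that
phrase could also be read as a median per-cell residence time — the
exponential-decay reading is implemented, and the ambiguity matters (see
below).

## Reproducibility and problem sizes

All stages consume R's RNG only; `run_full_pipeline()` derives every
stage seed from one master seed, records it with the configuration in a
JSON sidecar next to the outputs, and reproduces byte-identical artefacts
from the same seed. The shipped analysis scale — 60-track measured-like
cohorts, 200 remixed 8-h tracks, 100 cells × 50 replicates — runs in well
under a minute on one CPU; statistical checks in the test suite use up to
10⁴ simulated tracks where a law-of-large-numbers or distributional
assertion needs them.

## Limitations and observed discrepancies

* The generator constrains only the published summary statistics (speed,
  MC, qualitative turning/speed coupling); infinitely many walk models
  satisfy them. Its two presets necessarily differ in turning behaviour
  (\(\kappa_0\) 2.625 vs 1.71875) because at near-equal speeds only
  persistence can halve the MC — whereas measured Itk-deficient cohorts
  are described as having WT-like turning-angle distributions. Where the
  acceptance checks compare end-to-end encounter outcomes against
  published values, the slower preset's outcome is sensitive to exactly
  this modelling gap: less persistent walkers stay confined near the
  DC-rich centre longer, which offsets their reduced scanning rate. The
  package reports what its model computes rather than adjusting
  parameters per outcome.
* The exponential-decay residence half-life computed from these presets
  falls short of the 11-h published calibration value; a
  back-of-envelope Gaussian-dispersal estimate with the dispersal implied
  by MC = 64 µm²/min under this package's MC convention gives ~5–7 h, so
  the gap most likely reflects a different MC convention or residency
  metric upstream, not a simulation defect. The acceptance script reports
  the computed value as is.
* Group-comparison hypothesis testing, image processing and tracking
  itself are out of scope; the contact model ignores DC motility, T–T
  crowding, contact duration and chemokine guidance, and the T cell zone
  is a bare sphere.
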