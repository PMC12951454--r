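---
title: "Hydration-shell, hydrogen-bond and NMR stability analysis with hydrashell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell, hydrogen-bond and NMR stability analysis with hydrashell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrashell)
```

## The problem

Designed proteins that resist heat, acid and pressure often differ from
their templates mainly at the surface, where charged residues reorganise
the adjacent water. Quantifying that reorganisation requires a consistent
set of trajectory-level observables — how many waters sit against the
protein surface, how long they stay, how they hydrogen-bond to the protein
and to each other, and how strongly the protein interacts with its
solvent — together with the solution-NMR observables that report on the
same physics experimentally: amide-shift temperature coefficients,
hydrogen–deuterium exchange (HDX) protection, and rotational correlation
times. `hydrashell` implements this pipeline end to end, with a seeded
synthetic-data generator whose outputs carry known ground truth, so each
stage can be verified against construction rather than against opaque
reference numbers.

## Hydration shells

A water belongs to the **primary hydration shell** when the minimum
distance from its oxygen to any solute heavy (non-hydrogen) atom is at
most `primary_cutoff` (default 3.5 Å), to the **secondary shell** when
that distance lies in `(primary_cutoff, secondary_cutoff]` (default upper
bound 10 Å), and to bulk beyond. Two conventions are deliberate:

* **Ties go to the inner shell.** The band notations "0–3.5 Å" and
  "3.5–10 Å" leave the boundary ambiguous; a closed inner boundary makes
  the partition deterministic and matches the inclusive reading of
  "within 3.5 Å".
* **The water is its oxygen.** Counting "water molecules" needs a single
  reference point per molecule; the oxygen is the standard proxy and makes
  counts unambiguous when hydrogens straddle the boundary.

Distances are computed with a vectorised all-pairs minimum-distance kernel
(`|p - r|^2` expansion with a clamped square root). At the package's
problem sizes — hundreds of waters against tens to hundreds of solute
heavy atoms — this is fast, allocation-bounded by chunking where needed,
and easy to audit; the test suite checks it against an explicit scalar
double loop, so the implementation and its oracle share no code. Periodic
imaging is not applied: the toy systems are non-periodic by construction
and crystallographic waters are finite sets.

**Residence runs.** The literature rarely states how residence times are
computed (continuous versus intermittent survival definitions differ by
factors). Here a run is a *maximal stretch of frames* in which a water
occupies the shell, with interior excursions of at most `gap_tolerance`
frames forgiven (default 0, since no tolerance is given by the protocols
this mirrors). This operational definition is declared, not inferred, and
`gap_tolerance > 0` demands uniform frame spacing because merging runs
across uneven gaps has no well-defined duration.

**Shell volumes and densities.** Water counts per shell are well defined,
but a *density* needs a volume normalisation that protocols usually leave
implicit. `shell_density()` makes it explicit: the shell volume is
estimated by Monte-Carlo rejection sampling in the solute bounding box
padded by `secondary_cutoff`, with the standard error of the hit fraction
propagated to the volume. For a single atom the primary-shell volume must
converge to \((4/3)\pi r^3 = 179.59\,Å^3\) at \(r = 3.5\) Å; the tests
assert agreement within three Monte-Carlo standard errors.

## Geometric hydrogen bonds

A hydrogen bond is a donor–H–acceptor triple with donor–acceptor distance
\(\le\) `hb_distance_cutoff` (default 3.5 Å) and a D–H···A angle within
`hb_angle_cutoff` (default 30°) of linearity. Donors are N/O heavy atoms
with a covalently bound hydrogen; acceptors are all N/O atoms; sulfur is
excluded by default (configurable) because the networks of interest are
water-mediated. Three conventions deserve a note:

* A bare "30° criterion" does not say *which* angle. The common reading
  with a 3.5 Å heavy-atom cutoff is the deviation of D–H···A from 180°,
  and that is the default here; `hb_distance_mode` switches the distance
  to H···A for sensitivity checks rather than pretending the convention
  is unique truth.
* When two hydrogens of one donor both satisfy the criterion toward the
  same acceptor, only the best (smallest deviation) is kept: one physical
  bond, one record.
* Each bond is classified protein–water, water–water or protein–protein,
  and carries the hydration shell of its participating water (the donor
  water for water–water bonds) so per-shell counts fall out directly.

Counts are provably monotone in both cutoffs, invariant to water
enumeration order, and are tested against an exhaustive triple-loop
oracle on randomly generated systems.

## Nonbonded energies and compactness

`nonbonded_energy()` sums, over cross pairs within `energy_cutoff`
(default 12 Å), the 12-6 Lennard-Jones term with Lorentz–Berthelot mixing
and the Coulomb term with \(k_C = 332.0637\) kcal Å mol\(^{-1}\)
e\(^{-2}\) and configurable relative dielectric. Truncation is plain — no
switching function, no Ewald, no long-range correction — because this is
an *analysis* energy over saved frames, not a simulation force field; the
declared cutoff is the entire protocol. Parameters (charges, σ, ε) are
never guessed: they come from the generator or from a side-car table, and
missing parameters are an error naming the atoms.

The radius of gyration uses the mass-weighted second moment about the
mass-weighted centroid; `detect_unfolding()` flags the first frame whose
Rg exceeds `factor` (default 1.5) times the mean over a leading baseline
window (default 5 % of the series). Both thresholds are artifact
parameters, declared rather than fitted: high-temperature unfolding
claims at production scale cannot be regenerated at desk scale, so the
unfolding detector is validated on constructed step series only.

**Cumulative averages.** All trajectory metrics can be smoothed by a
running mean after a burn-in (`burn_in_time`, default 40 000 ps, i.e.
the first 40 ns of a 500 ns protocol). Frames with `time <` burn-in are
discarded; with frames saved every 100 ps from \(t = 0\) this retains
exactly 4600 of 5000 frames — the frame bookkeeping the tests assert.

## NMR observables

* **Temperature coefficients.** Ordinary least squares of shift (ppm)
  against temperature (K) per residue, reported in ppb/K. The default
  temperature grid of the generator spans 281–320 K in 5 K increments.
  Residues with fewer than three points are skipped with a warning. The
  empirical hydrogen-bond rule is a *strict* threshold: slope \(>\)
  `tempco_threshold` (default −5.0 ppb/K; −2.72 ppb/K is the common
  alternative calibration) ⇒ intramolecularly hydrogen bonded. Profile
  comparisons use Pearson correlation over the residue-key intersection
  (Spearman available), with no imputation.
* **HDX protection.** The ratio \(I(t)/I(0)\) per residue, residues with
  non-positive reference intensity excluded with a warning. Threshold
  inclusivity follows the source notation: "ratio ≥ 0.2" is inclusive,
  thresholds quoted as "> 60 %" or "> 10 %" are strict; both are exposed.
  No intrinsic-exchange (pH) correction is applied — ratios are reported
  raw.
* **Rotational correlation time.** The single-field isotropic estimator
  \(\tau_c = \sqrt{6 R_2/R_1 - 7} / (4\pi\nu_N)\) with
  \(\nu_N = 0.10136767\,\nu_{1H}\). This closed form replaces full
  spectral-density/anisotropic fitting: it is defined, invertible (the
  tests verify round-trip identity to \(10^{-6}\)) and adequate for
  magnitude-level comparisons; it assumes isotropic tumbling and
  negligible fast internal motion, and errors outside its domain
  (\(6R_2/R_1 - 7 \le 0\)) instead of returning complex values.

## Sequence charges

The default charge scheme counts K/R positive and D/E negative, histidine
neutral, termini excluded. This scheme reproduces two independent
bookkeeping anchors for the ubiquitin system family: the 11 positive / 11
negative composition of the 76-residue ubiquitin sequence, and the three
sodium counterions required by a 12/15 variant composition (net −3). Note
a documented inconsistency in the source material for one variant: a
printed 15/16 composition (net −1) coexists with the statement that no
counterions were needed for that variant, and the stated enrichment
percentages (~6 %/~3.5 %) do not follow from 15/16 vs 11/11 over 76
residues under any single normalisation. The default scheme is therefore
validated on the two self-consistent anchors only and the discrepancy is
surfaced here rather than silently resolved. Percent compositions use the
full sequence length as denominator; no pKa model is applied (pH-dependent
charge is out of scope).

## The synthetic generator: what it emulates and what it does not

`make_toy_system()` builds a compact convex solute — charged heavy
pseudo-atoms on a Fibonacci-sphere shell (spacing ≈ 2.5 Å, alternating
±0.5 e, N/O elements so the solute can accept hydrogen bonds) — and
places three-site waters with TIP3P-like charges (O −0.834 e, H +0.417 e,
LJ on oxygen only) at *exact* prescribed distances from their nearest
solute atom. The convex shell is what makes exactness cheap: a water
placed radially outward from the extreme atom along any direction has
that atom as its nearest neighbour by construction. Hydrogen-bond
geometry is prescribed in closed form: for a bent geometry the O–H
direction is solved (law of sines in the D–H–A triangle) so the realised
D–H···A deviation equals the requested angle exactly, not approximately.

`make_trajectory()` realises per-water occupancy patterns: inside its
intervals a water sits at an "in" position in the pattern's shell,
outside at a bulk position beyond the secondary cutoff, with isotropic
Gaussian jitter truncated at 3 sd. Truncation is what turns jitter into a
*guarantee*: the 3 sd bound is checked against every shell-boundary
margin up front, so a generated trajectory can never flip a shell
assignment by noise, and an infeasible jitter level is an error rather
than a silent corruption. The whole system additionally receives a common
rigid translation per frame so the solute moves without internal motion.

The generator's NMR tables are linear shift series with known slopes
(realistic magnitudes −0.64 to −5.3 ppb/K), mono-exponential HDX decays
with a designated protected subset, and variant sets with exactly
`extra_pos`/`extra_neg` charged substitutions at non-charged positions.
Every generator stores its ground truth (as attributes and side-car
tables), and the invariant tested throughout is: *the corresponding
analysis operation applied to generator output recovers the stored truth
exactly in noise-free settings*.

What the toys do **not** emulate: realistic water dynamics and exchange
kinetics, periodic boundary conditions, force-field-accurate internal
geometries, correlated noise in spectra. A green test suite therefore
demonstrates that the *computations* are correct on inputs with known
answers — it does not certify conclusions about any particular real
protein, for which real trajectories and spectra must be supplied through
the same interfaces.

## Problem sizes and numerical choices

The test suite runs on systems of up to ~100 waters (≥ 20 random systems
per oracle-comparison property) and trajectories of tens of frames;
Monte-Carlo volumes use \(2\times10^4\)–\(2\times10^5\) samples with
3-standard-error assertions. These sizes were chosen so the whole suite
exercises every code path in seconds while keeping Monte-Carlo and
least-squares assertions statistically meaningful. Other numerical
choices: distances compare squared norms clamped at zero before the
square root; angle cosines are clamped to [−1, 1]; the shell partition is
half-open with ties inward; energy chunking bounds the largest distance
matrix at ~3000 columns; r² is clipped to [0, 1] and set to 1 for exactly
constant responses (zero total sum of squares).

## Known limitations

* Production-scale comparisons (hundreds of nanoseconds, tens of
  thousands of atoms) are out of the tested envelope; the pure-R kernels
  will work but have not been profiled there.
* `read_structure()` accepts PDB only (fixed columns, multi-model);
  mmCIF and binary trajectory formats are out of scope, as is topology
  parsing — nonbonded parameters always arrive via side-car tables.
* The τc estimator is a single-field isotropic approximation; do not use
  it where anisotropic diffusion is the question.
* Residence-time results depend on the declared run-length definition;
  compare alternatives via `gap_tolerance` before quoting absolute times.

## A worked example

```{r example, eval = FALSE}
cfg <- analysis_config(burn_in_time = 0)
toy <- make_toy_system(12, c(
  lapply(1:4, function(i) water_placement("primary", 2.8, hb_partner = 2 * i,
                                          hb_geometry = "linear")),
  lapply(1:3, function(i) water_placement("secondary"))), seed = 1)
traj <- make_trajectory(toy, lapply(1:4, function(w)
  occupancy_pattern(w, c(1, 50))), n_frames = 50, jitter_sd = 0.05,
  seed = 2, config = cfg)

shell_counts(traj, toy$system, cfg)            # 4 primary, 3 -> bulk waters
hbond_counts(traj, toy$system, cfg)            # 4 protein-water bonds/frame
residence_times(traj, toy$system, cfg)$summary # one 50-frame run per water
protein_water_energy_series(traj, toy$system, cfg)$cumulative
```

The full end-to-end demonstration, including the comparative study and
all ground-truth assertions, is `run_synthetic_demo(seed = 1)`.
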