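---
title: "Supervised MD, metadynamics release and trajectory analysis on toy systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised MD, metadynamics release and trajectory analysis on toy systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumdr)
```

## The method

Supervised molecular dynamics (SuMD) accelerates the observation of rare
binding and unbinding events without adding any energetic bias.  A long
simulation is replaced by a sequence of short unbiased windows.  During each
window a supervised metric — by default the distance between the ligand
centroid and the binding-site centre — is sampled at regular intervals and
fitted to a straight line.  For binding, a negative slope makes the window
*productive*: the next window continues from the last coordinates and
velocities produced.  Otherwise the window is discarded and the simulation
restarts from the last accepted state with velocities freshly drawn from the
Maxwell–Boltzmann distribution (a tabu-like move: the rejected excursion is
forgotten, but the stochastic restart explores a different path).  Because
every window is plain MD, accepted trajectories are genuine dynamics; the
selection only redistributes which stretches of dynamics get kept.

The binding supervisor uses 500 ps windows sampled every 50 ps and stops
when the end-of-window supervised distance falls below 4 Å.  Unbinding uses
a *double supervision* — the site distance and the number of solvent beads
bridging ligand and receptor must both trend upward — and an adaptive window
length: with the distance r_L at the end of the previous productive window,

* r_L ≤ D1 → Δt = Δt0,
* D1 < r_L ≤ D2 → Δt = Δt0·Nt1,
* D2 < r_L ≤ D3 → Δt = Δt0·Nt2,
* D3 < r_L → Δt = Δt0·Nt3,

with defaults Δt0 = 300 ps, (Nt1, Nt2, Nt3) = (3, 6, 10) and
(D1, D2, D3) = (5, 8, 10) Å, so that windows lengthen as the ligand recedes
and metastable states along the exit pathway get sampled rather than rushed.
Unbinding terminates when no ligand–receptor pair remains within the 3.5 Å
contact cutoff.

Two companions complete the protocol family.  *Path sampling* removes the
(mild) selection bias of a supervised trajectory: frames are aligned on the
receptor, clustered by ligand RMSD to the start in 1 Å bins, one frame per
bin is drawn uniformly at random, and an unsupervised run is launched from
each with resampled velocities; downstream analyses use only these
continuations.  *Well-tempered metadynamics* drives ligand release by
depositing Gaussian hills (height 0.1 kcal/mol, width 0.1 Å, every 1 ps) on
the ligand-to-site distance, with heights tempered as
w_k = w0·exp(−V(s)/((γ−1)·kB·T)), γ = 20, until the biased distance reaches
50 Å.  The tempering formula is the standard well-tempered rule implied by a
stated bias factor; the first hill always has height exactly w0 because no
bias has accumulated yet.

## The toy engine and what it stands in for

All protocols here run on bead-and-potential toy systems integrated by a
Langevin BAOAB scheme, not on all-atom solvated complexes.  The composite
potential offers a Gaussian funnel well at the binding site (depth in
kcal/mol, width in Å), pairwise soft-core repulsion, a confining sphere, an
optional harmonic well (used by the calibration tests) and a quartic double
well (the barrier-crossing benchmark).  Receptor beads are held fixed by
default — the simplest stand-in for a restrained receptor scaffold — with an
opt-in harmonic restraint; solvent beads are inert spheres whose only job is
to exercise the bridging-solvent metric.  Units are Å, ps, K, kcal/mol and
amu throughout, with kB = 0.0019872 kcal/(mol·K).

A velocity-carrying integrator is not optional: the SuMD restart rule
("randomly reassign the velocities, keep the coordinates") only makes sense
if states carry velocities.  BAOAB was chosen because it samples the
configurational Boltzmann distribution accurately at large friction and
reduces gracefully to a deterministic velocity-Verlet-like scheme at T = 0
(the package's zero-temperature fixed-point tests rely on this).

### Friction, and the regime where supervision helps

The one genuinely consequential engine parameter is the friction
coefficient.  The fixtures use γ = 250 ps⁻¹, which gives a 20 amu bead the
diffusion constant of a small molecule in water,
D = kB·T/(m·γ) ≈ 0.05 Å²/ps.  This matters for a structural reason: SuMD
pays for rejected windows (their integration steps are spent and then
discarded), and it earns its keep only when a window is short compared with
the time the ligand needs to diffuse across the search volume — then an
accepted window locks in a genuine few-Å gain that diffusion would otherwise
undo.  At unrealistically low friction the ligand re-equilibrates across the
whole confining sphere *within* one 500 ps window, end-of-window states are
near-equilibrium draws regardless of acceptance, and no supervision scheme
could do better than unsupervised search.  At aqueous-like friction the
bundled funnel system reproduces the method's claim: the median number of
integration steps to reach the binding criterion is about 3× smaller for the
supervisor than for plain dynamics with the same engine settings (the test
suite measures and reports the ratio over 20 seeds).

### Fixture conditions

`funnel_binding` starts the ligand 32 Å from the site (in a random
direction, so different seeds give genuinely different searches) against a
5 kcal/mol, 2.5 Å-wide site well inside a 40 Å sphere — deep enough
(~8 kB·T) that capture is effectively absorbing.  `bound_complex` uses a
3 kcal/mol, 2 Å well with four receptor beads 3 Å from the ligand: a weak,
fast-off binder, so the unbinding and release protocols complete at desk
scale while still having to climb out of a real well; its confining sphere
is 60 Å so the metadynamics release can reach its 50 Å stop criterion.
`solvated_complex` adds 60 solvent beads in a 15 Å droplet (placed by
rejection sampling with a 2.2 Å exclusion distance) to make the
double-metric supervisor exercisable.  `double_well_1d` is a 5 kcal/mol
(~8 kB·T) quartic barrier with minima 5 Å apart and a transverse harmonic
restraint; its unbiased crossing time at 300 K is tens of nanoseconds,
against a few hundred picoseconds once hills accumulate.

## Design choices where the protocol is underdetermined

* **Zero slope is non-productive** in both directions.  The acceptance
  rules are stated as strictly "negative"/"positive"; a zero slope means no
  progress, so the conservative reading rejects it.  The choice only
  matters on measure-zero inputs — and for the degenerate case of a
  constant metric (e.g. supervising solvent bridges in a system with no
  solvent), where accepting would be clearly wrong.
* **Default unbinding metrics adapt to the system.**  The double metric is
  [site distance, bridging-solvent count] when solvent beads exist and the
  site distance alone otherwise: a solvent-free system has an identically
  zero second metric whose slope can never be positive, and supervising it
  would make unbinding non-terminating by construction.
* **Scheduling distance.**  Whether the r_L entering the window-length
  schedule is the supervised centroid distance or a minimum interatomic
  distance is not fixed by the protocol description; the supervised
  centroid distance is used (it is the quantity the supervisor already
  inspects), and the per-window log records the value each length was
  scheduled from, so the choice is auditable.
* **Termination is evaluated on the supervision stream** (end-of-window
  samples), not on mid-window minima: the supervisor should only act on
  what it observes.
* **Partner-set update.**  After each productive unbinding window the set
  of receptor beads defining the bridging-solvent metric is re-detected as
  those within the contact cutoff of the ligand; if the detection is empty
  the previous set is retained (the fall-back to "whatever still interacts"
  when no hydrogen bond remains).
* **Binding centroids are geometric** by default with a mass-weighted
  option, matching the tool's accepted usage of either.
* **Metadynamics runs on the built-in engine.**  The history-dependent
  bias force must be evaluated inside the integrator loop, which the
  pluggable run-N-ps engine contract cannot express; the supervisor and
  path sampler keep the generic contract.
* **Hills are stored exactly** (no grid interpolation); the bias and its
  analytic derivative are direct Gaussian sums, and hills beyond 8σ of the
  current CV value are skipped inside the integrator (an error below
  10⁻¹⁴ of a hill height).
* **Interaction energy replaces a solvated end-point energy.**  Landscape
  colouring uses the engine's ligand–receptor terms (site well plus
  ligand–receptor repulsion), which is the toy's exact analogue of an
  interaction energy; the landscape *depth* axis is the occupancy-derived
  −kB·T·ln p at the engine temperature, with empty bins reported as NA,
  never zero.
* **Boundary semantics of the detectors.**  Contacts are strict
  (< 3.5 Å); hydrogen bonds are inclusive (≤ 3.5 Å and ≥ 120°, the angle
  measured at the hydrogen).  The difference is only visible on
  measure-zero inputs but is frozen in the tests.
* **Contact persistency is residue-level** (a partner counts once per
  frame however many atom pairs qualify), configurable through the
  extractor function.
* **Occupancy mapping** uses 1 Å voxels by default and scores the fraction
  of pooled frames with at least one solvent bead in the voxel; "hydrated
  spots" are voxels above 0.5 occupancy.  This is an occupancy-fraction
  stand-in in the spirit of published hydration-site mapping tools, whose
  internals are not reproduced here.

## Numerical choices

The integrator timestep default is 0.01 ps; every fixture keeps
ω·dt ≤ 0.1 for its stiffest mode.  Durations must be integer multiples of
the save interval, and save intervals integer multiples of the timestep —
violations are validation errors, not silent rounding.  Runs are
bit-reproducible for a fixed seed (the C++ core draws from R's RNG);
supervised runs derive per-window simulation and restart seeds from the
root seed by a pre-generated table, so a rejected window's restart is
reproducible and independent of how many rejections preceded it.
Blow-ups (non-finite or absurd coordinates) abort with the frame index
rather than returning garbage.

## What the tests do and do not show

The test suite checks the machinery against independent oracles (closed-form
least squares, a hand-coded four-branch scheduler, brute-force O(N²)
detector recounts, a quaternion superposition method, equipartition at three
temperatures) and checks the protocol-level claims on the toy systems:
binding stops below 4 Å, unbinding stops contact-free, release stops at
50 Å, supervision beats unsupervised search, bias beats unbiased barrier
crossing.  Problem sizes are deliberately small — 5 to 65 beads,
nanosecond-scale runs, 20-seed medians — which is what the toy engine is
for.  None of this validates force fields, solvation, or any biological
claim about a real receptor; what it validates is that the adaptive-sampling
logic, the scheduler arithmetic, the bias bookkeeping and the analysis
operators do exactly what their definitions say, so that conclusions drawn
with this machinery on real engines fail only for physics reasons, not
bookkeeping ones.

## A complete run

```{r, eval = FALSE}
library(sumdr)

fx <- generate_fixture("funnel_binding", seed = 42)
res <- run_sumd_binding(fx$system,
                        config = supervision_config("binding", seed = 42))
print(res)
window_log(res)

# relax the supervision bias, then analyse only the relaxed runs
bins <- bin_frames_by_rmsd(res$trajectory, fx$system)
paths <- seed_path_sampling(bins, res$trajectory, fx$system,
                            run_length = 1000, seed = 42)

cv1 <- unlist(lapply(paths, function(p)
  vapply(seq_len(n_frames(p)), function(i)
    ligand_site_distance(fx$system, get_frame(p, i)), numeric(1))))
en <- unlist(lapply(paths, function(p)
  vapply(seq_len(n_frames(p)), function(i)
    interaction_energy(fx$system, get_frame(p, i)), numeric(1))))
z <- unlist(lapply(paths, function(p) p$coords[, 1, 3]))
energy_landscape(cv1, z, en, bin_width = c(1, 1),
                 temperature = fx$system$temperature)
```
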