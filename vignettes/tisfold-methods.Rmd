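---
title: "tisfold: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tisfold: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tisfold)
```

This vignette is the package's own account of the science it implements:
the coarse-grained model and its assumptions, the tunable parameters and
why their defaults are what they are, the analysis definitions, the
numerical choices, and the limits of what the shipped tests demonstrate.

## The three-interaction-site model

Each nucleotide is represented by three beads — phosphate (P), sugar (S)
and base (B) — so an N-nucleotide chain has 3N − 1 beads (the 5′-terminal
nucleotide carries no phosphate, leaving N − 1 backbone charges). Mg²⁺,
K⁺ and Cl⁻ ions are explicit point charges with excluded volume; water is
implicit and enters only through the empirical temperature-dependent
dielectric constant ε(T) (Malmberg–Maryott polynomial). All coordinates
are in nm, energies in kcal/mol, charges in units of e; the system lives
in a cubic periodic box under the minimum-image convention.

The potential is

$$U = U_{bond} + U_{angle} + U_{EV} + U_{HB} + U_{ST} + U_{ele}.$$

* **Bonds** are harmonic, $k_b (r - r_0)^2$, over P–S, S–B and S–P(+1)
  with natural lengths measured from the reference structure (Gō-style).
* **Angles** are cosine-harmonic,
  $k_\theta (\cos\theta - \cos\theta_0)^2$. The cosine form is a
  deliberate numerical choice: the gradient of $\theta$ itself is
  singular at straight angles, which backbone angles visit, and the
  singularity destabilizes stochastic integration; the gradient of
  $\cos\theta$ is regular everywhere.
* **Excluded volume** is a purely repulsive WCA-style shifted
  Lennard-Jones, active only below the contact distance
  $\sigma_{ij} = R_i + R_j$, zero (with continuous force) beyond it, and
  strictly nonnegative.
* **Hydrogen bonds** are Gaussian (Morse-like) wells in the base–base
  distance, modulated by the two flanking sugar–base–base angles in
  cosine space:
  $-\varepsilon \exp[-k_r (r - r_0)^2 - k_\theta \sum (\cos\theta_i -
  \cos\theta_{i,0})^2]$. Eligibility is dynamic: *any* canonical (G–C,
  A–U) or wobble (G–U) combination at sequence separation ≥ 4 becomes an
  active candidate once its base beads enter the capture range, so
  non-native (mispaired) helices arise naturally during folding. Each
  base may hold at most one secondary partner at a time; the most
  negative candidate wins, ties resolved toward the lower residue index.
  Native pairs use per-pair natural geometry from the reference frame and
  a deeper well than non-native pairs. Registered tertiary hydrogen bonds
  (read off the reference structure) are plain distance wells between
  arbitrary beads.
* **Stacking** wells act between base beads of consecutive nucleotides
  (natural distances from the reference), plus registered tertiary
  stacks.
* **Electrostatics** is truncated-and-shifted Coulomb under minimum
  image, $q_i q_j\, l_B k_B T / r$ up to a configurable cutoff (default
  3 nm). An Ewald treatment is deliberately out of scope for the system
  sizes this package targets; the truncation length should be kept small
  relative to the box.

Every constant lives in `tisParams()` and can be overridden per call. The
defaults form a self-consistent desk-scale calibration: they give stable
dynamics, a stably folded toy hairpin at 37 °C, and correct limiting
behaviour in the shipped tests. They are **not** the published
transferable TIS calibration fitted to nucleotide-dimer, hairpin and
pseudoknot thermodynamics, which is distributed with its original
simulation code; quantitative thermodynamic predictions for real RNAs
should not be read off these defaults.

Key parameters (units, default, rationale):

* `kBond` (kcal/mol/nm², 100) and `kAngle` (kcal/mol, 10): soft enough
  that the stiffest bonded modes relax over ≳ 1 ps, letting the Brownian
  integrator take 0.2 ps steps; stiff enough that the folded basin is
  structurally tight (≈ 0.1 nm RMSD for the toy hairpin).
* `epsHb` / `epsHbNonnative` / `epsHbTertiary` (kcal/mol, 8 / 5.5 / 6):
  native pairing is favoured over mispairing; the deep tertiary wells
  make the reference structure the clear global minimum.
* `krHb` (nm⁻², 40) and `kthHb` (1.0, in cos² units): well widths; wider
  wells cost less bound-state entropy and stabilize pairing.
* `radii` (nm): P 0.21 so that the P–Mg²⁺ contact distance is
  0.21 + 0.23 = 0.44 nm, placing the ion-contact shell just outside the
  excluded-volume wall; base radii (0.13–0.14) are small enough that
  stacked bases at ~0.35 nm clear the repulsive core — a clearance
  requirement, not a structural statement.
* `eleCutoff` (nm, 3.0): electrostatic truncation.
* `contactEnergyKT` (1): an interaction is counted as *formed* when its
  well energy is below −k_B T — the package's operational definition of
  contact formation, exposed because any such threshold is a convention.

## Simulation protocols

`simulationProtocol()` bundles temperature (default 37 °C), box edge, ion
concentrations, viscosity (water, 8.9 × 10⁻⁴ Pa·s), friction scale, time
step, save schedule and seed. Ion counts follow
`round(concentration × boxVolume × N_A)`; Cl⁻ enforces charge neutrality
(in boxes too small for the concentration-derived cations to neutralize
the RNA, extra K⁺ counterions are added — only relevant for toy systems).

**Unfolded-ensemble preparation** uses underdamped Langevin dynamics
(BAOAB splitting) at [Mg²⁺] = 0 with the friction reduced to 1% of the
solvent value: lower friction accelerates configurational diffusion
without changing the sampled Boltzmann distribution (verified in the test
suite by friction-independence of observable averages).
`selectSeparatedFrames()` then enforces a minimum pairwise RMSD between
frames kept as folding initial conditions — the package makes the
"well-separated initial structures" requirement operational with an
explicit, configurable criterion (default 1.5 nm, to be scaled down for
small systems).

**Folding runs** use free-draining Ermak–McCammon Brownian dynamics at
full water viscosity with per-bead Stokes–Einstein diffusion coefficients
$D_i = k_B T / 6\pi\eta a_i$; hydrodynamic interactions are omitted, the
standard choice for this model class. The Mg²⁺ jump is implemented
literally: ions are re-drawn at the folding condition around the final
equilibrium frame with the RNA coordinates untouched, and time restarts
at zero.

Numerical choices for the propagators:

* **Time step.** The Brownian default is 0.2 ps. The constraint is that
  the step resolve the fastest force relaxation time γ/k of the stiffest
  mode (bond and angle modes, ≈ 1–2 ps with the default constants) *and*
  that per-step displacements stay small against the excluded-volume
  shell width. Mapping a step count to physical time therefore depends on
  this choice and is configurable. The Langevin step must resolve the
  fastest vibrational period; 0.05 ps is safe with the default registry.
* **Safety rejection.** A step that would move any site farther than
  `maxDisp` (default 0.3 nm, several standard deviations of the thermal
  displacement) is redrawn at half the step, recursively with bounded
  depth, and counted in the trajectory's `nRejected`; if the recursion
  bottoms out the displacement is clamped. This catches the rare
  excluded-volume force spikes of discrete-step dynamics without
  affecting ordinary sampling.
* **Random numbers** come from a counter-based generator keyed by (seed,
  absolute step, stream index), so trajectories are bit-reproducible and
  a restart from a checkpoint with the same seed and step offset is
  bit-identical to the uninterrupted run (tested).
* Saved coordinates are wrapped into the box; `unwrapChain()` re-images a
  molecule split across periodic faces before RMSD/Rg analysis. The
  potential itself is minimum-image and unaffected.

## Analysis definitions

* **Rg and C.V.** Equal-mass radius of gyration over RNA beads (no mass
  table exists at this resolution); the ensemble coefficient of variation
  C.V.(t) = sd/mean across trajectories measures pathway heterogeneity.
* **Collapse fit.** `fitCollapse()` fits
  $R_g(t) = R_{gU} - (R_{gU} - R_{gF}) \sum_i \Phi_i (1 - e^{-t/\tau_i})$
  with $\sum_i \Phi_i = 1$, $\tau_i > 0$, $R_{gU} > R_{gF}$ enforced
  exactly by a softmax/log reparameterization, minimized by multi-start
  bounded quasi-Newton. The AIC supports the two-versus-three phase
  comparison. Time constants are bounded above at `tauMaxFactor` (1.5) ×
  the last observation time: a decay truncated at T cannot identify
  slower time constants, and leaving them unbounded lets the slowest
  phase drift and drag the plateau and amplitudes with it. The slowest
  fitted time constant of a truncated dataset is a lower-bound estimate
  by construction.
* **Folding and compactness.** Folded ⇔ superposition (Kabsch) RMSD to
  the native structure < 0.6 nm; compact ⇔ Rg ≤ 3.5 nm. Both cutoffs are
  arguments; the defaults are the full-ribozyme scales and should be
  scaled for smaller systems.
* **Structural overlap χ.** Defined here as the fraction of bead pairs
  (sequence separation ≥ 2 nucleotides) whose distance lies within 0.2 nm
  of its native value — a concrete realization of a similarity order
  parameter with the correct endpoints (1 at the native structure, → 0
  for unrelated conformations). Tolerance and separation are exposed.
* **Element formation** counts an element's registered interactions with
  well energy below −k_B T. **Mispaired-helix scanning** reports maximal
  runs of ≥ 4 (configurable) consecutive formed non-native pairs,
  labelled by the registry's strand segments.
* **Kinetic partitioning.** Empirical cumulative first-passage fractions
  Φ^F(t), Φ^M(t); outcomes split at 5 ms (rapid vs slow folding), with
  right-censoring at the duration cap.
* **Ion condensation** uses the Bjerrum length (0.73 nm at 37 °C,
  computed from first principles via ε(T)) as the distance cutoff, so
  monovalent and divalent cations are compared on equal footing; each ion
  counts once regardless of how many phosphates it neighbours. The
  **contact Mg²⁺ concentration** divides the time-averaged shell count
  (r₀ ± Δr, defaults 0.44 ± 0.15 nm) by the shell volume (0.7581 nm³)
  with 1 nm⁻³ = 1.66054 M; a permanently occupied shell is ≈ 2.19 M.
  **Binding kinetics** takes the first frame time at which any Mg²⁺
  enters a site's shell (frame resolution, no interpolation — binding is
  detected from recorded snapshots), averages over trajectories excluding
  censored runs (with a warning; exclusion vs imputation is a
  documented choice), and reports k_b = 1/MFPT. **Concurrency** flags
  trajectory pairs with |τ_contact − τ_ion| < 0.2 ms, reports the Pearson
  correlation over all pairs, and counts contact-precedes-binding
  violations for the necessity test.
* **Clustering.** Compact frames (Rg ≤ cutoff) are reduced by seeded
  random selection (floor(n/factor)), featurized with DRID — per-centroid
  mean, √second and ∛third central moments of reciprocal distances to all
  beads excluding the same and adjacent nucleotides; rigid-motion
  invariant by construction — and clustered with Ward's method. The
  number of clusters defaults to the largest merge-height gap in the
  dendrogram (an explicit, overridable convention); representatives are
  medoids.
* **Footprinting.** SASA by Shrake–Rupley sampling with a deterministic
  960-point spiral lattice and 0.14 nm probe, computed directly on the
  coarse-grained beads with the sugar bead as the per-nucleotide proxy
  for backbone accessibility. All-atom reconstruction is intentionally
  not performed; the bead-level proxy preserves the burial signal that
  the protection factor measures, at the cost of absolute-area accuracy.
  F_p(i) = ⟨SASA(i)⟩_Unfolded / ⟨SASA(i)⟩_state; nucleotides with
  F_p ≥ 1.2 (closed boundary) are predicted protected, and
  `compareProtection()` scores sensitivity/specificity against reference
  protected sets.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable without external inputs:

* `makeHairpin()` builds a stem-loop with idealized helical coordinates
  and a Gō-style registry — including a native contact network (bead
  pairs within 1.1 nm registered as tertiary wells), the analogue of
  registering crystal-structure tertiary contacts for a real RNA.
* `makeRgEnsemble()` draws per-trajectory collapse curves as the
  three-exponential model plus i.i.d. Gaussian per-frame noise (default
  σ = 0.3 nm). Real single-trajectory dispersion is temporally
  correlated and state-dependent; i.i.d. noise is the minimal model that
  exercises ensemble averaging and fit recovery.
* `makeIonEventTrajs()` synthesizes ion coordinates that reproduce drawn
  binding first-passage times exactly at frame resolution.
* `makeConformerEnsemble()` provides Native (jittered), Misfold (rigid
  displacement of the 3′ half) and Unfolded (affine expansion) analogs.
  The misfold analog is deliberately *not* a literal strand-threading
  topological trap — at 12 nt there is no room for one; it preserves the
  property the analyses must detect (native-like yet forming its own
  cluster with distinct protection pattern).

Consequently, passing tests demonstrate correctness of the machinery —
energies, integrators, estimators, classifiers — under controlled ground
truth. They do not demonstrate that a full-length ribozyme folds with the
published yields or per-site fingerprints; that requires the production
calibration and cluster-scale trajectories (95 × 30 ms at ~200
nucleotides), far beyond the desk-scale problem sizes used here (12-nt
hairpins in ~10 nm boxes, sub-microsecond runs, chosen so the whole suite
runs in minutes on one core).

## Degenerate inputs and edge behaviour

Overlapping sites (< 10⁻⁶ nm) abort energy evaluation naming the pair;
empty frame sets, mismatched time grids, unknown element names, bead
count mismatches, non-complementary registered pairs and non-RNA chains
are errors; all-censored MFPTs and sub-two-point correlations return NA
with a warning; infinite protection factors (zero mean SASA) are excluded
from comparisons with a warning. Ties in the hydrogen-bond matching go to
the lower residue index; the protection threshold boundary is closed
(F_p = threshold counts as protected).

## Known limitations

* The default force-field constants are a desk-scale calibration; no
  claim of thermodynamic transferability is made.
* Electrostatics is cutoff-based; long-range corrections (Ewald) are out
  of scope, so very large boxes with dilute ions should be treated with
  care.
* Hydrodynamic interactions are neglected (free-draining).
* Collapse-fit confidence intervals are local (Hessian-based) and
  approximate; the slowest time constant of truncated data is a lower
  bound.
* SASA on beads tracks burial trends, not absolute accessible areas.
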