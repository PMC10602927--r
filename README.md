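# tisfold

Coarse-grained RNA folding simulation with explicit ions, and the
downstream kinetic analyses used in Mg²⁺-driven folding studies of large
ribozymes — in one R package, testable end-to-end at desk scale.

## Who this is for

RNA folding is usually triggered by divalent cations: jumping the Mg²⁺
concentration collapses an unfolded ribozyme through multiple kinetic
phases into its native tertiary structure, with a fraction of molecules
trapped in misfolded states. Simulating this requires (i) a coarse-grained
representation cheap enough to reach milliseconds, (ii) explicit ions so
that counterion release and site-specific Mg²⁺ binding are observable, and
(iii) a battery of trajectory analyses — collapse-kinetics fitting,
folding/misfolding classification, ion condensation statistics,
conformational clustering and footprinting-style protection factors. This
package implements all three layers for researchers who want to run the
pipeline on small RNAs, prototype analyses against synthetic data with
known ground truth, or analyse externally produced coarse-grained
trajectories.

## The model

Each nucleotide is reduced to three interaction sites — phosphate (P,
charge −1e), sugar (S) and base (B) — with explicit Mg²⁺, K⁺ and Cl⁻ ions
in a periodic cubic box and implicit water entering only through the
temperature-dependent dielectric ε(T). The potential is

```
U_TIS = U_bond + U_angle + U_EV + U_HB + U_ST + U_ele
```

harmonic bonds and (cosine-harmonic) angles about natural values, purely
repulsive excluded volume, attractive distance/angle-modulated wells for
hydrogen bonds and base stacking, and truncated-and-shifted minimum-image
Coulomb electrostatics. Hydrogen bonding is dynamic: any canonical (G–C,
A–U) or wobble (G–U) combination can pair, so mispaired (non-native)
helices arise naturally, while tertiary hydrogen bonds and stacks are
registered from a reference structure. Two propagators cover the standard
protocol: low-friction underdamped Langevin dynamics to sample the
Mg²⁺-free unfolded ensemble, and Brownian dynamics at water viscosity for
folding runs after the Mg²⁺ jump. All force-field constants live in one
editable list (`tisParams()`); the defaults are a self-consistent
desk-scale calibration, not the published transferable-parameter set.

Analyses include: radius-of-gyration ensembles with the coefficient of
variation; the sum-constrained multi-exponential collapse fit
`Rg(t) = RgU − (RgU − RgF) Σᵢ Φᵢ (1 − exp(−t/τᵢ))` with AIC-based phase
selection; distance distributions P(r); superposition RMSD and the folded
(RMSD < 0.6 nm) and compact (Rg ≤ 3.5 nm) classifiers; structural overlap
χ; per-helix and per-element formation fractions; mispaired-helix
detection (runs of ≥ 4 consecutive non-native pairs); first-passage-time
analysis and kinetic partitioning; ion condensation (Bjerrum-length
cutoff), contact Mg²⁺ concentrations, binding MFPTs and rates, and
binding↔folding concurrency; DRID/Ward conformational clustering; and
hydroxyl-radical-footprinting-style protection factors from
Shrake–Rupley SASA on the coarse-grained beads.

## Worked example

Build a 12-nt toy hairpin, add 5 mM Mg²⁺ / 12 mM K⁺, run 100 ns of
Brownian dynamics, and analyse the result:

```r
library(tisfold)

hp <- makeHairpin(nStem = 4, nLoop = 4, boxEdge = 10)
proto <- simulationProtocol(boxEdge = 10, cMg = 5, cK = 12, dt = 0.2,
                            saveInterval = 50000L, nSteps = 500000L, seed = 1)
sys <- placeIons(hp$system, proto, seed = 1)
sys
#> CGSystem: 12 nt, 35 beads, 12 ions (3 Mg2+, 7 K+, 2 Cl-)
#>   box edge: 10 nm; numbering 1 .. 12
#>   net charge: 0 e

tr <- runBrownianFolding(sys, hp$registry, proto)
round(range(radiusOfGyration(tr)), 3)
#> [1] 0.849 0.873
nb <- nBeads(hp$system)
X <- unwrapChain(frameCoords(tr, nFrames(tr)), 10, nb)
round(rmsdToNative(X[1:nb, ], hp$native), 3)
#> [1] 0.086
elementFormationFraction(frameCoords(tr, nFrames(tr)), sys, hp$registry, "stem")
#> [1] 1
condensedIonCount(frameCoords(tr, nFrames(tr)), sys, "MG")
#> [1] 2
```

The hairpin stays folded (RMSD 0.09 nm to the native frame, all four stem
pairs formed) and two of the three Mg²⁺ ions are condensed onto the
backbone at the final frame.

Collapse-kinetics fitting on a synthetic 95-trajectory ensemble with known
generating parameters (amplitudes 0.76/0.11/0.13, time constants
0.15/1.6/33 ms, plateaus 7.8 → 3.0 nm, 0.3 nm per-frame noise):

```r
cur <- makeRgEnsemble(nTraj = 95, noiseSigma = 0.3, seed = 1)
er  <- ensembleRg(cur, attr(cur, "time"))
fitCollapse(er$time, er$mean, nPhases = 3)
#> KineticFit: 3 phases, RgU = 7.799 nm, RgF = 2.916 nm
#>   phase 1: Phi = 0.743, tau = 0.1492 ms
#>   phase 2: Phi = 0.111, tau = 1.435 ms
#>   phase 3: Phi = 0.146, tau = 40.19 ms
#>   RSS = 0.1353, AIC = -1444 (n = 200)
```

The fast and middle phases are recovered accurately; the slowest time
constant is only a lower-bound estimate because the curves are truncated
at 30 ms (see the methods vignette).

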