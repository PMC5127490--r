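---
title: "Comparing forced-unfolding mechanisms across coarse-grained protein models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing forced-unfolding mechanisms across coarse-grained protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pullscope)
```

## The problem

Single-molecule force spectroscopy unfolds one protein by moving a harmonic
tether at constant velocity and recording the resistive force; each sudden
force drop marks the rupture of a group of native contacts.  Simulated
versions of this assay are run with models of very different resolution —
all-atom explicit solvent, heavy-atom structure-based (Gō) models,
three-bead-per-residue backbone models, and one-bead-per-residue Cα-Gō
models.  Comparing the *mechanisms* these models predict is only meaningful
after their temperature, time and force scales have been put on a common
footing, and after the structural ensembles have been reduced to comparable
observables.  `pullscope` implements that comparison pipeline: a minimal
Cα-Gō steered-MD engine to generate data, the smoothed contact order
parameter Q and its derived observables, the cross-model normalizations,
and a TM-score-based taxonomy of unfolding pathways.

## The order parameter

All structural analysis is projected onto the smoothed fraction of native
contacts of a conformation $X$:

$$Q(X) = \frac{1}{|S|} \sum_{(i,j)\in S}
  \frac{w_{ij}}{1 + \exp\!\left[\beta_0\,(r_{ij}(X) - \lambda r^0_{ij})\right]},$$

where $S$ is the native pair set (moieties at least `minSeparation = 4`
residues apart with native distance under a resolution-dependent cutoff),
$r^0_{ij}$ the native distance and $|S|$ the total contact weight.  The
presets in `contactDefinition()` are, per model resolution:

| preset  | $\beta_0$ (nm$^{-1}$) | $\lambda$ | $r_{cut}$ (nm) | $R_0$ (nm) |
|---------|------|-----|------|------|
| `heavy` | 50 | 1.8 | 0.48 | 0.24 |
| `awsem` | 50 | 1.2 | 0.60 | 0.46 |
| `ca`    | 50 | 1.2 | 1.20 | 0.91 |

The wide Cα cutoff compensates for the loss of side-chain detail: with it,
maps at different resolutions count approximately the same contacts.
Cα maps can additionally be *weighted* by the number of heavy-atom contacts
each residue pair forms in a higher-resolution reference
(`buildNativeContactMap(..., weighting = "heavy-atom-count")`), so that
large interfaces count more.  Non-native contacts are scored against the
single length scale $R_0$, the mean native pair distance; the printed
per-model values above are shipped as defaults because the value for
heavy-atom models is not reproducible as a plain mean over the native pair
set, and a recomputed mean (`R0 = NA`) is available when internal
consistency matters more than cross-model comparability.

Note a numerical consequence of $\lambda = 1.2$: the smoothed term at the
native distance is $1/(1+e^{-\beta_0(\lambda-1)r_0})$, which for
$r_0 < 0.55$ nm is noticeably below 1, so a native conformation scores
$Q \approx 0.99$ rather than $Q > 0.999$; only the $\lambda = 1.8$
parameter set saturates past 0.999.  Tests assert accordingly.

## The bundled simulator

`buildCaGoModel()` constructs a structure-based Cα model in reduced units
(native-contact well depth $\epsilon = 1$, bead mass 1, $k_B = 1$, lengths
in nm, time in LJ units):

* harmonic bonds ($k_b = 2\times10^4\,\epsilon$/nm²) and angles
  ($k_a = 40\,\epsilon$/rad²) at native geometry;
* dihedrals $K[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)]$ with
  $K = 1\,\epsilon$;
* native pairs $U(r) = \epsilon_{ij}[5(r_0/r)^{12} - 6(r_0/r)^{10}]$, with
  $\epsilon_{ij}$ uniform or proportional to heavy-atom contact counts
  (normalized to mean 1);
* excluded volume $\epsilon_{nc}(\sigma_{NC}/r)^{12}$ with
  $\sigma_{NC} = 0.4$ nm for all other pairs, truncated and shifted at
  $2.5\,\sigma_{NC}$.

The force-field pair list uses sequence separation $\ge 3$ and a 0.8 nm
Cα cutoff — the usual Cα proxy for "heavy atoms within 0.6 nm".  This is
deliberately distinct from the *analysis* contact definition above
(separation $\ge 4$, cutoff 1.2 nm): the wide analysis cutoff exists for
cross-model comparability, but as an interaction list it would give ~9
attractive contacts per residue and a fold that does not melt at any
reasonable temperature.

Dynamics use the BAOAB Langevin splitting with the conventional time step
0.004 and thermostat time constant 12 (friction $1/12$); at zero friction
and temperature the scheme reduces exactly to velocity Verlet, which is
what the energy-conservation checks exercise.  Noise comes from a
xoshiro256+ generator seeded per run, so every stochastic operation is
deterministic given its seed and independent of R's RNG state.  With the
stiff SMOG-style bonds the bond modes sit at $\omega\,\Delta t \approx
0.57$ at the default step — stable, but tests of velocity statistics
(equipartition) use $\Delta t = 0.001$ where the $O((\omega\Delta t)^2)$
kinetic bias is negligible.

Pulling (`runPull()`) tethers both termini with springs of stiffness $k$
(default 837 $\epsilon$/nm², the reduced equivalent of
1000 kJ/(mol·nm²) under the display conversion below); the pulled
reference point moves at constant speed along the terminus-to-terminus
axis fixed at setup, and the run ends when the tether separation has grown
by $L$ (default $30\,\mathrm{nm}\times n/110$, the full-length limit scaled
by chain length).  The recorded force is the instantaneous spring extension
times $k$, projected on the pulling axis.

## The toy structure

`generateToyStructure()` builds a deterministic compact fold —
a two-layer antiparallel β-sandwich (`"hairpin-barrel"`) or a helix bundle —
with exact 0.38 nm virtual bonds, a seeded jitter, and bond-length
restoration by constraint projection.  It emulates the features the
analysis depends on: a heterogeneous native contact map with several
topologically distinct strand pairings, a cooperative (two-state-like)
melting transition, mechanical stability below the folding temperature,
and sawtooth force-extension curves with run-to-run pathway variation.
It does *not* emulate sequence effects, side-chain packing, solvent or
electrostatics, so passing tests demonstrate that the machinery recovers
what the generator put in — not that any particular real protein unfolds
this way.

A melting scan of the default 40-residue sandwich (`runTemperatureScan()`,
`fitTwoState(curve, R = 1)`) locates its folding temperature near 1.36
reduced units; the display constant `reducedToKelvin()` (116 K per reduced
unit) was calibrated once against that value so the toy transition maps
near 158 K, and is used for display only — all physics runs in reduced
units.

## Cross-model normalizations

* **Temperature.**  Melting curves are fit to the two-state form
  $\langle Q(T)\rangle = q_u \frac{1}{1+e^{\Delta G/RT}} +
  q_f\frac{e^{\Delta G/RT}}{1+e^{\Delta G/RT}}$ with
  $\Delta G = \Delta H - T\Delta S$ (`fitTwoState()`, multi-start
  Levenberg–Marquardt with a closed-form initial guess from the 80%/20%
  crossing temperatures).  The folding temperature is $T_f = \Delta
  H/\Delta S$, and production runs are placed at $0.9\,T_f$
  (`simulationTemperature()`, which rounds $T_f$ to integer kelvin before
  scaling, matching how printed values are derived from printed $T_f$).
  The transition width between 80% and 20% of the folded fraction has the
  closed form $T_{80} = \Delta H/(\Delta S + R\ln 4)$,
  $T_{20} = \Delta H/(\Delta S - R\ln 4)$ (`transitionWidth()`).  Note the
  width is a function of $\Delta S/R$ at fixed $T_f$; it is *not* invariant
  under scaling $\Delta H$ and $\Delta S$ alone.
* **Time.**  A characteristic relaxation time per model is measured by
  pulling residue pairs 1.5 nm apart, releasing them
  (`perturbAndRelax()`), and fitting the normalized Q autocorrelation to
  $A_1 e^{-\kappa_1 t} + A_2 e^{-\kappa_2 t}$ (`fitDoubleExponential()`,
  constrained $\kappa_1 \le \kappa_2$, degenerate fits collapse to a
  single exponential).  With $t = \langle\kappa_1\rangle^{-1}$, pulling
  speeds are matched by $v_{ref}\,t_{ref} = v_{model}\,t_{model}$
  (`normalizedPullingSpeed()`).  The steering scheme for the perturbation
  is a moving harmonic distance restraint ramped over `rampSteps`; the
  protocol only states the displacement, so the ramp is a design choice.
* **Force.**  Pulling works $W = \int_0^L F\,dx$ (`pullingWork()`,
  trapezoidal, with non-monotone records resampled onto a monotone grid)
  enter the Jarzynski estimator
  $\Delta G = -\beta^{-1}\ln\langle e^{-\beta W}\rangle$
  (`jarzynskiFreeEnergy()`, log-sum-exp stabilized; an upper-bound
  estimate by Jensen's inequality).  `solveForceScale()` finds the factor
  $\alpha$ that makes the rescaled works reproduce a reference unfolding
  free energy, by Brent root finding on a monotone function, and reports
  the run-by-run convergence trace.
* **Errors.**  Standard errors of correlated series use
  Flyvbjerg–Petersen blocking (`blockAverageSEM()`): successive pairwise
  blocking, estimate taken at the first level that changes by less than 5%
  for two successive levels, else the deepest level with at least 8 blocks
  (with a warning).  `integratedAutocorrelationTime()` supports trimming
  equilibration before averaging.

## Pathway taxonomy

At each Q level the *folded segment* is the largest contiguous run of
residues whose ensemble-averaged per-residue nativeness exceeds 0.5,
tolerating internal sub-threshold gaps of up to 10 residues
(`foldedSegment()`).  One frame per trajectory (Q closest to the bin
center) enters an all-against-all TM-score matrix over the segment's Cα
atoms:

$$\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = 1.24\,(N-15)^{1/3} - 1.8\ \text{Å},$$

with a 0.5 Å floor on $d_0$ (the formula turns negative below $N = 21$).
Because all conformations share one sequence, the residue correspondence
is fixed and only the superposition is optimized: seeds from sliding
fragments (plus all residue triples for fragments of ≤ 10 residues) are
each refined by re-selecting residues with $d_i < d_0$ and re-superposing
until stable, and the best score over seeds is kept.  An exhaustive
rotation-grid oracle cross-checks this search on small fixtures in the
test suite.

Conformations are clustered on distance $1 - \mathrm{TM}$ with average
linkage, cut at $1 - 0.6$ (`clusterByTM()`; a single-linkage variant is
available behind the `linkage` argument since the reference clustering
tool's exact behavior is not documented).  Cluster-to-cluster trajectory
flow across Q levels forms the pathway graph (`pathwayGraph()`); the
dominant pathway maximizes the bottleneck edge weight — the fraction of
trajectories carried end to end — with ties broken by larger cluster size
then lower cluster id (`dominantPathway()`).  The sliding-window reference
curve (`windowReferenceCurve()`) provides the "partially unfolded but
undistorted" baseline: partial native structures from all windows of all
lengths, binned by their Q, TM-aligned within bins (bins are subsampled to
a fixed number of windows for tractability).  Cross-model comparison
(`crossModelAlignment()`) reports mean TM and Kabsch RMSD between two
models' ensembles over the reference model's folded segment, with
bootstrap error bands; `unfoldingOrderCorrelation()` reduces per-residue
persistence (the Q at which a residue's profile first drops below 0.5,
scanning from Q = 1 downward; residues that never drop score 0) to
per-strand scores and correlates them between models.  The persistence
construction is one defensible reading of a band-darkness comparison that
is not given as a formula, and is documented as such.

## Numerical choices and degenerate inputs

* Frames are assigned to Q bins by nearest bin center; `contactMapAtQ()`
  pools frames within $\pm\delta Q$ (default 0.01) of each target, and a
  smoothed non-native term above 0.5 counts as "a contact present" when a
  binary statement is needed (the frequency maps and off-native counts) —
  the reference analyses do not state a binarization rule.
* Empty contact maps are warnings, not errors; empty Q bins are reported
  as missing, never as zero.
* Residues with no native contacts have undefined profiles (`NA`).
* Occupancy ties in PDB alternate locations are broken by label order
  (A first); insertion codes are rejected outright, since silently
  renumbering would corrupt strand assignments.
* The two-state fit refuses series that do not bracket the transition
  midpoint; the double-exponential fit collapses to a single-exponential
  report when the two rates agree within 5% or one amplitude vanishes.
* `meanTMvsQ()` falls back to the full chain when the pooled profile has
  no folded segment (incoherent ensembles at low Q), so the shuffled-order
  baseline remains defined.

## Scaling of the bundled experiments

Test-suite and pipeline defaults are sized for a single CPU: a 40-residue
toy fold, melting scans of $10^5$–$2\times10^5$ steps per temperature,
pulls at $v = 0.02$–0.05 nm per time unit, and scripted (geometric)
ensembles for the taxonomy recovery checks.  These sizes were chosen so
each stage's observable is converged enough for its stated tolerance —
larger systems and slower pulls sharpen the sawtooth structure but do not
change what the tests demonstrate.

## Known limitations

* The simulator is Cα-only: no explicit solvent, electrostatics,
  three-bead backbone dynamics or heavy-atom Gō dynamics.  Trajectories
  from such models are analyzed generically through the `Trajectory`
  container, but their dynamics are not generated here.
* The Jarzynski estimate carries the usual finite-sample bias and is used
  strictly as an upper bound; no bias corrections are applied.
* TM-based clustering is only defined for same-sequence ensembles; no
  sequence alignment is attempted.
* The toy generator's pathway variability is driven by thermal noise and
  (for scripted ensembles) explicit orders; it cannot reproduce
  sequence-specific intermediates.
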