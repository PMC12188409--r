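---
title: "Rotational biasing and conformational analysis of F1-type motors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational biasing and conformational analysis of F1-type motors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaryF1)
```

## The problem this package addresses

F1-ATPase is a rotary enzyme: three catalytic alpha/beta interfaces arranged
around a central gamma shaft interconvert between open/closed and
loose/tight conformations as the shaft turns.  Regulatory proteins such as
the ATPase inhibitory factor IF1 wedge themselves into the rotor-stator
interface and block the rotation in one direction only.  Analysing such
systems computationally requires a small set of recurring quantitative
tools:

* a way to place crystal structures of the complex on a common
  low-dimensional **conformational landscape** (a Calpha covariance PCA of
  the alpha/beta pairs),
* a reproducible definition of the **rotary angle** of the gamma subunit
  relative to a reference structure,
* a **biasing scheme** that forcibly rotates the shaft while leaving its
  internal flexibility untouched, with honest bookkeeping of the
  nonequilibrium work and torque that the bias injects,
* per-frame **trajectory metrics** (helix formation, residue contacts,
  helix bending, chi1 rotamer states, minimum distances), and
* the **energetic conversion** from torque to the proton motive force (pmf)
  that would sustain it.

This package implements all five, plus a seeded coarse-grained toy rotary
motor that generates the synthetic structures and trajectories the test
suite runs on.  The toy motor is a statistical stand-in, not a model of the
real enzyme: it reproduces the *structure* of the analysis problem (a
3-fold stator with two internal coordinates per unit, a two-layer rotor
whose core lags its protruded part, an inhibitor chain bridging rotor core
and one stator unit), never the real system's numbers.

## The mean-rotation-angle collective variable

The biasing scheme controls only the *average* rotation angle of the
biased group.  For current in-plane coordinates $(x_i, y_i)$, reference
coordinates $(x_i^{\mathrm{ref}}, y_i^{\mathrm{ref}})$ and weights $w_i$
summing to one, the collective variable is the in-plane Procrustes angle

$$\theta^\ast = \operatorname{atan2}\!\Big(
  \textstyle\sum_i w_i (x_i^{\mathrm{ref}} y_i - y_i^{\mathrm{ref}} x_i),\;
  \sum_i w_i (x_i^{\mathrm{ref}} x_i + y_i^{\mathrm{ref}} y_i)\Big),$$

the single rotation about the axis that best fits the current positions
onto the reference in the least-squares sense.  It is exact on rigid
rotations, closed-form, differentiable, and leaves every other degree of
freedom free — individual atoms can deform arbitrarily so long as the
optimal mean rotation tracks the target.  The published description of the
original biasing variable lives in supporting material that is not part of
this package's sources, so this closed-form Procrustes definition is the
documented contract here; it satisfies every stated property of the
original ("only the average angle controlled") and is validated against a
brute-force grid minimiser in the tests.

The moving restraint is $V(\theta, t) = \tfrac{1}{2}\kappa\,
(\theta - \theta_0(t))^2$ with $\theta_0(t) = \theta_0(0) + s\,\omega t$
($s = +1$ counterclockwise/hydrolysis, $-1$ clockwise/synthesis).  The
harmonic prefactor convention is $\tfrac12$; force constants quoted in
kcal mol$^{-1}$ rad$^{-2}$ are interpreted with this convention
(`kappaPerDegree(1e5)` is the corresponding 30.46 kcal mol$^{-1}$
deg$^{-2}$).  External work is accumulated as target-displacement work,
$dW = V(\theta_k, t_{k+1}) - V(\theta_k, t_k)$ at fixed system
coordinates — the Jarzynski convention — and the applied torque is
estimated as the windowed mean of $\kappa(\theta_0 - \theta)$.  For an
overdamped particle with friction $\gamma$ dragged at rate $\Omega$ these
definitions reproduce the closed forms lag $= \gamma\Omega/\kappa$ and
work rate $= \gamma\Omega^2$ (see `dragParticle()` and its tests).
Angles are continuity-unwrapped frame to frame, so protocols beyond 360
degrees accumulate correctly.

## The conformational landscape

`extractPairs()` pulls one flattened Calpha vector per alpha/beta pair
over fixed residue subsets (defaults: alpha 24-401, 413-483, 494-509;
beta 10-126, 129-310, 312-387, 396-464 — the regions resolved across the
reference crystal-structure set; 909 Calpha atoms per pair, in nm).
`superposePairs()` removes rigid motions by iterating to the mean: align
everything to the first pair, compute the mean, re-align to the mean, and
repeat until the mean moves less than $10^{-6}$ nm RMS (at most 20
rounds; a fixed-reference mode is available).  `fitPCA()` diagonalises
the population covariance (1/M normalisation — the explained-fraction
statistic is invariant to the 1/M vs 1/(M-1) choice, which is documented
for reproducibility) and fixes each eigenvector's sign so its
largest-magnitude component is positive, making plots identical across
eigensolvers and runs.  Projections are plain inner products with the
centred coordinates; on the reference set, PC1 separates open from closed
beta conformations and PC2 loose from tight interfaces.

The progress statistic for a rotating trajectory is the PC2 displacement
from a start value to a target value in percent, deliberately unclipped
so overshoot is visible.  The start defaults to the first frame's PC2 and
the target must be supplied (typically a cluster centroid of the target
state); the analysis does not fix these endpoints for you.

The covariance is unweighted (Calpha-only coordinates make mass weighting
nearly moot, and no mass convention is part of the contract); the
alignment convergence criterion above is this package's own, chosen well
below the resolution of any quantity derived from the landscape.

## The rotary angle

`buildRotaryFrame()` constructs a stator-fixed frame: the Calpha centres
of mass of the three beta N-terminal domains (residues 10-82) define the
origin (their centroid) and the z axis (their plane normal, oriented so
the protruding C-terminal half of gamma has positive z — the published
construction leaves this sign implicit); the frame is completed by
rotating about z until the beta_DP centre of mass lies on +x.  Which beta
is beta_DP is an *input* (user label, a prior landscape classification,
or `betaDPByNucleotide()` on entries with resolved ADP).  `gammaAngle()`
then takes the optimal proper (Kabsch) rotation fitting the gamma core
(residues 1-30 and 221-270, unweighted Calpha, rotation + translation)
of a frame-aligned model onto a frame-aligned reference and reports the
planar angle of the rotated x axis, counterclockwise (hydrolysis)
positive, in (-180, 180].  Synthetic rigid rotations are recovered below
$10^{-6}$ degrees and the operation is antisymmetric in its arguments.

## The toy motor

The simulator integrates overdamped (Euler-Maruyama) Langevin dynamics on
a deliberately small set of coordinates:

| coordinate | meaning | default |
|---|---|---|
| $g_j$, $j=1..3$ | stator gate, open $\approx 0$ / closed $\approx 1$ | double well, barrier 2 kcal/mol |
| $h_j$ | interface, loose $\approx 0$ / tight $\approx 1$ | double well, barrier 2 kcal/mol |
| $\theta_{\mathrm{core}}$ | buried rotor ring angle | torsion spring 100 kcal mol$^{-1}$ rad$^{-2}$ to the protruded mean |
| $\alpha_i$, $i=1..12$ | protruded rotor bead angles | shape springs 50 kcal mol$^{-1}$ rad$^{-2}$ about their mean |
| inhibitor beads | 10 beads, 3-D | bonds (10 kcal mol$^{-1}$ A$^{-2}$) + Gaussian contact wells (3 kcal/mol, width 2 A) |

The bias acts on the protruded ring through the collective variable and
its analytic gradient — exactly the machinery a biased simulation engine
would use — so the mean protruded angle has collective friction
$n_{\mathrm{prot}}\gamma_{\mathrm{ang}}$ (12 x 5 kcal mol$^{-1}$ ns
rad$^{-2}$ by default), which is the $\gamma$ to use in the lag oracle.
Gates respond to the rotor through a smooth threshold: rotating the mean
protruded angle past 20 degrees (120-degree periodic offsets per stator
unit, width 10 degrees) tilts the gate double-well toward closed.  The
inhibitor's short segment rides an arc on the rotor core and its long
segment binds stator unit 1 (offset inward), so forced rotation strains
the bridge between the two segments; the strain is direction-dependent
because the short-segment arc is placed to one side of the long-segment
anchor.  This *constructed* asymmetry is exercised as a regression test
and makes no quantitative claim about the real protein.

Temperature defaults to $k_BT = 0.6$ kcal/mol; frictions are 2 (gates),
5 (angles) and 0.5 (Cartesian beads) in kcal/mol ns units; the stability
bound of the integrator is $dt < \gamma/k$ for the stiffest spring acting
on a coordinate (with the default $dt = 10^{-3}$ ns every default spring
is at least a factor 20 inside the bound).  All parameters are module
constants chosen for a well-behaved toy — explicitly *not* measurements
of any enzyme — and every run's effective parameters are echoed
(`writeRunConfig()`), from which the run is bit-reproducible.

Randomness: one seed initialises one Mersenne-Twister stream; each step
draws one Gaussian vector covering all coordinates in a fixed order
(gates, interfaces, core angle, protruded angles, inhibitor xyz).  A
fixed seed, step count and time step reproduce trajectories and ledgers
bit-for-bit.  Per-coordinate counter-based streams would also work; the
single documented stream was chosen because R has no cheap stream
splitting and the reproducibility contract is identical.

What the generator emulates — and does not.  It reproduces the
statistical shapes the analysis assumes: two dominant orthogonal
deformation modes with a 9:1 variance split (`generatePcaDataset()`, with
rigid-body components projected out of the ground-truth modes so they
survive superposition), a rotor whose core lags its protruded part under
torque, contact networks that break under rotation, and backbone chains
of prescribed helicity (`generateHelixChain()`, ideal helical dihedrals
phi = -57, psi = -47 against extended phi = -120, psi = +120).  It does
not emulate atomic packing, solvent, nucleotide chemistry, or realistic
energy scales; passing tests therefore demonstrate the *correctness of
the operators*, not any property of real F1.

## Trajectory metrics

Helicity uses a dihedral-window criterion (phi in [-100, -30], psi in
[-67, -7] degrees; residue counted on the dihedrals it has at chain
termini) because the original secondary-structure method is not part of
the contract; the criterion is pluggable (`isHelical` argument) and on
ideal fixtures every reasonable criterion agrees.  Contacts count residue
pairs with any heavy-atom distance at or below 4.5 Angstrom (configurable
— the cutoff is this package's choice), are reported relative to an
equilibrium baseline in percent, and can be block-averaged over
non-overlapping windows (30 ns blocks are conventional for this
analysis).  The long-helix bending angle is the interior angle at the
middle Calpha of residues (21, 38, 45).  chi1 is the N-CA-CB-Xgamma
torsion reported in [0, 360) — chosen so the two rotamer states of
interest sit at 200 and 300 degrees rather than wrapping — with a
two-state assignment of half-width 40 degrees (configurable; the default
keeps the windows disjoint, and the partition is exhaustive:
state200/state300/unassigned).

## Energetics

A motor at torque $\tau$ does $2\pi\tau$ of work per turn; with $n$
protons per turn, each carrying $e \cdot \mathrm{pmf}$,
$\mathrm{pmf} = 2\pi\tau / (n e)$.  With the standard F1 torque of
40 pN nm/rad and a 20% excess for the inhibited state,
`torqueForEjection(40, 0.20)` gives 48 pN nm/rad and
`pmfRequired(48, 8)` gives 235 mV (nearest integer; rounding happens at
presentation only — elementary charge 1.602176634e-19 C exact SI,
1 pN nm = 1e-21 J, 1 kcal/mol = 6.9477 pN nm).  The torque is treated as
angle-independent; angle-resolved torque profiles are out of scope.

## Numerical choices and degenerate inputs

* Superposition uses the SVD-based optimal rotation with the determinant
  correction, so only proper rotations are returned; all-collinear
  coordinate sets are refused.
* The CV and its gradient are undefined when every atom sits on the
  rotation axis; both refuse such inputs.
* PDB I/O keeps altloc blank or 'A' (highest occupancy on ties), treats
  author residue numbering as authoritative, errors on missing residues
  in a selection (listing every gap) unless a batch-wide intersection is
  requested, and refuses coordinates outside the fixed-width PDB field
  rather than truncating them.
* Chain roles are auto-detected from residue counts (the three larger of
  the six largest chains are alpha, the smaller three beta, the largest
  remaining chain of 150+ residues gamma, chains of 8-60 residues
  inhibitor candidates); the heuristic cannot distinguish a short
  inhibitor from a small intrinsic subunit of similar length, so explicit
  role maps always win.
* Problem sizes in the shipped tests (2000-pair PCA fits, 150k-step gate
  sampling runs, 4000-step biased rotations) were chosen as the smallest
  sizes at which each statistical check has comfortable margin; they are
  the package's own defaults for desk-scale validation.

## Known limitations

* The real-crystal-structure checks (97% two-mode variance on the 78
  reference pairs; the 10-15 degree hydrolysis-ward offset of the
  inhibitor-bound rotor) need the public structure archive at run time;
  the corresponding tests download on demand and fail where the archive
  is unreachable.  The splitting of two-complex asymmetric units and the
  nucleotide-based beta_DP assignment implement the documented procedure
  but have only been exercised against synthetic fixtures here.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  package is an analysis library, not a shell tool.
* The toy motor's directional work asymmetry is a property of its
  constructed contact geometry, frozen as a regression; its magnitude
  (about 1% of the total work at default settings) has no biological
  meaning.
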