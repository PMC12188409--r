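# rotaryF1

Rotational biasing, conformational landscapes and energetics for
F1-ATPase-type rotary motors, in R.

F1-ATPase couples catalysis at three alpha/beta interfaces to the rotation
of a central gamma shaft; inhibitor proteins such as IF1 wedge into the
rotor-stator interface and block rotation in one direction only.  Studying
that kind of system computationally keeps demanding the same toolbox, which
this package provides for structural bioinformaticians and simulators:

* **Mean-rotation-angle biasing with work/torque accounting.**  The
  collective variable is the in-plane Procrustes angle
  θ\* = atan2(Σᵢ wᵢ (xᵢʳᵉᶠ yᵢ − yᵢʳᵉᶠ xᵢ), Σᵢ wᵢ (xᵢʳᵉᶠ xᵢ + yᵢʳᵉᶠ yᵢ)) —
  the single best-fit rotation of a group about the stator axis, so only
  the *average* angle is restrained and internal flexibility stays free.
  A moving harmonic target V = ½κ(θ − θ₀(t))² with θ₀(t) = θ₀ + sωt feeds
  a work ledger (dW = V(θ, t+dt) − V(θ, t) at fixed coordinates) and a
  torque estimator (windowed mean of κ(θ₀ − θ)).
* **A Calpha covariance PCA landscape** of alpha/beta pairs (iterate-to-mean
  superposition, population covariance, deterministic eigenvector signs)
  with a PC2-based conformational-progress statistic.
* **A stator-frame gamma rotary angle**: frame from the beta N-domain
  centres of mass (origin, plane normal z, beta_DP on +x), then the Kabsch
  best-fit rotation of the gamma core against a reference structure,
  counterclockwise (hydrolysis) positive.
* **Trajectory metrics**: dihedral-window helicity, heavy-atom residue
  contacts relative to an equilibrium baseline, long-helix bending angle,
  chi1 rotamer states (200°/300° two-state assignment), minimum distances.
* **Torque ↔ proton-motive-force bookkeeping**: pmf = 2πτ/(n e) for torque
  τ and n protons per turn.
* **A seeded coarse-grained toy rotary motor** (3-fold stator with
  open/closed and loose/tight coordinates, two-layer rotor whose core lags
  the protruded ring, inhibitor chain bridging core and one stator unit)
  that generates every synthetic structure and trajectory the test suite
  needs — no downloads.

## Worked example

Rotate the toy motor 40° in the synthesis (CW) direction at 10°/ns with a
κ = 500 kcal mol⁻¹ rad⁻² restraint, then read off the work and torque:

```r
library(rotaryF1)

motor <- buildMotor(seed = 0)
bias  <- rotorBias(kappa = 500, omegaDegNs = 10, direction = "CW")
run   <- runLangevin(motor, simProtocol(nSteps = 4000, dt = 1e-3, seed = 1,
                                        bias = bias, temperature = 0))
tail(ledgerTable(run$ledger), 3)
#>     time_ns theta_deg theta0_deg work_kcal_mol torque_pN_nm_per_rad
#> 399    3.98 -36.44765      -39.8      14.86604            -203.2532
#> 400    3.99 -36.54573      -39.9      14.91719            -203.3694
#> 401    4.00 -36.64382      -40.0      14.96836            -203.4856

estimateTorque(run$ledger, window = 1)$pN_nm
#> [1] -197.4609
```

The CV lags the −40° target by ≈3.4° (the collective friction of the
protruded ring against the restraint, plus the load of core, gates and
inhibitor contacts); pushing the target that far cost 15.0 kcal/mol of
external work, and the restraint applied ≈197 pN nm/rad on average over
the final nanosecond (negative = synthesis direction).

A synthetic conformational landscape with known ground truth:

```r
pairs <- generatePcaDataset(500, noiseSigma = 0.02, seed = 7)
model <- fitPCA(superposePairs(pairs))
round(explainedFraction(model)[1:3], 3)
#> [1] 0.875 0.097 0.005
```

The generator plants two orthogonal modes with a 9:1 variance split; the
fit recovers them (the residual goes to the isotropic noise floor).

And the energetic bookkeeping — the torque needed to eject a bound
inhibitor that costs 20% extra work, and the pmf that sustains it at
8 protons per turn:

```r
pmfTable(torqueForEjection(40, 0.20), 8)
#>   torque_pN_nm_rad protons_per_turn work_per_turn_pN_nm work_per_proton_pN_nm   pmf_mV
#> 1               48                8            301.5929              37.69911 235.2993
```

48 pN nm/rad of torque corresponds to a pmf of 235 mV (nearest integer) —
slightly above typical mitochondrial values, which is what makes
inhibitor ejection a deliberate, pmf-gated event rather than a side
effect of normal operation.

## Package layout

| area | entry points |
|---|---|
| structure/trajectory I/O | `readPDB`, `selectAtoms`, `writeMultiModelPDB`, `chainRoleMap` |
| conformational landscape | `extractPairs`, `superposePairs`, `fitPCA`, `projectPairs`, `conformationalProgress` |
| rotary geometry | `buildRotaryFrame`, `gammaAngle` |
| biasing + work | `rotorCV`, `meanRotationAngle`, `cvGradient`, `rotorBias`, `accumulateWork`, `estimateTorque`, `dragParticle` |
| toy motor | `buildMotor`, `runLangevin`, `rmsdSteer`, `generatePcaDataset`, `generateHelixChain`, `generateSyntheticF1` |
| trajectory metrics | `helicity`, `contactCount`, `relativeContacts`, `bendingAngle`, `chi1Dihedral`, `chi1State`, `minResidueDistance` |
| energetics | `torqueForEjection`, `pmfRequired`, `torqueFromPmf`, `pmfTable` |

The methods vignette (`vignettes/rotary-motor-analysis.Rmd`) documents the
model, parameter choices, numerical conventions and known limitations.
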