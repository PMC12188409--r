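## The mean-rotation-angle collective variable (CV), the moving harmonic
## torque bias, and nonequilibrium work / torque accounting.
##
## Only the average rotation angle of the biased group is controlled:
## theta* is the single in-plane rotation about the axis that best fits the
## current positions onto the reference (in-plane Procrustes angle),
##   theta* = atan2( sum_i w_i (x_i^ref y_i - y_i^ref x_i),
##                   sum_i w_i (x_i^ref x_i + y_i^ref y_i) ),
## so individual atoms move freely as long as the optimal mean rotation
## tracks the target.  Radians internally; degrees at user interfaces.

#' Construct a mean-rotation-angle collective variable
#'
#' @param refCoords n x 3 (or n x 2) reference coordinates of the biased
#'   group; only the in-plane (x, y) components matter.  The rotation axis
#'   is z by construction: transform coordinates into the stator frame
#'   first (see [buildRotaryFrame()]).
#' @param weights per-atom non-negative weights; default uniform.  They are
#'   normalised to sum to 1.
#' @return A [RotorCV-class].
#' @export
rotorCV <- function(refCoords, weights = NULL) {
  xy <- as.matrix(refCoords)[, 1:2, drop = FALSE]
  if (nrow(xy) < 2L) stop("need at least 2 atoms for a mean rotation angle")
  if (is.null(weights)) weights <- rep(1, nrow(xy))
  w <- weights / sum(weights)
  new("RotorCV", refXY = unname(xy), weights = w)
}

#' Mean rotation angle of a configuration
#'
#' @param coordsXY n x 3 or n x 2 current coordinates (same atom order as
#'   the CV reference).
#' @param cv a [RotorCV-class].
#' @param previous optional previous CV value (radians) for
#'   continuity-unwrapping along a trajectory: the returned angle is the
#'   2*pi image nearest to `previous`, so protocols beyond 360 degrees
#'   accumulate.
#' @return angle in radians ((-pi, pi] when `previous` is NULL).
#' @export
meanRotationAngle <- function(coordsXY, cv, previous = NULL) {
  xy <- as.matrix(coordsXY)[, 1:2, drop = FALSE]
  if (nrow(xy) != nrow(cv@refXY))
    stop("coordinate count does not match CV reference")
  w <- cv@weights; rx <- cv@refXY[, 1]; ry <- cv@refXY[, 2]
  A <- sum(w * (rx * xy[, 2] - ry * xy[, 1]))
  B <- sum(w * (rx * xy[, 1] + ry * xy[, 2]))
  if (abs(A) < 1e-300 && abs(B) < 1e-300)
    stop("all atoms on the rotation axis: angle undefined")
  th <- atan2(A, B)
  if (!is.null(previous)) th <- th + 2 * pi * round((previous - th) / (2 * pi))
  th
}

#' Analytic gradient of the mean rotation angle
#'
#' d theta*/d x_i and d theta*/d y_i from differentiating the atan2
#' expression; the z component is zero.  Validated against central finite
#' differences in the test suite.
#'
#' @inheritParams meanRotationAngle
#' @return n x 3 matrix of partial derivatives (rad per Angstrom).
#' @export
cvGradient <- function(coordsXY, cv) {
  xy <- as.matrix(coordsXY)[, 1:2, drop = FALSE]
  if (nrow(xy) != nrow(cv@refXY))
    stop("coordinate count does not match CV reference")
  w <- cv@weights; rx <- cv@refXY[, 1]; ry <- cv@refXY[, 2]
  A <- sum(w * (rx * xy[, 2] - ry * xy[, 1]))
  B <- sum(w * (rx * xy[, 1] + ry * xy[, 2]))
  den <- A^2 + B^2
  if (den < 1e-300) stop("all atoms on the rotation axis: gradient undefined")
  dA.dx <- -w * ry; dA.dy <- w * rx
  dB.dx <- w * rx;  dB.dy <- w * ry
  g <- cbind((B * dA.dx - A * dB.dx) / den,
             (B * dA.dy - A * dB.dy) / den,
             0)
  colnames(g) <- c("x", "y", "z")
  g
}

#' Construct a moving harmonic rotor bias
#'
#' @param kappa force constant, kcal mol^-1 rad^-2 (> 0).
#' @param omegaDegNs target speed magnitude, degrees/ns.
#' @param direction `"CCW"` (hydrolysis; target angle increases) or `"CW"`
#'   (synthesis; decreases).
#' @param theta0InitDeg initial target angle, degrees.
#' @return A [RotorBias-class].
#' @export
rotorBias <- function(kappa, omegaDegNs = 1, direction = c("CCW", "CW"),
                      theta0InitDeg = 0) {
  direction <- match.arg(direction)
  new("RotorBias", kappa = kappa, omegaDegNs = omegaDegNs,
      theta0Init = degToRad(theta0InitDeg), direction = direction)
}

## signed target angular velocity, rad/ns
omegaSigned <- function(bias) {
  s <- if (bias@direction == "CCW") 1 else -1
  s * degToRad(bias@omegaDegNs)
}

#' Target angle of the moving restraint at time t
#'
#' theta0(t) = theta0_init + s * omega * t.
#'
#' @param bias a [RotorBias-class].
#' @param t time, ns.
#' @return target angle, radians.
#' @export
biasTarget <- function(bias, t) bias@theta0Init + omegaSigned(bias) * t

#' Bias energy and restraint torque
#'
#' V = kappa/2 (theta - theta0(t))^2; the restraint torque exerted on the
#' system is tau_r = -kappa (theta - theta0).
#'
#' @param theta CV value, radians (unwrapped).
#' @param t time, ns.
#' @param bias a [RotorBias-class].
#' @return list with `energy` (kcal/mol), `torque` (kcal mol^-1 rad^-1),
#'   `theta0` (rad).
#' @export
biasEnergy <- function(theta, t, bias) {
  th0 <- biasTarget(bias, t)
  list(energy = 0.5 * bias@kappa * (theta - th0)^2,
       torque = -bias@kappa * (theta - th0),
       theta0 = th0)
}

#' Create an empty work ledger
#'
#' @param t0 initial time, ns.
#' @param theta0 initial CV value, radians.
#' @param bias a [RotorBias-class] (to record the initial target and
#'   torque).
#' @return A [WorkLedger-class] with one sample and zero work.
#' @export
newWorkLedger <- function(t0, theta0, bias) {
  b <- biasEnergy(theta0, t0, bias)
  new("WorkLedger", time = t0, theta = theta0, theta0 = b$theta0,
      work = 0, torque = b$torque)
}

#' Accumulate external work as the restraint target moves
#'
#' The work increment of one protocol step is the energy change caused by
#' moving the target at fixed system coordinates:
#' dW = V(theta_k, t_{k+1}) - V(theta_k, t_k) (Jarzynski external work).
#' The ledger records the state at t_{k+1} with `theta` the (possibly
#' updated) CV value after the step.
#'
#' @param ledger a [WorkLedger-class].
#' @param theta CV value at the beginning of the step (radians, unwrapped).
#' @param t0,t1 step start and end times, ns (t1 > t0).
#' @param bias a [RotorBias-class].
#' @param thetaNew CV value after the step (defaults to `theta`).
#' @return the updated [WorkLedger-class].
#' @export
accumulateWork <- function(ledger, theta, t0, t1, bias, thetaNew = theta) {
  if (t1 <= t0) stop("time reversal: t1 must exceed t0")
  dW <- biasEnergy(theta, t1, bias)$energy - biasEnergy(theta, t0, bias)$energy
  b <- biasEnergy(thetaNew, t1, bias)
  initTorque <- length(ledger@time) == 0L
  new("WorkLedger",
      time = c(ledger@time, t1),
      theta = c(ledger@theta, thetaNew),
      theta0 = c(ledger@theta0, b$theta0),
      work = c(ledger@work, (if (length(ledger@work))
                               ledger@work[length(ledger@work)] else 0) + dW),
      torque = c(ledger@torque, b$torque))
}

#' Windowed average torque estimate
#'
#' Mean of kappa (theta0 - theta) over the trailing `window` ns of the
#' ledger (whole run when `window` is NULL), i.e. the average torque the
#' restraint applies to the system.
#'
#' @param ledger a [WorkLedger-class].
#' @param window trailing window length, ns.
#' @return list with `kcal_mol_rad` and `pN_nm` (converted with
#'   1 kcal/mol = 6.9477 pN nm).
#' @export
estimateTorque <- function(ledger, window = NULL) {
  n <- length(ledger@time)
  if (!n) stop("empty ledger")
  keep <- if (is.null(window)) rep(TRUE, n)
          else ledger@time >= ledger@time[n] - window
  if (!any(keep)) stop("window contains no samples")
  tq <- mean(ledger@torque[keep])
  list(kcal_mol_rad = tq, pN_nm = tq * kcalMolInPNnm())
}

#' Drag an overdamped particle with the moving restraint
#'
#' Reference scenario for the work accounting: a single angular coordinate
#' with friction `gammaF` and no potential other than the moving harmonic
#' bias, integrated by Euler-Maruyama.  In the long-time limit the lag is
#' gammaF * Omega / kappa and the work rate gammaF * Omega^2 (Omega the
#' signed target rate in rad/ns), which the test suite uses as a
#' closed-form oracle.
#'
#' @param bias a [RotorBias-class].
#' @param gammaF friction, kcal mol^-1 ns rad^-2.
#' @param nSteps number of steps.
#' @param dt time step, ns.
#' @param kBT thermal energy, kcal/mol (0 for deterministic drift).
#' @param seed integer seed.
#' @param theta0 initial particle angle, radians.
#' @return A [WorkLedger-class] sampled at every step.
#' @export
dragParticle <- function(bias, gammaF, nSteps, dt = 1e-3, kBT = 0,
                         seed = 1L, theta0 = bias@theta0Init) {
  set.seed(seed)
  theta <- theta0
  ledger <- newWorkLedger(0, theta, bias)
  tm <- numeric(nSteps); th <- numeric(nSteps); th0 <- numeric(nSteps)
  wk <- numeric(nSteps); tq <- numeric(nSteps)
  w <- 0
  sd <- sqrt(2 * kBT * dt / gammaF)
  for (k in seq_len(nSteps)) {
    t0 <- (k - 1) * dt; t1 <- k * dt
    w <- w + biasEnergy(theta, t1, bias)$energy -
      biasEnergy(theta, t0, bias)$energy
    b <- biasEnergy(theta, t0, bias)
    theta <- theta + dt * b$torque / gammaF + sd * stats::rnorm(1)
    bb <- biasEnergy(theta, t1, bias)
    tm[k] <- t1; th[k] <- theta; th0[k] <- bb$theta0
    wk[k] <- w; tq[k] <- bb$torque
  }
  new("WorkLedger", time = c(0, tm), theta = c(theta0, th),
      theta0 = c(biasTarget(bias, 0), th0), work = c(0, wk),
      torque = c(biasEnergy(theta0, 0, bias)$torque, tq))
}

#' Write a work ledger as CSV
#'
#' Columns: time_ns, theta_deg, theta0_deg, work_kcal_mol,
#' torque_pN_nm_per_rad.
#'
#' @param ledger a [WorkLedger-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLedgerCSV <- function(ledger, path) {
  utils::write.csv(format(ledgerTable(ledger), digits = 10, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
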