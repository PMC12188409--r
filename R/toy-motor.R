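## Coarse-grained, seeded toy rotary motor.
##
## The generator emulates the statistical structure the analysis modules
## assume, at desk scale: a 3-fold stator ring whose units interconvert
## between open/closed (gate coordinate g) and loose/tight (interface
## coordinate h) conformations, a two-layer rotor whose buried core ring
## lags the protruded ring under torque (they are coupled by a torsion
## spring, and the bias acts only on the protruded ring through the mean
## rotation angle CV), and an optional inhibitor chain whose short segment
## contacts the rotor core and whose long segment contacts stator unit 1.
## All parameters are module constants chosen for a well-behaved overdamped
## toy; they are NOT measurements of any real enzyme.

#' Default toy-motor parameters
#'
#' Geometry in Angstrom, energies in kcal/mol, time in ns.  Friction
#' coefficients are per coordinate (kcal mol^-1 ns rad^-2 for angles,
#' kcal mol^-1 ns A^-2 for Cartesian coordinates).
#'
#' @param ... named overrides of any default.
#' @return parameter list.
#' @export
toyMotorParams <- function(...) {
  p <- list(
    statorRadius = 25, statorBeads = 5L,
    amplGate = 4, amplTight = 2,
    rProt = 8, zProt = 12, nProt = 12L,
    rCore = 4, nCoreN = 6L, nCoreC = 6L, zCoreC = 4,
    resProt = 101:112, resCoreN = 1:6, resCoreC = 267:272,
    nInh = 10L, bond0 = 3.8, kBond = 10,
    shortSeg = 1:4, longSeg = 5:10,
    contactEps = 3, contactSigma = 2, contactOffset = 3,
    barrierGate = 2, barrierTight = 2,
    kCouple = 1, thetaThDeg = 20, widthThDeg = 10,
    kShape = 50, kappaTw = 100,
    kBT = 0.6,
    gammaAng = 5, gammaGate = 2, gammaXYZ = 0.5,
    confRadius = 60, kConf = 0.5)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

## precompute static geometry: stator bead bases and displacement
## directions, rotor lattices, inhibitor anchor bindings
motorGeometry <- function(p) {
  phi <- 2 * pi * (0:2) / 3
  zloc <- seq(-8, 8, length.out = p$statorBeads)
  wz <- (zloc + 8) / 16                       # top beads move the most
  ## non-collinear local cluster: small radial/tangential offsets per bead
  rOff <- 2.0 * cos(1.7 * seq_len(p$statorBeads))
  tOff <- 2.5 * sin(2.3 * seq_len(p$statorBeads))
  units <- lapply(1:3, function(j) {
    er <- c(cos(phi[j]), sin(phi[j]), 0)
    et <- c(-sin(phi[j]), cos(phi[j]), 0)
    base <- t(vapply(seq_along(zloc), function(i)
      (p$statorRadius + rOff[i]) * er + tOff[i] * et + c(0, 0, zloc[i]),
      numeric(3)))
    dGate <- t(vapply(seq_along(zloc), function(i)
      -p$amplGate * wz[i] * er, numeric(3)))  # closing moves inward
    dTight <- t(vapply(seq_along(zloc), function(i)
      p$amplTight * wz[i] * et, numeric(3)))
    list(base = base, dGate = dGate, dTight = dTight)
  })
  latProt <- 2 * pi * (seq_len(p$nProt) - 1L) / p$nProt
  latCoreN <- 2 * pi * (seq_len(p$nCoreN) - 1L) / p$nCoreN
  latCoreC <- 2 * pi * (seq_len(p$nCoreC) - 1L) / p$nCoreC
  ## inhibitor native contacts: the short segment binds an arc riding on
  ## the rotor core (chord spacing ~ bond length, slight tangential tilt
  ## gives the contact geometry a handedness); the long segment binds
  ## stator-1 beads, offset inward toward the rotor
  nShort <- length(p$shortSeg); nLong <- length(p$longSeg)
  rAnch <- p$rCore + p$contactOffset
  dphiS <- p$bond0 / rAnch
  shortPhi <- (seq_len(nShort) - 1L) * dphiS + degToRad(10)
  longAnchor <- rev(rep(seq_len(p$statorBeads), length.out = nLong))
  list(units = units, latProt = latProt, latCoreN = latCoreN,
       latCoreC = latCoreC, rAnch = rAnch, shortPhi = shortPhi,
       longAnchor = longAnchor)
}

statorBeadPos <- function(geom, j, g, h) {
  u <- geom$units[[j]]
  u$base + g * u$dGate + h * u$dTight
}

coreBeadPos <- function(p, geom, thetaCore) {
  angN <- thetaCore + geom$latCoreN
  angC <- thetaCore + geom$latCoreC
  rbind(cbind(p$rCore * cos(angN), p$rCore * sin(angN), 0),
        cbind(p$rCore * cos(angC), p$rCore * sin(angC), p$zCoreC))
}

protBeadPos <- function(p, alpha) {
  cbind(p$rProt * cos(alpha), p$rProt * sin(alpha), p$zProt)
}

## anchor positions for the inhibitor native contacts, plus their
## derivatives with respect to the coordinates they ride on
inhAnchors <- function(p, geom, state) {
  angC <- state$thetaCore + geom$shortPhi
  rAnch <- geom$rAnch
  short <- cbind(rAnch * cos(angC), rAnch * sin(angC), p$zCoreC)
  dShort <- cbind(-rAnch * sin(angC), rAnch * cos(angC), 0)  # d/dThetaCore
  u <- geom$units[[1]]
  idx <- geom$longAnchor
  pos <- statorBeadPos(geom, 1L, state$g[1], state$h[1])[idx, , drop = FALSE]
  er <- c(cos(0), sin(0), 0)                   # unit 1 radial direction
  long <- sweep(pos, 2, p$contactOffset * er)  # offset inward
  list(short = short, dShortDtheta = dShort,
       long = long, dLongDg = u$dGate[idx, , drop = FALSE],
       dLongDh = u$dTight[idx, , drop = FALSE])
}

#' Build a toy motor
#'
#' Deterministic geometry for given parameters; the inhibitor chain starts
#' at its native-contact anchors.  `seed` is recorded for provenance (the
#' construction itself is deterministic).
#'
#' @param params parameter list from [toyMotorParams()].
#' @param seed integer seed recorded in the parameters.
#' @return A [ToyMotor-class].
#' @export
buildMotor <- function(params = toyMotorParams(), seed = 0L) {
  p <- params
  if (p$rProt <= 0 || p$rCore <= 0 || p$statorRadius <= 0)
    stop("non-physical parameters: radii must be positive")
  if (p$nInh > 0 && length(p$shortSeg) + length(p$longSeg) != p$nInh)
    stop("shortSeg and longSeg must partition the inhibitor beads")
  ## keep residue numbering in step with overridden bead counts
  if (length(p$resProt) != p$nProt) p$resProt <- seq(101L, by = 1L,
                                                     length.out = p$nProt)
  if (length(p$resCoreN) != p$nCoreN) p$resCoreN <- seq_len(p$nCoreN)
  if (length(p$resCoreC) != p$nCoreC)
    p$resCoreC <- seq(273L - p$nCoreC, 272L)
  geom <- motorGeometry(p)
  p$geom <- geom
  ## gates start at their rotor-coupled targets (unit 1 open, 2/3 closed)
  g0 <- vapply(1:3, function(j) gateTarget(p, 0, j), numeric(1))
  state <- list(g = g0, h = c(0, 0, 0), thetaCore = 0,
                alpha = geom$latProt, inh = matrix(numeric(0), ncol = 3))
  if (p$nInh > 0) {
    anch <- inhAnchors(p, geom, state)
    inh <- matrix(0, p$nInh, 3)
    inh[p$shortSeg, ] <- anch$short
    inh[p$longSeg, ] <- anch$long
    state$inh <- inh
    ## per-bond native rest lengths: the initial geometry is the unstrained
    ## reference, so the bridging short-to-long bond keeps its native span
    p$bondRest <- sqrt(rowSums((inh[-1, , drop = FALSE] -
                                  inh[-p$nInh, , drop = FALSE])^2))
  } else p$bondRest <- numeric(0)
  p$seed <- as.integer(seed)
  p$cvRef <- protBeadPos(p, state$alpha)      # CV reference: initial ring
  new("ToyMotor", params = p, state = state)
}

## mean protruded angle relative to the lattice
meanProtAngle <- function(p, alpha) mean(alpha - p$geom$latProt)

## gate target as a function of rotor angle: rotation past the threshold
## (120-degree periodic per unit) tilts the double-well toward "closed"
gateTarget <- function(p, abar, j, override = NA_real_) {
  if (!is.na(override)) return(override)
  delta <- wrapRad(abar - 2 * pi * (j - 1) / 3)
  0.5 * (1 + tanh((abs(delta) - degToRad(p$thetaThDeg)) /
                    degToRad(p$widthThDeg)))
}

dGateTargetDabar <- function(p, abar, j, override = NA_real_) {
  if (!is.na(override)) return(0)
  delta <- wrapRad(abar - 2 * pi * (j - 1) / 3)
  w <- degToRad(p$widthThDeg)
  s <- 1 / cosh((abs(delta) - degToRad(p$thetaThDeg)) / w)^2
  0.5 * s / w * sign(delta)
}

## total potential energy and (negative) gradients for every coordinate.
## Returns list(energy, Fg, Fh, FthetaCore, Falpha, Finh).
motorForces <- function(p, state, biasInfo = NULL, gateOverride = rep(NA_real_, 3)) {
  geom <- p$geom
  Fg <- numeric(3); Fh <- numeric(3); Fth <- 0
  Falpha <- numeric(p$nProt)
  Finh <- matrix(0, nrow(state$inh), 3)
  U <- 0
  ## gate / interface double wells: 16*h*q^2(1-q)^2, minima at 0 and 1
  dw <- function(q, barrier) {
    list(U = 16 * barrier * q^2 * (1 - q)^2,
         dU = 32 * barrier * q * (1 - q) * (1 - 2 * q))
  }
  for (j in 1:3) {
    a <- dw(state$g[j], p$barrierGate)
    U <- U + a$U; Fg[j] <- Fg[j] - a$dU
    b <- dw(state$h[j], p$barrierTight)
    U <- U + b$U; Fh[j] <- Fh[j] - b$dU
  }
  ## rotor-gate coupling
  abar <- meanProtAngle(p, state$alpha)
  for (j in 1:3) {
    G <- gateTarget(p, abar, j, gateOverride[j])
    dG <- dGateTargetDabar(p, abar, j, gateOverride[j])
    diffj <- state$g[j] - G
    U <- U + 0.5 * p$kCouple * diffj^2
    Fg[j] <- Fg[j] - p$kCouple * diffj
    dUdabar <- -p$kCouple * diffj * dG
    Falpha <- Falpha - dUdabar / p$nProt
  }
  ## ring shape springs (protruded beads about their mean)
  dev <- state$alpha - geom$latProt - abar
  U <- U + 0.5 * p$kShape * sum(dev^2)
  Falpha <- Falpha - p$kShape * dev
  ## torsion spring core <-> protruded mean
  tw <- abar - state$thetaCore
  U <- U + 0.5 * p$kappaTw * tw^2
  Falpha <- Falpha - p$kappaTw * tw / p$nProt
  Fth <- Fth + p$kappaTw * tw
  ## inhibitor: bonds, native contacts, confinement
  if (nrow(state$inh)) {
    r <- state$inh
    for (i in seq_len(nrow(r) - 1L)) {
      d <- r[i + 1L, ] - r[i, ]
      dn <- sqrt(sum(d^2))
      b0 <- if (length(p$bondRest) >= i) p$bondRest[i] else p$bond0
      U <- U + 0.5 * p$kBond * (dn - b0)^2
      f <- p$kBond * (dn - b0) * d / max(dn, 1e-9)
      Finh[i, ] <- Finh[i, ] + f
      Finh[i + 1L, ] <- Finh[i + 1L, ] - f
    }
    anch <- inhAnchors(p, geom, state)
    gauss <- function(bead, a) {
      d2 <- sum((bead - a)^2)
      e <- -p$contactEps * exp(-d2 / (2 * p$contactSigma^2))
      list(U = e, dUdBead = -e * (bead - a) / p$contactSigma^2)
    }
    for (k in seq_along(p$shortSeg)) {
      i <- p$shortSeg[k]
      gk <- gauss(r[i, ], anch$short[k, ])
      U <- U + gk$U
      Finh[i, ] <- Finh[i, ] - gk$dUdBead
      ## reaction on the core angle through the moving anchor
      Fth <- Fth - sum(-gk$dUdBead * anch$dShortDtheta[k, ])
    }
    for (k in seq_along(p$longSeg)) {
      i <- p$longSeg[k]
      gk <- gauss(r[i, ], anch$long[k, ])
      U <- U + gk$U
      Finh[i, ] <- Finh[i, ] - gk$dUdBead
      Fg[1] <- Fg[1] - sum(-gk$dUdBead * anch$dLongDg[k, ])
      Fh[1] <- Fh[1] - sum(-gk$dUdBead * anch$dLongDh[k, ])
    }
    ## flat-bottom spherical confinement
    rad <- sqrt(rowSums(r^2))
    out <- rad > p$confRadius
    if (any(out)) {
      ex <- rad[out] - p$confRadius
      U <- U + 0.5 * p$kConf * sum(ex^2)
      Finh[out, ] <- Finh[out, ] -
        p$kConf * ex / rad[out] * r[out, , drop = FALSE]
    }
  }
  ## torque bias on the protruded ring, applied through the CV gradient
  if (!is.null(biasInfo)) {
    xyz <- protBeadPos(p, state$alpha)
    gr <- cvGradient(xyz, biasInfo$cv)
    dUdtheta <- biasInfo$kappa * (biasInfo$theta - biasInfo$theta0)
    U <- U + 0.5 * biasInfo$kappa * (biasInfo$theta - biasInfo$theta0)^2
    ## chain rule to the angular coordinates of the beads
    tang <- cbind(-p$rProt * sin(state$alpha), p$rProt * cos(state$alpha), 0)
    Falpha <- Falpha - dUdtheta * rowSums(gr * tang)
  }
  list(energy = U, Fg = Fg, Fh = Fh, FthetaCore = Fth, Falpha = Falpha,
       Finh = Finh)
}

#' Total potential energy of a motor state
#'
#' @param motor a [ToyMotor-class].
#' @return energy in kcal/mol (bias excluded).
#' @export
motorEnergy <- function(motor) {
  motorForces(motor@params, motor@state)$energy
}

#' Simulation protocol
#'
#' @param nSteps number of integration steps.
#' @param dt time step, ns.  Stability bound for the Euler-Maruyama
#'   integrator: dt < gamma / k_stiff for the stiffest spring acting on a
#'   coordinate with friction gamma (the bias spring is usually stiffest:
#'   dt < gammaAng / kappa).
#' @param seed integer seed; a fixed seed makes the run bit-reproducible.
#' @param bias optional [RotorBias-class] applied to the protruded ring.
#' @param stride sampling stride (frames and ledger samples every `stride`
#'   steps).
#' @param stateSwitch optional data.frame(time, unit, target): from `time`
#'   on, the gate target of stator `unit` is pinned to `target` (0 = open,
#'   1 = closed), mimicking a nucleotide-state replacement.
#' @param temperature optional kBT override (kcal/mol).
#' @return protocol list.
#' @export
simProtocol <- function(nSteps, dt = 1e-3, seed = 1L, bias = NULL,
                        stride = 10L, stateSwitch = NULL,
                        temperature = NULL) {
  if (dt <= 0) stop("dt must be positive")
  list(nSteps = as.integer(nSteps), dt = dt, seed = as.integer(seed),
       bias = bias, stride = as.integer(stride), stateSwitch = stateSwitch,
       temperature = temperature)
}

#' Run overdamped Langevin dynamics on a toy motor
#'
#' Euler-Maruyama updates on every coordinate:
#' q <- q + dt F / gamma + sqrt(2 kBT dt / gamma) xi.  All randomness flows
#' from `protocol$seed` through one Mersenne-Twister stream with a fixed
#' draw order (one Gaussian vector per step, coordinates in the order
#' g, h, thetaCore, alpha, inhibitor-xyz), so runs are bit-reproducible for
#' fixed seed, step count and dt.  The rotor bias is applied through the
#' mean-rotation-angle CV and its gradient on the protruded ring; external
#' work is accumulated per step as the target-displacement work.
#'
#' @param motor a [ToyMotor-class].
#' @param protocol list from [simProtocol()].
#' @return list with `trajectory` ([Trajectory-class]), `ledger`
#'   ([WorkLedger-class] or NULL when unbiased), `motor` (final state).
#' @export
runLangevin <- function(motor, protocol) {
  p <- motor@params
  st <- motor@state
  kBT <- if (is.null(protocol$temperature)) p$kBT else protocol$temperature
  dt <- protocol$dt
  bias <- protocol$bias
  nInh3 <- 3L * nrow(st$inh)
  ndof <- 3L + 3L + 1L + p$nProt + nInh3
  sdGate <- sqrt(2 * kBT * dt / p$gammaGate)
  sdAng <- sqrt(2 * kBT * dt / p$gammaAng)
  sdXYZ <- sqrt(2 * kBT * dt / p$gammaXYZ)
  cv <- rotorCV(p$cvRef)
  theta <- meanRotationAngle(protBeadPos(p, st$alpha), cv)
  ledger <- NULL
  if (!is.null(bias)) {
    ledger <- list(time = 0, theta = theta,
                   theta0 = biasTarget(bias, 0), work = 0,
                   torque = biasEnergy(theta, 0, bias)$torque)
    wcum <- 0
  }
  sw <- protocol$stateSwitch
  frames <- list(); ftimes <- numeric(0); meta <- list()
  sampleFrame <- function(t) {
    frames[[length(frames) + 1L]] <<- motorStateXYZ(p, st)
    ftimes[length(ftimes) + 1L] <<- t
    meta[[length(meta) + 1L]] <<- c(
      g1 = st$g[1], g2 = st$g[2], g3 = st$g[3],
      h1 = st$h[1], h2 = st$h[2], h3 = st$h[3],
      thetaCore = st$thetaCore, meanProt = meanProtAngle(p, st$alpha))
  }
  set.seed(protocol$seed)
  sampleFrame(0)
  for (step in seq_len(protocol$nSteps)) {
    t0 <- (step - 1L) * dt
    t1 <- step * dt
    gateOv <- rep(NA_real_, 3)
    if (!is.null(sw)) {
      for (e in seq_len(nrow(sw)))
        if (t0 >= sw$time[e]) gateOv[sw$unit[e]] <- sw$target[e]
    }
    biasInfo <- NULL
    if (!is.null(bias)) {
      theta <- meanRotationAngle(protBeadPos(p, st$alpha), cv, previous = theta)
      biasInfo <- list(cv = cv, kappa = bias@kappa, theta = theta,
                       theta0 = biasTarget(bias, t0))
    }
    f <- motorForces(p, st, biasInfo, gateOv)
    xi <- stats::rnorm(ndof)
    st$g <- st$g + dt * f$Fg / p$gammaGate + sdGate * xi[1:3]
    st$h <- st$h + dt * f$Fh / p$gammaGate + sdGate * xi[4:6]
    st$thetaCore <- st$thetaCore + dt * f$FthetaCore / p$gammaAng +
      sdAng * xi[7]
    ia <- 7L + seq_len(p$nProt)
    st$alpha <- st$alpha + dt * f$Falpha / p$gammaAng + sdAng * xi[ia]
    if (nInh3) {
      ix <- 7L + p$nProt + seq_len(nInh3)
      st$inh <- st$inh + dt * f$Finh / p$gammaXYZ +
        sdXYZ * matrix(xi[ix], ncol = 3L)
    }
    bad <- !all(is.finite(c(st$g, st$h, st$thetaCore, st$alpha, st$inh))) ||
      max(abs(c(st$g, st$h, st$thetaCore, st$alpha, st$inh))) > 1e4
    if (bad) stop("dynamics diverged at step ", step,
                  " (reduce dt or spring constants)")
    if (!is.null(bias)) {
      ## target-displacement work at fixed coordinates, then re-measure CV
      wcum <- wcum + biasEnergy(theta, t1, bias)$energy -
        biasEnergy(theta, t0, bias)$energy
      theta <- meanRotationAngle(protBeadPos(p, st$alpha), cv,
                                 previous = theta)
    }
    if (step %% protocol$stride == 0L) {
      sampleFrame(t1)
      if (!is.null(bias)) {
        ledger$time <- c(ledger$time, t1)
        ledger$theta <- c(ledger$theta, theta)
        ledger$theta0 <- c(ledger$theta0, biasTarget(bias, t1))
        ledger$work <- c(ledger$work, wcum)
        ledger$torque <- c(ledger$torque,
                           biasEnergy(theta, t1, bias)$torque)
      }
    }
  }
  topo <- motorAsStructure(motor)
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  traj <- new("Trajectory", topology = topo, xyz = xyz, times = ftimes,
              metadata = as.data.frame(do.call(rbind, meta)))
  led <- NULL
  if (!is.null(bias))
    led <- new("WorkLedger", time = ledger$time, theta = ledger$theta,
               theta0 = ledger$theta0, work = ledger$work,
               torque = ledger$torque)
  out <- motor; out@state <- st
  list(trajectory = traj, ledger = led, motor = out,
       config = runConfig(p, protocol))
}

## effective-parameter echo for a run: everything needed to reproduce it
runConfig <- function(p, protocol) {
  cfg <- p[setdiff(names(p), c("geom", "cvRef", "bondRest"))]
  cfg$protocol <- protocol[c("nSteps", "dt", "seed", "stride")]
  if (!is.null(protocol$bias)) {
    b <- protocol$bias
    cfg$protocol$bias <- list(kappa = b@kappa, omegaDegNs = b@omegaDegNs,
                              theta0InitDeg = radToDeg(b@theta0Init),
                              direction = b@direction)
  }
  if (!is.null(protocol$stateSwitch))
    cfg$protocol$stateSwitch <- protocol$stateSwitch
  if (!is.null(protocol$temperature))
    cfg$protocol$temperature <- protocol$temperature
  cfg
}

#' Write the effective parameters of a run as a config echo
#'
#' YAML key-value echo of every effective parameter of a motor run, so any
#' artifact-producing run is reproducible from its echo alone.
#'
#' @param config the `config` element returned by [runLangevin()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## bead coordinates of the full motor, in the fixed export order:
## stator A,B,C then rotor core N, core C, protruded, then inhibitor
motorStateXYZ <- function(p, st) {
  rows <- list()
  for (j in 1:3) rows[[j]] <- statorBeadPos(p$geom, j, st$g[j], st$h[j])
  rows[[4]] <- coreBeadPos(p, p$geom, st$thetaCore)
  rows[[5]] <- protBeadPos(p, st$alpha)
  if (nrow(st$inh)) rows[[6]] <- st$inh
  do.call(rbind, rows)
}

#' Export a motor as a labelled structure
#'
#' Chains A/B/C are the stator units (role `beta`), chain G the rotor (core
#' residues numbered like a gamma subunit: N-core then C-core, protruded in
#' between; role `gamma`), chain I the inhibitor (role `inhibitor`).  Every
#' bead is a CA pseudo-atom, so the structure-IO and trajectory-metric
#' machinery operate on it unchanged.
#'
#' @param motor a [ToyMotor-class].
#' @return A [StructureModel-class].
#' @export
motorAsStructure <- function(motor) {
  p <- motor@params; st <- motor@state
  xyz <- motorStateXYZ(p, st)
  chain <- c(rep(c("A", "B", "C"), each = p$statorBeads),
             rep("G", p$nCoreN + p$nCoreC + p$nProt),
             rep("I", nrow(st$inh)))
  resno <- c(rep(seq_len(p$statorBeads), 3),
             p$resCoreN, p$resCoreC, p$resProt,
             seq_len(nrow(st$inh)))
  atoms <- data.frame(chain = chain, resno = resno, resname = "ALA",
                      elety = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
                      stringsAsFactors = FALSE)
  rm <- c(A = "beta", B = "beta", C = "beta", G = "gamma")
  if (nrow(st$inh)) rm <- c(rm, I = "inhibitor")
  StructureModel(atoms, title = "toy-motor", roleMap = rm)
}

#' Steer a motor toward a target state by RMSD reduction
#'
#' A harmonic penalty 0.5 k (RMSD - rho(t))^2 acts on the coordinate-space
#' RMSD between the current and target generalised coordinates (gates,
#' interface coordinates, rotor angles and inhibitor positions in one
#' vector), with rho(t) decreasing linearly from the initial RMSD to 0 over
#' `duration` ns - the steering analogue of targeted dynamics.
#'
#' @param motor a [ToyMotor-class].
#' @param target a [ToyMotor-class] with identical topology (the target
#'   coordinates), or a numeric vector from [motorDOF()].
#' @param duration steering time, ns (> 0).
#' @param kSteer steering force constant (kcal/mol per RMSD unit squared).
#' @param dt integration step, ns.
#' @param seed integer seed.
#' @param temperature kBT during steering (default 0: deterministic
#'   descent).
#' @return list with `trajectory` and `motor` (final state).
#' @export
rmsdSteer <- function(motor, target, duration, kSteer = 200, dt = 1e-3,
                      seed = 1L, temperature = 0) {
  if (duration <= 0) stop("duration must be positive")
  p <- motor@params
  qt <- if (is(target, "ToyMotor")) motorDOF(target) else as.numeric(target)
  q0 <- motorDOF(motor)
  if (length(qt) != length(q0))
    stop("topology mismatch: target has ", length(qt),
         " coordinates, motor has ", length(q0))
  n <- length(q0)
  rmsd0 <- sqrt(mean((q0 - qt)^2))
  nSteps <- max(1L, round(duration / dt))
  st <- motor@state
  nInh3 <- 3L * nrow(st$inh)
  sdGate <- sqrt(2 * temperature * dt / p$gammaGate)
  sdAng <- sqrt(2 * temperature * dt / p$gammaAng)
  sdXYZ <- sqrt(2 * temperature * dt / p$gammaXYZ)
  set.seed(seed)
  frames <- list(motorStateXYZ(p, st)); ftimes <- 0
  for (step in seq_len(nSteps)) {
    t1 <- step * dt
    rho <- rmsd0 * max(0, 1 - t1 / duration)
    q <- dofFromState(st)
    dq <- q - qt
    rmsd <- sqrt(mean(dq^2))
    f <- motorForces(p, st)
    fSteer <- if (rmsd > 1e-12)
      -kSteer * (rmsd - rho) * dq / (n * rmsd) else numeric(n)
    Fg <- f$Fg + fSteer[1:3]
    Fh <- f$Fh + fSteer[4:6]
    Fth <- f$FthetaCore + fSteer[7]
    Fa <- f$Falpha + fSteer[7L + seq_len(p$nProt)]
    xi <- stats::rnorm(7L + p$nProt + nInh3)
    st$g <- st$g + dt * Fg / p$gammaGate + sdGate * xi[1:3]
    st$h <- st$h + dt * Fh / p$gammaGate + sdGate * xi[4:6]
    st$thetaCore <- st$thetaCore + dt * Fth / p$gammaAng + sdAng * xi[7]
    st$alpha <- st$alpha + dt * Fa / p$gammaAng +
      sdAng * xi[7L + seq_len(p$nProt)]
    if (nInh3) {
      Fi <- f$Finh + matrix(fSteer[7L + p$nProt + seq_len(nInh3)], ncol = 3L)
      st$inh <- st$inh + dt * Fi / p$gammaXYZ +
        sdXYZ * matrix(xi[7L + p$nProt + seq_len(nInh3)], ncol = 3L)
    }
    if (step %% 10L == 0L) {
      frames[[length(frames) + 1L]] <- motorStateXYZ(p, st)
      ftimes <- c(ftimes, t1)
    }
  }
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  out <- motor; out@state <- st
  list(trajectory = new("Trajectory", topology = motorAsStructure(motor),
                        xyz = xyz, times = ftimes, metadata = data.frame()),
       motor = out)
}

#' Generalised coordinate vector of a motor
#'
#' Order: g (3), h (3), thetaCore, alpha (nProt), inhibitor xyz
#' (row-major).
#'
#' @param motor a [ToyMotor-class].
#' @return numeric vector.
#' @export
motorDOF <- function(motor) dofFromState(motor@state)

dofFromState <- function(st) {
  c(st$g, st$h, st$thetaCore, st$alpha, as.vector(t(st$inh)))
}

#' Generate a synthetic PCA dataset with known ground truth
#'
#' Pairs are sampled about a base conformation along two orthonormal
#' displacement vectors: an open/closed direction (the stator gate motion;
#' ground-truth PC1) and a smaller loose/tight direction (interface motion;
#' ground-truth PC2), plus optional isotropic noise.  Default mode
#' variances are 0.09 and 0.01 nm^2 (a 9:1 split).
#'
#' @param n number of pairs (>= 2).
#' @param noiseSigma isotropic noise standard deviation, nm.
#' @param seed integer seed.
#' @param modeSD standard deviations (nm) of the two mode amplitudes.
#' @param fractions optional numeric vector in \[0, 1\]: instead of random
#'   sampling, place pairs deterministically at these fractions of the
#'   open-to-closed displacement (amplitude `4 * modeSD[1]` end to end).
#' @return A [PairSet-class] with attribute `groundTruth`: list(center,
#'   v1, v2, modeSD).
#' @export
generatePcaDataset <- function(n, noiseSigma = 0, seed = 1L,
                               modeSD = c(0.3, 0.1), fractions = NULL) {
  if (n < 2L) stop("need at least 2 pairs")
  p <- toyMotorParams()
  geom <- motorGeometry(p)
  u <- geom$units[[1]]
  center <- as.vector(t(u$base)) / 10         # nm
  ## ground-truth modes must be internal deformations: project the rigid
  ## translation/rotation subspace out of the gate and tight displacement
  ## fields (otherwise superposition would absorb part of them)
  X <- sweep(u$base, 2, colMeans(u$base))
  nb <- nrow(X)
  rigid <- cbind(
    as.vector(t(matrix(rep(c(1, 0, 0), nb), ncol = 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 1, 0), nb), ncol = 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 0, 1), nb), ncol = 3, byrow = TRUE))),
    as.vector(t(cbind(0, -X[, 3], X[, 2]))),
    as.vector(t(cbind(X[, 3], 0, -X[, 1]))),
    as.vector(t(cbind(-X[, 2], X[, 1], 0))))
  Qr <- qr.Q(qr(rigid))
  deflate <- function(v) { v <- v - Qr %*% crossprod(Qr, v); as.vector(v) }
  v1 <- deflate(as.vector(t(u$dGate))); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- deflate(as.vector(t(u$dTight)))
  v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  set.seed(seed)
  if (is.null(fractions)) {
    a <- stats::rnorm(n, 0, modeSD[1])
    b <- stats::rnorm(n, 0, modeSD[2])
  } else {
    stopifnot(length(fractions) == n)
    a <- (fractions - 0.5) * 4 * modeSD[1]
    b <- numeric(n)
  }
  X <- outer(a, v1) + outer(b, v2)
  X <- sweep(X, 2, center, `+`)
  if (noiseSigma > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, noiseSigma), nrow = n)
  ps <- new("PairSet", coords = X,
            info = data.frame(sourceId = sprintf("synthetic%03d", seq_len(n)),
                              pairRole = NA_character_,
                              inhibitorBound = FALSE,
                              stringsAsFactors = FALSE))
  attr(ps, "groundTruth") <- list(center = center, v1 = v1, v2 = v2,
                                  modeSD = modeSD)
  ps
}

#' Generate a backbone chain with a prescribed helical fraction
#'
#' Builds N/CA/C backbone coordinates by internal-coordinate chain
#' extension: the first `floor(f * n)` residues get ideal alpha-helical
#' dihedrals (phi = -57, psi = -47 degrees), the rest extended dihedrals
#' (phi = -120, psi = 120 degrees); omega is fixed at 180.
#'
#' @param nRes number of residues (>= 2).
#' @param helicalFraction fraction in \[0, 1\] of leading helical residues.
#' @param chain chain identifier.
#' @return A [StructureModel-class] with N, CA, C atoms per residue.
#' @export
generateHelixChain <- function(nRes, helicalFraction = 1, chain = "P") {
  stopifnot(nRes >= 2L, helicalFraction >= 0, helicalFraction <= 1)
  nHel <- floor(helicalFraction * nRes)
  phi <- ifelse(seq_len(nRes) <= nHel, -57, -120)
  psi <- ifelse(seq_len(nRes) <= nHel, -47, 120)
  ## bond geometry (lengths in Angstrom, angles in degrees)
  bNCa <- 1.458; bCaC <- 1.525; bCN <- 1.329
  aNCaC <- 111.2; aCaCN <- 116.2; aCNCa <- 121.7
  coords <- matrix(NA_real_, nRes * 3L, 3L)
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(bNCa, 0, 0)
  ang <- degToRad(aNCaC)
  coords[3, ] <- coords[2, ] + bCaC * c(-cos(ang), sin(ang), 0)
  idx <- function(res, atom) (res - 1L) * 3L + atom   # atom: 1=N,2=CA,3=C
  for (i in seq_len(nRes - 1L)) {
    ## N_{i+1} from (N_i, CA_i, C_i): torsion psi_i
    coords[idx(i + 1L, 1L), ] <- placeAtom(
      coords[idx(i, 1L), ], coords[idx(i, 2L), ], coords[idx(i, 3L), ],
      bCN, aCaCN, psi[i])
    ## CA_{i+1} from (CA_i, C_i, N_{i+1}): torsion omega = 180
    coords[idx(i + 1L, 2L), ] <- placeAtom(
      coords[idx(i, 2L), ], coords[idx(i, 3L), ], coords[idx(i + 1L, 1L), ],
      bNCa, aCNCa, 180)
    ## C_{i+1} from (C_i, N_{i+1}, CA_{i+1}): torsion phi_{i+1}
    coords[idx(i + 1L, 3L), ] <- placeAtom(
      coords[idx(i, 3L), ], coords[idx(i + 1L, 1L), ], coords[idx(i + 1L, 2L), ],
      bCaC, aNCaC, phi[i + 1L])
  }
  atoms <- data.frame(
    chain = chain,
    resno = rep(seq_len(nRes), each = 3L),
    resname = "ALA",
    elety = rep(c("N", "CA", "C"), nRes),
    element = rep(c("N", "C", "C"), nRes),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], het = FALSE,
    stringsAsFactors = FALSE)
  StructureModel(atoms, title = sprintf("helix f=%.2f", helicalFraction),
                 roleMap = setNames("inhibitor", chain))
}

## internal-coordinate atom placement: position d from c at bond length b,
## angle (b-c-d) ang degrees, torsion (a-b-c-d) tor degrees
placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  ang <- degToRad(angleDeg); tor <- degToRad(torsionDeg)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- crossProd3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- crossProd3(n, bc)
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
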