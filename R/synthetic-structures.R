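## Synthetic F1-like assemblies: full desk-scale stand-ins for crystal
## structures, used wherever a test needs a complete stator ring, rotor and
## inhibitor chain with realistic chain sizes and author numbering.  All
## geometry is invented; these are labelled synthetic throughout.

#' Generate a synthetic F1-like assembly
#'
#' A Calpha-only model with three ~510-residue alpha chains (A, B, C),
#' three ~480-residue beta chains (D, E, F), a 272-residue rotor gamma
#' chain (G) winding along the z axis with its C-terminal half protruding
#' upward, and optionally a 60-residue inhibitor chain (I) near the
#' beta_DP interface.  Beta chains sit at azimuths 0/120/240 degrees
#' (chain D is the conventional beta_DP), alphas at 60/180/300.  The
#' rotor can be pre-rotated about z and each beta C-terminal domain can be
#' displaced outward by an "openness" amount, so frame construction,
#' rotary-angle recovery and pair extraction are all exercisable with
#' known ground truth.
#'
#' @param sourceId label stored as the model title.
#' @param gammaRotationDeg rigid rotation of the gamma chain about z,
#'   degrees (counterclockwise positive).
#' @param betaOpen numeric(3), outward displacement (Angstrom) of each
#'   beta C-terminal domain (residues 320-480), in chain order D, E, F.
#' @param inhibitor include the inhibitor chain.
#' @param noiseSigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed seed for the noise draw (ignored when `noiseSigma = 0`).
#' @return A [StructureModel-class] with an explicit role map.
#' @export
generateSyntheticF1 <- function(sourceId = "synthetic-f1",
                                gammaRotationDeg = 0,
                                betaOpen = c(0, 0, 0),
                                inhibitor = TRUE,
                                noiseSigma = 0, seed = 1L) {
  ring <- 30
  chainCurve <- function(n, azimuthDeg, phase = 0) {
    az <- degToRad(azimuthDeg)
    center <- c(ring * cos(az), ring * sin(az), 0)
    e1 <- c(cos(az), sin(az), 0)
    e2 <- c(-sin(az), cos(az), 0)
    t <- seq_len(n)
    r <- 8
    u <- 0.61 * t + phase
    z <- -20 + 40 * t / n
    cbind(center[1] + r * cos(u) * e1[1] + r * sin(u) * e2[1],
          center[2] + r * cos(u) * e1[2] + r * sin(u) * e2[2],
          z)
  }
  rows <- list()
  addChain <- function(ch, xyz, resno) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = ch, resno = resno, resname = "ALA", elety = "CA",
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  aAz <- c(60, 180, 300); bAz <- c(0, 120, 240)
  for (i in 1:3) addChain(c("A", "B", "C")[i],
                          chainCurve(510, aAz[i], phase = i), 1:510)
  for (i in 1:3) {
    xyz <- chainCurve(480, bAz[i], phase = i + 3)
    cterm <- 320:480
    az <- degToRad(bAz[i])
    xyz[cterm, 1] <- xyz[cterm, 1] + betaOpen[i] * cos(az)
    xyz[cterm, 2] <- xyz[cterm, 2] + betaOpen[i] * sin(az)
    addChain(c("D", "E", "F")[i], xyz, 1:480)
  }
  ## gamma: a tilted coil about the z axis, C-terminal half on top
  tg <- 1:272
  gAng <- 0.35 * tg + degToRad(gammaRotationDeg)
  gXYZ <- cbind(3.5 * cos(gAng), 3.5 * sin(gAng), -25 + 0.2 * tg)
  addChain("G", gXYZ, tg)
  rm <- c(A = "alpha", B = "alpha", C = "alpha",
          D = "beta", E = "beta", F = "beta", G = "gamma")
  if (inhibitor) {
    ti <- 1:60
    iAng <- degToRad(10) + 0.05 * ti
    iXYZ <- cbind(15 * cos(iAng), 15 * sin(iAng), 2 + 0.3 * ti)
    addChain("I", iXYZ, ti)
    rm <- c(rm, I = "inhibitor")
  }
  atoms <- do.call(rbind, rows)
  if (noiseSigma > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noiseSigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noiseSigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noiseSigma)
  }
  StructureModel(atoms, title = sourceId, roleMap = rm)
}

#' Manifest of the reference crystal-structure set
#'
#' The 23 PDB identifiers of the bovine mitochondrial F1 reference set,
#' with the number of F1 complexes each crystal form contributes (three
#' entries contain two complexes per asymmetric unit), totalling 26
#' structures and hence 78 alpha/beta pairs.
#'
#' @return data.frame with columns `id`, `copies`, `inhibitorBound`.
#' @export
referenceEntryManifest <- function() {
  path <- system.file("extdata", "bmf1_entries.txt", package = "rotaryF1")
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
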