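# Shared fixtures and independent oracles for the test suite.

# rotation matrix about z, angle in degrees
rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# random proper rotation + translation, seeded
randomRigidMotion <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

applyRigid <- function(coords, rm) sweep(coords %*% t(rm$R), 2, rm$t, `+`)

# rigidly move every atom of a StructureModel
transformModel <- function(model, rm) {
  xyz <- applyRigid(as.matrix(atomData(model)[, c("x", "y", "z")]), rm)
  a <- atomData(model)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  StructureModel(a, title = model@title, roleMap = roleMap(model))
}

# brute-force grid minimiser of the in-plane squared deviation, the
# independent oracle for the mean-rotation-angle CV (0.001 degree grid)
gridSearchAngle <- function(coords, ref, weights = NULL, window = c(-180, 180),
                            stepDeg = 0.001) {
  xy <- as.matrix(coords)[, 1:2]; rxy <- as.matrix(ref)[, 1:2]
  if (is.null(weights)) weights <- rep(1 / nrow(xy), nrow(xy))
  # coarse pass then fine pass around the coarse optimum
  evalSS <- function(degs) {
    vapply(degs, function(d) {
      R <- rotZ(d)[1:2, 1:2]
      rot <- rxy %*% t(R)
      sum(weights * rowSums((rot - xy)^2))
    }, numeric(1))
  }
  coarse <- seq(window[1], window[2], by = 0.1)
  c0 <- coarse[which.min(evalSS(coarse))]
  fine <- seq(c0 - 0.2, c0 + 0.2, by = stepDeg)
  fine[which.min(evalSS(fine))]
}

# brute-force all-pairs residue contact count (independent of contactCount)
bruteContacts <- function(coordsA, resA, coordsB, resB, cutoff) {
  n <- 0L
  for (ra in unique(resA)) for (rb in unique(resB)) {
    A <- coordsA[resA == ra, , drop = FALSE]
    B <- coordsB[resB == rb, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      dmin <- min(dmin, sqrt(sum((A[i, ] - B[j, ])^2)))
    if (dmin <= cutoff) n <- n + 1L
  }
  n
}

# minimal hand-built structure: one chain of CA beads at given coordinates
caChainModel <- function(xyz, chain = "X", resno = seq_len(nrow(xyz)),
                         role = "gamma") {
  StructureModel(data.frame(
    chain = chain, resno = resno, resname = "ALA", elety = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
    stringsAsFactors = FALSE),
    roleMap = setNames(role, chain))
}

# minimal stator-plus-rotor model for frame tests: three beta chains
# (residues 10-82 clustered at given centres) and a gamma chain along +z
frameTestModel <- function(betaCentres, gammaTwistDeg = 0) {
  rows <- list()
  for (i in 1:3) {
    ctr <- betaCentres[i, ]
    set.seed(100 + i)
    off <- matrix(rnorm(73 * 3, sd = 0.5), ncol = 3)
    xyz <- sweep(off, 2, ctr, `+`)
    rows[[i]] <- data.frame(chain = c("D", "E", "F")[i], resno = 10:82,
                            resname = "ALA", elety = "CA", element = "C",
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            het = FALSE, stringsAsFactors = FALSE)
  }
  t <- 1:272
  ang <- 0.35 * t + gammaTwistDeg * pi / 180
  gxyz <- cbind(3 * cos(ang), 3 * sin(ang), -20 + 0.15 * t)
  rows[[4]] <- data.frame(chain = "G", resno = t, resname = "ALA",
                          elety = "CA", element = "C",
                          x = gxyz[, 1], y = gxyz[, 2], z = gxyz[, 3],
                          het = FALSE, stringsAsFactors = FALSE)
  StructureModel(do.call(rbind, rows),
                 roleMap = c(D = "beta", E = "beta", F = "beta",
                             G = "gamma"))
}
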