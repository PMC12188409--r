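# Small geometry and unit helpers shared by all modules.
# Internal convention: radians internally, degrees at every user interface;
# coordinates in Angstrom except the PCA landscape, which works in nm.

degToRad <- function(x) x * pi / 180
radToDeg <- function(x) x * 180 / pi

## wrap an angle (radians) into (-pi, pi]
wrapRad <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

## wrap an angle (degrees) into (-180, 180]
wrapDeg <- function(x) radToDeg(wrapRad(degToRad(x)))

## continuity-unwrap a series of angles (radians): remove +-2pi jumps
## between consecutive samples (nearest-image continuation)
unwrapRad <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jump <- -2 * pi * round(d / (2 * pi))
  theta + c(0, cumsum(jump))
}

## Optimal proper rotation (Kabsch, via SVD) mapping centred P onto centred Q.
## P, Q: n x 3 matrices of paired coordinates.  Returns the 3x3 rotation R
## such that (P - centroid(P)) %*% t(R) best fits (Q - centroid(Q)).
kabschRotation <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)                   # proper rotation, det = +1
}

## Rigid least-squares superposition of P onto Q (rotation + translation).
## Returns list(coords = transformed P, R, rmsd).
rigidSuperpose <- function(P, Q) {
  if (nrow(P) != nrow(Q))
    stop("superposition requires equal atom counts: ", nrow(P), " vs ", nrow(Q))
  R <- kabschRotation(P, Q)
  Pc <- sweep(P, 2, colMeans(P))
  fitted <- Pc %*% t(R)
  fitted <- sweep(fitted, 2, colMeans(Q), `+`)
  list(coords = fitted, R = R,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

## Torsion angle of four points, degrees in (-180, 180].
## The numerical kernel is bio3d's torsion routine.
torsionDeg <- function(p1, p2, p3, p4) {
  ang <- bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
  as.numeric(ang[1])
}

## Interior angle (degrees, [0, 180]) at vertex b of the triplet a-b-c.
interiorAngleDeg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9)
    stop("coincident points: bending angle undefined")
  cosang <- sum(u * v) / (nu * nv)
  radToDeg(acos(max(-1, min(1, cosang))))
}

#' 1 kcal/mol expressed in pN nm (per molecule)
#'
#' 4184 J per mole divided by the Avogadro constant, in units of 1e-21 J
#' (about 6.9477 pN nm).
#'
#' @return numeric(1).
#' @export
kcalMolInPNnm <- function() 4184 / 6.02214076e23 * 1e21

#' Convert a rotational spring constant to per-degree units
#'
#' kcal mol^-1 rad^-2 to kcal mol^-1 deg^-2 (factor (pi/180)^2); 1e5
#' kcal mol^-1 rad^-2 is about 30.5 kcal mol^-1 deg^-2.
#'
#' @param kappaRad2 spring constant, kcal mol^-1 rad^-2.
#' @return spring constant, kcal mol^-1 deg^-2.
#' @export
kappaPerDegree <- function(kappaRad2) kappaRad2 * (pi / 180)^2

#' Parse a residue-range string
#'
#' `"1-26,228-272"` becomes a sorted 2-column matrix of inclusive
#' intervals; overlapping intervals are an error.
#'
#' @param txt range string, or an already-parsed 2-column matrix.
#' @return 2-column integer matrix with columns start, end.
#' @export
parseRanges <- function(txt) {
  if (is.matrix(txt)) {
    rng <- txt
  } else {
    parts <- strsplit(gsub("[[:space:]]", "", txt), ",", fixed = TRUE)[[1]]
    rng <- t(vapply(parts, function(p) {
      ab <- strsplit(p, "-", fixed = TRUE)[[1]]
      if (length(ab) == 1L) ab <- c(ab, ab)
      as.integer(ab)
    }, integer(2)))
  }
  colnames(rng) <- c("start", "end")
  rownames(rng) <- NULL
  if (any(rng[, 2] < rng[, 1]))
    stop("range end precedes start")
  rng <- rng[order(rng[, 1]), , drop = FALSE]
  if (nrow(rng) > 1L && any(rng[-1, 1] <= rng[-nrow(rng), 2]))
    stop("residue ranges overlap")
  rng
}

## Expand a range matrix to the ordered vector of residue numbers it covers.
expandRanges <- function(rng) {
  unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]),
         use.names = FALSE)
}
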