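## Conformational landscape of alpha/beta pairs: Calpha subset extraction,
## iterative mean superposition, covariance PCA, projection, and the
## PC2-based conformational-progress statistic.
##
## The landscape works in nm (coordinates are converted from Angstrom on
## extraction); the covariance is normalised by the number of pairs M
## (population covariance) - the explained-fraction statistic is invariant
## to that choice.

## default Calpha residue subsets: the regions resolved in all structures of
## the reference set of F1 entries
#' Default alpha/beta Calpha residue subsets
#'
#' The alpha-subunit subset 24-401, 413-483, 494-509 (465 residues) and the
#' beta-subunit subset 10-126, 129-310, 312-387, 396-464 (444 residues),
#' i.e. the regions resolved across the full reference set of structures;
#' one pair contributes 909 Calpha atoms.
#'
#' @return named list of two [Selection-class] objects (`alpha`, `beta`).
#' @export
defaultPairSubsets <- function() {
  list(alpha = Selection("alpha", "24-401,413-483,494-509", "CA"),
       beta = Selection("beta", "10-126,129-310,312-387,396-464", "CA"))
}

#' Extract alpha/beta pairs from structures
#'
#' Each structure must carry three alpha and three beta chains (via its role
#' map) and yields exactly three pairs, so N structures give 3N pairs.
#' Chains are paired geometrically: alpha and beta chains are ordered by
#' azimuth about the pseudo-threefold axis (the axis through the stator
#' centroid, normal to the plane of the beta centroids) and each beta is
#' paired with the nearest alpha clockwise.  Pair roles (E/TP/DP) are taken
#' from `roles` when supplied, otherwise left `NA` for later annotation.
#'
#' @param structures list of [StructureModel-class].
#' @param subsets list with `alpha` and `beta` [Selection-class] (defaults
#'   to [defaultPairSubsets()]).
#' @param roles optional character matrix/list of per-structure pair roles
#'   (length-3 each).
#' @param inhibitorBound optional logical vector or per-structure length-3
#'   list marking inhibitor-bound pairs.
#' @param intersect if TRUE, restrict each subset to the residues resolved
#'   in every structure of the batch (see [commonResidues()]).
#' @return A [PairSet-class]; coordinates in nm.
#' @export
extractPairs <- function(structures, subsets = defaultPairSubsets(),
                         roles = NULL, inhibitorBound = NULL,
                         intersect = FALSE) {
  if (is(structures, "StructureModel")) structures <- list(structures)
  restrictA <- restrictB <- NULL
  if (intersect) {
    restrictA <- commonResidues(structures, "alpha")
    restrictB <- commonResidues(structures, "beta")
  }
  rows <- list(); info <- list()
  for (si in seq_along(structures)) {
    m <- structures[[si]]
    sid <- if (nzchar(m@title)) m@title else paste0("structure", si)
    aCh <- names(m@roleMap)[m@roleMap == "alpha"]
    bCh <- names(m@roleMap)[m@roleMap == "beta"]
    if (length(aCh) != 3L || length(bCh) != 3L)
      stop(sid, ": need exactly 3 alpha and 3 beta chains, found ",
           length(aCh), " alpha / ", length(bCh), " beta")
    pairing <- pairChainsByAzimuth(m, aCh, bCh)
    for (k in 1:3) {
      ca <- selectAtoms(m, subsets$alpha, chain = pairing$alpha[k],
                        restrict = restrictA)
      cb <- selectAtoms(m, subsets$beta, chain = pairing$beta[k],
                        restrict = restrictB)
      v <- as.vector(t(rbind(ca$coords, cb$coords))) / 10   # Angstrom -> nm
      rows[[length(rows) + 1L]] <- v
      role <- if (!is.null(roles)) roles[[si]][k] else NA_character_
      inh <- if (!is.null(inhibitorBound)) {
        if (is.list(inhibitorBound)) inhibitorBound[[si]][k]
        else inhibitorBound[si]
      } else FALSE
      info[[length(info) + 1L]] <- data.frame(
        sourceId = sid, pairRole = role, inhibitorBound = inh,
        stringsAsFactors = FALSE)
    }
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("pairs have inconsistent vector lengths; use intersect = TRUE")
  new("PairSet", coords = do.call(rbind, rows), info = do.call(rbind, info))
}

## order alpha/beta chains around the stator axis and pair them:
## beta_k with the alpha adjacent in the clockwise direction
pairChainsByAzimuth <- function(m, aCh, bCh) {
  a <- m@atoms[m@atoms$elety == "CA" & !m@atoms$het, , drop = FALSE]
  cen <- function(ch) colMeans(as.matrix(
    a[a$chain %in% ch, c("x", "y", "z"), drop = FALSE]))
  origin <- cen(c(aCh, bCh))
  bc <- t(vapply(bCh, cen, numeric(3))) ; ac <- t(vapply(aCh, cen, numeric(3)))
  ## plane normal from the three beta centroids
  n <- c(crossProd3(bc[2, ] - bc[1, ], bc[3, ] - bc[1, ]))
  n <- n / sqrt(sum(n^2))
  ex <- bc[1, ] - origin; ex <- ex - sum(ex * n) * n; ex <- ex / sqrt(sum(ex^2))
  ey <- crossProd3(n, ex)
  az <- function(p) atan2(sum((p - origin) * ey), sum((p - origin) * ex))
  aAz <- apply(ac, 1, az); bAz <- apply(bc, 1, az)
  aOrd <- order(aAz); bOrd <- order(bAz)
  ## pair each beta with the alpha whose azimuth is nearest going clockwise
  pa <- character(3)
  for (k in 1:3) {
    d <- wrapRad(aAz - bAz[bOrd[k]])
    cand <- which(d <= 1e-9)
    pa[k] <- if (length(cand)) aCh[cand[which.max(d[cand])]]
             else aCh[which.min(d)]
  }
  list(alpha = pa, beta = bCh[bOrd])
}

crossProd3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Superpose pairs onto their iterative mean
#'
#' Rigid least-squares superposition (rotation + translation, proper
#' rotations only).  By default all pairs are aligned to the first pair, the
#' mean is computed, all pairs are re-aligned to the mean, and the mean is
#' recomputed until it shifts by less than `tol` nm RMS (at most `maxIter`
#' rounds).  `reference = "first"` performs a single alignment to a fixed
#' reference pair instead.
#'
#' @param pairs a [PairSet-class].
#' @param reference `"mean"` (iterate to the mean) or `"first"`.
#' @param tol convergence tolerance on the mean shift, nm RMS.
#' @param maxIter maximum number of re-alignment rounds.
#' @return list with `pairs` (aligned [PairSet-class]), `mean` (3N vector),
#'   `iterations`, `converged`.
#' @export
superposePairs <- function(pairs, reference = c("mean", "first"),
                           tol = 1e-6, maxIter = 20L) {
  reference <- match.arg(reference)
  X <- pairCoords(pairs)
  if (nrow(X) < 2L) stop("need at least 2 pairs to superpose")
  asMat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  flat <- function(m) as.vector(t(m))
  alignTo <- function(X, refVec) {
    Q <- asMat(refVec)
    t(apply(X, 1, function(v) {
      P <- asMat(v)
      if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
        stop("degenerate (collinear) coordinates: superposition undefined")
      flat(rigidSuperpose(P, Q)$coords)
    }))
  }
  ref <- X[1, ]
  X <- alignTo(X, ref)
  mu <- colMeans(X)
  iterations <- 0L; converged <- (reference == "first")
  if (reference == "mean") {
    for (it in seq_len(maxIter)) {
      iterations <- it
      X <- alignTo(X, mu)
      mu2 <- colMeans(X)
      shift <- sqrt(mean((mu2 - mu)^2) * 3)   # RMS over atoms
      mu <- mu2
      if (shift < tol) { converged <- TRUE; break }
    }
  }
  out <- pairs; out@coords <- X
  list(pairs = out, mean = mu, iterations = iterations,
       converged = converged)
}

#' Fit the covariance PCA of aligned pairs
#'
#' Covariance of the flattened Calpha coordinates over M pairs with 1/M
#' normalisation, diagonalised; modes sorted by descending eigenvalue;
#' explained fraction of mode k is lambda_k / sum(lambda).  Eigenvector
#' signs follow the convention that the largest-magnitude component is
#' positive, making plots reproducible across eigensolvers.
#'
#' @param aligned result of [superposePairs()], or a [PairSet-class] already
#'   aligned (its column means are then used as the centre).
#' @param modes number of modes to retain (default: all).
#' @return A [PCAModel-class] (units nm / nm^2).
#' @export
fitPCA <- function(aligned, modes = NULL) {
  if (is(aligned, "PairSet")) {
    X <- pairCoords(aligned); mu <- colMeans(X)
  } else {
    X <- pairCoords(aligned$pairs); mu <- aligned$mean
  }
  M <- nrow(X)
  if (M < 2L) stop("need at least 2 pairs to fit a PCA")
  D <- sweep(X, 2, mu)
  cv <- crossprod(D) / M
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (is.null(modes)) modes <- length(lam)
  modes <- min(modes, length(lam))
  V <- e$vectors[, seq_len(modes), drop = FALSE]
  for (k in seq_len(ncol(V))) {           # sign convention
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  new("PCAModel", center = mu, evecs = V,
      evals = lam[seq_len(modes)],
      explained = lam / sum(lam))
}

#' Project pairs onto PCA modes
#'
#' pc_k = (coords - mean) . eigenvector_k, in nm.
#'
#' @param pairs a [PairSet-class], or a numeric matrix/vector of flattened
#'   coordinates (nm).
#' @param model a [PCAModel-class].
#' @param modes how many leading modes to report (default 2).
#' @return data.frame with `pc1`, `pc2`, ... plus the pair annotations when
#'   available.
#' @export
projectPairs <- function(pairs, model, modes = 2L) {
  X <- if (is(pairs, "PairSet")) pairCoords(pairs)
       else if (is.matrix(pairs)) pairs
       else matrix(pairs, nrow = 1L)
  if (ncol(X) != length(model@center))
    stop("coordinate length ", ncol(X), " does not match model dimension ",
         length(model@center))
  modes <- min(modes, ncol(model@evecs))
  S <- sweep(X, 2, model@center) %*% model@evecs[, seq_len(modes), drop = FALSE]
  out <- as.data.frame(S)
  names(out) <- paste0("pc", seq_len(modes))
  if (is(pairs, "PairSet")) out <- cbind(out, pairInfo(pairs))
  out
}

#' Conformational progress along PC2
#'
#' The fraction of the PC2 displacement from a start value to a target
#' value, reported in percent and deliberately unclipped (values outside
#' 0-100 indicate overshoot).
#'
#' @param pc2 numeric series of PC2 values (nm).
#' @param start PC2 at the initial state (nm); defaults to `pc2[1]`.
#' @param target PC2 at the target state (nm).
#' @return numeric series, percent.
#' @export
conformationalProgress <- function(pc2, start = pc2[1], target) {
  if (!is.finite(start) || !is.finite(target) ||
      abs(target - start) < .Machine$double.eps)
    stop("start and target PC2 must differ")
  100 * (pc2 - start) / (target - start)
}
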