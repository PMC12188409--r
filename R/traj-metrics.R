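## Per-frame structural metrics: helix formation, contacts relative to an
## equilibrium baseline, long-helix bending angle, chi1 rotamer states and
## minimum inter-residue distances.

#' Named residue segments of the inhibitor chain
#'
#' Short helix 14-18; long helix 21-45 with sub-segments 21-30, 31-37,
#' 38-45; bending-angle triplet of Calpha 21, 38, 45.
#'
#' @return list of range matrices plus `bendTriplet`.
#' @export
inhibitorSegments <- function() {
  list(shortHelix = parseRanges("14-18"),
       longHelix = parseRanges("21-45"),
       longSub1 = parseRanges("21-30"),
       longSub2 = parseRanges("31-37"),
       longSub3 = parseRanges("38-45"),
       bendTriplet = c(21L, 38L, 45L))
}

#' Backbone dihedrals of a chain
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues lack phi (first) and psi (last); those entries are NA.
#'
#' @param model a [StructureModel-class] with N, CA, C atoms.
#' @param chain chain id (default: the single chain present).
#' @return data.frame with `resno`, `phi`, `psi` (degrees, (-180, 180]).
#' @export
backboneDihedrals <- function(model, chain = NULL) {
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) != 1L)
      stop("multiple chains present; specify `chain`")
    chain <- ch
  }
  a <- a[a$chain == chain, , drop = FALSE]
  res <- sort(unique(a$resno))
  get <- function(r, name) {
    row <- a[a$resno == r & a$elety == name, c("x", "y", "z")]
    if (nrow(row) != 1L)
      stop("missing backbone atom ", name, " in residue ", r)
    as.numeric(row)
  }
  phi <- psi <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    r <- res[k]
    if (k > 1L && res[k - 1L] == r - 1L)
      phi[k] <- torsionDeg(get(r - 1L, "C"), get(r, "N"),
                           get(r, "CA"), get(r, "C"))
    if (k < length(res) && res[k + 1L] == r + 1L)
      psi[k] <- torsionDeg(get(r, "N"), get(r, "CA"),
                           get(r, "C"), get(r + 1L, "N"))
  }
  data.frame(resno = res, phi = phi, psi = psi)
}

#' Helical fraction of a residue interval
#'
#' A residue counts as helical when its backbone dihedrals fall in the
#' alpha-helical window phi in \[-100, -30\], psi in \[-67, -7\] degrees
#' (dihedral-window criterion; an H-bond-based assignment can be
#' substituted through `isHelical`).  Residues whose phi or psi is
#' undefined (chain termini) are judged on the dihedrals they do have.
#'
#' @param model a [StructureModel-class].
#' @param interval residue range (string, matrix, or integer vector).
#' @param chain chain id (default: single chain).
#' @param phiWindow,psiWindow helical windows, degrees.
#' @param isHelical optional function(phi, psi) -> logical replacing the
#'   window criterion.
#' @return fraction in \[0, 1\].
#' @export
helicity <- function(model, interval, chain = NULL,
                     phiWindow = c(-100, -30), psiWindow = c(-67, -7),
                     isHelical = NULL) {
  want <- if (is.numeric(interval) && is.null(dim(interval))) as.integer(interval)
          else expandRanges(parseRanges(interval))
  if (length(want) < 2L) stop("interval must span at least 2 residues")
  tor <- backboneDihedrals(model, chain)
  tor <- tor[tor$resno %in% want, , drop = FALSE]
  if (nrow(tor) != length(want))
    stop("missing residues in interval: ",
         paste(setdiff(want, tor$resno), collapse = ", "))
  if (is.null(isHelical)) {
    isHelical <- function(phi, psi) {
      okPhi <- is.na(phi) | (phi >= phiWindow[1] & phi <= phiWindow[2])
      okPsi <- is.na(psi) | (psi >= psiWindow[1] & psi <= psiWindow[2])
      ok <- okPhi & okPsi
      ok[is.na(phi) & is.na(psi)] <- FALSE
      ok
    }
  }
  mean(isHelical(tor$phi, tor$psi))
}

## heavy atoms of one residue
residueHeavy <- function(model, chain, resno) {
  a <- model@atoms
  rows <- a[a$chain == chain & a$resno == resno &
              toupper(a$element) != "H", , drop = FALSE]
  if (!nrow(rows))
    stop("residue ", chain, "/", resno, " absent or has no heavy atoms")
  as.matrix(rows[, c("x", "y", "z")])
}

#' Residue-residue contacts between two selections
#'
#' A residue pair is in contact when any heavy-atom distance is at or below
#' `cutoff` (default 4.5 Angstrom).
#'
#' @param model a [StructureModel-class].
#' @param selA,selB [Selection-class] objects (must not overlap).
#' @param cutoff Angstrom.
#' @return list with `count` and `pairs` (data.frame chainA, resA, chainB,
#'   resB, minDist).
#' @export
contactCount <- function(model, selA, selB, cutoff = 4.5) {
  ga <- selectAtoms(model, selA)
  gb <- selectAtoms(model, selB)
  if (!nrow(ga$coords) || !nrow(gb$coords)) stop("empty selection")
  keyA <- paste(ga$labels$chain, ga$labels$resno)
  keyB <- paste(gb$labels$chain, gb$labels$resno)
  if (length(intersect(unique(keyA), unique(keyB))))
    stop("selections overlap: groups must be disjoint")
  heavyA <- toupper(ga$labels$elety) != "H" &
    substr(ga$labels$elety, 1, 1) != "H"
  heavyB <- toupper(gb$labels$elety) != "H" &
    substr(gb$labels$elety, 1, 1) != "H"
  A <- ga$coords[heavyA, , drop = FALSE]; kA <- keyA[heavyA]
  B <- gb$coords[heavyB, , drop = FALSE]; kB <- keyB[heavyB]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  pairs <- list()
  for (ra in unique(kA)) for (rb in unique(kB)) {
    md <- min(d[kA == ra, kB == rb])
    if (md <= cutoff) {
      ca <- strsplit(ra, " ")[[1]]; cb <- strsplit(rb, " ")[[1]]
      pairs[[length(pairs) + 1L]] <- data.frame(
        chainA = ca[1], resA = as.integer(ca[2]),
        chainB = cb[1], resB = as.integer(cb[2]), minDist = md,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chainA = character(0), resA = integer(0),
               chainB = character(0), resB = integer(0),
               minDist = numeric(0))
  list(count = nrow(pairs), pairs = pairs)
}

#' Contacts relative to an equilibrium baseline
#'
#' 100 * count / baseline.  With `blockLength` set, the series is averaged
#' over consecutive non-overlapping time blocks first (one value per
#' block, reported at the block end).
#'
#' @param counts numeric contact-count series.
#' @param baseline equilibrium contact count (> 0).
#' @param times frame times (ns), required for block averaging.
#' @param blockLength block length, ns.
#' @return percent series, or data.frame(time_ns, percent) for block
#'   averaging.
#' @export
relativeContacts <- function(counts, baseline, times = NULL,
                             blockLength = NULL) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline contact count must be positive")
  pct <- 100 * counts / baseline
  if (is.null(blockLength)) return(pct)
  if (is.null(times) || length(times) != length(counts))
    stop("block averaging needs one time per count")
  block <- ceiling((times - min(times) + 1e-12) / blockLength)
  block[block < 1] <- 1
  agg <- tapply(pct, block, mean)
  data.frame(time_ns = min(times) + as.numeric(names(agg)) * blockLength,
             percent = as.numeric(agg))
}

#' Bending angle of a residue triplet
#'
#' Interior angle (degrees) at the middle Calpha of the triplet; collinear
#' points give 180.
#'
#' @param model a [StructureModel-class].
#' @param triplet three residue numbers (default: the long-helix triplet
#'   21, 38, 45).
#' @param chain chain id (default: single chain).
#' @return angle in degrees, \[0, 180\].
#' @export
bendingAngle <- function(model, triplet = inhibitorSegments()$bendTriplet,
                         chain = NULL) {
  stopifnot(length(triplet) == 3L)
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) != 1L) stop("multiple chains present; specify `chain`")
    chain <- ch
  }
  ca <- lapply(triplet, function(r) {
    row <- a[a$chain == chain & a$resno == r & a$elety == "CA",
             c("x", "y", "z")]
    if (nrow(row) != 1L) stop("missing CA of residue ", r)
    as.numeric(row)
  })
  interiorAngleDeg(ca[[1]], ca[[2]], ca[[3]])
}

## gamma-branch atom used for chi1, by residue type
chi1GammaAtom <- function(resname) {
  switch(toupper(resname),
         SER = "OG", THR = "OG1", CYS = "SG", SEC = "SE",
         VAL = "CG1", ILE = "CG1",
         ALA = , GLY = NA_character_,
         "CG")
}

#' chi1 side-chain dihedral of a residue
#'
#' Standard N-CA-CB-Xgamma torsion, reported in \[0, 360) degrees (so the
#' two common rotamer states discussed in this package sit near 200 and
#' 300 degrees).
#'
#' @param model a [StructureModel-class].
#' @param chain chain id.
#' @param resno residue number.
#' @return angle in degrees, \[0, 360).
#' @export
chi1Dihedral <- function(model, chain, resno) {
  a <- model@atoms
  rows <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  if (!nrow(rows)) stop("residue ", chain, "/", resno, " not found")
  gatom <- chi1GammaAtom(rows$resname[1])
  if (is.na(gatom))
    stop("residue ", rows$resname[1], " has no gamma atom: chi1 undefined")
  pick <- function(name) {
    row <- rows[rows$elety == name, c("x", "y", "z")]
    if (nrow(row) != 1L)
      stop("missing side-chain atom ", name, " in residue ",
           chain, "/", resno)
    as.numeric(row)
  }
  ang <- torsionDeg(pick("N"), pick("CA"), pick("CB"), pick(gatom))
  (ang + 360) %% 360
}

#' Two-state chi1 rotamer assignment
#'
#' Assigns each angle to `state200` when within `halfWidth` of 200 degrees,
#' `state300` within `halfWidth` of 300 degrees, else `unassigned`.  The
#' partition is exhaustive and mutually exclusive for the default windows.
#'
#' @param chi1 numeric chi1 series, degrees in \[0, 360).
#' @param centers the two state centres, degrees.
#' @param halfWidth window half-width, degrees (default 40; must not make
#'   the windows overlap).
#' @return factor with levels state200, state300, unassigned.
#' @export
chi1State <- function(chi1, centers = c(200, 300), halfWidth = 40) {
  if (abs(wrapDeg(centers[2] - centers[1])) / 2 < halfWidth)
    warning("chi1 windows overlap; ties go to the first centre")
  d1 <- abs(wrapDeg(chi1 - centers[1]))
  d2 <- abs(wrapDeg(chi1 - centers[2]))
  out <- rep("unassigned", length(chi1))
  out[d2 <= halfWidth] <- "state300"
  out[d1 <= halfWidth] <- "state200"
  factor(out, levels = c("state200", "state300", "unassigned"))
}

#' Minimum heavy-atom distance between two residues
#'
#' @param model a [StructureModel-class].
#' @param chainA,resA,chainB,resB the two residues (must differ).
#' @return minimum distance, Angstrom.
#' @export
minResidueDistance <- function(model, chainA, resA, chainB, resB) {
  if (chainA == chainB && resA == resB)
    stop("the two residues must differ")
  A <- residueHeavy(model, chainA, resA)
  B <- residueHeavy(model, chainB, resB)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Apply a per-frame metric over a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param fun function(model, ...) returning one number per frame.
#' @param ... passed to `fun`.
#' @param name metric name for the output.
#' @return data.frame(frame, time_ns, metric, value).
#' @export
trajMetric <- function(traj, fun, ..., name = deparse(substitute(fun))) {
  vals <- vapply(seq_len(nFrames(traj)),
                 function(i) as.numeric(fun(getFrame(traj, i), ...)),
                 numeric(1))
  data.frame(frame = seq_len(nFrames(traj)), time_ns = frameTimes(traj),
             metric = name, value = vals, stringsAsFactors = FALSE)
}
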