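#' @import methods
NULL

#' StructureModel: labelled atomic coordinates
#'
#' A single structural model: one row per atom with chain identifier, author
#' residue numbering, residue and atom names, element, Cartesian coordinates
#' in Angstrom, and a heteroatom flag.  A role map associates chain
#' identifiers with the functional roles used throughout the package
#' (`alpha`, `beta`, `gamma`, `inhibitor`, `other`).
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `elety`,
#'   `element`, `x`, `y`, `z`, `het`.
#' @slot title character(1), free text.
#' @slot modelIndex integer(1), index of the model in its source file.
#' @slot roleMap named character vector mapping chain id to role.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", title = "character",
                 modelIndex = "integer", roleMap = "character"),
  prototype(title = "", modelIndex = 1L, roleMap = character(0)))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "elety", "element", "x", "y", "z", "het")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    key <- paste(a$chain, a$resno, a$elety)
    if (anyDuplicated(key))
      return(paste("duplicated (chain, resno, atom) triple:",
                   key[anyDuplicated(key)]))
    if (!all(is.finite(c(a$x, a$y, a$z))))
      return("non-finite coordinates")
  }
  TRUE
})

#' Selection: a chain-role/residue-range/atom-filter triple
#'
#' @slot chainRole one of `alpha`, `beta`, `gamma`, `inhibitor`.
#' @slot ranges 2-column integer matrix of inclusive residue intervals,
#'   sorted and non-overlapping.
#' @slot atomFilter one of `"CA"`, `"heavy"`, `"all"`.
#' @export
setClass("Selection",
  representation(chainRole = "character", ranges = "matrix",
                 atomFilter = "character"))

setValidity("Selection", function(object) {
  if (!object@chainRole %in% c("alpha", "beta", "gamma", "inhibitor"))
    return("chainRole must be alpha, beta, gamma or inhibitor")
  if (!object@atomFilter %in% c("CA", "heavy", "all"))
    return("atomFilter must be CA, heavy or all")
  r <- object@ranges
  if (ncol(r) != 2L) return("ranges must be a 2-column matrix")
  if (any(r[, 2] < r[, 1])) return("range end precedes start")
  if (nrow(r) > 1L) {
    if (is.unsorted(r[, 1], strictly = TRUE)) return("ranges must be sorted")
    if (any(r[-1, 1] <= r[-nrow(r), 2])) return("ranges overlap")
  }
  TRUE
})

#' Trajectory: an ordered set of frames over one topology
#'
#' Frames share one atom table (the topology); coordinates are stored as a
#' frames x (3 * natoms) matrix in bio3d xyz layout.  Per-frame times are in
#' ns and strictly increasing; arbitrary per-frame metadata (target angle,
#' work, ...) ride along as a data.frame.
#'
#' @slot topology a [StructureModel] giving labels for every atom.
#' @slot xyz numeric matrix, one row per frame, columns x1,y1,z1,x2,...
#' @slot times numeric vector, ns.
#' @slot metadata data.frame with one row per frame.
#' @export
setClass("Trajectory",
  representation(topology = "StructureModel", xyz = "matrix",
                 times = "numeric", metadata = "data.frame"))

setValidity("Trajectory", function(object) {
  n <- nrow(object@xyz)
  if (ncol(object@xyz) != 3L * nrow(object@topology@atoms))
    return("xyz width must be 3 * natoms")
  if (length(object@times) != n) return("times length must match frame count")
  if (n > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (nrow(object@metadata) && nrow(object@metadata) != n)
    return("metadata rows must match frame count")
  TRUE
})

#' PairSet: flattened Calpha coordinate vectors for alpha/beta pairs
#'
#' Each row is one alpha-beta pair as a 3N vector (nm) over the fixed
#' residue subsets; `info` carries `sourceId`, `pairRole` and
#' `inhibitorBound` per pair.
#'
#' @slot coords numeric matrix, pairs x 3N, nm.
#' @slot info data.frame with columns `sourceId`, `pairRole`,
#'   `inhibitorBound`.
#' @export
setClass("PairSet",
  representation(coords = "matrix", info = "data.frame"))

setValidity("PairSet", function(object) {
  if (nrow(object@coords) != nrow(object@info))
    return("info rows must match coordinate rows")
  if (!all(c("sourceId", "pairRole", "inhibitorBound") %in% names(object@info)))
    return("info needs sourceId, pairRole, inhibitorBound")
  if (ncol(object@coords) %% 3L != 0L)
    return("coordinate width must be a multiple of 3")
  TRUE
})

#' PCAModel: mean, modes and explained variance of a pair landscape
#'
#' @slot center numeric 3N mean vector (nm).
#' @slot evecs orthonormal eigenvector matrix, one column per mode.
#' @slot evals eigenvalues (nm^2), descending, non-negative.
#' @slot explained per-mode fraction of total variance.
#' @export
setClass("PCAModel",
  representation(center = "numeric", evecs = "matrix", evals = "numeric",
                 explained = "numeric"))

setValidity("PCAModel", function(object) {
  if (ncol(object@evecs) != length(object@evals))
    return("one eigenvalue per eigenvector")
  if (length(object@evals)) {
    if (any(object@evals < -1e-10)) return("negative eigenvalue")
    if (is.unsorted(rev(object@evals))) return("eigenvalues must be descending")
    G <- crossprod(object@evecs)
    if (max(abs(G - diag(ncol(G)))) > 1e-8)
      return("eigenvectors not orthonormal to 1e-8")
    if (abs(sum(object@explained) - 1) > 1e-8)
      return("explained fractions must sum to 1")
  }
  TRUE
})

#' RotaryFrame: stator-fixed orthonormal frame
#'
#' @slot origin Angstrom triplet.
#' @slot axes 3x3 matrix with columns x, y, z; right-handed orthonormal.
#' @export
setClass("RotaryFrame",
  representation(origin = "numeric", axes = "matrix"))

setValidity("RotaryFrame", function(object) {
  A <- object@axes
  if (!all(dim(A) == c(3L, 3L))) return("axes must be 3x3")
  if (max(abs(crossprod(A) - diag(3))) > 1e-10)
    return("axes not orthonormal to 1e-10")
  handed <- crossprod(A[, 3],
                      c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
                        A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
                        A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2]))
  if (handed < 0) return("axes must be right-handed (x cross y = z)")
  TRUE
})

#' RotorCV: mean-rotation-angle collective variable
#'
#' In-plane reference positions of the biased atom group (about the z axis)
#' and non-negative per-atom weights summing to one.
#'
#' @slot refXY n x 2 matrix of in-plane reference coordinates (Angstrom).
#' @slot weights numeric weights, sum 1.
#' @export
setClass("RotorCV",
  representation(refXY = "matrix", weights = "numeric"))

setValidity("RotorCV", function(object) {
  if (nrow(object@refXY) != length(object@weights))
    return("one weight per atom")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-12)
    return("weights must sum to 1 within 1e-12")
  if (all(sqrt(rowSums(object@refXY^2)) < 1e-9))
    return("all reference atoms lie on the rotation axis")
  TRUE
})

#' RotorBias: moving harmonic restraint on the mean rotation angle
#'
#' V(theta, t) = kappa/2 * (theta - theta0(t))^2 with
#' theta0(t) = theta0Init + s * omega * t, where s = +1 for the
#' counterclockwise (hydrolysis) direction and -1 for clockwise (synthesis).
#'
#' @slot kappa kcal mol^-1 rad^-2, > 0.
#' @slot omegaDegNs target angular speed magnitude, degrees/ns.
#' @slot theta0Init initial target angle, radians.
#' @slot direction `"CCW"` (hydrolysis, positive) or `"CW"` (synthesis).
#' @export
setClass("RotorBias",
  representation(kappa = "numeric", omegaDegNs = "numeric",
                 theta0Init = "numeric", direction = "character"))

setValidity("RotorBias", function(object) {
  if (object@kappa <= 0) return("kappa must be positive")
  if (!object@direction %in% c("CCW", "CW"))
    return("direction must be CCW or CW")
  TRUE
})

#' WorkLedger: time, angle, target, work and torque series
#'
#' @slot time ns.
#' @slot theta unwrapped CV value, radians.
#' @slot theta0 target angle, radians.
#' @slot work cumulative external work, kcal/mol; starts at 0.
#' @slot torque instantaneous restraint torque kappa*(theta0-theta),
#'   kcal mol^-1 rad^-1.
#' @export
setClass("WorkLedger",
  representation(time = "numeric", theta = "numeric", theta0 = "numeric",
                 work = "numeric", torque = "numeric"))

setValidity("WorkLedger", function(object) {
  n <- length(object@time)
  if (any(lengths(list(object@theta, object@theta0, object@work,
                       object@torque)) != n))
    return("all series must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (n && abs(object@work[1]) > 1e-12) return("work must start at 0")
  TRUE
})

#' ToyMotor: coarse-grained three-fold rotary motor state
#'
#' Three stator units each carry a gate coordinate (open ~ 0, closed ~ 1)
#' and an interface coordinate (loose ~ 0, tight ~ 1); the rotor has a core
#' ring (single angle) and a protruded ring of individually mobile beads
#' whose mean angle is the biased collective variable; an optional inhibitor
#' chain contacts the rotor core (short segment) and stator unit 1 (long
#' segment).
#'
#' @slot params full parameter list (geometry, springs, temperature,
#'   friction); see [toyMotorParams()].
#' @slot state list with elements `g`, `h` (length-3 gate/interface
#'   coordinates), `thetaCore` (rad), `alpha` (protruded bead angles, rad),
#'   `inh` (n x 3 inhibitor coordinates, Angstrom).
#' @export
setClass("ToyMotor",
  representation(params = "list", state = "list"))

setValidity("ToyMotor", function(object) {
  st <- object@state
  if (!all(c("g", "h", "thetaCore", "alpha", "inh") %in% names(st)))
    return("state needs g, h, thetaCore, alpha, inh")
  if (length(st$g) != 3L || length(st$h) != 3L)
    return("three stator units expected")
  if (!all(is.finite(unlist(st[c("g", "h", "thetaCore", "alpha")]))) ||
      (length(st$inh) && !all(is.finite(st$inh))))
    return("non-finite state")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms,",
      length(unique(a$chain)), "chains")
  if (nzchar(object@title)) cat(" |", object@title)
  cat("\n")
  if (length(object@roleMap)) {
    cat("  roles:", paste(names(object@roleMap), object@roleMap,
                          sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@xyz), "frames x",
      nrow(object@topology@atoms), "atoms, t =",
      if (length(object@times)) paste0(min(object@times), "..",
                                       max(object@times), " ns") else "-",
      "\n")
})

setMethod("show", "PairSet", function(object) {
  cat("PairSet:", nrow(object@coords), "pairs x",
      ncol(object@coords) / 3, "Calpha atoms (nm)\n")
})

setMethod("show", "PCAModel", function(object) {
  k <- min(2L, length(object@evals))
  cat("PCAModel: ", length(object@center), " dims, ",
      length(object@evals), " modes; top-", k, " explained = ",
      paste(sprintf("%.3f", object@explained[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "WorkLedger", function(object) {
  n <- length(object@time)
  cat("WorkLedger:", n, "samples")
  if (n) cat(sprintf(", t = %.3g..%.3g ns, W = %.4g kcal/mol",
                     object@time[1], object@time[n], object@work[n]))
  cat("\n")
})

setMethod("show", "ToyMotor", function(object) {
  p <- object@params
  cat("ToyMotor: 3 stator units,", p$nProt, "protruded +",
      p$nCoreN + p$nCoreC, "core rotor beads,",
      p$nInh, "inhibitor beads\n")
})
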