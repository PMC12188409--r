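## Constructors and accessor generics.  Slot access from user code should go
## through these, Bioconductor-style.

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `elety`, `element`, `x`, `y`, `z` and optionally `het`.
#' @param title free-text title.
#' @param modelIndex integer model index.
#' @param roleMap named character vector chain id -> role, or NULL to
#'   auto-detect with [chainRoleMap()].
#' @return A [StructureModel-class] object.
#' @export
StructureModel <- function(atoms, title = "", modelIndex = 1L,
                           roleMap = NULL) {
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$element))
    atoms$element <- substr(trimws(atoms$elety), 1L, 1L)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL
  m <- new("StructureModel", atoms = atoms, title = title,
           modelIndex = as.integer(modelIndex),
           roleMap = if (is.null(roleMap)) character(0) else roleMap)
  if (is.null(roleMap)) m@roleMap <- chainRoleMap(m)
  m
}

#' Construct a Selection
#'
#' @param chainRole one of `"alpha"`, `"beta"`, `"gamma"`, `"inhibitor"`.
#' @param ranges range string like `"1-26,228-272"` or a 2-column matrix of
#'   inclusive intervals.
#' @param atomFilter `"CA"`, `"heavy"` or `"all"`.
#' @return A [Selection-class] object.
#' @export
Selection <- function(chainRole, ranges, atomFilter = "CA") {
  new("Selection", chainRole = chainRole, ranges = parseRanges(ranges),
      atomFilter = atomFilter)
}

#' @rdname atomData
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Atom table of a structure or trajectory topology
#'
#' @param x a [StructureModel-class] or [Trajectory-class].
#' @return data.frame of atom records.
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' @rdname coords
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Cartesian coordinates (Angstrom)
#'
#' @param x a [StructureModel-class] or [Trajectory-class].
#' @param frame for trajectories, the frame index.
#' @param ... unused.
#' @return n x 3 numeric matrix.
#' @export
setMethod("coords", "StructureModel", function(x, ...) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = 1L, ...) {
  matrix(x@xyz[frame, ], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of frames in a trajectory
#' @param x a [Trajectory-class].
#' @return integer(1).
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' @rdname frameTimes
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Frame times in ns
#' @param x a [Trajectory-class].
#' @return numeric vector.
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameMetadata
#' @export
setGeneric("frameMetadata", function(x) standardGeneric("frameMetadata"))

#' Per-frame metadata
#' @param x a [Trajectory-class].
#' @return data.frame, one row per frame.
#' @export
setMethod("frameMetadata", "Trajectory", function(x) x@metadata)

#' Extract one frame of a trajectory as a StructureModel
#'
#' @param traj a [Trajectory-class].
#' @param i frame index.
#' @return A [StructureModel-class].
#' @export
getFrame <- function(traj, i) {
  stopifnot(i >= 1L, i <= nFrames(traj))
  m <- traj@topology
  xyz <- coords(traj, frame = i)
  m@atoms$x <- xyz[, 1]; m@atoms$y <- xyz[, 2]; m@atoms$z <- xyz[, 3]
  m@modelIndex <- as.integer(i)
  m
}

#' Chain role map of a structure
#' @param x a [StructureModel-class].
#' @return named character vector chain id -> role.
#' @export
roleMap <- function(x) x@roleMap

#' Replace the chain role map
#' @param x a [StructureModel-class].
#' @param value named character vector chain id -> role.
#' @return the modified object.
#' @export
`roleMap<-` <- function(x, value) { x@roleMap <- value; validObject(x); x }

#' @rdname pairInfo
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' Pair annotation table of a PairSet
#' @param x a [PairSet-class].
#' @return data.frame with sourceId, pairRole, inhibitorBound.
#' @export
setMethod("pairInfo", "PairSet", function(x) x@info)

#' @rdname pairCoords
#' @export
setGeneric("pairCoords", function(x) standardGeneric("pairCoords"))

#' Flattened pair coordinate matrix (nm)
#' @param x a [PairSet-class].
#' @return pairs x 3N numeric matrix.
#' @export
setMethod("pairCoords", "PairSet", function(x) x@coords)

#' Eigen decomposition pieces of a PCAModel
#' @param x a [PCAModel-class].
#' @return see individual accessors.
#' @export
pcaCenter <- function(x) x@center

#' @rdname pcaCenter
#' @export
pcaEigenvectors <- function(x) x@evecs

#' @rdname pcaCenter
#' @export
pcaEigenvalues <- function(x) x@evals

#' @rdname pcaCenter
#' @export
explainedFraction <- function(x) x@explained

#' Ledger series as a data.frame
#'
#' Columns: `time_ns`, `theta_deg`, `theta0_deg`, `work_kcal_mol`,
#' `torque_pN_nm_per_rad` (angles in degrees, torque converted with
#' 1 kcal/mol = 6.9477 pN nm).
#'
#' @param x a [WorkLedger-class].
#' @param ... unused.
#' @return data.frame.
#' @export
ledgerTable <- function(x, ...) {
  data.frame(time_ns = x@time,
             theta_deg = radToDeg(x@theta),
             theta0_deg = radToDeg(x@theta0),
             work_kcal_mol = x@work,
             torque_pN_nm_per_rad = x@torque * kcalMolInPNnm())
}

#' Motor parameters
#' @param x a [ToyMotor-class].
#' @return parameter list.
#' @export
motorParams <- function(x) x@params

#' Motor dynamical state
#' @param x a [ToyMotor-class].
#' @return list with g, h, thetaCore, alpha, inh.
#' @export
motorState <- function(x) x@state
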