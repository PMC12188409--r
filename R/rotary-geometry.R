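## Stator-frame construction and the gamma rotary-angle algorithm.
##
## The stator frame is built from the N-terminal domains of the three beta
## subunits: their Calpha centres of mass define the origin (centroid) and
## the z axis (plane normal, oriented so the protruding C-terminal half of
## gamma has positive z); the frame is then rotated about z so the beta_DP
## N-domain centre lies on +x.  The rotary angle of gamma relative to a
## reference structure is the in-plane angle of the best-fit rotation of
## its core residues, counterclockwise (hydrolysis) positive.

#' Default residue subsets for the rotary frame and angle
#'
#' Beta N-terminal domain: residues 10-82; gamma fit subset: residues 1-30
#' and 221-270 (the coiled-coil core).
#'
#' @return list with `betaN` and `gammaFit` range matrices.
#' @export
rotaryDefaults <- function() {
  list(betaN = parseRanges("10-82"), gammaFit = parseRanges("1-30,221-270"))
}

#' Build the stator-fixed rotary frame
#'
#' @param model a [StructureModel-class] with three `beta` chains and one
#'   `gamma` chain in its role map.
#' @param dpChain chain id of the beta_DP subunit (placed on +x).  Required:
#'   role assignment comes from user input or a prior landscape
#'   classification.
#' @param betaN residue range (string or matrix) of the beta N-terminal
#'   domain used for the centres of mass.
#' @param gammaFit gamma residue range used only to orient z (its second
#'   interval is taken as the C-terminal half).
#' @return list with `frame` (a [RotaryFrame-class]) and `model` (the input
#'   transformed into the frame).
#' @export
buildRotaryFrame <- function(model, dpChain,
                             betaN = rotaryDefaults()$betaN,
                             gammaFit = rotaryDefaults()$gammaFit) {
  betaN <- parseRanges(betaN)
  bCh <- names(model@roleMap)[model@roleMap == "beta"]
  gCh <- names(model@roleMap)[model@roleMap == "gamma"]
  if (length(bCh) != 3L) stop("need exactly 3 beta chains, found ", length(bCh))
  if (length(gCh) != 1L) stop("need exactly 1 gamma chain, found ", length(gCh))
  if (missing(dpChain) || !dpChain %in% bCh)
    stop("dpChain must name one of the beta chains (",
         paste(bCh, collapse = ", "), "); beta_DP assignment is an input")
  sel <- Selection("beta", betaN, "CA")
  com <- t(vapply(sort(bCh), function(ch)
    colMeans(selectAtoms(model, sel, chain = ch)$coords), numeric(3)))
  origin <- colMeans(com)
  n <- crossProd3(com[2, ] - com[1, ], com[3, ] - com[1, ])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("beta centres are collinear: no plane normal")
  n <- n / nn
  ## orient z toward the protruding C-terminal half of gamma
  gAll <- model@atoms[model@atoms$chain == gCh & model@atoms$elety == "CA" &
                        !model@atoms$het, , drop = FALSE]
  gRng <- parseRanges(gammaFit)
  cHalf <- gAll[gAll$resno >= gRng[nrow(gRng), 1], c("x", "y", "z")]
  if (!nrow(cHalf)) cHalf <- gAll[, c("x", "y", "z")]
  if (sum((colMeans(as.matrix(cHalf)) - origin) * n) < 0) n <- -n
  ## x axis: beta_DP centre projected into the plane
  v <- com[dpChain, ] - origin
  v <- v - sum(v * n) * n
  if (sqrt(sum(v^2)) < 1e-9) stop("beta_DP centre lies on the axis")
  ex <- v / sqrt(sum(v^2))
  ey <- crossProd3(n, ex)
  axes <- cbind(x = ex, y = ey, z = n)
  frame <- new("RotaryFrame", origin = origin, axes = axes)
  out <- model
  xyz <- sweep(coords(model), 2, origin) %*% axes
  out@atoms$x <- xyz[, 1]; out@atoms$y <- xyz[, 2]; out@atoms$z <- xyz[, 3]
  list(frame = frame, model = out)
}

#' Rotary angle of gamma relative to a reference structure
#'
#' Both structures are first placed in their stator frames (see
#' [buildRotaryFrame()]); the optimal proper rotation fitting the model's
#' gamma core onto the reference's is computed by least squares, and the
#' reported angle is the signed planar angle of the rotated x axis
#' projected on the xy plane, wrapped to (-180, 180], hydrolysis
#' (counterclockwise) positive.
#'
#' @param model,reference [StructureModel-class] objects, or the `$model`
#'   output of [buildRotaryFrame()] when `aligned = TRUE`.
#' @param dpChain,dpChainRef beta_DP chain ids for model and reference
#'   (reference defaults to the same id).
#' @param gammaFit gamma residue subset used for the fit.
#' @param aligned set TRUE when both inputs are already frame-aligned.
#' @param hydrolysisPositive flip the sign convention when FALSE.
#' @return angle in degrees, (-180, 180].
#' @export
gammaAngle <- function(model, reference, dpChain, dpChainRef = dpChain,
                       gammaFit = rotaryDefaults()$gammaFit,
                       aligned = FALSE, hydrolysisPositive = TRUE) {
  if (!aligned) {
    model <- buildRotaryFrame(model, dpChain, gammaFit = gammaFit)$model
    reference <- buildRotaryFrame(reference, dpChainRef,
                                  gammaFit = gammaFit)$model
  }
  selM <- Selection("gamma", gammaFit, "CA")
  P <- selectAtoms(reference, selM)$coords
  Q <- selectAtoms(model, selM)$coords
  if (nrow(P) != nrow(Q))
    stop("gamma subset mismatch: ", nrow(P), " vs ", nrow(Q), " atoms")
  R <- kabschRotation(P, Q)      # rotation carrying reference gamma to model
  ang <- radToDeg(atan2(R[2, 1], R[1, 1]))
  if (!hydrolysisPositive) ang <- -ang
  wrapDeg(ang)
}
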