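## Torque <-> proton-motive-force bookkeeping.
##
## An F1 motor working against a load at torque tau does 2*pi*tau of work
## per turn; driving the turn costs n protons, each carrying e * pmf of
## electrochemical energy.  Equating the two gives the pmf required to
## sustain a given torque.  Constants: elementary charge 1.602176634e-19 C
## (exact SI), 1 pN nm = 1e-21 J.  Rounding to integer mV is presentation
## only.

elementaryCharge <- 1.602176634e-19   # C, exact SI definition
pNnmInJoule <- 1e-21

#' Torque required to eject a bound inhibitor
#'
#' Scales a baseline motor torque by an excess-work fraction:
#' tau_eject = baseline * (1 + fraction).  With the standard F1 torque of
#' 40 pN nm/rad and a 20 percent excess this gives 48 pN nm/rad.
#'
#' @param baselineTorque baseline torque, pN nm/rad (> 0).
#' @param excessFraction fractional excess work (>= 0), e.g. 0.20.
#' @return torque in pN nm/rad.
#' @export
torqueForEjection <- function(baselineTorque, excessFraction) {
  stopifnot(baselineTorque > 0, excessFraction >= 0)
  baselineTorque * (1 + excessFraction)
}

#' Proton motive force required to sustain a torque
#'
#' pmf (mV) = 1000 * (tau * 1e-21 J * 2 pi / n) / e, for torque tau in
#' pN nm/rad and n protons per turn.
#'
#' @param torque pN nm/rad (>= 0).
#' @param protonsPerTurn protons translocated per full turn (>= 1).
#' @return pmf in mV (unrounded; round only at presentation).
#' @export
pmfRequired <- function(torque, protonsPerTurn) {
  stopifnot(torque >= 0)
  if (protonsPerTurn < 1) stop("protonsPerTurn must be at least 1")
  workPerTurn <- torque * pNnmInJoule * 2 * pi
  1000 * (workPerTurn / protonsPerTurn) / elementaryCharge
}

#' Torque sustainable at a given proton motive force
#'
#' Exact inverse of [pmfRequired()].
#'
#' @param pmf mV (>= 0).
#' @param protonsPerTurn protons per turn (>= 1).
#' @return torque in pN nm/rad.
#' @export
torqueFromPmf <- function(pmf, protonsPerTurn) {
  stopifnot(pmf >= 0)
  if (protonsPerTurn < 1) stop("protonsPerTurn must be at least 1")
  (pmf / 1000) * elementaryCharge * protonsPerTurn / (2 * pi) / pNnmInJoule
}

#' Full pmf bookkeeping for one torque value
#'
#' @param torque pN nm/rad.
#' @param protonsPerTurn protons per turn.
#' @return data.frame with torque, protons per turn, work per turn (pN nm),
#'   work per proton (pN nm) and pmf (mV).
#' @export
pmfTable <- function(torque, protonsPerTurn) {
  wTurn <- 2 * pi * torque
  data.frame(torque_pN_nm_rad = torque,
             protons_per_turn = protonsPerTurn,
             work_per_turn_pN_nm = wTurn,
             work_per_proton_pN_nm = wTurn / protonsPerTurn,
             pmf_mV = pmfRequired(torque, protonsPerTurn))
}
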