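#' Isolation-with-migration model parameters
#'
#' Holds the demographic parameters of the two-population IM model: an
#' ancestral population of diploid effective size \code{nAnc} splits
#' instantaneously \code{tDiv} generations before present into population A
#' (size \code{nA}) and population P (size \code{nP}), connected by constant
#' bi-directional gene flow. \code{mPA} is the forward per-generation
#' migration rate from P into A, i.e. the proportion of population A replaced
#' by P migrants each generation; \code{mAP} is the reverse. Backwards in
#' time this means a lineage sampled in A traces its ancestry into P at rate
#' \code{mPA} per generation (and vice versa). \code{mu} is the mutation
#' rate per site per generation.
#'
#' @slot nAnc,nA,nP diploid effective population sizes (individuals), >= 1.
#' @slot tDiv divergence time in generations before present (>= 0, may be
#'   \code{Inf} for an equilibrium two-deme model).
#' @slot mPA,mAP forward per-generation migration rates in [0, 0.5].
#' @slot mu mutation rate per site per generation (>= 0).
#' @export
setClass("IMParams",
  representation(nAnc = "numeric", nA = "numeric", nP = "numeric",
                 tDiv = "numeric", mPA = "numeric", mAP = "numeric",
                 mu = "numeric"))

setValidity("IMParams", function(object) {
  msg <- character()
  for (s in c("nAnc", "nA", "nP", "tDiv", "mPA", "mAP", "mu")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, sprintf("'%s' must be a single non-NA number", s))
  }
  if (length(msg)) return(msg)
  if (object@nAnc < 1 || object@nA < 1 || object@nP < 1)
    msg <- c(msg, "effective sizes must be >= 1")
  if (object@tDiv < 0) msg <- c(msg, "tDiv must be >= 0")
  if (object@mPA < 0 || object@mPA > 0.5 || object@mAP < 0 || object@mAP > 0.5)
    msg <- c(msg, "migration rates must lie in [0, 0.5]")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct IM model parameters
#'
#' @param nAnc,nA,nP diploid effective sizes of the ancestral population and
#'   of populations A and P.
#' @param tDiv divergence time in generations (\code{Inf} allowed).
#' @param mPA forward migration rate P -> A (proportion of A replaced per
#'   generation).
#' @param mAP forward migration rate A -> P.
#' @param mu mutation rate per site per generation.
#' @return An [IMParams-class] object.
#' @examples
#' IMParams(nAnc = 33000, nA = 2000, nP = 52000, tDiv = 33000,
#'          mPA = 0.048, mAP = 0.003)
#' @export
IMParams <- function(nAnc, nA, nP, tDiv, mPA = 0, mAP = 0, mu = 7.3e-9) {
  new("IMParams", nAnc = as.numeric(nAnc), nA = as.numeric(nA),
      nP = as.numeric(nP), tDiv = as.numeric(tDiv), mPA = as.numeric(mPA),
      mAP = as.numeric(mAP), mu = as.numeric(mu))
}

#' @export
setMethod("show", "IMParams", function(object) {
  cat("IMParams (two-population isolation-with-migration)\n")
  cat(sprintf("  N_anc = %g, N_A = %g, N_P = %g (diploid)\n",
              object@nAnc, object@nA, object@nP))
  cat(sprintf("  T_div = %g generations\n", object@tDiv))
  cat(sprintf("  m(P->A) = %g, m(A->P) = %g per generation (forward)\n",
              object@mPA, object@mAP))
  cat(sprintf("  mu = %g per site per generation\n", object@mu))
})

#' Simulation control settings for the coalescent engine
#'
#' Tuning knobs for the structured-coalescent simulator. The engine simulates
#' every coalescence and migration event exactly (Gillespie) unless migration
#' is so fast relative to coalescence that lineage locations can be treated as
#' stationary (the strong-migration limit), in which case it switches -- after
#' an exact burn-in that lets the location chain forget the sampling
#' configuration -- to location-averaged coalescence rates. The collapse is
#' entered only when \code{mPA + mAP > strongFactor / (2 min(nA, nP))}, or as
#' a guarded fallback after \code{maxExactEvents} exact events per genealogy.
#'
#' @param strongFactor dimensionless threshold on the ratio of the location
#'   relaxation rate to the fastest per-pair coalescence rate; larger values
#'   are more conservative. \code{Inf} forces fully exact simulation.
#' @param relaxTime exact burn-in before the collapse, in units of
#'   \code{1/(mPA + mAP)} (location-chain relaxation times).
#' @param maxExactEvents cap on exact events per genealogy before the
#'   collapse is forced (guards extreme parameter corners).
#' @return a named list understood by the simulation functions.
#' @export
simControl <- function(strongFactor = 30, relaxTime = 5, maxExactEvents = 2000) {
  stopifnot(strongFactor > 0, relaxTime > 0, maxExactEvents > 0)
  list(strong_factor = as.numeric(strongFactor),
       relax_time = as.numeric(relaxTime),
       max_exact_events = as.numeric(maxExactEvents))
}
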