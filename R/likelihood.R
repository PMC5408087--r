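#' Composite log-likelihood of an observed joint SFS
#'
#' Multinomial composite log-likelihood sum(w(i,j) * ln p(i,j)) over the
#' unmasked cells, treating SNPs as independent. Expected probabilities are
#' renormalized over the unmasked cells after replacing zero-probability
#' cells that carry observed weight by the floor \code{epsilon} (tie the
#' floor to the simulation budget used to estimate \code{probs}, e.g.
#' 1 / (10 * simulations)). Because of the renormalization the result never
#' exceeds [saturatedLogLik()] (Gibbs inequality).
#'
#' @param obs a [JointSFS-class] object of observed weights.
#' @param probs numeric matrix of expected cell probabilities, same shape.
#' @param epsilon floor for zero expected probabilities at observed cells.
#' @return the composite log-likelihood (<= 0 scale-free quantity).
#' @export
compositeLogLik <- function(obs, probs, epsilon = 1e-12) {
  stopifnot(is(obs, "JointSFS"))
  w <- obs@weights
  if (!identical(dim(w), dim(probs)))
    stop("probs must match the spectrum's shape")
  if (any(w < 0)) stop("negative observed weights")
  use <- !obs@masked
  p <- probs[use]
  ww <- w[use]
  p[p <= 0 & ww > 0] <- epsilon
  tot <- sum(p)
  if (tot <= 0) stop("expected probabilities sum to zero over unmasked cells")
  p <- p / tot
  sum(ww[ww > 0] * log(p[ww > 0]))
}

#' Saturated (observed) composite log-likelihood
#'
#' The maximum attainable composite log-likelihood, reached when the
#' expected probabilities equal the observed relative weights:
#' sum(w * ln(w / W)) over unmasked cells with w > 0.
#'
#' @param obs a [JointSFS-class] object.
#' @return the saturated log-likelihood.
#' @export
saturatedLogLik <- function(obs) {
  stopifnot(is(obs, "JointSFS"))
  w <- obs@weights[!obs@masked]
  W <- sum(w)
  if (W <= 0) stop("no unmasked observed weight")
  w <- w[w > 0]
  sum(w * log(w / W))
}
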