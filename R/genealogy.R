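#' A realized coalescent genealogy
#'
#' One realization of the IM structured coalescent for \code{n} sampled
#' lineages: \code{n - 1} binary merge events in strictly increasing time
#' order. Leaves are numbered \code{1..n}; the k-th merge creates internal
#' node \code{n + k}.
#'
#' @slot merges integer matrix (n-1) x 2 of the two child node ids of each
#'   merge, in time order.
#' @slot times numeric vector of merge times (generations before present).
#' @slot leafPop integer vector, 0 for lineages sampled in population A and
#'   1 for population P.
#' @slot totalLength total branch length in generations.
#' @export
setClass("Genealogy",
  representation(merges = "matrix", times = "numeric", leafPop = "integer",
                 totalLength = "numeric"))

setValidity("Genealogy", function(object) {
  n <- length(object@leafPop)
  if (nrow(object@merges) != n - 1L || length(object@times) != n - 1L)
    return("a genealogy of n lineages must contain exactly n - 1 merges")
  if (is.unsorted(object@times, strictly = FALSE))
    return("merge times must be non-decreasing")
  TRUE
})

#' Simulate one genealogy under the IM model
#'
#' Draws a genealogy for \code{nA} lineages sampled in population A and
#' \code{nP} in population P under the backward-in-time structured
#' coalescent: within a population of diploid size N each lineage pair
#' coalesces at rate 1/(2N) per generation; a lineage currently in A moves
#' (backwards) to P at rate \code{mPA} and a lineage in P moves to A at rate
#' \code{mAP}; at \code{tDiv} all lineages transfer to the ancestral
#' population of size \code{nAnc}.
#'
#' Uses the RNG state of the R session; call [set.seed()] for reproducibility.
#'
#' @param params an [IMParams-class] object.
#' @param nA,nP numbers of sampled lineages (haploid) per population.
#' @param control engine settings from [simControl()].
#' @return a [Genealogy-class] object.
#' @examples
#' set.seed(1)
#' g <- simulateGenealogy(IMParams(1e4, 1e4, 1e4, tDiv = 0), nA = 4, nP = 4)
#' coalescenceTimes(g)
#' @export
simulateGenealogy <- function(params, nA, nP, control = simControl()) {
  stopifnot(is(params, "IMParams"))
  validObject(params)
  nA <- as.integer(nA); nP <- as.integer(nP)
  if (nA < 0 || nP < 0 || nA + nP < 2L)
    stop("need at least two sampled lineages in total")
  res <- .sim_genealogy_cpp(params@nAnc, params@nA, params@nP, params@tDiv,
                            params@mPA, params@mAP, nA, nP, control)
  new("Genealogy", merges = res$merges, times = as.numeric(res$times),
      leafPop = as.integer(res$leaf_pop), totalLength = res$total_length)
}

#' Batch of coalescence-time vectors
#'
#' Simulates \code{reps} independent genealogies and returns the matrix of
#' their ordered coalescence times (one row per replicate), without building
#' genealogy objects; intended for Monte-Carlo calibration such as checking
#' E[T2] = 2N for a panmictic pair.
#'
#' @inheritParams simulateGenealogy
#' @param reps number of replicate genealogies.
#' @return numeric matrix \code{reps x (nA + nP - 1)}.
#' @export
simulateCoalescenceTimes <- function(params, nA, nP, reps,
                                     control = simControl()) {
  stopifnot(is(params, "IMParams"), reps >= 1)
  nA <- as.integer(nA); nP <- as.integer(nP)
  if (nA + nP < 2L) stop("need at least two sampled lineages in total")
  .sim_coal_times_cpp(params@nAnc, params@nA, params@nP, params@tDiv,
                      params@mPA, params@mAP, nA, nP, as.integer(reps),
                      control)
}

#' @rdname coalescenceTimes
#' @export
setGeneric("coalescenceTimes", function(x) standardGeneric("coalescenceTimes"))

#' Coalescence times of a genealogy
#'
#' @param x a [Genealogy-class] object.
#' @return numeric vector of the n - 1 merge times, increasing.
#' @export
setMethod("coalescenceTimes", "Genealogy", function(x) x@times)

#' @rdname totalBranchLength
#' @export
setGeneric("totalBranchLength", function(x) standardGeneric("totalBranchLength"))

#' Total branch length of a genealogy
#'
#' @param x a [Genealogy-class] object.
#' @return total branch length in generations.
#' @export
setMethod("totalBranchLength", "Genealogy", function(x) x@totalLength)

#' @export
setMethod("show", "Genealogy", function(object) {
  n <- length(object@leafPop)
  cat(sprintf("Genealogy: %d lineages (%d from A, %d from P), %d coalescences\n",
              n, sum(object@leafPop == 0L), sum(object@leafPop == 1L), n - 1L))
  cat(sprintf("  TMRCA = %.1f generations, total length = %.1f\n",
              max(object@times), object@totalLength))
})

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param x a [Genealogy-class] object.
#' @return an object of class \code{phylo} with branch lengths in generations.
#' @export
asPhylo <- function(x) {
  stopifnot(is(x, "Genealogy"))
  n <- length(x@leafPop)
  # ape numbering: leaves 1..n, root n+1; our k-th internal node (id n+k)
  # maps to ape id 2n - k so that the root (k = n-1) becomes n + 1.
  apeId <- function(id) ifelse(id <= n, id, 2L * n - (id - n))
  nodeTime <- c(rep(0, n), x@times)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  len <- numeric(2L * (n - 1L))
  r <- 1L
  for (k in seq_len(n - 1L)) {
    for (child in x@merges[k, ]) {
      edge[r, ] <- c(apeId(n + k), apeId(child))
      len[r] <- x@times[k] - nodeTime[child]
      r <- r + 1L
    }
  }
  structure(list(edge = edge, edge.length = len, Nnode = n - 1L,
                 tip.label = paste0(ifelse(x@leafPop == 0L, "A", "P"),
                                    seq_len(n))),
            class = "phylo", order = "unknown")
}
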