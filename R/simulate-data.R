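#' Simulate a folded joint SFS under the IM model
#'
#' SNP-conditioned simulation of the segregating-site law: \code{nSnps}
#' independent genealogies are drawn and the branch length subtending every
#' (derived-in-A, derived-in-P) configuration is accumulated; under
#' infinite sites a SNP shows configuration (i, j) with probability
#' E[L(i,j)] / E[L_tot], so the length-weighted ratio of sums across
#' genealogies estimates the cell law without the smalls-sample bias of
#' single-mutation-per-tree sampling. The observed spectrum is then a
#' multinomial draw of \code{nSnps} SNPs from that law, folded to
#' pooled-minor-allele orientation (exact-0.5 ties split 0.5/0.5). The mean
#' total branch length is stored in \code{meta$meanTotalLength}; together
#' with a fixed mutation rate it anchors absolute population sizes in
#' [fitIMModel()].
#'
#' Uses the session RNG; call [set.seed()] for reproducibility.
#'
#' @param params an [IMParams-class] object.
#' @param kA,kP numbers of sampled alleles (lineages) per population.
#' @param nSnps number of SNPs to simulate (0 gives an all-zero spectrum).
#' @param control engine settings from [simControl()].
#' @param fold fold to minor-allele orientation (default); \code{FALSE}
#'   returns the unfolded derived-count spectrum.
#' @param expected return the expected (fractional, length-weighted) cell
#'   weights scaled to \code{nSnps} instead of an integer multinomial draw.
#' @return a [JointSFS-class] object with total weight \code{nSnps}.
#' @export
simulateJointSFS <- function(params, kA, kP, nSnps, control = simControl(),
                             fold = TRUE, expected = FALSE) {
  stopifnot(is(params, "IMParams"), nSnps >= 0)
  validObject(params)
  kA <- as.integer(kA); kP <- as.integer(kP)
  if (kA + kP < 2L) stop("need at least two sampled alleles in total")
  if (nSnps == 0)
    return(jointSFS(matrix(0, kA + 1L, kP + 1L), kA, kP))
  res <- .sim_joint_sfs_cpp(params@nAnc, params@nA, params@nP, params@tDiv,
                            params@mPA, params@mAP, kA, kP,
                            as.numeric(nSnps), control)
  p <- res$lengths / sum(res$lengths)
  w <- if (expected) nSnps * p else {
    m <- matrix(0, kA + 1L, kP + 1L)
    m[] <- rmultinom(1L, as.integer(nSnps), as.vector(p))
    m
  }
  if (fold) w <- .fold_matrix(w, kA, kP)
  jointSFS(w, kA, kP, meta = list(meanTotalLength = res$mean_total_length))
}

#' Simulate a diploid genotype dataset under the IM model
#'
#' Simulates \code{nLoci = ceiling(L / locusLen)} independent
#' non-recombining loci (free recombination between loci, none within),
#' drops infinite-sites mutations on each genealogy at rate \code{mu} per
#' site per generation, and pairs haplotypes at random within populations
#' into diploid genotypes (monoecious Wright-Fisher idealization, i.e.
#' Hardy-Weinberg pairing). Each locus is reported as its own scaffold with
#' 1-based positions. Constant placeholder DP (30) and GQ (99) assays are
#' attached so the result can feed the filter cascade directly.
#'
#' @param params an [IMParams-class] object (uses \code{params@mu}).
#' @param nInd integer vector of length 2: diploid individuals sampled in
#'   populations A and P (either may be 0).
#' @param L total genome length in sites.
#' @param locusLen length of each independent locus (default 500 bp).
#' @param popNames population labels, default \code{c("A", "P")}.
#' @param control engine settings from [simControl()].
#' @return a [GenotypeData-class] object of the variant sites.
#' @examples
#' set.seed(7)
#' gd <- simulateGenotypes(IMParams(1e4, 1e4, 1e4, 0, mu = 1e-7),
#'                         nInd = c(4, 4), L = 1e4)
#' @export
simulateGenotypes <- function(params, nInd, L, locusLen = 500,
                              popNames = c("A", "P"),
                              control = simControl()) {
  stopifnot(is(params, "IMParams"), length(nInd) == 2L, L >= 1)
  validObject(params)
  nInd <- as.integer(nInd)
  if (sum(nInd) < 1L) stop("need at least one individual")
  nLoci <- as.integer(ceiling(L / locusLen))
  res <- .sim_haplotypes_cpp(params@nAnc, params@nA, params@nP, params@tDiv,
                             params@mPA, params@mAP,
                             2L * nInd[1L], 2L * nInd[2L],
                             nLoci, as.numeric(locusLen), params@mu, control)
  hap <- res$haplotypes            # haplotypes x SNPs
  S <- ncol(hap)
  nTot <- sum(nInd)
  odd <- seq(1L, 2L * nTot, by = 2L)
  gt <- t(hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- vapply(ref, function(b) {
    if (runif(1) < 2 / 3) transit[[b]] else sample(setdiff(bases, c(b, transit[[b]])), 1L)
  }, character(1L))
  pop <- rep(popNames, nInd)
  genotypeData(gt,
               scaffold = sprintf("scf%05d", res$locus),
               pos = res$pos, ref = ref, alt = alt,
               population = pop,
               dp = matrix(30L, S, nTot), gq = matrix(99L, S, nTot))
}
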