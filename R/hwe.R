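#' Exact Hardy-Weinberg test with a heterozygote-excess one-sided p-value
#'
#' Enumerates the conditional (Levene) distribution of the heterozygote
#' count given the observed allele counts: with n diploids and nA copies of
#' allele A, P(nAa = h) = n! / (nAA! nAa! naa!) * 2^h * nA! na! / (2n)!.
#' Returns the two-sided exact HWE p-value (sum of point probabilities not
#' exceeding that of the observed configuration) and the one-sided
#' heterozygote-excess p-value P(nAa >= observed). The latter implements the
#' filter rule that discards a site only when HWE deviation is driven by
#' significant heterozygote excess.
#'
#' @param nAA,nAa,naa observed genotype counts.
#' @return list with elements \code{pHWE} (two-sided exact),
#'   \code{pHetExcess} (one-sided, P(het >= observed)) and \code{pHetDeficit}.
#' @examples
#' hweExactTest(1, 2, 1)$pHetExcess   # 64/70
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype is required")
  nA <- 2L * nAA + nAa
  na <- 2L * n - nA
  # admissible heterozygote counts share the parity of min(nA, na)
  hMax <- min(nA, na)
  h <- seq.int(hMax %% 2L, hMax, by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(nAa, h)
  if (is.na(obs)) stop("inconsistent genotype counts")
  list(pHWE = sum(p[p <= p[obs] * (1 + 1e-12)]),
       pHetExcess = sum(p[h >= nAa]),
       pHetDeficit = sum(p[h <= nAa]))
}

#' One-sided heterozygote-excess exact probability
#'
#' Convenience wrapper around [hweExactTest()] returning only
#' P(het count >= observed) under the Levene distribution.
#'
#' @inheritParams hweExactTest
#' @return a probability in (0, 1].
#' @export
hetExcessExactP <- function(nAA, nAa, naa) hweExactTest(nAA, nAa, naa)$pHetExcess
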