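#' Weir-Cockerham (1984) F_ST
#'
#' Computes the per-locus variance components a (among populations), b
#' (among individuals within populations) and c (within individuals) of the
#' Weir & Cockerham (1984) estimator for diploid data in the observed-
#' heterozygosity form, using per-locus non-missing sample sizes, and the
#' multi-locus ratio-of-sums estimate sum(a) / sum(a + b + c) (the
#' "weighted" convention of vcftools). Monomorphic loci contribute zero to
#' both sums.
#'
#' @param x a [GenotypeData-class] object.
#' @param pair character vector of two population labels; default the first
#'   two populations present.
#' @return list with \code{fst} (ratio of sums), \code{components} (per-
#'   locus data.frame with a, b, c) and \code{nLoci} (loci with defined
#'   components).
#' @export
fstWeirCockerham <- function(x, pair = NULL) {
  stopifnot(is(x, "GenotypeData"))
  pops <- populations(x)
  if (is.null(pair)) pair <- unique(pops)[1:2]
  stopifnot(length(pair) == 2L, all(pair %in% pops))
  gt <- genotypes(x)
  cols <- lapply(pair, function(p) which(pops == p))
  r <- 2L
  comp <- t(apply(gt, 1L, function(g) {
    n <- vapply(cols, function(ix) sum(!is.na(g[ix])), numeric(1))
    if (any(n < 2)) return(c(NA_real_, NA_real_, NA_real_))
    p <- vapply(cols, function(ix) sum(g[ix], na.rm = TRUE), numeric(1)) / (2 * n)
    h <- vapply(cols, function(ix) mean(g[ix] == 1L, na.rm = TRUE), numeric(1))
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }))
  comp <- as.data.frame(comp)
  names(comp) <- c("a", "b", "c")
  ok <- complete.cases(comp)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom == 0)
    stop("F_ST is undefined: no polymorphic locus with sufficient data")
  list(fst = sum(comp$a[ok]) / denom, components = comp, nLoci = sum(ok))
}

#' Per-population diversity and F-statistics (Nei 1987 conventions)
#'
#' Sample-size-corrected gene diversities following the basic-statistics
#' conventions of Nei (1987) as implemented in standard F-statistics
#' packages: per locus, with r populations of (non-missing) sample sizes
#' n_k, harmonic mean nh, allele frequencies p_k and observed heterozygote
#' frequencies,
#' \deqn{H_O = mean_k h_k}
#' \deqn{H_S = nh/(nh-1) (1 - mean_k \sum p_k^2 - H_O/(2 nh))}
#' \deqn{H_T = 1 - \sum (mean_k p_k)^2 + H_S/(nh r) - H_O/(2 nh r)}
#' Across loci the quantities are averaged and
#' F_ST = (HT - HS)/HT, F_IS = 1 - HO/HS on the locus means.
#'
#' @param x a [GenotypeData-class] object with >= 2 populations.
#' @param pair optional character vector of two population labels to
#'   restrict to.
#' @return a [DiversityStats-class] object.
#' @export
neiBasicStats <- function(x, pair = NULL) {
  stopifnot(is(x, "GenotypeData"))
  pops <- populations(x)
  labs <- if (is.null(pair)) unique(pops) else pair
  if (length(labs) < 2L) stop("Nei F_ST requires at least two populations")
  gt <- genotypes(x)
  cols <- lapply(labs, function(p) which(pops == p))
  r <- length(labs)
  per <- t(apply(gt, 1L, function(g) {
    n <- vapply(cols, function(ix) sum(!is.na(g[ix])), numeric(1))
    if (any(n < 1)) return(c(NA_real_, NA_real_, NA_real_))
    p <- vapply(cols, function(ix) sum(g[ix], na.rm = TRUE), numeric(1)) / (2 * n)
    h <- vapply(cols, function(ix) mean(g[ix] == 1L, na.rm = TRUE), numeric(1))
    nh <- r / sum(1 / n)                       # harmonic mean sample size
    ho <- mean(h)
    msp2 <- mean(p^2 + (1 - p)^2)
    hs <- nh / (nh - 1) * (1 - msp2 - ho / (2 * nh))
    pb <- mean(p)
    ht <- 1 - (pb^2 + (1 - pb)^2) + hs / (nh * r) - ho / (2 * nh * r)
    c(ho, hs, ht)
  }))
  ok <- complete.cases(per)
  if (!any(ok)) stop("no locus with data in every population")
  m <- colMeans(per[ok, , drop = FALSE])
  new("DiversityStats", HO = m[1L], HS = m[2L], HT = m[3L],
      FIS = 1 - m[1L] / m[2L], FSTNei = (m[3L] - m[2L]) / m[3L],
      perLocus = data.frame(HO = per[, 1L], HS = per[, 2L], HT = per[, 3L]),
      populations = labs)
}

#' Diversity statistics container
#'
#' @slot HO,HS,HT locus-averaged observed heterozygosity, within-population
#'   and overall gene diversity (sample-size corrected).
#' @slot FIS,FSTNei inbreeding coefficient and Nei's fixation index on the
#'   locus-averaged quantities.
#' @slot perLocus per-locus values.
#' @slot populations population labels used.
#' @export
setClass("DiversityStats",
  representation(HO = "numeric", HS = "numeric", HT = "numeric",
                 FIS = "numeric", FSTNei = "numeric",
                 perLocus = "data.frame", populations = "character"))

#' @export
setMethod("show", "DiversityStats", function(object) {
  cat(sprintf("DiversityStats over %d loci, populations: %s\n",
              nrow(object@perLocus), paste(object@populations, collapse = ", ")))
  cat(sprintf("  H_O = %.4f  H_S = %.4f  H_T = %.4f\n",
              object@HO, object@HS, object@HT))
  cat(sprintf("  F_IS = %.4f  F_ST(Nei) = %.4f\n", object@FIS, object@FSTNei))
})

#' Pairwise F_ST result
#'
#' @slot pair the two population labels.
#' @slot fstWC,fstNei point estimates under the two conventions.
#' @slot ciLow,ciHigh bootstrap 95% percentile interval for F_ST(W&C).
#' @slot p bootstrap p-value, floored at 1/(B+1).
#' @slot pHolm sequential-Bonferroni adjusted p (NA until adjusted).
#' @slot nLoci,B loci used and bootstrap replicates.
#' @export
setClass("FstResult",
  representation(pair = "character", fstWC = "numeric", fstNei = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                 pHolm = "numeric", nLoci = "integer", B = "integer"))

#' @export
setMethod("show", "FstResult", function(object) {
  cat(sprintf("FstResult %s vs %s (%d loci, B = %d)\n",
              object@pair[1L], object@pair[2L], object@nLoci, object@B))
  cat(sprintf("  F_ST(W&C) = %.4f [%.4f, %.4f], p = %.4g (Holm: %s)\n",
              object@fstWC, object@ciLow, object@ciHigh, object@p,
              ifelse(is.na(object@pHolm), "-", format(object@pHolm, digits = 3))))
  cat(sprintf("  F_ST(Nei) = %.4f\n", object@fstNei))
})

#' Locus bootstrap for Weir-Cockerham F_ST
#'
#' Resamples loci with replacement B times, recomputing the ratio-of-sums
#' estimate each time; the 95% CI is the 2.5/97.5 percentile interval and
#' the p-value is (#\{replicates <= 0\} + 1) / (B + 1) (floored rather than
#' reporting zero). Uses the session RNG.
#'
#' @param x a [GenotypeData-class] object.
#' @param pair two population labels.
#' @param B bootstrap replicates (>= 100).
#' @return an [FstResult-class] object.
#' @export
bootstrapFst <- function(x, pair = NULL, B = 1000L) {
  stopifnot(B >= 100L)
  wc <- fstWeirCockerham(x, pair)
  if (is.null(pair)) pair <- unique(populations(x))[1:2]
  comp <- wc$components[complete.cases(wc$components), , drop = FALSE]
  poly <- comp$a + comp$b + comp$c > 0
  if (sum(poly) < 2L) stop("bootstrap requires at least two polymorphic loci")
  L <- nrow(comp)
  reps <- vapply(seq_len(B), function(i) {
    ix <- sample.int(L, L, replace = TRUE)
    den <- sum(comp$a[ix] + comp$b[ix] + comp$c[ix])
    if (den == 0) return(NA_real_)
    sum(comp$a[ix]) / den
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  ci <- quantile(reps, c(0.025, 0.975), names = FALSE)
  nei <- neiBasicStats(x, pair = pair)
  new("FstResult", pair = pair, fstWC = wc$fst, fstNei = nei@FSTNei,
      ciLow = ci[1L], ciHigh = ci[2L],
      p = (sum(reps <= 0) + 1) / (length(reps) + 1),
      pHolm = NA_real_, nLoci = as.integer(wc$nLoci), B = as.integer(B))
}

#' All pairwise F_ST estimates with Holm correction
#'
#' @param x a [GenotypeData-class] object.
#' @param B bootstrap replicates per pair.
#' @return data.frame with one row per population pair: popA, popB, fstWC,
#'   fstNei, ciLow, ciHigh, p, pHolm, nLoci.
#' @export
pairwiseFst <- function(x, B = 1000L) {
  pops <- unique(populations(x))
  prs <- combn(pops, 2L)
  res <- lapply(seq_len(ncol(prs)), function(i)
    bootstrapFst(x, pair = prs[, i], B = B))
  out <- data.frame(
    popA = prs[1L, ], popB = prs[2L, ],
    fstWC = vapply(res, slot, numeric(1), "fstWC"),
    fstNei = vapply(res, slot, numeric(1), "fstNei"),
    ciLow = vapply(res, slot, numeric(1), "ciLow"),
    ciHigh = vapply(res, slot, numeric(1), "ciHigh"),
    p = vapply(res, slot, numeric(1), "p"),
    nLoci = vapply(res, slot, integer(1), "nLoci"))
  out$pHolm = holmAdjust(out$p)
  out
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Step-down correction: the i-th smallest p-value is multiplied by
#' (m - i + 1), monotonicity is enforced and values are capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holmAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}
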