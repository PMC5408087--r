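#' Filter-cascade configuration
#'
#' Thresholds for the site- and genotype-level filter cascade. Defaults
#' follow common practice for two-caller short-read callsets: GATK-style
#' hard filters (FS > 60, MQRankSum < -12.5, ReadPosRankSum < -8, QD < 2,
#' MQ < 40, all strict inequalities as printed), removal of SNPs within
#' 10 bp of an indel, per-genotype masking at GQ < 20 or DP < 3 or DP > 100,
#' pooled minor-allele count >= 2, Hardy-Weinberg removal only for
#' significant heterozygote excess (both p-values below 1e-4), minor-allele
#' frequency and per-site missingness ceilings, and LD pruning at r^2 > 0.8.
#'
#' @param mac minimum pooled minor-allele count.
#' @param hweP,hetExcessP HWE / heterozygote-excess p-value thresholds; a
#'   site is removed only when BOTH fall below their thresholds.
#' @param maf minor-allele-frequency threshold (site kept when MAF > maf).
#' @param maxMissing maximum fraction of missing genotypes per site.
#' @param r2 LD-pruning threshold (site dropped when r^2 with a retained
#'   upstream site exceeds this).
#' @param indelDist exclusion distance around indels in bp.
#' @param gqMin,dpMin,dpMax genotype masking bounds.
#' @param fsMax,mqrsMin,rprsMin,qdMin,mqMin site hard-filter bounds.
#' @param ldWindow maximum pair distance considered during LD pruning (bp).
#' @return a classed list of thresholds.
#' @export
filterConfig <- function(mac = 2L, hweP = 1e-4, hetExcessP = 1e-4,
                         maf = 0.01, maxMissing = 0.2, r2 = 0.8,
                         indelDist = 10L, gqMin = 20, dpMin = 3, dpMax = 100,
                         fsMax = 60.0, mqrsMin = -12.5, rprsMin = -8.0,
                         qdMin = 2.0, mqMin = 40.0, ldWindow = 10e6) {
  stopifnot(mac >= 0, hweP >= 0, hweP <= 1, hetExcessP >= 0, hetExcessP <= 1,
            maf >= 0, maf <= 0.5, maxMissing >= 0, maxMissing <= 1,
            r2 >= 0, r2 <= 1, indelDist >= 0, gqMin >= 0,
            dpMin >= 0, dpMax >= dpMin)
  structure(list(mac = mac, hweP = hweP, hetExcessP = hetExcessP, maf = maf,
                 maxMissing = maxMissing, r2 = r2, indelDist = indelDist,
                 gqMin = gqMin, dpMin = dpMin, dpMax = dpMax, fsMax = fsMax,
                 mqrsMin = mqrsMin, rprsMin = rprsMin, qdMin = qdMin,
                 mqMin = mqMin, ldWindow = ldWindow),
            class = "FilterConfig")
}

.site_key <- function(sites)
  paste(sites$scaffold, sites$pos, sites$ref, sites$alt, sep = ":")

.check_sorted <- function(sites, what) {
  o <- order(sites$scaffold, sites$pos)
  if (!identical(o, seq_len(nrow(sites))))
    stop(what, " must be sorted by (scaffold, position)")
}

#' Intersect two caller site lists
#'
#' Returns the sites present in both callsets, matched on (scaffold,
#' position, ref, alt), in sorted order. Inputs must already be sorted by
#' (scaffold, position).
#'
#' @param sitesA,sitesB data.frames with at least columns scaffold, pos,
#'   ref, alt (e.g. from [siteTable()]).
#' @return the rows of \code{sitesA} whose key also occurs in \code{sitesB}.
#' @export
intersectCallsets <- function(sitesA, sitesB) {
  .check_sorted(sitesA, "sitesA"); .check_sorted(sitesB, "sitesB")
  keep <- .site_key(sitesA) %in% .site_key(sitesB)
  sitesA[keep, , drop = FALSE]
}

#' Site-level hard filters
#'
#' Removes indels, non-biallelic sites, sites failing any of the hard-filter
#' predicates (FS > fsMax, MQRankSum < mqrsMin, ReadPosRankSum < rprsMin,
#' QD < qdMin, MQ < mqMin; strict inequalities) and SNPs within
#' \code{indelDist} bp of an indel's affected reference span. Missing INFO
#' annotations do NOT trigger removal (rank-sum annotations are undefined at
#' sites without heterozygotes).
#'
#' @param sites data.frame with columns scaffold, pos, ref, alt, isIndel and
#'   (optionally) FS, MQ, QD, MQRankSum, ReadPosRankSum.
#' @param config a [filterConfig()].
#' @return the retained rows of \code{sites}.
#' @export
hardFilterSites <- function(sites, config = filterConfig()) {
  n <- nrow(sites)
  isIndel <- if ("isIndel" %in% names(sites)) sites$isIndel else
    nchar(sites$ref) != 1L | nchar(sites$alt) != 1L
  fails <- function(col, bad) {
    if (!col %in% names(sites)) return(rep(FALSE, n))
    v <- sites[[col]]
    !is.na(v) & bad(v)
  }
  drop <- isIndel |
    grepl(",", sites$alt, fixed = TRUE) |
    fails("FS", function(v) v > config$fsMax) |
    fails("MQRankSum", function(v) v < config$mqrsMin) |
    fails("ReadPosRankSum", function(v) v < config$rprsMin) |
    fails("QD", function(v) v < config$qdMin) |
    fails("MQ", function(v) v < config$mqMin)
  # indel proximity: distance from a SNP to the indel's reference span
  # (pos .. pos + nchar(ref) - 1); remove when <= indelDist
  idl <- which(isIndel)
  if (length(idl)) {
    for (i in idl) {
      span <- c(sites$pos[i] - config$indelDist,
                sites$pos[i] + nchar(sites$ref[i]) - 1L + config$indelDist)
      near <- sites$scaffold == sites$scaffold[i] &
        sites$pos >= span[1L] & sites$pos <= span[2L]
      drop <- drop | near
    }
  }
  sites[!drop, , drop = FALSE]
}

#' Mask low-confidence genotypes
#'
#' Sets individual genotypes to missing when GQ < gqMin, DP < dpMin or
#' DP > dpMax (any failing criterion masks; genotypes without DP/GQ
#' annotation are left untouched). Site-level data are unchanged.
#'
#' @param x a [GenotypeData-class] object with DP and/or GQ assays.
#' @param config a [filterConfig()].
#' @return \code{x} with masked GT entries set to \code{NA}.
#' @export
maskGenotypes <- function(x, config = filterConfig()) {
  stopifnot(is(x, "GenotypeData"))
  gt <- assay(x, "GT")
  bad <- matrix(FALSE, nrow(gt), ncol(gt))
  if ("GQ" %in% assayNames(x)) {
    gq <- assay(x, "GQ")
    bad <- bad | (!is.na(gq) & gq < config$gqMin)
  }
  if ("DP" %in% assayNames(x)) {
    dp <- assay(x, "DP")
    bad <- bad | (!is.na(dp) & (dp < config$dpMin | dp > config$dpMax))
  }
  gt[bad] <- NA_integer_
  assays(x)$GT <- gt
  x
}

.site_stats <- function(g) {
  ok <- !is.na(g)
  nAll <- 2L * sum(ok)
  alt <- sum(g[ok])
  list(miss = mean(!ok), nAlleles = nAll, mac = min(alt, nAll - alt),
       maf = if (nAll > 0) min(alt, nAll - alt) / nAll else NA_real_,
       nAA = sum(g[ok] == 0L), nAa = sum(g[ok] == 1L), naa = sum(g[ok] == 2L))
}

#' Site filter pipeline
#'
#' Applies, in order: pooled minor-allele count >= \code{mac}; removal of
#' sites deviating from Hardy-Weinberg equilibrium only when the deviation
#' is due to significant heterozygote excess (exact HWE p below \code{hweP}
#' AND one-sided heterozygote-excess p below \code{hetExcessP}, tested on
#' the pooled sample); minor-allele frequency > \code{maf}; missing-data
#' fraction <= \code{maxMissing}. Returns the filtered object together with
#' a per-stage attrition report.
#'
#' @param x a [GenotypeData-class] object (typically after
#'   [maskGenotypes()]).
#' @param config a [filterConfig()].
#' @return list with elements \code{data} (filtered [GenotypeData-class])
#'   and \code{report} (data.frame: stage, sitesIn, sitesRemoved, sitesOut).
#' @export
siteFilterPipeline <- function(x, config = filterConfig()) {
  stopifnot(is(x, "GenotypeData"))
  gt <- genotypes(x)
  stats <- apply(gt, 1L, .site_stats)
  report <- data.frame(stage = character(), sitesIn = integer(),
                       sitesRemoved = integer(), sitesOut = integer())
  note <- function(stage, keepIdx, total) {
    report <<- rbind(report, data.frame(
      stage = stage, sitesIn = total,
      sitesRemoved = total - length(keepIdx), sitesOut = length(keepIdx)))
  }
  idx <- seq_len(nrow(gt))

  keep <- idx[vapply(stats[idx], function(s) s$mac >= config$mac, logical(1))]
  note("mac", keep, length(idx)); idx <- keep

  hweKeep <- vapply(stats[idx], function(s) {
    if (s$nAa == 0L) return(TRUE)            # no heterozygotes, no excess
    hw <- hweExactTest(s$nAA, s$nAa, s$naa)
    !(hw$pHWE < config$hweP && hw$pHetExcess < config$hetExcessP)
  }, logical(1))
  keep <- idx[hweKeep]
  note("hwe_het_excess", keep, length(idx)); idx <- keep

  keep <- idx[vapply(stats[idx], function(s) !is.na(s$maf) && s$maf > config$maf,
                     logical(1))]
  note("maf", keep, length(idx)); idx <- keep

  keep <- idx[vapply(stats[idx], function(s) s$miss <= config$maxMissing,
                     logical(1))]
  note("missingness", keep, length(idx)); idx <- keep

  list(data = x[idx, ], report = report)
}

#' Greedy LD pruning
#'
#' Scans sites in position order within each scaffold and drops a site when
#' its genotype-dosage r^2 with any retained upstream site on the same
#' scaffold (within \code{ldWindow} bp) exceeds \code{r2}. Deterministic;
#' on ties the site with the smaller position is the one retained.
#'
#' @param x a [GenotypeData-class] object, sites sorted by position within
#'   scaffold.
#' @param r2 threshold (default from \code{config}).
#' @param config a [filterConfig()].
#' @return the pruned [GenotypeData-class] object.
#' @export
ldPrune <- function(x, r2 = config$r2, config = filterConfig()) {
  stopifnot(is(x, "GenotypeData"))
  st <- siteTable(x)
  .check_sorted(st, "sites")
  gt <- genotypes(x)
  keep <- logical(nrow(gt))
  for (scf in unique(st$scaffold)) {
    ids <- which(st$scaffold == scf)
    kept <- integer()
    for (i in ids) {
      prev <- kept[st$pos[kept] >= st$pos[i] - config$ldWindow]
      linked <- FALSE
      for (j in prev) {
        r <- ldR2(gt[j, ], gt[i, ])
        if (!is.na(r) && r > r2) { linked <- TRUE; break }
      }
      if (!linked) { keep[i] <- TRUE; kept <- c(kept, i) }
    }
  }
  x[keep, ]
}
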