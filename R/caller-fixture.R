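#' Two-caller VCF fixture with a filtering truth table
#'
#' Emulates a two-caller variant-calling setup on top of a simulated
#' genotype dataset: writes two VCFs with controlled overlap (caller-unique
#' sites), injected indels and indel-proximal SNPs, sites violating each
#' hard-filter annotation, a multiallelic site, heterozygote-excess and
#' heterozygote-deficit sites, a minor-allele-count singleton, a low-MAF
#' site and a high-missingness site (driven through the DP/GQ masking
#' bounds) -- together with a truth table recording, for every site, which
#' stage of the filter cascade is expected to remove it.
#'
#' Base sites are taken from \code{x} and kept only when they pass every
#' filter with a safety margin (so that the truth is unambiguous);
#' engineered sites are appended on dedicated scaffolds. Uses the session
#' RNG.
#'
#' @param x a [GenotypeData-class] object from [simulateGenotypes()]
#'   supplying realistic base sites (>= 10 samples recommended).
#' @param dir output directory.
#' @param config the [filterConfig()] the truth table refers to; the
#'   default uses \code{maf = 0.03} so a MAC-passing site can still fail
#'   the MAF filter.
#' @param callerUniqueFrac fraction of keepable base sites made unique to
#'   one caller (half VCF-A-only, half VCF-B-only).
#' @param nKeepMax cap on base sites retained.
#' @return list with \code{vcfA}, \code{vcfB} (paths), \code{truth}
#'   (data.frame: scaffold, pos, ref, alt, category, inA, inB, survives)
#'   and \code{config}.
#' @export
makeCallerFixture <- function(x, dir, config = filterConfig(maf = 0.03),
                              callerUniqueFrac = 0.1, nKeepMax = 30L) {
  stopifnot(is(x, "GenotypeData"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(x)
  if (n < 10L) stop("fixture construction needs at least 10 samples")
  pops <- populations(x)

  goodInfo <- function(k) data.frame(FS = rep(10, k), MQ = 60, QD = 20,
                                     MQRankSum = 0, ReadPosRankSum = 0)
  naInfo <- function(k) data.frame(FS = rep(NA_real_, k), MQ = NA_real_,
                                   QD = NA_real_, MQRankSum = NA_real_,
                                   ReadPosRankSum = NA_real_)

  # --- base sites that clearly pass everything -------------------------------
  gt <- genotypes(x)
  st <- siteTable(x)
  passes <- vapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    if (anyNA(g)) return(FALSE)
    alt <- sum(g); mac <- min(alt, 2L * n - alt)
    if (mac < config$mac + 1L) return(FALSE)
    if (mac / (2 * n) <= 1.5 * config$maf) return(FALSE)
    hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))$pHWE > 0.01
  }, logical(1))
  keepIdx <- head(which(passes), nKeepMax)
  if (length(keepIdx) < 10L)
    stop("too few clearly-passing base sites; simulate a larger dataset")
  nU <- max(2L, 2L * floor(callerUniqueFrac * length(keepIdx) / 2))
  unique_ids <- sample(keepIdx, nU)
  aOnly <- unique_ids[seq_len(nU / 2L)]
  bOnly <- setdiff(unique_ids, aOnly)

  mkSite <- function(scaffold, pos, ref, alt, g, category, survives,
                     inA = TRUE, inB = TRUE, info = NULL,
                     dp = rep(30L, n), gq = rep(99L, n), indel = FALSE) {
    list(scaffold = scaffold, pos = pos, ref = ref, alt = alt, g = g,
         dp = dp, gq = gq, info = info, category = category,
         survives = survives, inA = inA, inB = inB, indel = indel)
  }
  # deterministic genotype pattern near Hardy-Weinberg for p ~ 0.3
  hwCounts <- function() {
    nAa <- round(2 * 0.3 * 0.7 * n); naa <- round(0.09 * n)
    g <- sample(rep(c(0L, 1L, 2L), c(n - nAa - naa, nAa, naa)))
    stopifnot(hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))$pHWE > 0.01)
    g
  }

  sites <- list()
  for (i in keepIdx) {
    cat_i <- if (i %in% aOnly) "caller_unique_A" else
      if (i %in% bOnly) "caller_unique_B" else "keep_base"
    sites[[length(sites) + 1L]] <- mkSite(
      st$scaffold[i], st$pos[i], st$ref[i], st$alt[i], gt[i, ],
      category = cat_i, survives = cat_i == "keep_base",
      inA = !(i %in% bOnly), inB = !(i %in% aOnly),
      info = if (runif(1) < 0.3) NULL else goodInfo(1L))
  }

  # --- engineered sites on dedicated scaffolds -------------------------------
  add <- function(...) sites[[length(sites) + 1L]] <<- mkSite(...)
  hardFails <- list(FS = 70, MQ = 30, QD = 1.0, MQRankSum = -13,
                    ReadPosRankSum = -9)
  p0 <- 1000L
  for (j in seq_along(hardFails)) {
    info <- goodInfo(1L)
    info[[names(hardFails)[j]]] <- hardFails[[j]]
    add("fx_hard", p0 + 100L * j, "A", "G", hwCounts(),
        category = paste0("hard_", names(hardFails)[j]), survives = FALSE,
        info = info)
  }
  add("fx_multi", 500L, "A", "C,T", hwCounts(),
      category = "multiallelic", survives = FALSE)
  # indel at 2000 spanning 2000..2002; SNP at 2008 within 10 bp; SNP at 2013
  # at distance 11, retained
  add("fx_indel", 2000L, "ATT", "A", hwCounts(),
      category = "indel", survives = FALSE, indel = TRUE)
  add("fx_indel", 2008L, "C", "A", hwCounts(),
      category = "near_indel", survives = FALSE)
  add("fx_indel", 2013L, "G", "T", hwCounts(),
      category = "keep_far_from_indel", survives = TRUE)
  # pooled MAC singleton
  g <- rep(0L, n); g[sample.int(n, 1L)] <- 1L
  add("fx_mac", 100L, "T", "A", g, category = "mac_singleton",
      survives = FALSE)
  # all-heterozygote site: extreme heterozygote excess
  add("fx_hwe", 100L, "C", "G", rep(1L, n), category = "het_excess",
      survives = FALSE)
  # strong heterozygote deficit: HWE p tiny but excess p = 1 -> kept
  g <- sample(rep(c(0L, 2L), c(ceiling(n / 2), floor(n / 2))))
  add("fx_hwe", 300L, "A", "T", g, category = "keep_het_deficit",
      survives = TRUE)
  # MAC passes (2 copies in 2 heterozygotes) but MAF below 3%
  g <- rep(0L, n); g[sample.int(n, 2L)] <- 1L
  add("fx_maf", 100L, "G", "C", g, category = "low_maf",
      survives = 2 / (2 * n) > config$maf)
  # the unmasked remainder of a partially masked site must itself pass the
  # later stages cleanly, so redraw the mask until it does by a margin
  clearlyPasses <- function(g) {
    alt <- sum(g); mac <- min(alt, 2L * length(g) - alt)
    mac >= config$mac + 1L && mac / (2 * length(g)) > 1.5 * config$maf &&
      hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))$pHWE > 0.01
  }
  maskedSubset <- function(g, nBad) {
    for (i in 1:200) {
      bad <- sample.int(n, nBad)
      if (clearlyPasses(g[-bad])) return(bad)
    }
    stop("could not construct an unambiguous partially-masked site")
  }
  # high missingness driven through DP masking
  g <- hwCounts()
  nBad <- ceiling((config$maxMissing + 0.1) * n)
  bad <- maskedSubset(g, nBad)
  dp <- rep(30L, n); dp[bad] <- 1L
  add("fx_miss", 100L, "T", "G", g, category = "high_missing",
      survives = FALSE, dp = dp)
  # a few masked genotypes but still well under the missingness ceiling
  g <- hwCounts()
  bad <- maskedSubset(g, 2L)
  gq <- rep(99L, n); gq[bad] <- 10L
  add("fx_miss", 400L, "A", "C", g, category = "keep_some_masked",
      survives = TRUE, gq = gq)

  # --- assemble GenotypeData per caller and write ----------------------------
  build <- function(flag) {
    use <- sites[vapply(sites, `[[`, logical(1), flag)]
    ord <- order(vapply(use, `[[`, character(1), "scaffold"),
                 vapply(use, `[[`, integer(1), "pos"))
    use <- use[ord]
    info <- do.call(rbind, lapply(use, function(s)
      if (is.null(s$info)) naInfo(1L) else s$info))
    genotypeData(
      do.call(rbind, lapply(use, `[[`, "g")),
      scaffold = vapply(use, `[[`, character(1), "scaffold"),
      pos = vapply(use, `[[`, integer(1), "pos"),
      ref = vapply(use, `[[`, character(1), "ref"),
      alt = vapply(use, `[[`, character(1), "alt"),
      population = pops,
      dp = do.call(rbind, lapply(use, `[[`, "dp")),
      gq = do.call(rbind, lapply(use, `[[`, "gq")),
      info = info,
      isIndel = vapply(use, `[[`, logical(1), "indel"),
      sampleIds = colnames(x))
  }
  vcfA <- file.path(dir, "callerA.vcf.gz")
  vcfB <- file.path(dir, "callerB.vcf.gz")
  writeVcfGenotypes(build("inA"), vcfA)
  writeVcfGenotypes(build("inB"), vcfB)
  truth <- data.frame(
    scaffold = vapply(sites, `[[`, character(1), "scaffold"),
    pos = vapply(sites, `[[`, integer(1), "pos"),
    ref = vapply(sites, `[[`, character(1), "ref"),
    alt = vapply(sites, `[[`, character(1), "alt"),
    category = vapply(sites, `[[`, character(1), "category"),
    inA = vapply(sites, `[[`, logical(1), "inA"),
    inB = vapply(sites, `[[`, logical(1), "inB"),
    survives = vapply(sites, `[[`, logical(1), "survives"))
  truth <- truth[order(truth$scaffold, truth$pos), ]
  rownames(truth) <- NULL
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(vcfA = vcfA, vcfB = vcfB, truth = truth, config = config)
}
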