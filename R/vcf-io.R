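#' Read a VCF into a GenotypeData object
#'
#' Reads GT/DP/GQ and the site-level INFO annotations FS, MQ, QD,
#' MQRankSum, ReadPosRankSum via \pkg{vcfR}. Genotypes are coded as
#' alternate-allele dosage; any genotype containing a missing allele
#' becomes \code{NA}. Sites are flagged as indels when ref or any alt
#' allele is longer than one base.
#'
#' @param file VCF path (plain or gzipped).
#' @param popmap named character vector sample -> population, or a
#'   data.frame with columns sample, population; samples absent from the
#'   map get population "pop1".
#' @return a [GenotypeData-class] object.
#' @export
readVcfGenotypes <- function(file, popmap = NULL) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcf@fix
  gtChar <- vcfR::extract.gt(vcf, "GT")
  gt <- matrix(NA_integer_, nrow(gtChar), ncol(gtChar))
  clean <- gsub("\\|", "/", gtChar)
  gt[clean == "0/0"] <- 0L
  gt[clean %in% c("0/1", "1/0")] <- 1L
  gt[clean == "1/1"] <- 2L
  num <- function(x) suppressWarnings(as.numeric(x))
  dp <- apply(vcfR::extract.gt(vcf, "DP"), 2L, num)
  gq <- apply(vcfR::extract.gt(vcf, "GQ"), 2L, num)
  dim(dp) <- dim(gt); dim(gq) <- dim(gt)
  info <- data.frame(
    FS = num(vcfR::extract.info(vcf, "FS")),
    MQ = num(vcfR::extract.info(vcf, "MQ")),
    QD = num(vcfR::extract.info(vcf, "QD")),
    MQRankSum = num(vcfR::extract.info(vcf, "MQRankSum")),
    ReadPosRankSum = num(vcfR::extract.info(vcf, "ReadPosRankSum")))
  alt <- fix[, "ALT"]
  isIndel <- nchar(fix[, "REF"]) > 1L |
    vapply(strsplit(alt, ","), function(a) any(nchar(a) > 1L), logical(1))
  samples <- colnames(gtChar)
  pop <- rep("pop1", length(samples))
  if (!is.null(popmap)) {
    if (is.data.frame(popmap))
      popmap <- setNames(popmap$population, popmap$sample)
    hit <- samples %in% names(popmap)
    pop[hit] <- popmap[samples[hit]]
  }
  genotypeData(gt, scaffold = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = alt, population = pop,
               dp = dp, gq = gq, info = info, isIndel = isIndel,
               sampleIds = samples)
}

#' Write a GenotypeData object as VCF 4.2
#'
#' Emits GT:DP:GQ genotype fields and the FS/MQ/QD/MQRankSum/ReadPosRankSum
#' INFO annotations where present (written gzipped via \pkg{vcfR}; use a
#' \code{.vcf.gz} file name).
#'
#' @param x a [GenotypeData-class] object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeVcfGenotypes <- function(x, file) {
  stopifnot(is(x, "GenotypeData"))
  st <- siteTable(x)
  gt <- genotypes(x)
  dp <- if ("DP" %in% assayNames(x)) assay(x, "DP") else
    matrix(30L, nrow(gt), ncol(gt))
  gq <- if ("GQ" %in% assayNames(x)) assay(x, "GQ") else
    matrix(99L, nrow(gt), ncol(gt))
  infoCols <- intersect(c("FS", "MQ", "QD", "MQRankSum", "ReadPosRankSum"),
                        names(st))
  info <- vapply(seq_len(nrow(st)), function(i) {
    kv <- vapply(infoCols, function(cn) {
      v <- st[[cn]][i]
      if (is.na(v)) NA_character_ else sprintf("%s=%g", cn, v)
    }, character(1))
    kv <- kv[!is.na(kv)]
    if (length(kv)) paste(kv, collapse = ";") else "."
  }, character(1))
  gtStr <- matrix(".", nrow(gt), ncol(gt))
  gtStr[gt == 0L] <- "0/0"; gtStr[gt == 1L] <- "0/1"; gtStr[gt == 2L] <- "1/1"
  gtStr[is.na(gt)] <- "./."
  body <- matrix(sprintf("%s:%d:%d", gtStr, dp, gq), nrow(gt), ncol(gt))
  colnames(body) <- colnames(x)
  meta <- c("##fileformat=VCFv4.2",
            "##source=tunapopgen",
            "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
            "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
            "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
            "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
            "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  fix <- cbind(CHROM = st$scaffold, POS = as.character(st$pos), ID = ".",
               REF = st$ref, ALT = st$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  obj <- new("vcfR", meta = meta, fix = fix,
             gt = cbind(FORMAT = rep("GT:DP:GQ", nrow(gt)), body))
  vcfR::write.vcf(obj, file)
  invisible(file)
}
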