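#' Diploid genotype matrix with site and sample annotation
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass holding diploid genotype calls for sites (rows) by samples
#' (columns). The \code{"GT"} assay codes genotypes as the count of the
#' alternate allele (0, 1, 2) with \code{NA} for missing; optional
#' \code{"DP"} (read depth) and \code{"GQ"} (genotype quality) assays carry
#' the per-genotype masking variables. Row metadata holds the site table
#' (scaffold, 1-based position, ref, alt, indel flag and the site-level INFO
#' annotations FS, MQ, QD, MQRankSum, ReadPosRankSum where available);
#' \code{colData(x)$population} assigns samples to populations.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!("GT" %in% assayNames(object))) return("assay 'GT' is required")
  gt <- assay(object, "GT")
  if (!all(gt %in% c(0L, 1L, 2L, NA))) return("GT values must be 0, 1, 2 or NA")
  rd <- rowData(object)
  need <- c("scaffold", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (any(rd$pos < 1)) return("positions are 1-based and must be >= 1")
  if (!("population" %in% colnames(colData(object))))
    return("colData must contain 'population'")
  for (a in intersect(c("DP", "GQ"), assayNames(object))) {
    v <- assay(object, a)
    if (any(v < 0, na.rm = TRUE)) return(sprintf("assay '%s' must be >= 0", a))
  }
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param gt integer matrix of alternate-allele dosages (sites x samples),
#'   values 0/1/2/NA.
#' @param scaffold,pos,ref,alt site table vectors (pos is 1-based).
#' @param population population label per sample.
#' @param dp,gq optional per-genotype read depth / genotype quality matrices.
#' @param info optional data.frame of site INFO annotations (FS, MQ, QD,
#'   MQRankSum, ReadPosRankSum).
#' @param isIndel logical per site; default all \code{FALSE}.
#' @param sampleIds sample names; default \code{colnames(gt)} or S1..Sn.
#' @return a [GenotypeData-class] object.
#' @export
genotypeData <- function(gt, scaffold, pos, ref, alt, population,
                         dp = NULL, gq = NULL, info = NULL,
                         isIndel = rep(FALSE, nrow(gt)), sampleIds = NULL) {
  gt <- as.matrix(gt)
  mode(gt) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(colnames(gt))) colnames(gt) else
      sprintf("S%02d", seq_len(ncol(gt)))
  rd <- DataFrame(scaffold = as.character(scaffold), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  isIndel = as.logical(isIndel))
  if (!is.null(info)) for (nm in colnames(info)) rd[[nm]] <- info[[nm]]
  assays <- list(GT = gt)
  if (!is.null(dp)) assays$DP <- as.matrix(dp)
  if (!is.null(gq)) assays$GQ <- as.matrix(gq)
  assays <- lapply(assays, function(m) {
    dimnames(m) <- list(NULL, sampleIds); m
  })
  se <- SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = DataFrame(population = as.character(population),
                        row.names = sampleIds))
  new("GenotypeData", se)
}

#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Extract the genotype dosage matrix
#'
#' @param x a [GenotypeData-class] object.
#' @return integer matrix sites x samples (0/1/2/NA).
#' @export
setMethod("genotypes", "GenotypeData", function(x) assay(x, "GT"))

#' @rdname populations
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Population assignment of samples
#'
#' @param x a [GenotypeData-class] object.
#' @return named character vector, one population label per sample.
#' @export
setMethod("populations", "GenotypeData", function(x)
  setNames(colData(x)$population, colnames(x)))

#' Site table of a GenotypeData object
#'
#' @param x a [GenotypeData-class] object.
#' @return data.frame with scaffold, pos, ref, alt, isIndel and any INFO
#'   columns.
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  as.data.frame(rowData(x))
}

#' @export
setMethod("show", "GenotypeData", function(object) {
  pops <- table(colData(object)$population)
  cat(sprintf("GenotypeData: %d sites x %d samples\n",
              nrow(object), ncol(object)))
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  mono <- sum(apply(assay(object, "GT"), 1,
                    function(g) length(unique(g[!is.na(g)])) < 2L))
  cat(sprintf("  missing genotypes: %.1f%%, monomorphic sites: %d\n",
              100 * mean(is.na(assay(object, "GT"))), mono))
})
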