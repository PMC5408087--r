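#' Genotype-dosage linkage disequilibrium r^2
#'
#' Squared Pearson correlation of alternate-allele dosages over pairwise-
#' complete samples. Undefined (NA) when fewer than two complete pairs
#' remain or either vector has zero variance.
#'
#' @param gA,gB dosage vectors (0/1/2, NA allowed) of equal length.
#' @return r^2 in [0, 1], or NA when undefined.
#' @examples
#' ldR2(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1
#' @export
ldR2 <- function(gA, gB) {
  stopifnot(length(gA) == length(gB))
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2L) return(NA_real_)
  a <- gA[ok]; b <- gB[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Linkage-decay profile
#'
#' Computes r^2 for all within-scaffold site pairs up to \code{maxDist}
#' apart, assigns each pair to a distance bin (\code{floor(d / binSize)})
#' and reports the mean r^2 and pair count per bin. Pairs with undefined
#' r^2 are excluded.
#'
#' @param x a [GenotypeData-class] object.
#' @param maxDist maximum pair distance in bp (default 10 Mb).
#' @param binSize bin width in bp (default 1 kb).
#' @return data.frame with columns bin (0-based index), distFrom, distTo,
#'   meanR2, nPairs.
#' @export
ldDecayProfile <- function(x, maxDist = 10e6, binSize = 1000) {
  stopifnot(is(x, "GenotypeData"))
  st <- siteTable(x)
  gt <- genotypes(x)
  bins <- integer(); r2s <- numeric()
  for (scf in unique(st$scaffold)) {
    ids <- which(st$scaffold == scf)
    if (length(ids) < 2L) next
    ids <- ids[order(st$pos[ids])]
    for (ii in seq_len(length(ids) - 1L)) {
      for (jj in seq.int(ii + 1L, length(ids))) {
        d <- st$pos[ids[jj]] - st$pos[ids[ii]]
        if (d > maxDist) break
        r <- ldR2(gt[ids[ii], ], gt[ids[jj], ])
        if (is.na(r)) next
        bins <- c(bins, d %/% binSize)
        r2s <- c(r2s, r)
      }
    }
  }
  if (!length(bins))
    return(data.frame(bin = integer(), distFrom = numeric(),
                      distTo = numeric(), meanR2 = numeric(),
                      nPairs = integer()))
  agg <- tapply(r2s, bins, mean)
  cnt <- tapply(r2s, bins, length)
  b <- as.integer(names(agg))
  data.frame(bin = b, distFrom = b * binSize, distTo = (b + 1) * binSize - 1,
             meanR2 = as.numeric(agg), nPairs = as.integer(cnt),
             row.names = NULL)
}
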