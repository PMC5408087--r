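#' Folded joint minor-allele site-frequency spectrum
#'
#' Two-dimensional spectrum of minor-allele counts in two groups after
#' projection to fixed allele counts \code{kA} and \code{kP}. Cell (i, j)
#' (0-based) holds the (possibly fractional) number of sites at which the
#' pooled minor allele was seen i times in group A and j times in group P.
#' Sites whose pooled frequency is exactly 0.5 contribute weight 0.5 to each
#' of the two folded orientations. The (0, 0) cell collects sites that are
#' monomorphic after projection (folded together with the (kA, kP) corner)
#' and is flagged masked: SNP-conditioned likelihoods must ignore it.
#'
#' @slot weights numeric (kA+1) x (kP+1) matrix of non-negative cell weights.
#' @slot kA,kP projected allele counts per group.
#' @slot nSites total number of contributing sites (equals the total weight).
#' @slot masked logical matrix flagging cells excluded from likelihoods.
#' @slot meta list of provenance values (seed, mean total branch length, ...).
#' @export
setClass("JointSFS",
  representation(weights = "matrix", kA = "integer", kP = "integer",
                 nSites = "numeric", masked = "matrix", meta = "list"))

setValidity("JointSFS", function(object) {
  w <- object@weights
  if (nrow(w) != object@kA + 1L || ncol(w) != object@kP + 1L)
    return("weights must be a (kA+1) x (kP+1) matrix")
  if (any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - object@nSites) > 1e-9 * max(1, object@nSites))
    return("total weight must equal the number of contributing sites")
  if (!identical(dim(object@masked), dim(w)))
    return("masked must have the same shape as weights")
  TRUE
})

.default_mask <- function(kA, kP) {
  m <- matrix(FALSE, kA + 1L, kP + 1L)
  m[1L, 1L] <- TRUE   # monomorphic cell
  m
}

#' Construct a JointSFS object
#'
#' @param weights numeric (kA+1) x (kP+1) matrix.
#' @param kA,kP projected allele counts.
#' @param masked optional logical matrix; default masks only the (0,0) cell.
#' @param meta list of provenance values.
#' @return a [JointSFS-class] object.
#' @export
jointSFS <- function(weights, kA, kP, masked = NULL, meta = list()) {
  kA <- as.integer(kA); kP <- as.integer(kP)
  if (is.null(masked)) masked <- .default_mask(kA, kP)
  new("JointSFS", weights = unname(as.matrix(weights)), kA = kA, kP = kP,
      nSites = sum(weights), masked = masked, meta = meta)
}

#' @rdname sfsWeights
#' @export
setGeneric("sfsWeights", function(x) standardGeneric("sfsWeights"))

#' Cell weights of a joint SFS
#'
#' @param x a [JointSFS-class] object.
#' @return the (kA+1) x (kP+1) weight matrix with 0-based dimnames.
#' @export
setMethod("sfsWeights", "JointSFS", function(x) {
  w <- x@weights
  dimnames(w) <- list(A = 0:x@kA, P = 0:x@kP)
  w
})

#' @export
setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS: %d x %d folded minor-allele spectrum\n",
              object@kA + 1L, object@kP + 1L))
  cat(sprintf("  %.1f sites (%.1f in the masked monomorphic cell)\n",
              object@nSites, sum(object@weights[object@masked])))
})

# fold an unfolded derived-count weight matrix to pooled-minor orientation
.fold_matrix <- function(w, kA, kP) {
  out <- matrix(0, kA + 1L, kP + 1L)
  k <- kA + kP
  nz <- which(w != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1L] - 1L; j <- nz[r, 2L] - 1L
    wt <- w[i + 1L, j + 1L]
    pooled2 <- 2L * (i + j)
    if (pooled2 < k) {
      out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + wt
    } else if (pooled2 > k) {
      out[kA - i + 1L, kP - j + 1L] <- out[kA - i + 1L, kP - j + 1L] + wt
    } else {
      out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + wt / 2
      out[kA - i + 1L, kP - j + 1L] <- out[kA - i + 1L, kP - j + 1L] + wt / 2
    }
  }
  out
}

#' Fold a joint SFS to minor-allele orientation
#'
#' Orientation is decided on the pooled (both groups) allele count: cells
#' with pooled count above half the total are reflected onto their
#' complement; cells at exactly half keep weight 0.5 on each orientation.
#' Folding an already folded spectrum is the identity.
#'
#' @param x a [JointSFS-class] object (folded or unfolded).
#' @return a folded [JointSFS-class] object.
#' @export
foldJointSFS <- function(x) {
  stopifnot(is(x, "JointSFS"))
  jointSFS(.fold_matrix(x@weights, x@kA, x@kP), x@kA, x@kP,
           masked = x@masked, meta = x@meta)
}

#' Project one site's genotypes to a fixed allele count
#'
#' Implements the downsampling rule used for joint-SFS construction: a site
#' is skipped for a group when more than \code{maxMissing} of its genotypes
#' are missing or fewer than \code{k} non-missing alleles remain; otherwise
#' \code{k} alleles are drawn at random without replacement (a hypergeometric
#' draw on the alternate-allele count).
#'
#' @param genos integer vector of dosages (0/1/2/NA) for one group.
#' @param k target allele count.
#' @param maxMissing maximum tolerated fraction of missing genotypes.
#' @return the drawn alternate-allele count (0..k), or \code{NA} if the site
#'   is skipped for this group.
#' @export
projectSiteCounts <- function(genos, k, maxMissing = 0.5) {
  stopifnot(k >= 1)
  miss <- is.na(genos)
  nAlleles <- 2L * sum(!miss)
  if (mean(miss) > maxMissing || nAlleles < k) return(NA_integer_)
  nAlt <- sum(genos[!miss])
  if (nAlleles == k) return(as.integer(nAlt))
  as.integer(rhyper(1L, m = nAlt, n = nAlleles - nAlt, k = k))
}

#' Build the folded joint minor-allele SFS from genotype data
#'
#' For every site, each group's genotypes are projected to \code{kA} /
#' \code{kP} alleles with [projectSiteCounts()] (sites failing the missing
#' data rule in either group are skipped), the pooled post-projection minor
#' allele determines orientation, and weight 1 is added to the corresponding
#' cell -- split 0.5/0.5 across the two orientations when the pooled
#' frequency is exactly 0.5. Sites monomorphic after projection fall into
#' the masked (0, 0) cell.
#'
#' @param x a [GenotypeData-class] object.
#' @param groups character vector of two distinct population labels, or a
#'   list of two disjoint sample-id vectors.
#' @param kA,kP projected allele counts per group.
#' @param maxMissing per-group missing-data ceiling (default 0.5).
#' @return a [JointSFS-class] object.
#' @export
buildJointSFS <- function(x, groups, kA = 14L, kP = 14L, maxMissing = 0.5) {
  stopifnot(is(x, "GenotypeData"))
  if (is.character(groups)) {
    stopifnot(length(groups) == 2L)
    pops <- populations(x)
    idx <- list(which(pops == groups[1L]), which(pops == groups[2L]))
  } else {
    stopifnot(is.list(groups), length(groups) == 2L)
    idx <- lapply(groups, function(g) match(g, colnames(x)))
  }
  if (length(intersect(idx[[1L]], idx[[2L]])) > 0L)
    stop("groups must not overlap")
  if (!length(idx[[1L]]) || !length(idx[[2L]]))
    stop("both groups must contain samples")
  gt <- genotypes(x)
  kA <- as.integer(kA); kP <- as.integer(kP)
  w <- matrix(0, kA + 1L, kP + 1L)
  n <- 0
  for (s in seq_len(nrow(gt))) {
    cA <- projectSiteCounts(gt[s, idx[[1L]]], kA, maxMissing)
    if (is.na(cA)) next
    cP <- projectSiteCounts(gt[s, idx[[2L]]], kP, maxMissing)
    if (is.na(cP)) next
    n <- n + 1
    pooled2 <- 2L * (cA + cP)
    k <- kA + kP
    if (pooled2 < k) {
      w[cA + 1L, cP + 1L] <- w[cA + 1L, cP + 1L] + 1
    } else if (pooled2 > k) {
      w[kA - cA + 1L, kP - cP + 1L] <- w[kA - cA + 1L, kP - cP + 1L] + 1
    } else {
      w[cA + 1L, cP + 1L] <- w[cA + 1L, cP + 1L] + 0.5
      w[kA - cA + 1L, kP - cP + 1L] <- w[kA - cA + 1L, kP - cP + 1L] + 0.5
    }
  }
  jointSFS(w, kA, kP, meta = list(skipped = nrow(gt) - n))
}

#' Write / read a joint SFS as TSV
#'
#' The spectrum is written as a tab-separated matrix with allele-count
#' header row and column, plus a sidecar metadata file (\code{<file>.meta})
#' recording kA, kP, the site total and the masked cells.
#'
#' @param x a [JointSFS-class] object.
#' @param file output path.
#' @return \code{writeJointSFS}: \code{file}, invisibly.
#' @export
writeJointSFS <- function(x, file) {
  stopifnot(is(x, "JointSFS"))
  w <- sfsWeights(x)
  df <- data.frame(d = rownames(w), w, check.names = FALSE)
  colnames(df) <- c("d", colnames(w))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- which(x@masked, arr.ind = TRUE) - 1L
  meta <- c(k_A = x@kA, k_P = x@kP, sites = x@nSites,
            seed = if (!is.null(x@meta$seed)) x@meta$seed else NA,
            masked = paste(sprintf("%d,%d", mk[, 1L], mk[, 2L]),
                           collapse = ";"))
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(file, ".meta"))
  invisible(file)
}

#' @rdname writeJointSFS
#' @return \code{readJointSFS}: the [JointSFS-class] object read back.
#' @export
readJointSFS <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  meta <- read.table(paste0(file, ".meta"), sep = "\t",
                     col.names = c("key", "value"), colClasses = "character")
  kv <- setNames(meta$value, meta$key)
  kA <- as.integer(kv[["k_A"]]); kP <- as.integer(kv[["k_P"]])
  masked <- matrix(FALSE, kA + 1L, kP + 1L)
  if (nzchar(kv[["masked"]])) {
    for (cell in strsplit(kv[["masked"]], ";")[[1L]]) {
      ij <- as.integer(strsplit(cell, ",")[[1L]])
      masked[ij[1L] + 1L, ij[2L] + 1L] <- TRUE
    }
  }
  seed <- suppressWarnings(as.numeric(kv[["seed"]]))
  jointSFS(w, kA, kP, masked = masked,
           meta = if (is.na(seed)) list() else list(seed = seed))
}
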