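#' Parse a PSMC time-interval pattern
#'
#' Patterns such as \code{"4*4 + 13*2 + 4*4 + 6"} describe how atomic time
#' intervals are grouped into free parameters: a term \code{a*b} contributes
#' \code{a} free parameters each spanning \code{b} atomic intervals; a bare
#' \code{b} contributes one parameter spanning \code{b} intervals.
#'
#' @param pattern the pattern string (whitespace ignored).
#' @return list with \code{nFreeParams}, \code{nIntervals} and \code{spans}
#'   (the per-parameter interval spans).
#' @examples
#' parsePsmcPattern("4*4 + 13*2 + 4*4 + 6")$nFreeParams   # 22
#' @export
parsePsmcPattern <- function(pattern) {
  terms <- strsplit(gsub("[[:space:]]", "", pattern), "+", fixed = TRUE)[[1L]]
  if (!length(terms) || !all(grepl("^[0-9]+(\\*[0-9]+)?$", terms)))
    stop("malformed PSMC pattern: ", pattern)
  spans <- unlist(lapply(terms, function(tm) {
    ab <- as.integer(strsplit(tm, "*", fixed = TRUE)[[1L]])
    if (length(ab) == 2L) rep(ab[2L], ab[1L]) else ab
  }))
  list(nFreeParams = length(spans), nIntervals = sum(spans), spans = spans)
}

#' Calibrate a mutation rate from interspecific divergence
#'
#' mu = (S / L) / (lineages * T / g): the per-site divergence between two
#' genomes divided by the number of generations separating them. With the
#' default \code{lineages = 2} the elapsed generations are counted along
#' both lineages since the species split (2T/g); \code{lineages = 1} gives
#' the single-lineage variant.
#'
#' @param S substitution count between the two genomes.
#' @param L aligned genome length in sites.
#' @param T_years species divergence time in years.
#' @param g generation time in years.
#' @param lineages 2 (both lineages, default) or 1.
#' @return mutation rate in substitutions per site per generation.
#' @examples
#' calibrateMutationRate(S = 9.24e6, L = 684e6, T_years = 1.9965e6, g = 2.5)
#' @export
calibrateMutationRate <- function(S, L, T_years, g, lineages = 2) {
  stopifnot(S >= 0, L > 0, T_years > 0, g > 0, lineages %in% c(1, 2))
  (S / L) / (lineages * T_years / g)
}

.windows_encode <- function(hets, callable, len, s) {
  nw <- ceiling(len / s)
  win <- function(p) (p - 1L) %/% s + 1L
  hetw <- tabulate(win(hets), nbins = nw)
  ncall <- if (is.null(callable)) rep(s, nw) else
    tabulate(win(which(callable)), nbins = nw)
  size <- c(rep(s, nw - 1L), len - (nw - 1L) * s)
  sym <- ifelse(ncall < 0.5 * size, "N", ifelse(hetw >= 1L, "K", "T"))
  list(sym = sym, hetw = hetw, isN = ncall < 0.5 * size)
}

#' Encode heterozygosity windows in psmcfa format
#'
#' Divides each scaffold into consecutive windows of \code{s} bases and
#' emits 'K' when the window contains at least one heterozygous site, 'T'
#' otherwise, and 'N' when more than half of the window's bases are
#' uncallable (e.g. outside consensus depth bounds). Scaffolds shorter than
#' \code{minScaffoldLen} are dropped. The encoding is returned as a named
#' character vector of symbol strings (one per scaffold), wrapped to
#' \code{lineWidth} symbols per line by [writePsmcfa()].
#'
#' @param hetPos named list of sorted 1-based heterozygous-site positions
#'   per scaffold.
#' @param scaffoldLen named integer vector of scaffold lengths.
#' @param callable optional named list of per-base logical callable masks
#'   (default: everything callable).
#' @param s window size in bases (default 20).
#' @param minScaffoldLen minimum scaffold length retained (default 10000).
#' @return named character vector of window-symbol strings.
#' @export
encodePsmcfa <- function(hetPos, scaffoldLen, callable = NULL, s = 20L,
                         minScaffoldLen = 10000L) {
  stopifnot(all(names(hetPos) %in% names(scaffoldLen)))
  out <- character()
  for (scf in names(scaffoldLen)) {
    len <- scaffoldLen[[scf]]
    if (len < minScaffoldLen) next
    hets <- if (scf %in% names(hetPos)) hetPos[[scf]] else integer()
    if (is.unsorted(hets)) stop("heterozygous positions must be sorted")
    if (length(hets) && (min(hets) < 1L || max(hets) > len))
      stop("heterozygous position outside scaffold ", scf)
    cal <- if (!is.null(callable) && scf %in% names(callable))
      callable[[scf]] else NULL
    enc <- .windows_encode(hets, cal, len, as.integer(s))
    out[scf] <- paste(enc$sym, collapse = "")
  }
  out
}

#' Write a psmcfa encoding to file
#'
#' @param enc named character vector from [encodePsmcfa()].
#' @param file output path.
#' @param lineWidth symbols per line (default 60).
#' @return \code{file}, invisibly.
#' @export
writePsmcfa <- function(enc, file, lineWidth = 60L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (scf in names(enc)) {
    writeLines(paste0(">", scf), con)
    x <- enc[[scf]]
    starts <- seq(1L, nchar(x), by = lineWidth)
    writeLines(substring(x, starts, pmin(starts + lineWidth - 1L, nchar(x))),
               con)
  }
  invisible(file)
}

#' Choose the psmcfa window size from the SNP density
#'
#' For each candidate window size, computes the fraction of callable
#' (non-'N') windows containing two or more heterozygous sites and returns
#' the candidate whose fraction is closest to \code{target} (ties go to the
#' smaller size). Window sizes are conventionally tuned so that about 1% of
#' windows contain two or more SNPs.
#'
#' @inheritParams encodePsmcfa
#' @param candidates candidate window sizes.
#' @param target desired fraction of multi-SNP windows (default 0.01).
#' @return the selected window size.
#' @export
tuneWindowSize <- function(hetPos, scaffoldLen, candidates, callable = NULL,
                           target = 0.01, minScaffoldLen = 10000L) {
  stopifnot(length(candidates) >= 1L)
  candidates <- sort(as.integer(candidates))
  frac <- vapply(candidates, function(s) {
    multi <- 0L; tot <- 0L
    for (scf in names(scaffoldLen)) {
      len <- scaffoldLen[[scf]]
      if (len < minScaffoldLen) next
      hets <- if (scf %in% names(hetPos)) hetPos[[scf]] else integer()
      cal <- if (!is.null(callable) && scf %in% names(callable))
        callable[[scf]] else NULL
      enc <- .windows_encode(hets, cal, len, s)
      ok <- !enc$isN
      tot <- tot + sum(ok)
      multi <- multi + sum(enc$hetw[ok] >= 2L)
    }
    if (tot == 0L) 0 else multi / tot
  }, numeric(1))
  candidates[which.min(abs(frac - target))]
}

#' Scale raw PSMC output to years and individuals
#'
#' PSMC reports a scaled mutation parameter theta0, relative sizes
#' lambda_k and scaled segment boundaries t_k; converting to natural units
#' requires the per-generation mutation rate, the generation time and the
#' input bin size: N0 = theta0 / (4 mu s), N_e(k) = N0 lambda_k,
#' time(k) = 2 N0 t_k g years.
#'
#' @param theta0 scaled mutation parameter from the PSMC output.
#' @param lambda relative population sizes per time segment.
#' @param t scaled segment boundaries (increasing).
#' @param s input window (bin) size in bases (default 20).
#' @param mu mutation rate per site per generation.
#' @param g generation time in years.
#' @return data.frame with columns timeYears and Ne.
#' @examples
#' scalePsmcOutput(0.00584, lambda = 1, t = 0, s = 20, mu = 7.3e-9, g = 2.5)
#' @export
scalePsmcOutput <- function(theta0, lambda, t, s = 20, mu, g) {
  stopifnot(length(lambda) == length(t), all(lambda > 0),
            !is.unsorted(t, strictly = TRUE))
  if (mu <= 0 || s <= 0) stop("mu and s must be positive")
  n0 <- theta0 / (4 * mu * s)
  data.frame(timeYears = 2 * n0 * t * g, Ne = n0 * lambda)
}
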