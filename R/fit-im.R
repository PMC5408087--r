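#' Configuration for IM-model fitting
#'
#' Replicate/loop protocol for simulated-SFS composite-likelihood
#' estimation: \code{nSets} independent replicate sets are run, each
#' spending \code{nLoops * simsPerLoop} coalescent simulations on a
#' derivative-free search that starts from log-uniform prior draws (a
#' cheap screen), refines the best draw with a Nelder-Mead simplex on
#' log-parameters under common random numbers, and scores the result with
#' one full-budget evaluation shared across sets. The \code{nBest}
#' best-fitting sets (smallest gap to the saturated likelihood) are
#' averaged into the reported estimates.
#'
#' @param nSets replicate sets (default 80).
#' @param nLoops estimation loops per set (default 40).
#' @param simsPerLoop coalescent simulations per likelihood evaluation
#'   (default 1e5).
#' @param nBest number of best-fitting sets summarized (default 10).
#' @param priors 6 x 2 matrix of log-uniform prior bounds, rows nAnc, nA,
#'   nP, tDiv, mPA, mAP.
#' @param mu fixed mutation rate per site per generation.
#' @return a classed list.
#' @export
fitConfig <- function(nSets = 80L, nLoops = 40L, simsPerLoop = 1e5,
                      nBest = 10L, priors = NULL, mu = 7.3e-9) {
  if (is.null(priors))
    priors <- rbind(nAnc = c(1e2, 1e6), nA = c(1e2, 1e6), nP = c(1e2, 1e6),
                    tDiv = c(1e2, 1e6), mPA = c(1e-5, 0.5), mAP = c(1e-5, 0.5))
  stopifnot(nBest <= nSets, all(priors[, 1L] > 0),
            all(priors[, 1L] < priors[, 2L]), mu > 0)
  structure(list(nSets = as.integer(nSets), nLoops = as.integer(nLoops),
                 simsPerLoop = simsPerLoop, nBest = as.integer(nBest),
                 priors = priors, mu = mu),
            class = "FitConfig")
}

.par_names <- c("nAnc", "nA", "nP", "tDiv", "mPA", "mAP")

#' Fit the two-population IM model to an observed joint SFS
#'
#' Estimates the six demographic parameters (three effective sizes,
#' divergence time, two migration rates; mutation rate fixed) by matching
#' simulated to observed folded joint spectra under the composite
#' likelihood of [compositeLogLik()]. The SNP-conditioned spectrum is
#' invariant under the rescaling (N, T) -> (cN, cT), m -> m/c, so absolute
#' sizes are identified only through the fixed-mu anchor: when
#' \code{nSites} (the number of sequenced sites the observed SNPs came
#' from) is supplied, a Poisson term on the SNP total with expectation
#' \code{nSites * mu * E[total branch length]} is added to the likelihood.
#' Without it the fit explores the scale-free ridge and only parameter
#' ratios and migration asymmetry are meaningful.
#'
#' Uses the session RNG; call [set.seed()] for reproducibility.
#'
#' @param obs a folded [JointSFS-class] of observed weights.
#' @param config a [fitConfig()].
#' @param nSites total sequence length that yielded the observed SNPs
#'   (anchors absolute sizes); \code{NULL} disables the anchor.
#' @param control coalescent engine settings from [simControl()].
#' @param verbose print per-set progress.
#' @return an [IMFit-class] object.
#' @export
fitIMModel <- function(obs, config = fitConfig(), nSites = NULL,
                       control = simControl(), verbose = FALSE) {
  stopifnot(is(obs, "JointSFS"), inherits(config, "FitConfig"))
  S <- sum(obs@weights[!obs@masked])
  if (S <= 0) stop("observed spectrum carries no unmasked weight")
  satM <- saturatedLogLik(obs)
  sat <- satM + if (!is.null(nSites)) S * log(S) - S else 0
  lb <- log(config$priors[, 1L]); ub <- log(config$priors[, 2L])
  eps <- 1 / (10 * config$simsPerLoop)

  # One likelihood evaluation: the folded SFS shape law is estimated by
  # simulation; the Poisson anchor on the SNP total is then maximized
  # analytically over the exact scale invariance (N, T) -> (cN, cT),
  # m -> m/c, which leaves the shape law and hence the composite term
  # untouched (a conditional-maximization step). Returns the profiled
  # parameters and the total log-likelihood.
  evalPar <- function(x, seed, sims = config$simsPerLoop) {
    set.seed(seed)
    p <- exp(x)
    res <- .sim_joint_sfs_cpp(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L],
                              obs@kA, obs@kP, sims, control)
    w <- .fold_matrix(res$lengths, obs@kA, obs@kP)
    probs <- w / sum(w)
    cll <- compositeLogLik(obs, probs, epsilon = eps)
    if (cll > satM + 1e-8)
      stop("internal error: composite likelihood exceeded the saturated bound")
    if (!is.null(nSites)) {
      ltot <- res$mean_total_length
      delta <- log(S / (nSites * config$mu * ltot))   # optimal log-scale shift
      dlo <- max(lb[1:4] - x[1:4], x[5:6] - ub[5:6])
      dhi <- min(ub[1:4] - x[1:4], x[5:6] - lb[5:6])
      delta <- min(max(delta, dlo), dhi)
      x <- x + c(rep(delta, 4L), rep(-delta, 2L))
      lambda <- nSites * config$mu * ltot * exp(delta)
      cll <- cll + S * log(lambda) - lambda
    }
    list(x = x, cll = cll)
  }

  # Per-set search, derivative-free, spending nLoops x simsPerLoop
  # simulations per set in a multi-fidelity layout:
  #  * a screen of cheap prior draws (one loop budget split across draws)
  #    localizes a promising region of the 6-dimensional log-space;
  #  * a Nelder-Mead simplex refines it on a surface frozen by one random
  #    substream (common random numbers make the comparisons nearly
  #    deterministic in the parameters), each evaluation at a fifth of the
  #    loop budget -- the simplex handles the strong ridge correlations
  #    between sizes, time and migration that defeat axis-wise moves;
  #  * one final full-budget evaluation under a substream shared by all
  #    sets makes the best-set ranking fair.
  freshSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)
  rankSeed <- freshSeed()
  nmIter <- max(10L, 2L * config$nLoops)

  sets <- vector("list", config$nSets)
  for (s in seq_len(config$nSets)) {
    seed0 <- freshSeed()
    nDraw <- 20L
    draws <- lapply(seq_len(nDraw), function(i)
      evalPar(lb + runif(6L) * (ub - lb), seed0,
              sims = max(200, config$simsPerLoop / nDraw)))
    x0 <- draws[[which.max(vapply(draws, `[[`, numeric(1), "cll"))]]$x
    negll <- function(x) -evalPar(pmin(pmax(x, lb), ub), seed0,
                                  sims = config$simsPerLoop / 2)$cll
    op <- stats::optim(x0, negll, method = "Nelder-Mead",
                       control = list(maxit = nmIter))
    ev <- evalPar(pmin(pmax(op$par, lb), ub), rankSeed,
                  sims = config$simsPerLoop)
    x <- ev$x; cll <- ev$cll
    sets[[s]] <- c(exp(x), cll = cll)
    if (verbose)
      message(sprintf("set %d/%d: CLL = %.2f (gap %.2f)",
                      s, config$nSets, cll, sat - cll))
  }
  df <- as.data.frame(do.call(rbind, sets))
  names(df) <- c(.par_names, "cll")
  df <- cbind(set = seq_len(config$nSets), df)
  df$saturated <- sat
  df$gap <- sat - df$cll
  sel <- selectBestReplicates(df, config$nBest)
  new("IMFit", sets = df, selected = sel$selected, summary = sel$summary,
      saturated = sat, anchored = !is.null(nSites))
}

#' Select the best-fitting replicate sets
#'
#' Ranks replicate sets by the gap between the estimated and the saturated
#' (observed) composite log-likelihood, ascending, keeps the first \code{n}
#' and reports the per-parameter mean and standard deviation across them.
#'
#' @param sets data.frame with the parameter columns and either a
#'   \code{gap} column or \code{cll} + \code{saturated} columns.
#' @param n number of sets to keep.
#' @return list with \code{selected} (the kept rows) and \code{summary}
#'   (data.frame: parameter, mean, sd).
#' @export
selectBestReplicates <- function(sets, n) {
  if (nrow(sets) < 1L) stop("no replicate sets given")
  stopifnot(n >= 1L, n <= nrow(sets))
  gap <- if ("gap" %in% names(sets)) sets$gap else sets$saturated - sets$cll
  keep <- sets[order(gap)[seq_len(n)], , drop = FALSE]
  pars <- intersect(.par_names, names(sets))
  list(selected = keep,
       summary = data.frame(
         parameter = pars,
         mean = vapply(pars, function(p) mean(keep[[p]]), numeric(1)),
         sd = vapply(pars, function(p) sd(keep[[p]]), numeric(1)),
         row.names = NULL))
}

#' Result of an IM-model fit
#'
#' @slot sets per-replicate-set table (parameters, composite log-likelihood,
#'   gap to the saturated likelihood).
#' @slot selected the best-fitting sets used for the summary.
#' @slot summary per-parameter mean and sd over the selected sets.
#' @slot saturated the saturated log-likelihood of the observed spectrum.
#' @slot anchored whether the fixed-mu Poisson anchor on the SNP total was
#'   active (absolute sizes are only meaningful when TRUE).
#' @export
setClass("IMFit",
  representation(sets = "data.frame", selected = "data.frame",
                 summary = "data.frame", saturated = "numeric",
                 anchored = "logical"))

#' @export
setMethod("show", "IMFit", function(object) {
  cat(sprintf("IMFit: %d replicate sets, %d selected (%s)\n",
              nrow(object@sets), nrow(object@selected),
              if (object@anchored) "mu-anchored" else
                "shape-only: absolute sizes not identified"))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %12.4g +/- %.4g\n", s$parameter[i], s$mean[i], s$sd[i]))
  cat(sprintf("  best likelihood gap: %.2f\n", min(object@sets$gap)))
})
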