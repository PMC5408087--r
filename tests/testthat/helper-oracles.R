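# Independent brute-force oracles, written as plain scalar loops so they
# share no code path with the package implementations they check.

# Weir & Cockerham (1984) variance components, two populations, one locus
# at a time; gt is a sites x samples dosage matrix.
oracle_wc_fst <- function(gt, pop, pair) {
  r <- 2
  sumA <- 0; sumAll <- 0
  for (l in seq_len(nrow(gt))) {
    n <- c(0, 0); p <- c(0, 0); h <- c(0, 0)
    for (k in 1:2) {
      g <- gt[l, pop == pair[k]]
      g <- g[!is.na(g)]
      n[k] <- length(g)
      if (n[k] > 0) {
        p[k] <- sum(g) / (2 * n[k])
        h[k] <- sum(g == 1) / n[k]
      }
    }
    if (any(n < 2)) next
    nbar <- (n[1] + n[2]) / 2
    nc <- (r * nbar - (n[1]^2 + n[2]^2) / (r * nbar)) / (r - 1)
    pbar <- (n[1] * p[1] + n[2] * p[2]) / (r * nbar)
    s2 <- (n[1] * (p[1] - pbar)^2 + n[2] * (p[2] - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n[1] * h[1] + n[2] * h[2]) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sumA <- sumA + a
    sumAll <- sumAll + a + b + cc
  }
  sumA / sumAll
}

# Nei (1987) corrected gene diversities, any number of populations.
oracle_nei_stats <- function(gt, pop, labs = unique(pop)) {
  r <- length(labs)
  HO <- c(); HS <- c(); HT <- c()
  for (l in seq_len(nrow(gt))) {
    n <- numeric(r); p <- numeric(r); h <- numeric(r)
    ok <- TRUE
    for (k in seq_len(r)) {
      g <- gt[l, pop == labs[k]]
      g <- g[!is.na(g)]
      if (length(g) < 1) { ok <- FALSE; break }
      n[k] <- length(g)
      p[k] <- sum(g) / (2 * n[k])
      h[k] <- sum(g == 1) / n[k]
    }
    if (!ok) next
    nh <- r / sum(1 / n)
    ho <- mean(h)
    msp2 <- mean(p^2 + (1 - p)^2)
    hs <- nh / (nh - 1) * (1 - msp2 - ho / (2 * nh))
    pb <- mean(p)
    ht <- 1 - (pb^2 + (1 - pb)^2) + hs / (nh * r) - ho / (2 * nh * r)
    HO <- c(HO, ho); HS <- c(HS, hs); HT <- c(HT, ht)
  }
  list(HO = mean(HO), HS = mean(HS), HT = mean(HT),
       FIS = 1 - mean(HO) / mean(HS),
       FST = (mean(HT) - mean(HS)) / mean(HT))
}

# Levene's conditional distribution of the heterozygote count, by direct
# enumeration of exact point probabilities.
oracle_levene <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- sapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) + lfactorial(nA) +
          lfactorial(na) - lfactorial(2 * n))
  })
  list(h = hs, p = pr, pHetExcess = sum(pr[hs >= nAa]),
       pHWE = sum(pr[pr <= pr[hs == nAa] * (1 + 1e-12)]))
}

# Holm step-down, hand-rolled.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    v <- (m - i + 1) * p[o[i]]
    run <- max(run, v)
    adj[o[i]] <- min(1, run)
  }
  adj
}

# analytic folded SFS of a panmictic constant-size population, k alleles
oracle_folded_eta <- function(k) {
  i <- seq_len(floor(k / 2))
  eta <- (1 / i + 1 / (k - i)) / (1 + (i == k - i))
  eta / sum(eta)
}

# small GenotypeData builder
make_gd <- function(gt, pop, scaffold = NULL, pos = NULL) {
  S <- nrow(gt)
  genotypeData(gt,
               scaffold = if (is.null(scaffold)) rep("s1", S) else scaffold,
               pos = if (is.null(pos)) seq_len(S) * 100L else pos,
               ref = rep("A", S), alt = rep("G", S), population = pop)
}
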