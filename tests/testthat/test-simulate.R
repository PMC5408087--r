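test_that("genealogies satisfy the coalescent-count and ordering identities", {
  set.seed(101)
  p <- IMParams(5000, 2000, 8000, tDiv = 10000, mPA = 1e-3, mAP = 5e-4)
  for (rep in 1:25) {
    nA <- sample(0:6, 1); nP <- sample(0:6, 1)
    if (nA + nP < 2) nP <- nP + 2
    g <- simulateGenealogy(p, nA, nP)
    expect_length(coalescenceTimes(g), nA + nP - 1L)
    expect_false(is.unsorted(coalescenceTimes(g)))
    expect_gt(totalBranchLength(g), 0)
  }
})

test_that("sampling fewer than two lineages is rejected", {
  p <- IMParams(1e4, 1e4, 1e4, 0)
  expect_error(simulateGenealogy(p, 1, 0), "two sampled lineages")
  expect_error(simulateGenealogy(p, 0, 0), "two sampled lineages")
})

test_that("isolated demes cannot coalesce before the divergence time", {
  set.seed(102)
  p <- IMParams(1e3, 1e3, 1e3, tDiv = 1000, mPA = 0, mAP = 0)
  t1 <- simulateCoalescenceTimes(p, 1, 1, reps = 200)
  expect_true(all(t1 > 1000))
})

test_that("isolated lineages with infinite divergence time raise an error", {
  p <- IMParams(1e3, 1e3, 1e3, tDiv = Inf, mPA = 0, mAP = 0)
  expect_error(simulateGenealogy(p, 1, 1), "never coalesce")
})

test_that("pairwise coalescence time averages 2N in a panmictic deme", {
  set.seed(103)
  p <- IMParams(1e4, 1e4, 1e4, tDiv = Inf)
  tt <- simulateCoalescenceTimes(p, 2, 0, reps = 2e4)
  expect_lt(abs(mean(tt) - 2e4) / 2e4, 0.03)
})

test_that("the panmictic folded SFS matches the analytic expectation", {
  set.seed(104)
  p <- IMParams(1e4, 1e4, 1e4, tDiv = 0)
  s <- simulateJointSFS(p, 14, 0, nSnps = 2e4)
  w <- s@weights
  props <- w[2:8, 1] / sum(w)
  expect_lt(max(abs(props - oracle_folded_eta(14))), 0.015)
})

test_that("a zero-SNP spectrum is all zero", {
  s <- simulateJointSFS(IMParams(1e4, 1e4, 1e4, 0), 6, 6, nSnps = 0)
  expect_equal(sum(s@weights), 0)
})

test_that("symmetric parameters give a statistically symmetric joint spectrum", {
  set.seed(105)
  p <- IMParams(5000, 3000, 3000, tDiv = 8000, mPA = 1e-3, mAP = 1e-3)
  s <- simulateJointSFS(p, 8, 8, nSnps = 2e4)
  w <- sfsWeights(s)
  # under axis exchange, paired off-diagonal counts are Binomial(n, 1/2)
  chi <- 0; df <- 0
  for (i in 1:9) for (j in seq_len(i - 1)) {
    tot <- w[i, j] + w[j, i]
    if (tot >= 10) { chi <- chi + (w[i, j] - tot / 2)^2 / (tot / 4); df <- df + 1 }
  }
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("mutation rate zero yields no variant sites", {
  set.seed(106)
  gd <- simulateGenotypes(IMParams(1e4, 1e4, 1e4, 0, mu = 0), c(4, 4), L = 1e4)
  expect_equal(nrow(gd), 0L)
})

test_that("panmictic nucleotide diversity is close to 4 N mu", {
  set.seed(107)
  p <- IMParams(1e4, 1e4, 1e4, tDiv = 0, mu = 1e-7)
  L <- 4e5
  gd <- simulateGenotypes(p, c(5, 5), L = L, locusLen = 500)
  gt <- genotypes(gd)
  n <- 2 * ncol(gt)
  freq <- rowSums(gt) / n
  pi_hat <- sum(2 * freq * (1 - freq) * n / (n - 1)) / L
  expect_lt(abs(pi_hat - 4e-3) / 4e-3, 0.15)
})

test_that("the two-deme equilibrium island model reproduces the F_ST closed forms", {
  # backward migration m per lineage, Nm = 0.25: Nei/G_ST-type (total
  # population) F_ST -> 1/(1+16Nm) = 0.2 and the two-deme Weir-Cockerham
  # expectation -> 1/(1+8Nm) = 1/3
  set.seed(108)
  p <- IMParams(1000, 1000, 1000, tDiv = Inf, mPA = 2.5e-4, mAP = 2.5e-4,
                mu = 1e-7)
  gd <- simulateGenotypes(p, c(8, 8), L = 5e5, locusLen = 500)
  nei <- neiBasicStats(gd)
  expect_lt(abs(nei@FSTNei - 0.2) / 0.2, 0.25)
  wc <- fstWeirCockerham(gd)
  expect_lt(abs(wc$fst - 1 / 3) / (1 / 3), 0.25)
})

test_that("the strong-migration collapse agrees with the forced-exact engine", {
  p <- IMParams(33000, 2000, 52000, 33000, mPA = 0.048, mAP = 0.003)
  exact <- simControl(strongFactor = Inf, maxExactEvents = 1e12)
  set.seed(109)
  sE <- simulateJointSFS(p, 8, 8, 4e3, fold = FALSE, expected = TRUE,
                         control = exact)
  set.seed(110)
  sH <- simulateJointSFS(p, 8, 8, 2e4, fold = FALSE, expected = TRUE)
  norm <- function(w) { w[1, 1] <- 0; w[9, 9] <- 0; w / sum(w) }
  tv <- 0.5 * sum(abs(norm(sE@weights) - norm(sH@weights)))
  expect_lt(tv, 0.04)
})

test_that("the simulator matches msprime on an asymmetric IM model", {
  # external oracle: msprime's structured coalescent, branch-mode joint SFS.
  # msprime's set_migration_rate(source, dest) is the backwards-in-time
  # lineage movement source -> dest, so forward mPA (P -> A individuals,
  # i.e. lineages A -> P backwards) maps to source="A", dest="P"; sizes are
  # per-ploidy, so diploid N maps to initial_size = 2N with ploidy = 1.
  script <- c(
    "import json, msprime, numpy as np",
    "NA, NP, NANC, TDIV, mPA, mAP = 5000., 5000., 5000., 20000., 2e-4, 1e-4",
    "kA, kP, reps = 6, 6, 2000",
    "dem = msprime.Demography()",
    "dem.add_population(name='A', initial_size=2*NA)",
    "dem.add_population(name='P', initial_size=2*NP)",
    "dem.add_population(name='ANC', initial_size=2*NANC)",
    "dem.set_migration_rate(source='A', dest='P', rate=mPA)",
    "dem.set_migration_rate(source='P', dest='A', rate=mAP)",
    "dem.add_population_split(time=TDIV, derived=['A','P'], ancestral='ANC')",
    "acc = np.zeros((kA+1, kP+1))",
    "for ts in msprime.sim_ancestry(samples={'A': kA, 'P': kP}, demography=dem,",
    "        ploidy=1, num_replicates=reps, random_seed=11):",
    "    acc += ts.allele_frequency_spectrum(",
    "        sample_sets=[list(range(kA)), list(range(kA, kA+kP))],",
    "        mode='branch', polarised=True, span_normalise=False)",
    "print(json.dumps(acc.tolist()))")
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", py, stdout = TRUE)
  m <- jsonlite::fromJSON(paste(out, collapse = ""))
  set.seed(111)
  s <- simulateJointSFS(IMParams(5000, 5000, 5000, 20000, 2e-4, 1e-4),
                        6, 6, 3e4, fold = FALSE, expected = TRUE)
  norm <- function(w) { w[1, 1] <- 0; w[7, 7] <- 0; w / sum(w) }
  tv <- 0.5 * sum(abs(norm(s@weights) - norm(m)))
  # combined Monte-Carlo noise of the two estimates is ~0.02-0.03 TV;
  # a reversed migration orientation would sit near 0.07
  expect_lt(tv, 0.045)
})

test_that("identical seeds reproduce identical spectra and genotypes", {
  p <- IMParams(4000, 2000, 6000, 5000, 1e-3, 2e-3, mu = 1e-7)
  set.seed(42); a <- simulateJointSFS(p, 6, 6, 5000)
  set.seed(42); b <- simulateJointSFS(p, 6, 6, 5000)
  expect_identical(a@weights, b@weights)
  set.seed(43); ga <- simulateGenotypes(p, c(3, 3), 5e4)
  set.seed(43); gb <- simulateGenotypes(p, c(3, 3), 5e4)
  expect_identical(genotypes(ga), genotypes(gb))
  expect_identical(siteTable(ga), siteTable(gb))
})
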