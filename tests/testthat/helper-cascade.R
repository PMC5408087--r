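# shared fixture construction and cascade driver for the two-caller tests

make_fixture <- function(seed, config = filterConfig(maf = 0.03)) {
  set.seed(seed)
  p <- IMParams(10000, 10000, 10000, 0, mu = 2e-7)
  gd <- simulateGenotypes(p, c(20, 20), L = 3e5)
  dir <- tempfile("fx")
  fx <- makeCallerFixture(gd, dir, config = config)
  fx
}

run_cascade <- function(fx) {
  a <- readVcfGenotypes(fx$vcfA)
  b <- readVcfGenotypes(fx$vcfB)
  common <- intersectCallsets(siteTable(a), siteTable(b))
  hard <- hardFilterSites(common, fx$config)
  keys <- paste(hard$scaffold, hard$pos)
  aKeys <- paste(siteTable(a)$scaffold, siteTable(a)$pos)
  sub <- a[aKeys %in% keys, ]
  masked <- maskGenotypes(sub, fx$config)
  res <- siteFilterPipeline(masked, fx$config)
  paste(siteTable(res$data)$scaffold, siteTable(res$data)$pos)
}

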