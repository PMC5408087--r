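aln4 <- haplotypeAlignment(c(h1 = "ACGT", h2 = "ACGA", h3 = "GCGT",
                             h4 = "ACGT"))

test_that("identical sequences collapse to a single node with score zero", {
  aln <- haplotypeAlignment(c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"))
  tre <- parsimonyTree(aln)
  expect_null(tre)
  g <- buildHaplotypeGraph(tre, fitchSubstitutions(tre, aln), aln)
  s <- graphSummary(g)
  expect_equal(s$sampledNodes, 1L)
  expect_equal(s$intermediateNodes, 0L)
  expect_equal(s$totalEdgeWeight, 0L)
  expect_equal(s$largestNodeSize, 3L)
})

test_that("a supported split is recovered with score equal to the variable sites", {
  # two clades (t1,t2) vs (t3,t4) supported by two binary characters;
  # two additional autapomorphies
  aln <- haplotypeAlignment(c(t1 = "AAAA", t2 = "AATA", t3 = "CCAA",
                              t4 = "CCAC"))
  tre <- parsimonyTree(aln)
  expect_equal(attr(tre, "score"), 4L)
  # the minimum tree separates {t1,t2} from {t3,t4}
  sub <- fitchSubstitutions(tre, aln)
  expect_equal(nrow(sub), 4L)
  # sites 1 and 2 change on the same (internal) edge
  expect_equal(length(unique(sub$edge[sub$site %in% c(1, 2)])), 1L)
})

test_that("invariant sites yield no substitutions and one difference maps once", {
  aln <- haplotypeAlignment(c(x = "AAAA", y = "AAAG"))
  tre <- parsimonyTree(aln)
  sub <- fitchSubstitutions(tre, aln)
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$site, 4L)
  expect_setequal(c(sub$from, sub$to), c("A", "G"))
})

test_that("total Fitch assignments equal the parsimony score on random alignments", {
  set.seed(91)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    len <- 12
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
    names(seqs) <- paste0("s", seq_len(n))
    aln <- haplotypeAlignment(seqs)
    tre <- parsimonyTree(aln)
    sub <- fitchSubstitutions(tre, aln)
    expect_equal(nrow(sub), attr(tre, "score"))
  }
})

test_that("exhaustive search attains the brute-force minimum score (phangorn oracle)", {
  set.seed(92)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10,
                                      replace = TRUE), collapse = ""))
    names(seqs) <- paste0("s", seq_len(n))
    aln <- haplotypeAlignment(seqs)
    tre <- parsimonyTree(aln)
    ph <- phangorn::phyDat(do.call(rbind, strsplit(tolower(seqs), "")))
    best <- min(vapply(phangorn::allTrees(n, tip.label = names(seqs)),
                       function(tr) phangorn::parsimony(tr, ph), numeric(1)))
    expect_equal(attr(tre, "score"), as.integer(best))
  }
})

test_that("transition-only neighbours merge into one node under the transversion metric", {
  aln <- haplotypeAlignment(c(a = "ACGT", b = "ACGC"))  # T<->C transition
  tre <- parsimonyTree(aln)
  g <- buildHaplotypeGraph(tre, fitchSubstitutions(tre, aln), aln,
                           transversionsOnly = TRUE)
  s <- graphSummary(g)
  expect_equal(s$sampledNodes, 1L)
  expect_equal(s$largestNodeSize, 2L)
  expect_equal(nrow(g@edges), 0L)
})

test_that("the four-sequence worked example gives the documented graph", {
  tre <- parsimonyTree(aln4)
  sub <- fitchSubstitutions(tre, aln4)
  g <- buildHaplotypeGraph(tre, sub, aln4, transversionsOnly = TRUE)
  s <- graphSummary(g)
  expect_equal(s$sampledNodes, 2L)
  expect_equal(s$intermediateNodes, 0L)
  expect_equal(s$totalEdgeWeight, 1L)
  expect_equal(s$largestNodeSize, 3L)
  szs <- sort(g@nodes$size)
  expect_equal(szs, c(1L, 3L))
  big <- which(g@nodes$size == 3L)
  expect_setequal(g@members[[big]], c("h1", "h3", "h4"))
})

test_that("a star of transversion-separated haplotypes keeps an intermediate hub", {
  aln <- haplotypeAlignment(c(u = "CAA", v = "ACA", w = "AAC"))
  tre <- parsimonyTree(aln)
  sub <- fitchSubstitutions(tre, aln)
  g <- buildHaplotypeGraph(tre, sub, aln, transversionsOnly = TRUE)
  s <- graphSummary(g)
  expect_equal(s$sampledNodes, 3L)
  expect_equal(s$intermediateNodes, 1L)
  expect_equal(s$totalEdgeWeight, 3L)
  expect_equal(s$largestNodeSize, 1L)
  expect_true(all(g@edges$weight == 1L))
})

test_that("node sizes always sum to the number of sequences", {
  set.seed(93)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                      replace = TRUE,
                                      prob = c(0.4, 0.3, 0.2, 0.1)),
                               collapse = ""))
    names(seqs) <- paste0("s", seq_len(n))
    aln <- haplotypeAlignment(seqs)
    tre <- parsimonyTree(aln)
    sub <- fitchSubstitutions(tre, aln)
    for (flag in c(FALSE, TRUE)) {
      g <- buildHaplotypeGraph(tre, sub, aln, transversionsOnly = flag)
      expect_equal(sum(g@nodes$size), n)
    }
    gAll <- buildHaplotypeGraph(tre, sub, aln, FALSE)
    gTv <- buildHaplotypeGraph(tre, sub, aln, TRUE)
    expect_lte(sum(gTv@edges$weight), sum(gAll@edges$weight))
  }
})

test_that("repeated seeded searches give the same node partition", {
  set.seed(94)
  seqs <- replicate(10, paste(sample(c("A", "C", "G", "T"), 20,
                                     replace = TRUE,
                                     prob = c(0.5, 0.3, 0.1, 0.1)),
                              collapse = ""))
  names(seqs) <- paste0("s", 1:10)
  aln <- haplotypeAlignment(seqs)
  partition <- function(g)
    sort(vapply(g@members[lengths(g@members) > 0],
                function(m) paste(sort(m), collapse = "+"), character(1)))
  ref <- NULL
  for (seed in 1:5) {
    set.seed(seed)
    tre <- parsimonyTree(aln)
    g <- buildHaplotypeGraph(tre, fitchSubstitutions(tre, aln), aln,
                             transversionsOnly = TRUE)
    if (is.null(ref)) ref <- partition(g) else
      expect_equal(partition(g), ref)
  }
})

test_that("FASTA round trip, site composition and DOT output work together", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "CAA", ">b", "ACA", ">c", "AAC", ">d", "CAA"), f)
  sm <- tempfile()
  writeLines(c("a\tATL", "b\tPAC", "c\tPAC", "d\tATL"), sm)
  aln <- readHaplotypeAlignment(f, sm)
  expect_equal(nrow(aln@seqs), 4L)
  tre <- parsimonyTree(aln)
  g <- buildHaplotypeGraph(tre, fitchSubstitutions(tre, aln), aln,
                           transversionsOnly = TRUE)
  s <- graphSummary(g)
  expect_equal(s$sampledNodes, 3L)
  comp <- s$composition[[which(g@nodes$size == 2L)]]
  expect_equal(unname(comp[["ATL"]]), 2L)
  dot <- tempfile(fileext = ".dot")
  writeHaploGraphDot(g, dot)
  ln <- readLines(dot)
  expect_equal(ln[1], "graph haplotypes {")
  expect_equal(sum(grepl("--", ln, fixed = TRUE)), nrow(g@edges))
})
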