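#' Haplotype sequence alignment
#'
#' Equal-length aligned haplotype sequences (alphabet A/C/G/T plus N and
#' '-', which are treated as missing) with unique labels and an optional
#' label-to-sampling-site mapping used for node composition in the
#' genealogy graph.
#'
#' @slot seqs character matrix, one row per sequence, one column per
#'   alignment position, uppercase.
#' @slot siteMap named character vector mapping sequence labels to sampling
#'   sites (may be empty).
#' @export
setClass("HaplotypeAlignment",
  representation(seqs = "matrix", siteMap = "character"))

setValidity("HaplotypeAlignment", function(object) {
  if (ncol(object@seqs) < 1L) return("alignment has length zero")
  if (is.null(rownames(object@seqs)) ||
      anyDuplicated(rownames(object@seqs)))
    return("sequence labels must be present and unique")
  TRUE
})

#' Construct a haplotype alignment
#'
#' @param seqs character vector of equal-length sequence strings (named),
#'   or a character matrix with one row per sequence.
#' @param labels sequence labels (default names of \code{seqs}).
#' @param siteMap optional named vector label -> sampling site.
#' @return a [HaplotypeAlignment-class] object.
#' @export
haplotypeAlignment <- function(seqs, labels = names(seqs),
                               siteMap = character()) {
  if (!is.matrix(seqs)) {
    if (length(unique(nchar(seqs))) != 1L)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- if (is.null(labels))
      sprintf("seq%d", seq_along(seqs)) else labels
  } else {
    m <- toupper(seqs)
    if (!is.null(labels)) rownames(m) <- labels
  }
  new("HaplotypeAlignment", seqs = m,
      siteMap = if (is.null(siteMap)) character() else siteMap)
}

#' Read a haplotype alignment from FASTA
#'
#' @param file FASTA path.
#' @param siteMapFile optional two-column TSV (label, site).
#' @return a [HaplotypeAlignment-class] object.
#' @export
readHaplotypeAlignment <- function(file, siteMapFile = NULL) {
  dna <- ape::read.FASTA(file)
  m <- toupper(as.character(as.matrix(dna)))
  sm <- character()
  if (!is.null(siteMapFile)) {
    tab <- read.table(siteMapFile, sep = "\t", header = FALSE,
                      col.names = c("label", "site"),
                      colClasses = "character")
    sm <- setNames(tab$site, tab$label)
  }
  new("HaplotypeAlignment", seqs = m, siteMap = sm)
}

#' @export
setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment: %d sequences x %d positions (%d distinct haplotypes)\n",
              nrow(object@seqs), ncol(object@seqs),
              length(unique(apply(object@seqs, 1L, paste, collapse = "")))))
})

# ---- internal: haplotype grouping and Fitch machinery -----------------------

.hap_groups <- function(aln) {
  key <- apply(aln@seqs, 1L, paste, collapse = "")
  split(rownames(aln@seqs), factor(key, levels = unique(key)))
}

.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.bit_first <- function(bits) c("A", "C", "G", "T")[match(TRUE, bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)]

.is_transversion <- function(from, to) {
  pur <- c("A", "G")
  (from %in% pur) != (to %in% pur)
}

# Root an unrooted phylo (basal trifurcation) on the edge to the first
# basal child, giving a strictly binary rooted tree. Returns children
# lists, a postorder, and the map from each node's stem branch back to the
# original tree edge (both halves of the split edge map to it).
.rooted_binary <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  kids <- vector("list", nnode + 1L)
  edgeOf <- rep(NA_integer_, nnode + 1L)
  for (r in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[r, 1L]]] <- c(kids[[phy$edge[r, 1L]]], phy$edge[r, 2L])
    edgeOf[phy$edge[r, 2L]] <- r
  }
  root <- ntip + 1L
  if (length(kids[[root]]) > 2L) {
    c1 <- kids[[root]][1L]
    kids[[root]] <- kids[[root]][-1L]
    newRoot <- nnode + 1L
    kids[[newRoot]] <- c(c1, root)
    edgeOf[root] <- edgeOf[c1]        # both halves of the split edge
  } else newRoot <- root
  post <- integer(0); stack <- newRoot
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(v, post)
    stack <- c(stack, kids[[v]])
  }
  list(ntip = ntip, kids = kids, root = newRoot, post = post,
       edgeOf = edgeOf)
}

# Fitch parsimony length of an unrooted tree (phylo) for bitmask columns
.fitch_score <- function(phy, bits) {
  rb <- .rooted_binary(phy)
  total <- 0L
  for (s in seq_len(ncol(bits))) {
    st <- integer(length(rb$kids))
    st[seq_len(rb$ntip)] <- bits[, s]
    for (v in rb$post) {
      if (v <= rb$ntip) next
      ch <- rb$kids[[v]]
      b <- bitwAnd(st[ch[1L]], st[ch[2L]])
      if (b == 0L) { total <- total + 1L; b <- bitwOr(st[ch[1L]], st[ch[2L]]) }
      st[v] <- b
    }
  }
  total
}

# bitmask matrix (tips x sites) for the variable sites of distinct haplotypes
.hap_bits <- function(seqs) {
  bits <- matrix(15L, nrow(seqs), ncol(seqs))
  for (b in names(.base_bits)) bits[seqs == b] <- .base_bits[[b]]
  bits
}

.variable_sites <- function(bits) {
  which(apply(bits, 2L, function(col) {
    obs <- unique(col[col %in% .base_bits])
    length(obs) >= 2L
  }))
}

# enumerate all unrooted binary topologies on k >= 3 tips (edge matrices)
.all_topologies <- function(k) {
  base <- matrix(c(k + 1L, 1L, k + 1L, 2L, k + 1L, 3L), ncol = 2L,
                 byrow = TRUE)
  trees <- list(list(edge = base, nextId = k + 2L))
  if (k == 3L) return(trees)
  for (tip in 4L:k) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        w <- tr$nextId
        edge <- tr$edge
        u <- edge[e, 1L]; v <- edge[e, 2L]
        edge[e, ] <- c(u, w)
        edge <- rbind(edge, c(w, v), c(w, tip))
        nxt[[length(nxt) + 1L]] <- list(edge = edge, nextId = w + 1L)
      }
    }
    trees <- nxt
  }
  trees
}

.edges_to_phylo <- function(edge, k, tipLabels) {
  # internal ids are k+1.. in creation order with k+1 the basal trifurcation
  structure(list(edge = edge, Nnode = max(edge) - k, tip.label = tipLabels),
            class = "phylo", order = "cladewise")
}

# all NNI neighbours of an unrooted tree given as a phylo
.nni_neighbours <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- list()
  internal <- which(phy$edge[, 2L] > ntip)
  for (e in internal) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    uKids <- setdiff(phy$edge[phy$edge[, 1L] == u, 2L], v)
    vKids <- phy$edge[phy$edge[, 1L] == v, 2L]
    if (!length(uKids) || length(vKids) < 2L) next
    a <- uKids[1L]
    for (cIdx in seq_along(vKids)) {
      edge <- phy$edge
      cNode <- vKids[cIdx]
      ra <- which(edge[, 1L] == u & edge[, 2L] == a)
      rc <- which(edge[, 1L] == v & edge[, 2L] == cNode)
      edge[ra, 2L] <- cNode
      edge[rc, 2L] <- a
      out[[length(out) + 1L]] <- structure(
        list(edge = edge, Nnode = phy$Nnode, tip.label = phy$tip.label),
        class = "phylo", order = "cladewise")
    }
  }
  out
}

#' Maximum-parsimony tree of the distinct haplotypes
#'
#' Collapses identical sequences into distinct haplotypes and searches for
#' a minimum-Fitch-length unrooted tree: exhaustively over all topologies
#' when there are at most \code{maxExhaustive} (default 8) distinct
#' haplotypes (guaranteed optimum), otherwise by nearest-neighbour-
#' interchange hill climbing from a neighbour-joining start tree. Gaps and
#' N are treated as missing. Tip labels are the first member label of each
#' haplotype group.
#'
#' @param aln a [HaplotypeAlignment-class] object.
#' @param maxExhaustive exhaustive-search ceiling on distinct haplotypes.
#' @return an unrooted \code{phylo} tree with attributes \code{score}
#'   (Fitch parsimony length) and \code{groups} (members per tip); a
#'   two-haplotype alignment gives the single two-tip tree, and a single
#'   haplotype gives \code{NULL} (the downstream graph is then one node).
#' @export
parsimonyTree <- function(aln, maxExhaustive = 8L) {
  stopifnot(is(aln, "HaplotypeAlignment"))
  groups <- .hap_groups(aln)
  reps <- vapply(groups, `[`, character(1L), 1L)
  k <- length(groups)
  seqs <- aln@seqs[reps, , drop = FALSE]
  bits <- .hap_bits(seqs)
  vs <- .variable_sites(bits)
  bits <- bits[, vs, drop = FALSE]
  if (k == 1L) return(NULL)   # single haplotype: no tree, graph is one node
  if (k == 2L) {
    tre <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, byrow = TRUE),
                          Nnode = 1L, tip.label = reps),
                     class = "phylo", order = "cladewise")
    attr(tre, "score") <- .fitch_score(tre, bits)
    attr(tre, "groups") <- groups
    return(tre)
  }
  if (k <= maxExhaustive) {
    best <- NULL; bestScore <- Inf
    for (tr in .all_topologies(k)) {
      phy <- .edges_to_phylo(tr$edge, k, reps)
      sc <- .fitch_score(phy, bits)
      if (sc < bestScore) { bestScore <- sc; best <- phy }
    }
  } else {
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      ok <- bits[i, ] %in% .base_bits & bits[j, ] %in% .base_bits
      d[i, j] <- d[j, i] <- sum(bits[i, ok] != bits[j, ok])
    }
    dimnames(d) <- list(reps, reps)
    best <- ape::unroot(ape::nj(stats::as.dist(d)))
    best$edge.length <- NULL
    bestScore <- .fitch_score(best, bits)
    repeat {
      improved <- FALSE
      for (nb in .nni_neighbours(best)) {
        sc <- .fitch_score(nb, bits)
        if (sc < bestScore) { best <- nb; bestScore <- sc; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  attr(best, "score") <- bestScore
  attr(best, "groups") <- groups
  best
}

#' Most-parsimonious substitution placement (Fitch)
#'
#' Runs the Fitch down-pass/up-pass on each variable site of the alignment
#' restricted to the tree's tips, breaking state ties by the fixed alphabet
#' order A < C < G < T, and reports one most-parsimonious substitution set:
#' per tree edge the list of (site, from, to) changes. Gaps and N are
#' missing and never generate substitutions.
#'
#' @param tree an unrooted \code{phylo} (e.g. from [parsimonyTree()]), or
#'   \code{NULL} for the degenerate single-haplotype case.
#' @param aln the [HaplotypeAlignment-class] the tree tips belong to.
#' @return data.frame with columns edge (row of \code{tree$edge}), site,
#'   from, to.
#' @export
fitchSubstitutions <- function(tree, aln) {
  stopifnot(is(aln, "HaplotypeAlignment"))
  empty <- data.frame(edge = integer(), site = integer(),
                      from = character(), to = character())
  if (is.null(tree)) return(empty)
  if (!all(tree$tip.label %in% rownames(aln@seqs)))
    stop("tree tips must be labelled with alignment sequence labels")
  seqs <- aln@seqs[tree$tip.label, , drop = FALSE]
  bitsAll <- .hap_bits(seqs)
  vs <- .variable_sites(bitsAll)
  if (!length(vs)) return(empty)
  rb <- .rooted_binary(tree)
  parentOf <- rep(NA_integer_, length(rb$kids))
  for (v in seq_along(rb$kids))
    for (ch in rb$kids[[v]]) parentOf[ch] <- v
  res <- list()
  for (s in vs) {
    st <- integer(length(rb$kids))
    st[seq_len(rb$ntip)] <- bitsAll[, s]
    # down-pass on the edge-rooted binary tree
    for (v in rb$post) {
      if (v <= rb$ntip) next
      ch <- rb$kids[[v]]
      b <- bitwAnd(st[ch[1L]], st[ch[2L]])
      st[v] <- if (b == 0L) bitwOr(st[ch[1L]], st[ch[2L]]) else b
    }
    # up-pass assignment with alphabet-order tie-breaking
    asg <- character(length(rb$kids))
    for (v in rev(rb$post)) {
      if (v == rb$root) { asg[v] <- .bit_first(st[v]); next }
      par <- parentOf[v]
      pbit <- .base_bits[[asg[par]]]
      asg[v] <- if (bitwAnd(st[v], pbit) > 0L) asg[par] else .bit_first(st[v])
      if (asg[v] != asg[par] && st[v] != 15L)
        res[[length(res) + 1L]] <- data.frame(
          edge = rb$edgeOf[v], site = s, from = asg[par], to = asg[v])
    }
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

#' Haplotype genealogy graph
#'
#' @slot nodes data.frame: id, size (sampled-sequence count), intermediate
#'   flag.
#' @slot members list of member sequence labels per node (empty for
#'   intermediates).
#' @slot composition list of per-node sampling-site count tables.
#' @slot edges data.frame: from, to, weight (substitution count under the
#'   active metric).
#' @slot metric "all" or "transversions".
#' @export
setClass("HaploGraph",
  representation(nodes = "data.frame", members = "list",
                 composition = "list", edges = "data.frame",
                 metric = "character"))

setValidity("HaploGraph", function(object) {
  if (nrow(object@edges) && any(object@edges$weight < 1))
    return("edge weights must be >= 1 (zero-weight edges are contracted)")
  TRUE
})

#' Build the haplotype genealogy graph from a parsimony tree
#'
#' Weights every tree edge by its substitution count -- transversions only
#' (A<->C, A<->T, G<->C, G<->T) when \code{transversionsOnly} -- contracts
#' all zero-weight edges (merging their endpoint haplotype sets, so that
#' sequences identical or separated only by transitions share one node),
#' and keeps contraction survivors without sampled members as intermediate
#' (unsampled) nodes. Edge weights retain the full multi-substitution
#' count.
#'
#' @param tree unrooted \code{phylo} from [parsimonyTree()] (or \code{NULL}
#'   for a single haplotype).
#' @param assignments substitution table from [fitchSubstitutions()].
#' @param aln the underlying [HaplotypeAlignment-class].
#' @param transversionsOnly ignore transitions in edge weights.
#' @return a [HaploGraph-class] object.
#' @export
buildHaplotypeGraph <- function(tree, assignments, aln,
                                transversionsOnly = FALSE) {
  stopifnot(is(aln, "HaplotypeAlignment"))
  groups <- .hap_groups(aln)
  metric <- if (transversionsOnly) "transversions" else "all"
  siteOf <- function(members) {
    if (!length(aln@siteMap)) return(table(character()))
    table(unname(aln@siteMap[members]))
  }
  if (is.null(tree)) {
    members <- list(unlist(groups, use.names = FALSE))
    return(new("HaploGraph",
               nodes = data.frame(id = 1L, size = length(members[[1L]]),
                                  intermediate = FALSE),
               members = members, composition = list(siteOf(members[[1L]])),
               edges = data.frame(from = integer(), to = integer(),
                                  weight = integer()),
               metric = metric))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  wts <- integer(nrow(tree$edge))
  if (nrow(assignments)) {
    counted <- if (transversionsOnly)
      assignments[.is_transversion(assignments$from, assignments$to), ] else
      assignments
    if (nrow(counted)) {
      tb <- table(counted$edge)
      wts[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  # union-find contraction of zero-weight edges
  parent <- seq_len(nnode)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in which(wts == 0L))
    parent[find(tree$edge[r, 1L])] <- find(tree$edge[r, 2L])
  comp <- vapply(seq_len(nnode), find, integer(1L))
  # members per component (tips carry their haplotype group's sequences)
  tipMembers <- groups[match(tree$tip.label,
                             vapply(groups, `[`, character(1L), 1L))]
  compIds <- unique(comp)
  members <- lapply(compIds, function(cid)
    unlist(tipMembers[which(comp[seq_len(ntip)] == cid)], use.names = FALSE))
  keep <- rep(TRUE, length(compIds))
  # intermediate nodes: contraction survivors with no sampled members that
  # remain as junctions of the positive-weight edges
  edgeList <- data.frame(
    from = match(comp[tree$edge[wts > 0L, 1L]], compIds),
    to = match(comp[tree$edge[wts > 0L, 2L]], compIds),
    weight = wts[wts > 0L])
  sizes <- lengths(members)
  deg <- tabulate(c(edgeList$from, edgeList$to), nbins = length(compIds))
  # unsampled leaves/pass-throughs cannot occur on a binary tree; any
  # unsampled component retained here is a genuine junction
  nodes <- data.frame(id = seq_along(compIds), size = sizes,
                      intermediate = sizes == 0L)
  composition <- lapply(members, siteOf)
  new("HaploGraph", nodes = nodes, members = members,
      composition = composition, edges = edgeList, metric = metric)
}

#' Summary counts of a haplotype genealogy graph
#'
#' @param graph a [HaploGraph-class] object.
#' @return list with sampledNodes, intermediateNodes, totalEdgeWeight,
#'   largestNodeSize and composition (per-node sampling-site tables).
#' @export
graphSummary <- function(graph) {
  stopifnot(is(graph, "HaploGraph"))
  list(sampledNodes = sum(!graph@nodes$intermediate),
       intermediateNodes = sum(graph@nodes$intermediate),
       totalEdgeWeight = sum(graph@edges$weight),
       largestNodeSize = max(graph@nodes$size),
       composition = graph@composition)
}

#' @export
setMethod("show", "HaploGraph", function(object) {
  s <- graphSummary(object)
  cat(sprintf("HaploGraph (%s metric): %d sampled + %d intermediate nodes, %d edges\n",
              object@metric, s$sampledNodes, s$intermediateNodes,
              nrow(object@edges)))
  cat(sprintf("  total edge weight %d, largest node %d sequences\n",
              s$totalEdgeWeight, s$largestNodeSize))
})

#' Write a haplotype genealogy graph in DOT (GraphViz) format
#'
#' Nodes carry size and composition attributes; intermediates are drawn as
#' points.
#'
#' @param graph a [HaploGraph-class] object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeHaploGraphDot <- function(graph, file) {
  ln <- c("graph haplotypes {", "  node [shape=circle];")
  for (i in seq_len(nrow(graph@nodes))) {
    if (graph@nodes$intermediate[i]) {
      ln <- c(ln, sprintf("  n%d [shape=point, label=\"\"];", i))
    } else {
      comp <- graph@composition[[i]]
      lab <- if (length(comp))
        paste(names(comp), comp, sep = ":", collapse = ",") else
        sprintf("%d", graph@nodes$size[i])
      ln <- c(ln, sprintf("  n%d [label=\"%s\", width=%.2f];",
                          i, lab, 0.3 + 0.15 * sqrt(graph@nodes$size[i])))
    }
  }
  for (r in seq_len(nrow(graph@edges)))
    ln <- c(ln, sprintf("  n%d -- n%d [label=\"%d\", len=%d];",
                        graph@edges$from[r], graph@edges$to[r],
                        graph@edges$weight[r], graph@edges$weight[r]))
  ln <- c(ln, "}")
  writeLines(ln, file)
  invisible(file)
}
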