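# Independent oracles used across the suite. Each re-derives the
# quantity under test by a different route from the implementation:
# full-matrix R dynamic programming for alignment scores, phangorn for
# parsimony scores and all-topology enumeration, explicit edge walks
# for bipartitions, and plain column scans for alignment statistics.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Brute-force Gotoh DP oracle: full (m+1)x(n+1) matrices in plain R,
# affine gaps costing open + k*ext, free end gaps in both sequences
# (the empty alignment, score 0, is admissible). Returns the optimal
# score only.
oracleOverlapScore <- function(a, b, sub, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e18
  V <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  V[1, ] <- 0; V[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, V[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, V[i - 1, j] - open - ext)
      V[i, j] <- max(V[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(V[m + 1, ], V[, n + 1])
}

oracleBlosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Enumerate every ATG..stop ORF by brute force (all start positions, all
# frames, both strands), then keep the longest ORF per (strand, frame,
# stop) and apply the length floor — mirroring the documented collapse
# rule through an independent code path.
oracleOrfs <- function(seq, minAA, requireFull = TRUE) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                       "")[[1]]), collapse = "")
  gc <- Biostrings::GENETIC_CODE
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    L <- nchar(s)
    for (start in seq_len(L - 2)) {
      if (substr(s, start, start + 2) != "ATG") next
      # walk codons until a stop
      pos <- start
      aa <- character(0)
      stopped <- FALSE
      while (pos + 2 <= L) {
        cod <- substr(s, pos, pos + 2)
        tr <- gc[[cod]]
        if (is.null(tr)) tr <- "X"
        if (tr == "*") { stopped <- TRUE; break }
        aa <- c(aa, tr)
        pos <- pos + 3
      }
      if (!stopped && requireFull) next
      frame <- (start - 1) %% 3
      stopKey <- paste(strand, frame, if (stopped) pos else "end")
      prot <- paste(aa, collapse = "")
      if (nchar(prot) < minAA) next
      prev <- found[[stopKey]]
      if (is.null(prev) || nchar(prot) > nchar(prev))
        found[[stopKey]] <- prot
    }
  }
  out <- unlist(found)
  if (is.null(out)) character(0) else sort(unname(out))
}

# Bipartitions of an unrooted tree by explicit edge traversal: for each
# internal edge, the tip set below the child node, canonicalised to the
# lexicographically smaller side.
oracleSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  canonical <- function(tips) {
    other <- sort(setdiff(tree$tip.label, tips))
    tips <- sort(tips)
    ka <- paste(tips, collapse = "\r"); kb <- paste(other, collapse = "\r")
    if (ka < kb) ka else kb
  }
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    tips <- below(child)
    if (length(tips) >= 2 && length(tips) <= ntip - 2)
      out <- c(out, canonical(tips))
  }
  sort(unique(out))
}

# Monophyly oracle: a tip set forms a clade on the unrooted tree iff its
# canonical bipartition key appears among the enumerated splits (or is
# trivial).
oracleFormsClade <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  k <- length(unique(tips))
  if (k <= 1 || k >= ntip - 1) return(TRUE)
  other <- sort(setdiff(tree$tip.label, tips))
  tips <- sort(tips)
  ka <- paste(tips, collapse = "\r"); kb <- paste(other, collapse = "\r")
  key <- if (ka < kb) ka else kb
  key %in% oracleSplits(tree)
}

# Parsimony-informative sites by a plain per-column scan.
oraclePis <- function(mat, states = c("A", "C", "G", "T")) {
  sum(apply(mat, 2, function(col) {
    tab <- table(col[col %in% states])
    sum(tab >= 2) >= 2
  }))
}

# Random support-labelled tree for collapse/round-trip tests.
randomSupportTree <- function(ntip, supports = NULL) {
  tr <- ape::rtree(ntip)
  n <- tr$Nnode
  if (is.null(supports)) supports <- sample(0:100, n, replace = TRUE)
  tr$node.label <- as.character(supports)
  tr
}

# A tiny deterministic MultiAlign fixture.
fixtureMsa <- function(rows, species = NULL, locusId = "locus") {
  MultiAlign(rows, species = if (is.null(species)) names(rows) else species,
             locusId = locusId)
}
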