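# Exhaustive maximum parsimony over all unrooted topologies. For the
# handful of taxa the design arm sees (<= 5, hard ceiling 8) the
# topology space is tiny — 3 taxa: 1 tree, 4: 3, 5: 15, 8: 10,395 — so
# an exact search is cheap, deterministic, and trivially auditable.

#' Enumerate all unrooted topologies for a set of taxa
#'
#' Stepwise addition: taxa are added in sorted order, each onto every
#' edge of every partial tree. For n taxa this yields
#' (2n-5)!! topologies.
#'
#' @param taxa character vector of 3 to 8 tip labels.
#' @return list of unrooted [ape::phylo] trees.
#' @export
enumerateTopologies <- function(taxa) {
  taxa <- sort(unique(taxa))
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > 8L) stop("exhaustive search refused for more than 8 taxa (got ",
                   n, ")")
  # Trees are nested lists (tips = character scalars) rooted at the
  # unresolved trifurcation; a new tip can be grafted onto the edge
  # above any node except that root.
  trees <- list(list(taxa[1], taxa[2], taxa[3]))
  for (k in seq_len(n - 3L)) {
    newtip <- taxa[3L + k]
    nxt <- list()
    for (tr in trees) nxt <- c(nxt, .graftEverywhere(tr, newtip, TRUE))
    trees <- nxt
  }
  lapply(trees, function(tr)
    ape::read.tree(text = paste0(.nestedNewick(tr), ";")))
}

# All ways of grafting `tip` onto an edge of the subtree rooted at
# `node` (including the edge above `node` itself, unless it is the
# root trifurcation).
#' @noRd
.graftEverywhere <- function(node, tip, isRoot) {
  res <- list()
  if (!isRoot) res[[1L]] <- list(node, tip)
  if (is.list(node)) {
    for (i in seq_along(node)) {
      for (s in .graftEverywhere(node[[i]], tip, FALSE)) {
        nn <- node
        nn[[i]] <- s
        res[[length(res) + 1L]] <- nn
      }
    }
  }
  res
}

#' @noRd
.nestedNewick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, .nestedNewick, character(1)),
                    collapse = ","), ")")
}

#' Fitch parsimony score of a topology
#'
#' Small-parsimony score (minimum number of state changes) of an
#' alignment on a given unrooted topology, computed by the Fitch
#' algorithm with bit-set state unions. Gaps, N and other ambiguity
#' codes are treated as missing (compatible with every state); for
#' protein data the 20 standard residues are states and X/gaps are
#' missing.
#'
#' @param msa a [MultiAlign-class]; row species labels must match the
#'   tree's tip labels.
#' @param tree an [ape::phylo] topology over the alignment's species.
#' @return integer parsimony score.
#' @export
fitchScore <- function(msa, tree) {
  m <- alnMatrix(msa)
  rownames(m) <- unname(msa@species[names(msa@aln)])
  .fitchScoreMat(m, tree)
}

#' @noRd
.fitchStates <- function(chars, type) {
  if (type == "dna") {
    states <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    full <- 15L
  } else {
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
    states <- setNames(bitwShiftL(1L, seq_along(aas) - 1L), aas)
    full <- sum(states)
  }
  v <- unname(states[chars])
  v[is.na(v)] <- full
  v
}

#' @noRd
.fitchScoreMat <- function(m, tree) {
  type <- if (all(m %in% c("A", "C", "G", "T", "N", "-", "?"))) "dna"
          else "protein"
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncol <- ncol(m)
  if (ncol == 0L) return(0L)
  tipStates <- lapply(tree$tip.label, function(tl)
    .fitchStates(m[tl, ], type))
  states <- vector("list", nnode)
  states[seq_len(ntip)] <- tipStates
  score <- integer(ncol)
  child <- tree$edge[, 2L]; parent <- tree$edge[, 1L]
  for (nd in unique(parent)) {          # postorder guarantees children ready
    kids <- child[parent == nd]
    s <- states[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- bitwAnd(s, states[[k]])
      un <- bitwOr(s, states[[k]])
      empty <- inter == 0L
      score <- score + empty
      s <- ifelse(empty, un, inter)
    }
    states[[nd]] <- s
  }
  sum(score)
}

#' Exhaustive maximum-parsimony topology search
#'
#' Evaluates the Fitch parsimony score of every unrooted topology over
#' the alignment's species and returns the set of minimum-score
#' topologies. Refuses more than 8 taxa.
#'
#' @param msa a [MultiAlign-class] with unique species labels (3-8).
#' @return list with `trees` (the co-optimal unrooted [ape::phylo]
#'   topologies), `score` (the minimum score) and `nEvaluated`.
#' @export
inferTopology <- function(msa) {
  taxa <- unname(msa@species)
  if (anyDuplicated(taxa)) stop("species labels must be unique for topology inference")
  if (length(taxa) < 3L) stop("need at least 3 taxa")
  m <- alnMatrix(msa)
  rownames(m) <- taxa
  topos <- enumerateTopologies(taxa)
  scores <- vapply(topos, function(tr) .fitchScoreMat(m, tr), numeric(1))
  best <- which(scores == min(scores))
  list(trees = topos[best], score = min(scores), nEvaluated = length(topos))
}
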