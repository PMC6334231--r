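# Gene-tree operations for post-capture QC: paralog screening by
# monophyly on unrooted trees, low-support branch collapsing,
# outgroup rooting, and per-branch bipartition concordance.

# Non-trivial splits (bipartitions) of an unrooted tree, as a list of
# tip-label sets (the side not containing the first tip is returned
# canonically: each split is the smaller side, ties broken by sort).
#' @noRd
.treeSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(list())
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- list()
  for (cl in pp) {
    tips <- labs[cl]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    out[[length(out) + 1L]] <- sort(tips)
  }
  unique(out)
}

#' @noRd
.splitKey <- function(tips, allTips) {
  a <- sort(tips); b <- sort(setdiff(allTips, tips))
  # canonical side: lexicographically smaller joined string
  ka <- paste(a, collapse = "\r"); kb <- paste(b, collapse = "\r")
  if (ka < kb) ka else kb
}

#' Do a set of tips form a clade on an unrooted tree?
#'
#' TRUE iff some edge of the unrooted tree bipartitions the tips into
#' exactly `tips` versus the rest. Single tips and the full tip set are
#' trivially clades.
#'
#' @param tree an [ape::phylo].
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
tipsFormClade <- function(tree, tips) {
  all <- tree$tip.label
  if (!all(tips %in% all)) stop("tips absent from tree: ",
                                paste(setdiff(tips, all), collapse = ", "))
  k <- length(unique(tips))
  if (k <= 1L || k >= length(all) - 1L) return(TRUE)
  key <- .splitKey(tips, all)
  any(vapply(.treeSplits(tree), function(s) .splitKey(s, all) == key,
             logical(1)))
}

#' Gene-tree paralog screen by sample monophyly
#'
#' For every sample with multiple copies (tips) in the gene tree, tests
#' whether its tips form a clade on the unrooted tree. If every
#' multi-copy sample is monophyletic the putative paralogs are likely
#' alleles or assembly splits and the main sequence can be kept
#' (`keep_main`); if any sample's copies land in separate clades the
#' locus is a probable true paralog and the whole locus is dropped
#' (`drop_locus`).
#'
#' @param tree gene tree ([ape::phylo], >= 4 tips).
#' @param tipSamples named character vector mapping every tip label to
#'   its sample id (several tips may share a sample; the copy tag is
#'   irrelevant to the verdict). Defaults to splitting tip labels at the
#'   last `"__"` (so `sampleA__main`, `sampleA__alt` are two copies of
#'   `sampleA`).
#' @param locusId optional locus id recorded in the verdict.
#' @return list with `locus`, `verdict` (`"keep_main"`/`"drop_locus"`),
#'   `flags` (named logical, per multi-copy sample monophyly) and
#'   `note`.
#' @export
paralogCladeTest <- function(tree, tipSamples = NULL, locusId = NA_character_) {
  if (length(tree$tip.label) < 4L) stop("need at least 4 tips")
  if (is.null(tipSamples)) {
    tipSamples <- setNames(sub("__[^_]*$", "", tree$tip.label),
                           tree$tip.label)
  }
  if (!all(tree$tip.label %in% names(tipSamples)))
    stop("every tip needs a sample label")
  bySample <- split(tree$tip.label, unname(tipSamples[tree$tip.label]))
  multi <- bySample[lengths(bySample) >= 2L]
  if (length(multi) == 0L)
    return(list(locus = locusId, verdict = "keep_main",
                flags = logical(0), note = "no multi-copy samples"))
  flags <- vapply(multi, function(tips) tipsFormClade(tree, tips), logical(1))
  list(locus = locusId,
       verdict = if (all(flags)) "keep_main" else "drop_locus",
       flags = flags, note = NA_character_)
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support value is below the
#' threshold (the widely used practice for gene trees fed to summary
#' methods). Tip edges are never collapsed; the root trifurcation of an
#' unrooted tree is untouched; supports of surviving edges are kept.
#' `invert = TRUE` collapses branches at or above the threshold instead
#' (provided because published pipelines occasionally state the rule in
#' that direction).
#'
#' @param tree an [ape::phylo] with numeric internal node labels
#'   (supports).
#' @param threshold support threshold (default 10, on the bootstrap
#'   percentage scale).
#' @param invert collapse `support >= threshold` instead of
#'   `support < threshold`.
#' @return the collapsed [ape::phylo].
#' @export
collapseLowSupport <- function(tree, threshold = 10, invert = FALSE) {
  if (is.null(tree$node.label))
    stop("tree has no internal support labels")
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  # internal edges: child is an internal node; support stored on child
  internal <- tree$edge[, 2L] > ntip
  childSup <- rep(NA_real_, nrow(tree$edge))
  childSup[internal] <- sup[tree$edge[internal, 2L] - ntip]
  drop <- internal & !is.na(childSup) &
    (if (invert) childSup >= threshold else childSup < threshold)
  if (!any(drop)) return(tree)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree$edge.length[drop] <- 0
    out <- ape::di2multi(tree, tol = 1e-8)
    out$edge.length <- NULL
  } else {
    tree$edge.length[drop] <- 0
    out <- ape::di2multi(tree, tol = 1e-8)
  }
  out
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge subtending the outgroup, which must be
#' present and monophyletic on the unrooted tree.
#'
#' @param tree an [ape::phylo].
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted [ape::phylo].
#' @export
rootAtOutgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup tips absent: ", paste(missing, collapse = ", "))
  if (!tipsFormClade(tree, outgroup))
    stop("outgroup is not monophyletic: ",
         paste(outgroup, collapse = ", "))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Per-branch gene-tree concordance
#'
#' For every internal bipartition A|B of the species tree, the fraction
#' of gene trees that (a) are informative for the branch — at least two
#' tips from each side present — and (b) contain the induced
#' bipartition A∩L | B∩L, where L is the gene tree's tip set.
#' Uninformative gene trees are excluded from that branch's
#' denominator. This is a bipartition-support summary, not a quartet
#' score.
#'
#' @param speciesTree rooted or unrooted [ape::phylo].
#' @param geneTrees list of [ape::phylo]; tip sets must be subsets of
#'   the species tree's tips.
#' @return data.frame with one row per internal species-tree
#'   bipartition: `split` (smaller side, comma-joined), `n_agree`,
#'   `n_informative`, `concordance` (NA when no gene tree is
#'   informative).
#' @export
branchConcordance <- function(speciesTree, geneTrees) {
  if (methods::is(geneTrees, "phylo")) geneTrees <- list(geneTrees)
  st <- ape::unroot(speciesTree)
  allTips <- st$tip.label
  for (gt in geneTrees)
    if (!all(gt$tip.label %in% allTips))
      stop("gene-tree tips must be a subset of the species tree's tips")
  splits <- .treeSplits(st)
  geneSplitKeys <- lapply(geneTrees, function(gt) {
    vapply(.treeSplits(gt), .splitKey, character(1),
           allTips = gt$tip.label)
  })
  rows <- lapply(splits, function(A) {
    B <- setdiff(allTips, A)
    nInf <- 0L; nAgr <- 0L
    for (k in seq_along(geneTrees)) {
      L <- geneTrees[[k]]$tip.label
      A2 <- intersect(A, L); B2 <- intersect(B, L)
      if (length(A2) < 2L || length(B2) < 2L) next
      nInf <- nInf + 1L
      if (.splitKey(A2, L) %in% geneSplitKeys[[k]]) nAgr <- nAgr + 1L
    }
    data.frame(split = paste(A, collapse = ","), n_agree = nAgr,
               n_informative = nInf,
               concordance = if (nInf > 0) nAgr / nInf else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
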