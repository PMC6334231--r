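# Reciprocal-best-hit orthology: star-topology reciprocity between a
# focal taxon and every other species, the N-way RBH search that turns
# screened per-species protein sets into candidate ortholog groups.

#' Best-hit map between two protein sets
#'
#' For every A-protein, the B-protein with maximal alignment score; ties
#' are broken by lexicographically smaller B id so the map is
#' deterministic.
#'
#' @param scores numeric score matrix (rows = A ids, cols = B ids), as
#'   from [crossScoreMatrix()]; alternatively `protsA`/`protsB` can be
#'   given and the matrix is computed.
#' @param protsA,protsB named character vectors or AAStringSets (used
#'   when `scores` is missing).
#' @param params an [alignParams()] list.
#' @return named character vector, A id -> B id.
#' @export
bestHitMap <- function(scores = NULL, protsA = NULL, protsB = NULL,
                       params = alignParams()) {
  if (is.null(scores)) {
    if (is.null(protsA) || is.null(protsB))
      stop("give either a score matrix or both protein sets")
    if (length(protsA) == 0L || length(protsB) == 0L)
      stop("both protein sets must be non-empty")
    scores <- crossScoreMatrix(protsA, protsB, params)
  }
  ord <- order(colnames(scores))
  s <- scores[, ord, drop = FALSE]
  best <- apply(s, 1L, function(r) colnames(s)[which.max(r)])
  setNames(unname(best), rownames(scores))
}

#' Reciprocal-best-hit ortholog groups
#'
#' For every protein f of the focal species, species s contributes its
#' protein p iff p is f's best hit in s and f is p's best hit in the
#' focal species (reciprocity against the focal taxon only — a star
#' topology; set `allPairs = TRUE` to additionally require reciprocity
#' between every member pair). Groups with fewer than `minSpecies`
#' members (focal included) are dropped. Member-pair percent identities
#' are computed for every retained group.
#'
#' @param proteinSets named list, species -> named character vector (or
#'   AAStringSet) of that species' screened proteins.
#' @param focal focal species label (must be in `proteinSets`).
#' @param minSpecies minimum number of member species (default 3).
#' @param cutoff clustering cutoff to record on the groups (bookkeeping
#'   only; default `NA`).
#' @param allPairs require reciprocity between all member pairs, not
#'   just focal vs others.
#' @param scoreCache optional environment used to memoise cross-species
#'   score matrices across repeated calls (see [designOrthologGroups()]).
#' @param computeIdentities fill `pairIdentities` before returning
#'   (default); [designOrthologGroups()] defers this until after
#'   de-duplication so discarded groups are never aligned.
#' @param params an [alignParams()] list.
#' @return list of [OrthoGroup-class] objects, ordered by group id.
#' @export
rbhGroups <- function(proteinSets, focal, minSpecies = 3, cutoff = NA_real_,
                      allPairs = FALSE, scoreCache = NULL,
                      computeIdentities = TRUE, params = alignParams()) {
  if (!focal %in% names(proteinSets))
    stop("focal species '", focal, "' not among protein sets")
  if (minSpecies < 3) stop("minSpecies must be >= 3")
  proteinSets <- lapply(proteinSets, .asSeqChar)
  others <- setdiff(names(proteinSets), focal)
  if (length(proteinSets[[focal]]) == 0L) return(list())

  getScores <- function(spA, spB) {
    .cachedScores(proteinSets, spA, spB, scoreCache, params)
  }

  fwd <- list(); rev <- list()
  for (s in others) {
    if (length(proteinSets[[s]]) == 0L) next
    m <- getScores(focal, s)
    fwd[[s]] <- bestHitMap(m)
    rev[[s]] <- bestHitMap(t(m))
  }

  groups <- list()
  for (f in sort(names(proteinSets[[focal]]))) {
    members <- setNames(f, focal)
    for (s in names(fwd)) {
      p <- fwd[[s]][[f]]
      if (!is.null(p) && identical(rev[[s]][[p]], f))
        members[s] <- p
    }
    if (length(members) < minSpecies) next
    members <- members[sort(names(members))]
    if (allPairs && !.allPairsReciprocal(members, focal, proteinSets,
                                         getScores)) next
    gid <- paste(focal, f, sep = "|")
    groups[[gid]] <- methods::new("OrthoGroup", groupId = gid,
                                  members = members, cutoff = cutoff,
                                  focal = focal,
                                  pairIdentities = numeric(0))
  }
  if (length(groups) == 0L) return(list())
  groups <- groups[order(names(groups))]
  if (computeIdentities)
    groups <- fillPairIdentities(groups, proteinSets, params)
  groups
}

#' Fill member-pair identities for a set of groups
#'
#' Aligns every unique member pair of every group in one batched kernel
#' call and writes the percent identities back into the groups.
#'
#' @inheritParams rbhGroups
#' @param groups list of [OrthoGroup-class] objects.
#' @return the groups, with `pairIdentities` populated.
#' @export
fillPairIdentities <- function(groups, proteinSets, params = alignParams()) {
  if (length(groups) == 0L) return(groups)
  seqOf <- unlist(unname(lapply(proteinSets, function(x) x)))
  pairRows <- list()
  for (g in groups) {
    mem <- groupMembers(g)
    sps <- sort(names(mem))
    if (length(sps) < 2L) next
    for (pr in utils::combn(sps, 2L, simplify = FALSE)) {
      pairRows[[length(pairRows) + 1L]] <-
        c(gid = groupId(g), key = .pairKey(pr[1], pr[2]),
          idA = mem[[pr[1]]], idB = mem[[pr[2]]])
    }
  }
  pr <- do.call(rbind, pairRows)
  ids <- unique(c(pr[, "idA"], pr[, "idB"]))
  seqs <- seqOf[ids]
  al <- .alignAlphabet(seqs, params, "protein")
  sc <- .intScoring(al$sub, params)
  enc <- .encodeSeqs(seqs, sc$sub)
  idx <- cbind(match(pr[, "idA"], ids), match(pr[, "idB"], ids))
  st <- cpp_pair_stats_many(enc, idx, sc$sub, sc$open, sc$ext)
  lens <- nchar(seqs)
  pid <- 100 * st[, 2L] / pmin(lens[idx[, 1L]], lens[idx[, 2L]])
  for (k in seq_len(nrow(pr))) {
    g <- groups[[pr[k, "gid"]]]
    g@pairIdentities[[pr[k, "key"]]] <- pid[[k]]
    groups[[pr[k, "gid"]]] <- g
  }
  groups
}

# Cross-species score matrices are memoised per unordered species pair
# (stored with rows = lexicographically first species). A cached matrix
# computed on a superset of the current proteins (the per-cutoff
# clustered subsets differ) is subset to the ids present; if it does not
# cover them, a fresh matrix is computed for the current sets only.
#' @noRd
.cachedScores <- function(proteinSets, spA, spB, cache, params) {
  ks <- sort(c(spA, spB))
  key <- paste(ks, collapse = "|")
  idsA <- names(proteinSets[[spA]]); idsB <- names(proteinSets[[spB]])
  if (!is.null(cache) && !is.null(cache[[key]])) {
    m <- cache[[key]]
    if (ks[1] != spA) m <- t(m)
    if (all(idsA %in% rownames(m)) && all(idsB %in% colnames(m)))
      return(m[idsA, idsB, drop = FALSE])
  }
  m <- crossScoreMatrix(proteinSets[[spA]], proteinSets[[spB]], params)
  if (!is.null(cache) && is.null(cache[[key]]))
    cache[[key]] <- if (ks[1] == spA) m else t(m)
  m
}

#' @noRd
.allPairsReciprocal <- function(members, focal, proteinSets, getScores) {
  sps <- names(members)
  for (pr in utils::combn(sps, 2L, simplify = FALSE)) {
    a <- pr[1]; b <- pr[2]
    if (focal %in% pr) next  # already enforced
    m <- getScores(a, b)
    if (!identical(bestHitMap(m)[[members[[a]]]], members[[b]])) return(FALSE)
    if (!identical(bestHitMap(t(m))[[members[[b]]]], members[[a]])) return(FALSE)
  }
  TRUE
}

#' Full ortholog-discovery sweep over clustering cutoffs and focal taxa
#'
#' Runs, for every percent-identity cutoff (default 99, 97, 95, 90):
#' per-species greedy clustering, representative extraction,
#' within-species low-copy screening, and the reciprocal-best-hit search
#' once per focal taxon. Groups found with different focal taxa but
#' identical member sets are de-duplicated; when the same focal protein
#' yields groups at several cutoffs, the group from the highest cutoff
#' is kept (the most conservative redundancy reduction).
#'
#' @param proteins named list, species -> named character vector or
#'   AAStringSet of translated proteins.
#' @param focalTaxa character vector of focal species labels.
#' @param cutoffs percent-identity cutoffs to sweep (descending order is
#'   applied internally).
#' @param minSpecies minimum member species per group.
#' @param minIdentity,minCov self-screen thresholds, see [selfScreen()].
#' @param params an [alignParams()] list.
#' @param verbose print per-stage progress.
#' @return list of [OrthoGroup-class] objects.
#' @export
designOrthologGroups <- function(proteins, focalTaxa,
                                 cutoffs = c(99, 97, 95, 90),
                                 minSpecies = 3, minIdentity = 40,
                                 minCov = 0.5, params = alignParams(),
                                 verbose = FALSE) {
  proteins <- lapply(proteins, .asSeqChar)
  stopifnot(all(focalTaxa %in% names(proteins)))
  cutoffs <- sort(cutoffs, decreasing = TRUE)

  if (verbose) message("within-species all-vs-all alignment ...")
  statsBySp <- lapply(proteins, pairStats, params = params)

  # Prefill the cross-species score cache on the full protein sets so
  # every cutoff-specific RBH pass is a pure subset lookup.
  cache <- new.env(parent = emptyenv())
  for (focal in focalTaxa) {
    for (s in setdiff(names(proteins), focal)) {
      if (verbose) message("cross alignment ", focal, " vs ", s, " ...")
      invisible(.cachedScores(proteins, focal, s, cache, params))
    }
  }

  seen <- new.env(parent = emptyenv())   # focal-protein key -> kept group
  memberKeys <- character(0)
  out <- list()
  for (co in cutoffs) {
    if (verbose) message("cutoff ", co, " ...")
    screened <- lapply(names(proteins), function(sp) {
      cl <- clusterProteins(proteins[[sp]], co, stats = statsBySp[[sp]])
      reps <- proteins[[sp]][clusterReps(cl)]
      keep <- selfScreen(reps, minIdentity, minCov,
                         stats = .subStats(statsBySp[[sp]], names(reps)))
      proteins[[sp]][keep$retained]
    })
    names(screened) <- names(proteins)
    for (focal in focalTaxa) {
      grps <- rbhGroups(screened, focal, minSpecies, cutoff = co,
                        scoreCache = cache, computeIdentities = FALSE,
                        params = params)
      for (g in grps) {
        if (!is.null(seen[[g@groupId]])) next     # higher cutoff already kept
        mk <- paste(sort(paste(names(g@members), g@members, sep = "=")),
                    collapse = ";")
        if (mk %in% memberKeys) next              # same member set, other focal
        seen[[g@groupId]] <- TRUE
        memberKeys <- c(memberKeys, mk)
        out[[g@groupId]] <- g
      }
    }
  }
  if (length(out) == 0L) return(list())
  out <- out[order(names(out))]
  if (verbose) message("computing member pair identities ...")
  fillPairIdentities(out, proteins, params)
}

#' @noRd
.subStats <- function(stats, ids) {
  list(score = stats$score[ids, ids, drop = FALSE],
       identity = stats$identity[ids, ids, drop = FALSE],
       cov = stats$cov[ids, ids, drop = FALSE])
}
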