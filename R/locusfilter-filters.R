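# Topology congruence and the identity/length/variance selection
# filters that decide which ortholog groups become bait targets.

#' Test congruence of candidate topologies with a reference
#'
#' TRUE iff the reference topology, restricted to the group's taxa, has
#' Robinson-Foulds distance 0 to at least one of the candidate
#' (typically co-optimal maximum-parsimony) topologies — co-optimal
#' trees get the benefit of the doubt. Any 3-taxon group is congruent
#' (a single unrooted topology exists).
#'
#' @param candidates list of unrooted [ape::phylo] trees (as returned in
#'   `inferTopology()$trees`), or a single tree.
#' @param reference the reference species topology ([ape::phylo]).
#' @param taxa taxa to restrict to (default: tips of the first
#'   candidate). All must be present in the reference.
#' @return logical.
#' @export
isCongruent <- function(candidates, reference, taxa = NULL) {
  if (methods::is(candidates, "phylo")) candidates <- list(candidates)
  if (is.null(taxa)) taxa <- candidates[[1L]]$tip.label
  missing <- setdiff(taxa, reference$tip.label)
  if (length(missing))
    stop("taxa missing from reference: ", paste(missing, collapse = ", "))
  if (length(taxa) <= 3L) return(TRUE)
  ref <- ape::unroot(ape::keep.tip(reference, taxa))
  for (cand in candidates) {
    if (!setequal(cand$tip.label, taxa)) next
    if (phangorn::RF.dist(ape::unroot(cand), ref) == 0) return(TRUE)
  }
  FALSE
}

#' Phylogenetically closest and furthest species pairs
#'
#' Nodal (edge-count) distances on the reference topology: every pair at
#' the minimum distance is "closest", every pair at the maximum is
#' "furthest". Branch lengths are ignored — only the topology counts.
#'
#' @param taxa at least 3 taxa, all present in the reference.
#' @param reference reference topology ([ape::phylo]).
#' @return list with `closest` and `furthest`, each a list of length-2
#'   character vectors (species pairs, sorted within pair), plus the
#'   full `dist` matrix of nodal distances.
#' @export
closestFurthestPairs <- function(taxa, reference) {
  if (length(taxa) < 3L) stop("need at least 3 taxa")
  missing <- setdiff(taxa, reference$tip.label)
  if (length(missing))
    stop("taxa missing from reference: ", paste(missing, collapse = ", "))
  ref <- ape::unroot(reference)
  ref$edge.length <- rep(1, nrow(ref$edge))
  d <- ape::cophenetic.phylo(ref)[taxa, taxa]
  pairs <- utils::combn(sort(taxa), 2L, simplify = FALSE)
  pd <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  list(closest = pairs[pd == min(pd)], furthest = pairs[pd == max(pd)],
       dist = d)
}

#' Apply the locus selection filters to an ortholog group
#'
#' Evaluates, in order:
#' \enumerate{
#'   \item divergence: maximum pairwise identity strictly below the
#'     group's clustering cutoff (the group must be more divergent
#'     between species than the redundancy-reduction step tolerated
#'     within species);
#'   \item length variation: (max - min)/max CDS length strictly below
#'     `maxLenVar`;
#'   \item minimum length: shortest CDS at least `minLenNt` bp;
#'   \item phylogeny-consistent identity: every phylogenetically closest
#'     species pair strictly above `closestMin` percent and every
#'     furthest pair strictly above `furthestMin`;
#'   \item long-sequence stringency: if the longest CDS exceeds
#'     `longLenNt`, every closest pair strictly above `longClosestMin`;
#'   \item identity dispersion: sample variance of all pairwise percent
#'     identities at most `maxIdentityVariance`.
#' }
#' The verdict is "pass" iff every rule passes. Identity rules use
#' strict inequalities as published; the length floor is inclusive
#' (300 bp passes).
#'
#' @param group an [OrthoGroup-class] with complete `pairIdentities`.
#' @param cdsLengths named numeric vector of per-species CDS lengths
#'   (bp) for the group members.
#' @param params a [FilterParams-class] (default [filterParams()]).
#' @param reference reference topology for the closest/furthest pairs.
#' @param populationVariance use the population (divide by n) instead of
#'   the sample variance in rule vi.
#' @return a [FilterReport-class].
#' @export
applySelectionFilters <- function(group, cdsLengths,
                                  params = filterParams(), reference,
                                  populationVariance = FALSE) {
  sps <- names(groupMembers(group))
  if (!all(sps %in% names(cdsLengths)))
    stop("missing CDS length for species: ",
         paste(setdiff(sps, names(cdsLengths)), collapse = ", "))
  len <- cdsLengths[sps]
  pid <- pairIdentities(group)

  cf <- closestFurthestPairs(sps, reference)
  pidOf <- function(pairList)
    vapply(pairList, function(p) pid[[.pairKey(p[1], p[2])]], numeric(1))

  rows <- list()
  addRule <- function(rule, observed, threshold, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      rule = rule, observed = observed, threshold = threshold,
      outcome = if (pass) "pass" else "fail", stringsAsFactors = FALSE)
  }

  maxId <- max(pid)
  addRule("divergence_below_cutoff", maxId, group@cutoff,
          is.na(group@cutoff) || maxId < group@cutoff)
  lenVar <- (max(len) - min(len)) / max(len)
  addRule("length_variation", lenVar, params@maxLenVar,
          lenVar < params@maxLenVar)
  addRule("min_length", min(len), params@minLenNt,
          min(len) >= params@minLenNt)
  closeId <- pidOf(cf$closest); farId <- pidOf(cf$furthest)
  addRule("closest_pair_identity", min(closeId), params@closestMin,
          all(closeId > params@closestMin))
  addRule("furthest_pair_identity", min(farId), params@furthestMin,
          all(farId > params@furthestMin))
  isLong <- max(len) > params@longLenNt
  addRule("long_seq_closest_identity", min(closeId),
          params@longClosestMin,
          !isLong || all(closeId > params@longClosestMin))
  v <- if (populationVariance) mean((pid - mean(pid))^2) else var(pid)
  if (is.na(v)) v <- 0  # a single pair has no dispersion
  addRule("identity_variance", v, params@maxIdentityVariance,
          v <= params@maxIdentityVariance)

  rules <- do.call(rbind, rows)
  methods::new("FilterReport", groupId = groupId(group),
               verdict = if (all(rules$outcome == "pass")) "pass" else "fail",
               rules = rules)
}

#' Write filter reports as TSV
#'
#' One row per (group, rule): group id, rule id, observed value,
#' threshold, outcome, plus the group verdict.
#'
#' @param reports list of [FilterReport-class] objects.
#' @param path output path.
#' @export
writeFilterReports <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    cbind(group = r@groupId, filterRules(r), verdict = r@verdict)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
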