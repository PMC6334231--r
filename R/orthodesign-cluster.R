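# Greedy incremental identity clustering, the redundancy-reduction step
# that collapses alleles and splice isoforms before orthology search.

#' Cluster proteins by greedy incremental identity
#'
#' Proteins are sorted by decreasing length (ties by id) and processed
#' in order: each protein joins the first existing cluster whose
#' representative it matches at or above the percent-identity cutoff,
#' otherwise it founds a new cluster. Because insertion order is by
#' decreasing length, the founder of each cluster is also its longest
#' member and serves as the representative. Identity uses the
#' shorter-sequence denominator (see [globalAlign()]).
#'
#' @param proteins named character vector or [Biostrings::AAStringSet].
#' @param cutoff percent identity cutoff in (50, 100]; the kit design
#'   sweep uses 99, 97, 95 and 90.
#' @param stats optional precomputed [pairStats()] result for `proteins`
#'   (computed on the fly otherwise); lets several cutoffs share one
#'   all-vs-all alignment pass.
#' @param params an [alignParams()] list.
#' @return a [ClusterSet-class].
#' @export
clusterProteins <- function(proteins, cutoff, stats = NULL,
                            params = alignParams()) {
  .assertScalarNumber(cutoff, "cutoff", lower = 50 + 1e-9, upper = 100)
  proteins <- .asSeqChar(proteins, "proteins")
  if (length(proteins) == 0L)
    return(methods::new("ClusterSet", cutoff = cutoff, clusters = list()))
  if (is.null(names(proteins)))
    stop("proteins must be named")
  if (is.null(stats)) stats <- pairStats(proteins, params)
  ids <- names(proteins)[order(-nchar(proteins), names(proteins))]
  reps <- character(0)
  clusters <- list()
  assign_to <- character(length(ids)); names(assign_to) <- ids
  for (id in ids) {
    hit <- NA_character_
    if (length(reps)) {
      idm <- stats$identity[id, reps]
      w <- which(idm >= cutoff)[1L]
      if (!is.na(w)) hit <- reps[w]
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      clusters[[id]] <- id
    } else {
      clusters[[hit]] <- c(clusters[[hit]], id)
    }
  }
  methods::new("ClusterSet", cutoff = cutoff, clusters = clusters)
}

#' Screen out multi-copy genes within one species
#'
#' A protein is discarded iff it has at least one non-self hit within
#' its own species meeting the identity and coverage thresholds — the
#' within-species "self-search" that removes gene families and keeps
#' only low-copy genes. Defaults (identity >= 40%, both coverages >=
#' 0.5) approximate default protein-search sensitivity.
#'
#' @param proteins named character vector or AAStringSet, all from one
#'   species.
#' @param minIdentity minimum percent identity for a hit (default 40).
#' @param minCov minimum coverage of both sequences (default 0.5).
#' @param stats optional precomputed [pairStats()] for `proteins`.
#' @param params an [alignParams()] list.
#' @return list with `retained` (character ids) and `audit` (a
#'   [S4Vectors::DataFrame] with one row per protein: id, decision,
#'   reason).
#' @export
selfScreen <- function(proteins, minIdentity = 40, minCov = 0.5,
                       stats = NULL, params = alignParams()) {
  proteins <- .asSeqChar(proteins, "proteins")
  ids <- names(proteins)
  if (length(proteins) == 0L)
    return(list(retained = character(0),
                audit = S4Vectors::DataFrame(id = character(0),
                                             decision = character(0),
                                             reason = character(0))))
  if (is.null(stats)) stats <- pairStats(proteins, params)
  n <- length(ids)
  decision <- rep("retained", n)
  reason <- rep("no within-species hit", n)
  if (n >= 2L) {
    hitmat <- stats$identity >= minIdentity & stats$cov >= minCov &
      t(stats$cov) >= minCov
    diag(hitmat) <- FALSE
    for (i in seq_len(n)) {
      hits <- which(hitmat[i, ])
      if (length(hits)) {
        decision[i] <- "discarded"
        reason[i] <- paste0("hit: ",
                            paste(head(ids[hits], 3), collapse = ","))
      }
    }
  }
  list(retained = ids[decision == "retained"],
       audit = S4Vectors::DataFrame(id = ids, decision = decision,
                                    reason = reason))
}
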