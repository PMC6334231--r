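# End-to-end design arm: transcriptomes in, tiled bait kit out.

#' Run the full bait-design pipeline
#'
#' Chains the design arm: six-frame ORF extraction and translation per
#' species; the ortholog-discovery sweep over clustering cutoffs and
#' focal taxa ([designOrthologGroups()]); per-group protein alignment,
#' gap trimming, exhaustive-parsimony topology inference and congruence
#' testing against the reference; the identity/length/variance
#' selection filters; and degenerate bait tiling over the survivors.
#'
#' @param transcripts named list, species -> [Biostrings::DNAStringSet]
#'   (or named character vector) of transcriptome contigs.
#' @param reference reference species topology ([ape::phylo]).
#' @param focalTaxa focal species for the reciprocal-best-hit search.
#' @param params a [FilterParams-class].
#' @param cutoffs clustering cutoffs (default 99, 97, 95, 90).
#' @param minAA minimum ORF length in residues (default 100).
#' @param minSpecies minimum species per ortholog group (default 3).
#' @param baitLen,step bait tiling geometry (defaults 120 / 40).
#' @param alnParams an [alignParams()] list.
#' @param verbose print stage progress.
#' @return list with `proteins` (per-species AAStringSets), `groups`
#'   (all ortholog groups), `congruent` (named logical), `reports`
#'   (list of [FilterReport-class]), `passing` (groups passing
#'   congruence + filters), `regions`, `baitSet`, `summary`
#'   (the [kitSummary()]).
#' @export
runBaitDesign <- function(transcripts, reference, focalTaxa,
                          params = filterParams(),
                          cutoffs = c(99, 97, 95, 90), minAA = 100,
                          minSpecies = 3, baitLen = 120, step = 40,
                          alnParams = alignParams(), verbose = FALSE) {
  stopifnot(is.list(transcripts), !is.null(names(transcripts)))
  if (verbose) message("extracting ORFs ...")
  orfs <- lapply(names(transcripts), function(sp)
    extractOrfs(transcripts[[sp]], minAA = minAA, requireFull = TRUE,
                species = sp))
  names(orfs) <- names(transcripts)
  proteins <- lapply(orfs, function(x) setNames(as.character(x), names(x)))

  groups <- designOrthologGroups(proteins, focalTaxa, cutoffs = cutoffs,
                                 minSpecies = minSpecies,
                                 params = alnParams, verbose = verbose)
  if (verbose) message(length(groups), " candidate groups")

  # provenance lookup: protein id -> CDS sequence and length
  cdsOf <- list()
  for (sp in names(orfs)) {
    mc <- S4Vectors::mcols(orfs[[sp]])
    src <- .asSeqChar(transcripts[[sp]])
    for (i in seq_along(orfs[[sp]])) {
      id <- names(orfs[[sp]])[i]
      cdsOf[[id]] <- orfCds(src[mc$source_id[i]], mc$cds_start[i],
                            mc$cds_end[i], mc$strand[i])
    }
  }

  congruent <- logical(length(groups))
  names(congruent) <- names(groups)
  reports <- list()
  passing <- list()
  variantSeqs <- list()
  for (gid in names(groups)) {
    g <- groups[[gid]]
    mem <- groupMembers(g)
    aaSeqs <- setNames(vapply(names(mem), function(sp)
      proteins[[sp]][[mem[[sp]]]], character(1)), names(mem))
    msa <- progressiveAlign(aaSeqs, species = names(mem), locusId = gid,
                            params = alnParams, type = "protein")
    trimmed <- trimGappy(msa, params@trimMaxGapFrac)$msa
    congruent[gid] <- if (length(mem) <= 3L) TRUE else {
      topo <- inferTopology(trimmed)
      isCongruent(topo$trees, reference, taxa = names(mem))
    }
    cdsLen <- setNames(vapply(mem, function(id) nchar(cdsOf[[id]]),
                              numeric(1)), names(mem))
    rep <- applySelectionFilters(g, cdsLen, params, reference)
    reports[[gid]] <- rep
    if (congruent[gid] && filterVerdict(rep) == "pass") {
      passing[[gid]] <- g
      variantSeqs[[gid]] <- setNames(vapply(mem, function(id)
        cdsOf[[id]], character(1)), names(mem))
    }
  }
  if (verbose) message(length(passing), " groups pass all filters")

  regions <- if (length(passing))
    collectVariants(passing, variantSeqs, minLenNt = params@minLenNt)
  else list()
  baitSet <- buildBaitSet(regions, baitLen = baitLen, step = step)
  list(proteins = orfs, groups = groups, congruent = congruent,
       reports = reports, passing = passing, regions = regions,
       baitSet = baitSet, summary = kitSummary(baitSet))
}
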