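#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# ClusterSet: result of greedy identity clustering of one species' proteins.
# ---------------------------------------------------------------------------

#' Greedy identity clustering result
#'
#' Holds the clusters produced by [clusterProteins()]: a percent-identity
#' cutoff and a list of clusters, each a character vector of member ids
#' whose first element is the representative (the longest member, ties
#' broken by id).
#'
#' @slot cutoff percent identity cutoff used (in (50, 100]).
#' @slot clusters named list; names are representative ids, elements are
#'   character vectors of member ids (representative included, first).
#' @exportClass ClusterSet
setClass("ClusterSet",
         representation(cutoff = "numeric", clusters = "list"))

setValidity("ClusterSet", function(object) {
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members))
    return("a protein appears in more than one cluster")
  reps <- vapply(object@clusters, function(x) x[[1L]], character(1))
  if (length(object@clusters) && !identical(unname(reps), unname(names(object@clusters))))
    return("cluster names must equal their representative (first member) id")
  TRUE
})

#' @describeIn ClusterSet-class number of clusters
#' @param x,object a `ClusterSet`
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

#' @export
setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet @", object@cutoff, "% identity:",
      length(object@clusters), "clusters,",
      length(unlist(object@clusters, use.names = FALSE)), "proteins\n")
})

#' Cluster membership accessor
#' @param x a `ClusterSet`
#' @return named list of member-id vectors, one per cluster.
#' @export
clusterMembers <- function(x) x@clusters

#' Cluster representative ids
#' @param x a `ClusterSet`
#' @export
clusterReps <- function(x) names(x@clusters)

# ---------------------------------------------------------------------------
# OrthoGroup: one candidate locus, one member per species.
# ---------------------------------------------------------------------------

#' Candidate ortholog group
#'
#' One candidate locus from the reciprocal-best-hit search: at most one
#' member protein per species, the clustering cutoff it was found at, the
#' focal taxon used, and the percent identities of every member pair.
#'
#' @slot groupId deterministic id (`<focal>|<focal member id>`).
#' @slot members named character vector, species -> protein id.
#' @slot cutoff percent-identity clustering cutoff the group came from.
#' @slot focal focal species label.
#' @slot pairIdentities named numeric vector of percent identities, one
#'   per unordered member species pair (names `spA|spB`, spA < spB).
#' @exportClass OrthoGroup
setClass("OrthoGroup",
         representation(groupId = "character", members = "character",
                        cutoff = "numeric", focal = "character",
                        pairIdentities = "numeric"))

setValidity("OrthoGroup", function(object) {
  if (anyDuplicated(names(object@members)))
    return("at most one member per species")
  sp <- sort(names(object@members))
  # pairIdentities may be left empty transiently (filled in batch after
  # de-duplication); once present it must cover exactly all pairs.
  if (length(sp) >= 2L && length(object@pairIdentities)) {
    want <- sort(apply(combn(sp, 2L), 2L, function(p) .pairKey(p[1], p[2])))
    if (!identical(sort(names(object@pairIdentities)), want))
      return("pairIdentities must cover exactly all member species pairs")
  }
  TRUE
})

#' @export
setMethod("show", "OrthoGroup", function(object) {
  cat("OrthoGroup", object@groupId, "(cutoff", object@cutoff,
      "%, focal", object@focal, "):", length(object@members),
      "species\n")
})

#' Accessors for OrthoGroup slots
#' @param x an `OrthoGroup`
#' @return `groupMembers`: named character (species -> protein id);
#'   `groupId`: character id; `pairIdentities`: named numeric.
#' @export
groupMembers <- function(x) x@members

#' @rdname groupMembers
#' @export
groupId <- function(x) x@groupId

#' @rdname groupMembers
#' @export
pairIdentities <- function(x) x@pairIdentities

# ---------------------------------------------------------------------------
# MultiAlign: a multiple sequence alignment.
# ---------------------------------------------------------------------------

#' Multiple sequence alignment
#'
#' Rows are aligned sequences (gap character `-`), all of equal width.
#' Each row has an id (its name) and a species label used by the
#' congruence and concatenation machinery.
#'
#' @slot locusId locus identifier.
#' @slot aln named character vector of aligned strings, equal width.
#' @slot species character vector parallel to `aln` (same names).
#' @exportClass MultiAlign
setClass("MultiAlign",
         representation(locusId = "character", aln = "character",
                        species = "character"))

setValidity("MultiAlign", function(object) {
  if (length(object@aln) && length(unique(nchar(object@aln))) != 1L)
    return("all rows must have equal width")
  if (anyDuplicated(names(object@aln)))
    return("row ids must be unique")
  if (length(object@species) != length(object@aln))
    return("species must parallel aln")
  TRUE
})

#' Construct a MultiAlign
#'
#' @param aln named character vector of equal-width aligned strings.
#' @param species species labels (recycled from names if missing).
#' @param locusId locus identifier.
#' @return a [MultiAlign-class] object.
#' @export
MultiAlign <- function(aln, species = names(aln), locusId = "locus") {
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  names(species) <- names(aln)
  methods::new("MultiAlign", locusId = locusId, aln = toupper(aln),
               species = species)
}

#' @export
setMethod("show", "MultiAlign", function(object) {
  cat("MultiAlign", object@locusId, ":", length(object@aln), "rows x",
      alnWidth(object), "columns\n")
})

#' MultiAlign accessors
#' @param x a `MultiAlign`
#' @return `alnWidth`: number of columns; `alnStrings`: the named aligned
#'   strings; `alnSpecies`: species labels; `alnMatrix`: character matrix
#'   (rows = sequences, one character per cell).
#' @export
alnWidth <- function(x) if (length(x@aln)) nchar(x@aln[[1L]]) else 0L

#' @rdname alnWidth
#' @export
alnStrings <- function(x) x@aln

#' @rdname alnWidth
#' @export
alnSpecies <- function(x) x@species

#' @rdname alnWidth
#' @export
alnMatrix <- function(x) .alnMatrix(x@aln)

# ---------------------------------------------------------------------------
# FilterParams: numeric constants of the locus selection filters.
# ---------------------------------------------------------------------------

#' Locus selection filter parameters
#'
#' All numeric thresholds of the design-arm selection filters, on the
#' scales noted. Identity thresholds are percent; length variation is a
#' fraction; the identity-variance cap is in percent-squared units.
#'
#' @slot minLenNt minimum CDS length in bp (inclusive; default 300).
#' @slot maxLenVar maximum relative length variation (max-min)/max among
#'   species, exclusive (default 0.05).
#' @slot closestMin percent identity the phylogenetically closest species
#'   pairs must exceed (default 75).
#' @slot furthestMin percent identity the furthest pairs must exceed
#'   (default 70).
#' @slot longLenNt CDS length in bp above which the stricter closest-pair
#'   rule applies (default 1500).
#' @slot longClosestMin closest-pair percent identity threshold for long
#'   sequences (default 80).
#' @slot maxIdentityVariance maximum sample variance of all pairwise
#'   percent identities (default 130).
#' @slot trimMaxGapFrac maximum per-column gap fraction kept by
#'   [trimGappy()] (default 0.5).
#' @exportClass FilterParams
setClass("FilterParams",
         representation(minLenNt = "numeric", maxLenVar = "numeric",
                        closestMin = "numeric", furthestMin = "numeric",
                        longLenNt = "numeric", longClosestMin = "numeric",
                        maxIdentityVariance = "numeric",
                        trimMaxGapFrac = "numeric"))

setValidity("FilterParams", function(object) {
  ok <- object@minLenNt > 0 && object@maxLenVar > 0 && object@maxLenVar <= 1 &&
    object@closestMin >= 0 && object@closestMin <= 100 &&
    object@furthestMin >= 0 && object@furthestMin <= 100 &&
    object@longLenNt > 0 && object@longClosestMin >= 0 &&
    object@longClosestMin <= 100 && object@maxIdentityVariance > 0 &&
    object@trimMaxGapFrac >= 0 && object@trimMaxGapFrac <= 1
  if (!ok) return("a threshold is outside its stated range")
  TRUE
})

#' Construct selection-filter parameters
#'
#' @param minLenNt,maxLenVar,closestMin,furthestMin,longLenNt,longClosestMin,maxIdentityVariance,trimMaxGapFrac
#'   see [FilterParams-class] for meanings, units and defaults.
#' @return a [FilterParams-class] object.
#' @examples
#' filterParams()                   # the kit's published constants
#' filterParams(closestMin = 80)    # a stricter variant
#' @export
filterParams <- function(minLenNt = 300, maxLenVar = 0.05, closestMin = 75,
                         furthestMin = 70, longLenNt = 1500,
                         longClosestMin = 80, maxIdentityVariance = 130,
                         trimMaxGapFrac = 0.5) {
  methods::new("FilterParams", minLenNt = minLenNt, maxLenVar = maxLenVar,
               closestMin = closestMin, furthestMin = furthestMin,
               longLenNt = longLenNt, longClosestMin = longClosestMin,
               maxIdentityVariance = maxIdentityVariance,
               trimMaxGapFrac = trimMaxGapFrac)
}

#' @export
setMethod("show", "FilterParams", function(object) {
  cat("FilterParams: minLen", object@minLenNt, "bp; lenVar <",
      object@maxLenVar, "; closest >", object@closestMin,
      "%; furthest >", object@furthestMin, "%; long >", object@longLenNt,
      "bp => closest >", object@longClosestMin, "%; identity variance <=",
      object@maxIdentityVariance, "\n")
})

# ---------------------------------------------------------------------------
# FilterReport: per-group audit of the selection filters.
# ---------------------------------------------------------------------------

#' Selection filter report
#'
#' The ordered rule-by-rule audit of [applySelectionFilters()] for one
#' ortholog group. The group passes iff every rule passes.
#'
#' @slot groupId the group audited.
#' @slot verdict `"pass"` or `"fail"`.
#' @slot rules data.frame with columns `rule`, `observed`, `threshold`,
#'   `outcome` in evaluation order.
#' @exportClass FilterReport
setClass("FilterReport",
         representation(groupId = "character", verdict = "character",
                        rules = "data.frame"))

setValidity("FilterReport", function(object) {
  if (!object@verdict %in% c("pass", "fail")) return("verdict must be pass/fail")
  anyFail <- any(object@rules$outcome == "fail")
  if ((object@verdict == "fail") != anyFail)
    return("verdict must be fail iff at least one rule fails")
  TRUE
})

#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport", object@groupId, "->", object@verdict, "\n")
  print(object@rules, row.names = FALSE)
})

#' FilterReport accessors
#' @param x a `FilterReport`
#' @export
filterVerdict <- function(x) x@verdict

#' @rdname filterVerdict
#' @export
filterRules <- function(x) x@rules

# ---------------------------------------------------------------------------
# TargetRegion / BaitSet
# ---------------------------------------------------------------------------

#' Selected exonic target with per-species variants
#'
#' @slot regionId region identifier (the originating group id).
#' @slot variants named character vector of nucleotide CDS strings, one
#'   per member species (names are species labels).
#' @exportClass TargetRegion
setClass("TargetRegion",
         representation(regionId = "character", variants = "character"))

setValidity("TargetRegion", function(object) {
  if (length(object@variants) < 1L) return("at least one variant required")
  if (anyDuplicated(names(object@variants)))
    return("one variant per species")
  TRUE
})

#' @export
setMethod("show", "TargetRegion", function(object) {
  cat("TargetRegion", object@regionId, ":", length(object@variants),
      "variant(s),", max(nchar(object@variants)), "bp (longest)\n")
})

#' TargetRegion accessors
#' @param x a `TargetRegion`
#' @export
regionVariants <- function(x) x@variants

#' @rdname regionVariants
#' @export
regionId <- function(x) x@regionId

#' Tiled bait set
#'
#' The baits tiled across every variant of every target region, plus the
#' regions themselves.
#'
#' @slot baits data.frame with columns `bait_id`, `region_id`, `species`,
#'   `start` (0-based on the variant), `length`, `seq`.
#' @slot regions list of [TargetRegion-class] objects, by region id.
#' @slot baitLen bait length in bp.
#' @slot step start-to-start spacing in bp.
#' @exportClass BaitSet
setClass("BaitSet",
         representation(baits = "data.frame", regions = "list",
                        baitLen = "numeric", step = "numeric"))

#' @export
setMethod("show", "BaitSet", function(object) {
  cat("BaitSet:", nrow(object@baits), "baits of", object@baitLen,
      "bp over", length(object@regions), "region(s), step",
      object@step, "bp\n")
})

#' BaitSet accessors
#' @param x a `BaitSet`
#' @export
baits <- function(x) x@baits

#' @rdname baits
#' @export
baitRegions <- function(x) x@regions

# ---------------------------------------------------------------------------
# RecoveryMatrix: locus x sample recovery lengths (SummarizedExperiment).
# ---------------------------------------------------------------------------

#' Locus-by-sample capture recovery matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass whose
#' single assay `recovered` holds the recovered length (bp, 0 when
#' absent) of each locus (rows) in each sample (columns). Per-locus
#' target lengths live in `rowData(x)$target_len`; an optional sample
#' grouping (e.g. subfamily) in `colData(x)$group`.
#'
#' @exportClass RecoveryMatrix
setClass("RecoveryMatrix", contains = "SummarizedExperiment")

setValidity("RecoveryMatrix", function(object) {
  if (!"recovered" %in% SummarizedExperiment::assayNames(object))
    return("assay 'recovered' is required")
  rec <- SummarizedExperiment::assay(object, "recovered")
  if (any(rec < 0)) return("recovered lengths must be non-negative")
  tl <- SummarizedExperiment::rowData(object)$target_len
  if (is.null(tl)) return("rowData column 'target_len' is required")
  if (any(tl < 0)) return("target lengths must be non-negative")
  TRUE
})

#' Construct a RecoveryMatrix
#'
#' @param recovered numeric matrix, loci (rows, named) x samples
#'   (columns, named), of recovered lengths in bp (0 = absent).
#' @param targetLen numeric vector of per-locus target lengths in bp,
#'   parallel to the rows.
#' @param group optional character vector of sample group labels,
#'   parallel to the columns.
#' @return a [RecoveryMatrix-class] object.
#' @export
RecoveryMatrix <- function(recovered, targetLen, group = NULL) {
  recovered <- as.matrix(recovered)
  if (is.null(rownames(recovered)))
    rownames(recovered) <- paste0("locus", seq_len(nrow(recovered)))
  if (is.null(colnames(recovered)))
    colnames(recovered) <- paste0("sample", seq_len(ncol(recovered)))
  rd <- S4Vectors::DataFrame(target_len = as.numeric(targetLen),
                             row.names = rownames(recovered))
  cd <- S4Vectors::DataFrame(row.names = colnames(recovered))
  if (!is.null(group)) cd$group <- as.character(group)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(recovered = recovered), rowData = rd, colData = cd)
  methods::new("RecoveryMatrix", se)
}

#' RecoveryMatrix accessors
#'
#' @param x a [RecoveryMatrix-class]
#' @return `targetLen`: named numeric per-locus target lengths;
#'   `recoveredLen`: the loci x samples matrix; `sampleGroups`: named
#'   character group labels (or NULL); `recoveryFractions`: recovered /
#'   target, capped at 1 (capture overhang past the target does not count
#'   towards completeness).
#' @export
targetLen <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$target_len, rownames(x))
}

#' @rdname targetLen
#' @export
recoveredLen <- function(x) SummarizedExperiment::assay(x, "recovered")

#' @rdname targetLen
#' @export
sampleGroups <- function(x) {
  g <- SummarizedExperiment::colData(x)$group
  if (is.null(g)) return(NULL)
  setNames(g, colnames(x))
}

#' @rdname targetLen
#' @export
recoveryFractions <- function(x) {
  tl <- targetLen(x)
  if (any(tl == 0))
    stop("zero target length for locus: ",
         paste(rownames(x)[tl == 0], collapse = ", "))
  pmin(recoveredLen(x) / tl, 1)
}
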