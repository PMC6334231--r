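# Degenerate bait tiling: every surviving group becomes one target
# region whose per-species CDS "variants" are all tiled, so a single
# exon is represented by up to one bait series per member species.

#' Collect target regions from filter-passing groups
#'
#' One [TargetRegion-class] per group, one variant per member species.
#' Region ids are the (deterministic) group ids.
#'
#' @param groups list of [OrthoGroup-class] objects that passed the
#'   selection filters.
#' @param variantSeqs named list keyed by group id; each element a named
#'   character vector species -> CDS nucleotide string.
#' @param minLenNt variants shorter than this are rejected with an error
#'   (default 300, matching [filterParams()]).
#' @return named list of [TargetRegion-class] objects (empty, with a
#'   warning, if `groups` is empty).
#' @export
collectVariants <- function(groups, variantSeqs, minLenNt = 300) {
  if (length(groups) == 0L) {
    warning("no groups passed the filters; empty kit")
    return(list())
  }
  out <- list()
  for (g in groups) {
    gid <- groupId(g)
    v <- variantSeqs[[gid]]
    if (is.null(v)) stop("no variant sequences for group ", gid)
    v <- toupper(v[sort(names(v))])
    if (any(nchar(v) < minLenNt))
      stop("variant shorter than ", minLenNt, " bp in region ", gid)
    out[[gid]] <- methods::new("TargetRegion", regionId = gid, variants = v)
  }
  out[order(names(out))]
}

#' Tile baits across one target region
#'
#' Per variant, bait start positions run 0, step, 2*step, ... while
#' start + baitLen <= L; when (L - baitLen) is not a multiple of the
#' step, one extra end-anchored bait at start = L - baitLen guarantees
#' the 3' end is covered. Defaults (120 bp baits, 40 bp start spacing)
#' give 3x tiling of interior positions.
#'
#' @param region a [TargetRegion-class].
#' @param baitLen bait length in bp (default 120).
#' @param step start-to-start spacing in bp (default 40).
#' @return data.frame of baits with columns `bait_id`, `region_id`,
#'   `species`, `start` (0-based on the variant), `length`, `seq`,
#'   sorted by species then start.
#' @examples
#' r <- methods::new("TargetRegion", regionId = "r1",
#'                   variants = c(sp1 = strrep("ACGT", 50)))  # L = 200
#' tileBaits(r)$start  # 0 40 80
#' @export
tileBaits <- function(region, baitLen = 120, step = 40) {
  .assertScalarNumber(baitLen, "baitLen", lower = 1)
  .assertScalarNumber(step, "step", lower = 1)
  v <- regionVariants(region)
  short <- nchar(v) < baitLen
  if (any(short))
    stop("variant(s) shorter than the bait length in region ",
         regionId(region), ": ", paste(names(v)[short], collapse = ", "))
  rows <- lapply(sort(names(v)), function(sp) {
    L <- nchar(v[[sp]])
    starts <- seq.int(0L, L - baitLen, by = step)
    if ((L - baitLen) %% step != 0L) starts <- c(starts, L - baitLen)
    data.frame(bait_id = sprintf("%s|%s|%d", regionId(region), sp, starts),
               region_id = regionId(region), species = sp, start = starts,
               length = baitLen,
               seq = substring(v[[sp]], starts + 1L, starts + baitLen),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Closed-form bait count for one variant length
#'
#' floor((L - baitLen)/step) + 1, plus one end-anchored bait when
#' (L - baitLen) is not a multiple of the step.
#'
#' @param L variant length (>= baitLen).
#' @param baitLen,step as in [tileBaits()].
#' @return integer bait count.
#' @export
baitCount <- function(L, baitLen = 120, step = 40) {
  r <- L - baitLen
  as.integer(r %/% step + 1L + (r %% step != 0L))
}

#' Build a bait set from target regions
#'
#' @param regions list of [TargetRegion-class] objects.
#' @param baitLen,step as in [tileBaits()].
#' @return a [BaitSet-class].
#' @export
buildBaitSet <- function(regions, baitLen = 120, step = 40) {
  tabs <- lapply(regions, tileBaits, baitLen = baitLen, step = step)
  bt <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(bait_id = character(0), region_id = character(0),
               species = character(0), start = integer(0),
               length = integer(0), seq = character(0))
  rownames(bt) <- NULL
  names(regions) <- vapply(regions, regionId, character(1))
  methods::new("BaitSet", baits = bt, regions = regions,
               baitLen = baitLen, step = step)
}

#' Kit-level summary of a bait set
#'
#' Counts unique regions and variant sequences, the region multiplicity
#' histogram (regions present as 1, 2, ... variants), the capture
#' footprint and the total bait count. The footprint counts every
#' unique region once, using its longest variant as the representative
#' length.
#'
#' @param baitSet a [BaitSet-class].
#' @return list with `n_unique_regions`, `n_variant_sequences`,
#'   `multiplicity` (named integer table), `footprint_bp`, `n_baits`.
#' @export
kitSummary <- function(baitSet) {
  regions <- baitRegions(baitSet)
  if (length(regions) == 0L)
    return(list(n_unique_regions = 0L, n_variant_sequences = 0L,
                multiplicity = integer(0), footprint_bp = 0L, n_baits = 0L))
  nv <- vapply(regions, function(r) length(regionVariants(r)), integer(1))
  mult <- table(factor(nv, levels = seq_len(max(nv))))
  mult <- setNames(as.integer(mult), names(mult))
  list(n_unique_regions = length(regions),
       n_variant_sequences = sum(nv),
       multiplicity = mult,
       footprint_bp = sum(vapply(regions, function(r)
         max(nchar(regionVariants(r))), numeric(1))),
       n_baits = nrow(baits(baitSet)))
}

#' Export baits as FASTA
#'
#' Bait ids are `region|species|start`.
#'
#' @param baitSet a [BaitSet-class].
#' @param path output path.
#' @export
exportBaitFasta <- function(baitSet, path) {
  b <- baits(baitSet)
  writeFasta(setNames(b$seq, b$bait_id), path)
}

#' Export baits as BED (0-based half-open, one line per bait on its
#' variant, named `<region>|<species>`).
#'
#' @inheritParams exportBaitFasta
#' @export
exportBaitBed <- function(baitSet, path) {
  b <- baits(baitSet)
  bed <- data.frame(chrom = paste(b$region_id, b$species, sep = "|"),
                    start = b$start, end = b$start + b$length,
                    name = b$bait_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
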