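# Alignment statistics and supermatrix assembly.

#' Count parsimony-informative sites
#'
#' A column is parsimony informative iff at least two distinct
#' unambiguous states each occur in at least two rows. Gaps, N and `?`
#' are not states. Nucleotide alignments use A/C/G/T; protein
#' alignments the 20 standard residues.
#'
#' @param msa a [MultiAlign-class].
#' @return integer count (0 for an empty or invariant alignment).
#' @examples
#' countPIS(MultiAlign(c(a = "AT", b = "AT", c = "TT", d = "TA")))  # 1
#' @export
countPIS <- function(msa) {
  m <- alnMatrix(msa)
  if (ncol(m) == 0L) return(0L)
  dna <- all(m %in% c("A", "C", "G", "T", "N", "-", "?"))
  states <- if (dna) c("A", "C", "G", "T")
            else strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  informative <- apply(m, 2L, function(col) {
    tab <- table(col[col %in% states])
    sum(tab >= 2L) >= 2L
  })
  sum(informative)
}

#' Per-locus alignment statistics
#'
#' @param msas list of [MultiAlign-class] objects.
#' @return data.frame with `locus`, `n_rows`, `width`, `pis`.
#' @export
alignmentStats <- function(msas) {
  rows <- lapply(msas, function(a)
    data.frame(locus = a@locusId, n_rows = length(a@aln),
               width = alnWidth(a), pis = countPIS(a),
               stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concatenate locus alignments into a supermatrix
#'
#' Loci are ordered lexicographically by id for reproducibility.
#' Samples missing from a locus receive an all-gap row, so every sample
#' spans the full supermatrix. The partition table maps each locus to
#' its 1-based inclusive column range.
#'
#' @param msas list of [MultiAlign-class] objects (row ids are sample
#'   ids; at most one row per sample within a locus).
#' @param samples master sample ordering; defaults to the sorted union
#'   of all row ids.
#' @return list with `supermatrix` (a [MultiAlign-class]) and
#'   `partitions` (data.frame `locus`, `start`, `end`).
#' @export
concatenateLoci <- function(msas, samples = NULL) {
  if (length(msas) == 0L) stop("no alignments to concatenate")
  ids <- vapply(msas, function(a) a@locusId, character(1))
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  msas <- msas[order(ids)]
  ids <- sort(ids)
  for (a in msas)
    if (anyDuplicated(names(a@aln)))
      stop("duplicate sample within locus ", a@locusId)
  if (is.null(samples))
    samples <- sort(unique(unlist(lapply(msas, function(a) names(a@aln)))))

  widths <- vapply(msas, alnWidth, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  parts <- data.frame(locus = ids, start = starts, end = ends,
                      stringsAsFactors = FALSE)

  pieces <- lapply(msas, function(a) {
    w <- alnWidth(a)
    out <- setNames(rep(strrep("-", w), length(samples)), samples)
    present <- intersect(samples, names(a@aln))
    out[present] <- a@aln[present]
    out
  })
  sm <- do.call(function(...) paste0(...), pieces)
  names(sm) <- samples
  list(supermatrix = MultiAlign(sm, species = samples,
                                locusId = "supermatrix"),
       partitions = parts)
}

#' Write a RAxML-style partition file
#'
#' One line per locus, exactly `DNA, <locus_id> = <start>-<end>`.
#'
#' @param partitions the partition table from [concatenateLoci()].
#' @param path output path.
#' @export
writePartitions <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Slice one locus back out of a supermatrix
#'
#' @param supermatrix the concatenated [MultiAlign-class].
#' @param partitions the partition table.
#' @param locus locus id to extract.
#' @return a [MultiAlign-class] with the gap-filled rows of that locus.
#' @export
slicePartition <- function(supermatrix, partitions, locus) {
  i <- match(locus, partitions$locus)
  if (is.na(i)) stop("unknown locus: ", locus)
  s <- substring(alnStrings(supermatrix), partitions$start[i],
                 partitions$end[i])
  MultiAlign(setNames(s, names(supermatrix@aln)),
             species = supermatrix@species, locusId = locus)
}
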