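# 75/75 locus selection and its bookkeeping: the quality-control rule
# that keeps loci with >= 75% of their target length recovered in
# >= 75% of samples, the threshold sweep reported for capture
# experiments, and shared-locus set logic between sample groups.

#' Read / write a recovery-length table
#'
#' The native dialect is a UTF-8 TSV whose header row is `sample`
#' followed by the locus ids; the first data row carries the literal
#' sample id `TARGET_LEN` with the per-locus target lengths, and each
#' subsequent row one sample's recovered lengths. The HybPiper
#' `seq_lengths` layout (same shape, mean-length row labelled
#' `MeanLength`) is accepted with `dialect = "hybpiper"`, in which case
#' the mean-length row is dropped and target lengths must be supplied.
#'
#' @param path TSV path.
#' @param dialect `"native"` or `"hybpiper"`.
#' @param targetLen per-locus target lengths, required for the HybPiper
#'   dialect (named numeric, names = locus ids).
#' @param group optional named character vector sample -> group label.
#' @return a [RecoveryMatrix-class].
#' @export
readRecoveryMatrix <- function(path, dialect = c("native", "hybpiper"),
                               targetLen = NULL, group = NULL) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  loci <- colnames(tab)[-1L]
  rown <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (dialect == "native") {
    if (rown[1L] != "TARGET_LEN")
      stop("native dialect requires a first data row 'TARGET_LEN'")
    tl <- as.numeric(m[1L, ])
    rec <- m[-1L, , drop = FALSE]
    rownames(rec) <- rown[-1L]
  } else {
    keep <- !(rown %in% c("MeanLength", "TARGET_LEN"))
    rec <- m[keep, , drop = FALSE]
    rownames(rec) <- rown[keep]
    if (is.null(targetLen))
      stop("HybPiper dialect requires explicit target lengths")
    tl <- as.numeric(targetLen[loci])
    if (anyNA(tl)) stop("target lengths missing for some loci")
  }
  g <- if (!is.null(group)) unname(group[rownames(rec)]) else NULL
  RecoveryMatrix(t(rec), tl, group = g)
}

#' @rdname readRecoveryMatrix
#' @param x a [RecoveryMatrix-class].
#' @export
writeRecoveryMatrix <- function(x, path) {
  rec <- recoveredLen(x)
  out <- rbind(TARGET_LEN = targetLen(x), t(rec))
  df <- data.frame(sample = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Select loci by the 75/75 rule
#'
#' A locus is selected iff the fraction of samples whose recovered
#' length reaches `lenFrac` of the target is at least `sampleFrac`.
#' Both thresholds are inclusive; recovery fractions are capped at 1
#' (overhang past the target does not count).
#'
#' @param x a [RecoveryMatrix-class].
#' @param lenFrac minimum recovered fraction of the target length
#'   (default 0.75).
#' @param sampleFrac minimum fraction of samples meeting `lenFrac`
#'   (default 0.75).
#' @return character vector of selected locus ids, in matrix row order.
#' @export
selectLoci <- function(x, lenFrac = 0.75, sampleFrac = 0.75) {
  .assertScalarNumber(lenFrac, "lenFrac", lower = 0, upper = 1)
  .assertScalarNumber(sampleFrac, "sampleFrac", lower = 1e-12, upper = 1)
  fr <- recoveryFractions(x)
  ok <- if (lenFrac > 0) fr >= lenFrac else fr > 0
  rownames(x)[rowMeans(ok) >= sampleFrac]
}

#' Locus counts across recovery-length thresholds
#'
#' Applies [selectLoci()] at each length threshold with the sample
#' fraction held fixed; the 0 threshold means "any nonzero recovery".
#' Counts are non-increasing as the length threshold rises.
#'
#' @param x a [RecoveryMatrix-class].
#' @param lenFracs length thresholds (default 0, 0.25, 0.5, 0.75, 0.95).
#' @param sampleFrac fixed sample fraction (default 0.75).
#' @return named integer vector of locus counts per threshold.
#' @export
thresholdSweep <- function(x, lenFracs = c(0, 0.25, 0.5, 0.75, 0.95),
                           sampleFrac = 0.75) {
  counts <- vapply(lenFracs, function(lf)
    length(selectLoci(x, lf, sampleFrac)), integer(1))
  setNames(counts, paste0(">=", lenFracs * 100, "%"))
}

#' Shared 75/75 locus sets between sample groups
#'
#' Runs [selectLoci()] within each sample group and returns the
#' per-group sets together with the full inclusion-exclusion (Venn)
#' region counts; supports up to 4 groups.
#'
#' @param x a [RecoveryMatrix-class] whose samples all carry a group
#'   label (`colData(x)$group` or the `grouping` argument).
#' @param grouping optional named character vector sample -> group.
#' @param lenFrac,sampleFrac selection thresholds (defaults 0.75/0.75).
#' @return list with `sets` (named list of per-group locus id vectors)
#'   and `regions` (named integer vector of exclusive Venn region
#'   sizes; names are `+`-joined group combinations).
#' @export
sharedLocusSets <- function(x, grouping = NULL, lenFrac = 0.75,
                            sampleFrac = 0.75) {
  if (is.null(grouping)) grouping <- sampleGroups(x)
  if (is.null(grouping)) stop("no sample grouping available")
  if (!all(colnames(x) %in% names(grouping)))
    stop("every sample must be grouped")
  groups <- sort(unique(unname(grouping[colnames(x)])))
  if (length(groups) > 4L) stop("Venn region counts support at most 4 groups")
  sets <- lapply(groups, function(g) {
    cols <- colnames(x)[grouping[colnames(x)] == g]
    if (length(cols) == 0L) stop("empty group: ", g)
    selectLoci(x[, cols], lenFrac, sampleFrac)
  })
  names(sets) <- groups
  combos <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, simplify = FALSE)), recursive = FALSE)
  regions <- vapply(combos, function(cm) {
    inside <- Reduce(intersect, sets[cm])
    outside <- unlist(sets[setdiff(groups, cm)], use.names = FALSE)
    length(setdiff(inside, outside))
  }, integer(1))
  names(regions) <- vapply(combos, paste, character(1), collapse = "+")
  list(sets = sets, regions = regions)
}
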