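# Per-group multiple alignment: deterministic guide-tree progressive
# alignment (pairwise distance matrix -> UPGMA -> profile-profile
# merges) with the same scoring scheme as the pairwise primitives, and
# gap-fraction column trimming.

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive alignment: percent-identity distances from
#' all-vs-all pairwise alignment, a UPGMA guide tree (average linkage),
#' then profile-profile merges in guide-tree order. Profiles are scored
#' column-against-column by the average substitution score of their
#' residues (gaps contribute zero); end gaps are charged so terminal
#' regions align compactly.
#'
#' @param seqs two or more residue strings (named character vector or
#'   XStringSet); species labels may be supplied via `species`.
#' @param species optional species labels, one per sequence.
#' @param locusId id for the returned alignment.
#' @param params an [alignParams()] list.
#' @param type `"auto"`, `"protein"` or `"dna"`.
#' @return a [MultiAlign-class] with rows in input order.
#' @examples
#' a <- progressiveAlign(c(x = "MKVL", y = "MKL"))
#' alnStrings(a)
#' @export
progressiveAlign <- function(seqs, species = NULL, locusId = "locus",
                             params = alignParams(),
                             type = c("auto", "protein", "dna")) {
  seqs <- .asSeqChar(seqs)
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(species)) species <- names(seqs)
  al <- .alignAlphabet(seqs, params, type)
  n <- length(seqs)

  st <- pairStats(seqs, params, type)
  d <- 100 - st$identity
  hc <- hclust(as.dist(d), method = "average")

  codes <- rownames(al$sub)
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    pa <- if (a < 0) profiles[[-a]] else merged[[a]]
    pb <- if (b < 0) profiles[[-b]] else merged[[b]]
    merged[[k]] <- .mergeProfiles(pa, pb, al$sub, codes, params)
  }
  final <- merged[[n - 1L]]
  final <- final[names(seqs), , drop = FALSE]  # restore input order
  MultiAlign(.collapseRows(final), species = setNames(species, names(seqs)),
             locusId = locusId)
}

# Align two profiles (character matrices, rows = sequences) and return
# the merged profile. Column score = mean substitution score over all
# residue pairs; gap cells score 0 against anything.
#' @noRd
.mergeProfiles <- function(pa, pb, sub, codes, params) {
  fa <- .profileFreqs(pa, codes)
  fb <- .profileFreqs(pb, codes)
  S <- fa %*% sub %*% t(fb)
  path <- cpp_affine_path(S, params$gapOpen, params$gapExt)
  la <- ncol(pa); lb <- ncol(pb)
  out <- matrix("-", nrow(pa) + nrow(pb), length(path),
                dimnames = list(c(rownames(pa), rownames(pb)), NULL))
  ia <- 0L; ib <- 0L
  ra <- seq_len(nrow(pa)); rb <- nrow(pa) + seq_len(nrow(pb))
  for (k in seq_along(path)) {
    mv <- path[k]
    if (mv == 1L || mv == 2L) { ia <- ia + 1L; out[ra, k] <- pa[, ia] }
    if (mv == 1L || mv == 3L) { ib <- ib + 1L; out[rb, k] <- pb[, ib] }
  }
  stopifnot(ia == la, ib == lb)
  out
}

# Residue frequency matrix (columns x codes), gaps excluded; frequencies
# are per-row so a column's weight does not depend on profile size.
#' @noRd
.profileFreqs <- function(p, codes) {
  f <- matrix(0, ncol(p), length(codes))
  colnames(f) <- codes
  nr <- nrow(p)
  for (i in seq_len(nr)) {
    idx <- match(p[i, ], codes)
    ok <- !is.na(idx)
    f[cbind(which(ok), idx[ok])] <- f[cbind(which(ok), idx[ok])] + 1 / nr
  }
  f
}

#' Remove gap-rich alignment columns
#'
#' Keeps exactly the columns whose gap fraction is at most
#' `maxGapFrac`, preserving order. The old-to-new column mapping is
#' returned alongside the trimmed alignment.
#'
#' @param msa a [MultiAlign-class].
#' @param maxGapFrac maximum tolerated per-column gap fraction
#'   (default 0.5: sites with more than 50% gaps are removed).
#' @return list with `msa` (trimmed [MultiAlign-class]) and `colMap`
#'   (integer vector of the original indices of the surviving columns).
#' @export
trimGappy <- function(msa, maxGapFrac = 0.5) {
  .assertScalarNumber(maxGapFrac, "maxGapFrac", lower = 0, upper = 1)
  m <- alnMatrix(msa)
  if (ncol(m) == 0L) return(list(msa = msa, colMap = integer(0)))
  gapFrac <- colMeans(m == "-")
  keep <- which(gapFrac <= maxGapFrac)
  if (length(keep) == 0L)
    warning("all columns removed from ", msa@locusId)
  trimmed <- MultiAlign(.collapseRows(m[, keep, drop = FALSE]),
                        species = msa@species, locusId = msa@locusId)
  list(msa = trimmed, colMap = keep)
}
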