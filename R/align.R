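# Pairwise similarity primitives. The similarity search used throughout
# the design arm is exhaustive optimal pairwise alignment (Gotoh, affine
# gaps, free end gaps) rather than a seeded heuristic: inputs are
# desk-scale (at most a few thousand proteins) so exact all-vs-all
# search is tractable and fully deterministic, and score/identity/
# coverage thresholds replace E-values.

#' Alignment scoring parameters
#'
#' Substitution matrix and affine gap penalties used by every alignment
#' in the package. A gap of length k costs `gapOpen + k * gapExt`.
#' Defaults are the classic protein-search settings: BLOSUM62 with gap
#' open 11 and extension 1. Nucleotide inputs use a +5/-4
#' match/mismatch matrix (N neutral) under the same gap costs.
#'
#' @param gapOpen gap opening penalty (>= 0).
#' @param gapExt gap extension penalty per residue (> 0).
#' @param proteinMatrix substitution matrix for amino acids; default
#'   BLOSUM62 (from Biostrings).
#' @param dnaMatch,dnaMismatch nucleotide match/mismatch scores.
#' @return a list of class `alignParams`.
#' @export
alignParams <- function(gapOpen = 11, gapExt = 1, proteinMatrix = NULL,
                        dnaMatch = 5, dnaMismatch = -4) {
  .assertScalarNumber(gapOpen, "gapOpen", lower = 0)
  .assertScalarNumber(gapExt, "gapExt", lower = 1e-9)
  if (is.null(proteinMatrix)) proteinMatrix <- .blosum62()
  structure(list(gapOpen = gapOpen, gapExt = gapExt,
                 proteinMatrix = proteinMatrix,
                 dnaMatrix = .dnaMatrix(dnaMatch, dnaMismatch)),
            class = "alignParams")
}

.blosumCache <- new.env(parent = emptyenv())

#' @noRd
.blosum62 <- function() {
  if (is.null(.blosumCache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumCache$B62 <- e$BLOSUM62
  }
  .blosumCache$B62
}

#' @noRd
.dnaMatrix <- function(match = 5, mismatch = -4) {
  codes <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(codes, codes))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# Pick the matrix for a pair/set of sequences and check alphabet
# consistency. DNA = strings over ACGTN only.
#' @noRd
.alignAlphabet <- function(seqs, params, type = c("auto", "protein", "dna")) {
  type <- match.arg(type)
  if (type == "auto") {
    isDna <- vapply(seqs, .isDnaAlphabet, logical(1))
    if (any(isDna) && !all(isDna))
      stop("mixed alphabets: some sequences are nucleotide, others protein")
    type <- if (all(isDna)) "dna" else "protein"
  }
  sub <- if (type == "dna") params$dnaMatrix else params$proteinMatrix
  bad <- !grepl(sprintf("^[%s-]*$", paste(rownames(sub), collapse = "")), seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside the ", type,
         " alphabet (mixed alphabets?): ",
         paste(head(names(seqs)[bad], 3), collapse = ", "))
  list(type = type, sub = sub)
}

# The pairwise kernels score in exact integer arithmetic; substitution
# scores and gap penalties must therefore be integer-valued (as BLOSUM
# matrices and the classic gap costs are).
#' @noRd
.intScoring <- function(sub, params) {
  if (any(sub != round(sub)) || params$gapOpen != round(params$gapOpen) ||
      params$gapExt != round(params$gapExt))
    stop("pairwise alignment requires integer-valued scores and gap penalties")
  storage.mode(sub) <- "integer"
  list(sub = sub, open = as.integer(params$gapOpen),
       ext = as.integer(params$gapExt))
}

# Encode sequences as 0-based integer codes into the substitution matrix.
#' @noRd
.encodeSeqs <- function(seqs, sub) {
  codes <- rownames(sub)
  lut <- integer(256)
  lut[utf8ToInt(paste(codes, collapse = "")) + 1L] <- seq_along(codes)
  lapply(seqs, function(s) {
    v <- lut[utf8ToInt(s) + 1L]
    if (any(v == 0L)) stop("unencodable residue in sequence")
    v - 1L
  })
}

#' Optimal global pairwise alignment
#'
#' End-gap-free global (overlap) alignment of two residue strings under
#' the configured substitution matrix and affine gap penalties. Percent
#' identity is defined as matches / min(length a, length b) * 100 — the
#' shorter-sequence convention used uniformly by the clustering,
#' screening and selection filters. Coverages are the fraction of each
#' sequence's residues lying inside the aligned region.
#'
#' @param a,b residue strings (non-empty, same alphabet), optionally
#'   named length-1 character vectors; names become the hit ids.
#' @param params an [alignParams()] list.
#' @param type `"auto"` (default), `"protein"` or `"dna"`.
#' @return a one-row [S4Vectors::DataFrame] with columns `query_id`,
#'   `target_id`, `score`, `pct_identity`, `aln_cols`, `q_cov`, `t_cov`.
#' @examples
#' globalAlign("ACDEFG", "ACDEFG")$pct_identity  # 100
#' globalAlign("ACDEFG", "ACDEFN")$pct_identity  # 83.33
#' @export
globalAlign <- function(a, b, params = alignParams(),
                        type = c("auto", "protein", "dna")) {
  qid <- if (!is.null(names(a))) names(a)[[1L]] else "query"
  tid <- if (!is.null(names(b))) names(b)[[1L]] else "target"
  a <- toupper(a[[1L]]); b <- toupper(b[[1L]])
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("cannot align an empty sequence")
  al <- .alignAlphabet(setNames(c(a, b), c(qid, tid)), params, type)
  sc <- .intScoring(al$sub, params)
  # Canonical orientation: co-optimal alignments are resolved by a fixed
  # traceback preference, so statistics are made exactly symmetric under
  # operand swap by always aligning in sorted-sequence order.
  swap <- a > b
  enc <- if (swap) .encodeSeqs(c(b, a), sc$sub) else .encodeSeqs(c(a, b), sc$sub)
  st <- cpp_gotoh_stats(enc[[1L]], enc[[2L]], sc$sub, sc$open, sc$ext)
  if (swap) {
    st[c("q_start", "t_start")] <- st[c("t_start", "q_start")]
    st[c("q_end", "t_end")] <- st[c("t_end", "q_end")]
  }
  la <- nchar(a); lb <- nchar(b)
  qcov <- if (st$aln_cols > 0) (st$q_end - st$q_start + 1) / la else 0
  tcov <- if (st$aln_cols > 0) (st$t_end - st$t_start + 1) / lb else 0
  S4Vectors::DataFrame(query_id = qid, target_id = tid, score = st$score,
                       pct_identity = 100 * st$matches / min(la, lb),
                       aln_cols = st$aln_cols, q_cov = qcov, t_cov = tcov)
}

#' All-vs-all pairwise statistics within one protein set
#'
#' Computes score, percent identity and coverages for every unordered
#' pair of a sequence set in one pass; the result is shared by
#' [clusterProteins()] and [selfScreen()] so each pair is aligned once.
#'
#' @param seqs named character vector or XStringSet.
#' @inheritParams globalAlign
#' @return list of square matrices `score`, `identity`, `cov` (row
#'   sequence's coverage against the column sequence), with sequence ids
#'   as dimnames. Diagonals are self-hits (identity 100, coverage 1).
#' @export
pairStats <- function(seqs, params = alignParams(),
                      type = c("auto", "protein", "dna")) {
  seqs <- .asSeqChar(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  al <- .alignAlphabet(seqs, params, type)
  dm <- list(ids, ids)
  score <- matrix(0, n, n, dimnames = dm)
  ident <- matrix(100, n, n, dimnames = dm)
  cov <- matrix(1, n, n, dimnames = dm)
  if (n >= 2L) {
    sc <- .intScoring(al$sub, params)
    enc <- .encodeSeqs(seqs, sc$sub)
    pairs <- t(combn(n, 2L))
    st <- cpp_pair_stats_many(enc, pairs, sc$sub, sc$open, sc$ext)
    len <- nchar(seqs)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      score[i, j] <- score[j, i] <- st[k, 1L]
      id <- 100 * st[k, 2L] / min(len[i], len[j])
      ident[i, j] <- ident[j, i] <- id
      if (st[k, 3L] > 0) {
        cov[i, j] <- (st[k, 5L] - st[k, 4L] + 1) / len[i]
        cov[j, i] <- (st[k, 7L] - st[k, 6L] + 1) / len[j]
      } else {
        cov[i, j] <- cov[j, i] <- 0
      }
    }
  }
  # self-hit diagonal: score of aligning a sequence to itself
  for (i in seq_len(n)) {
    sub <- al$sub
    score[i, i] <- sum(diag(sub)[match(strsplit(seqs[[i]], "")[[1L]],
                                       rownames(sub))])
  }
  list(score = score, identity = ident, cov = cov)
}

#' Cross-set alignment score matrix
#'
#' Score-only overlap alignment of every sequence in `seqsA` against
#' every sequence in `seqsB`; the workhorse behind [bestHitMap()].
#'
#' @param seqsA,seqsB named character vectors or XStringSets.
#' @inheritParams globalAlign
#' @return numeric matrix of scores, rows = `seqsA` ids, cols = `seqsB`.
#' @export
crossScoreMatrix <- function(seqsA, seqsB, params = alignParams(),
                             type = c("auto", "protein", "dna")) {
  seqsA <- .asSeqChar(seqsA); seqsB <- .asSeqChar(seqsB)
  al <- .alignAlphabet(c(seqsA, seqsB), params, type)
  sc <- .intScoring(al$sub, params)
  encA <- .encodeSeqs(seqsA, sc$sub)
  encB <- .encodeSeqs(seqsB, sc$sub)
  m <- cpp_score_matrix(encA, encB, sc$sub, sc$open, sc$ext)
  dimnames(m) <- list(names(seqsA), names(seqsB))
  m
}

# Identity between two specific sequences (used for group pair
# identities); shares the globalAlign machinery.
#' @noRd
.pairIdentity <- function(a, b, params, type = "auto") {
  globalAlign(a, b, params, type)$pct_identity
}
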