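# ORF extraction: six-frame scan for ATG..stop open reading frames.
# Nested ATGs upstream of the same stop are collapsed to the longest ORF
# per (strand, frame, stop) — the usual longest-ORF convention — so a
# methionine-rich CDS does not fan out into dozens of nested fragments.

#' Extract open reading frames from transcripts
#'
#' Scans all six reading frames of each input contig for ORFs beginning
#' at ATG. With `requireFull = TRUE` (the default) only complete ORFs —
#' start codon and stop codon both present — are returned; otherwise a
#' trailing ATG-to-sequence-end fragment per frame is also reported.
#' For every (strand, frame, stop codon) the longest ORF (the first ATG
#' after the previous in-frame stop) is kept. Coordinates are recorded
#' 0-based half-open on the forward strand and include the stop codon.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   nucleotide contigs; an optional `mcols(seqs)$species` (or the
#'   `species` argument) attaches a species label to every protein.
#' @param minAA minimum protein length in residues, stop excluded
#'   (default 100, the conventional minimum for transcriptome ORF
#'   calling).
#' @param requireFull keep only ORFs with both start and stop codons.
#' @param species optional species label (length 1 or one per contig).
#' @return an [Biostrings::AAStringSet] of translated ORFs, longest
#'   first within each source contig, with `mcols` columns `species`,
#'   `source_id`, `cds_start`, `cds_end`, `strand`, `frame`, `full_orf`.
#' @examples
#' extractOrfs(c(tx = "ATGAAATAA"), minAA = 1)  # one ORF, protein "MK"
#' @export
extractOrfs <- function(seqs, minAA = 100, requireFull = TRUE,
                        species = NULL) {
  if (is.null(species) && methods::is(seqs, "XStringSet") &&
      !is.null(S4Vectors::mcols(seqs)$species))
    species <- S4Vectors::mcols(seqs)$species
  seqs <- .asSeqChar(seqs, "transcripts")
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  if (is.null(species)) species <- rep(NA_character_, length(seqs))
  species <- rep_len(as.character(species), length(seqs))
  .assertScalarNumber(minAA, "minAA", lower = 1)

  rows <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    rows[[k]] <- .orfsOneSeq(seqs[[k]], names(seqs)[[k]], species[[k]],
                             minAA, requireFull)
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) {
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      species = character(0), source_id = character(0),
      cds_start = integer(0), cds_end = integer(0), strand = character(0),
      frame = integer(0), full_orf = logical(0))
    return(out)
  }
  out <- Biostrings::AAStringSet(df$aa)
  names(out) <- df$id
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species = df$species, source_id = df$source_id,
    cds_start = df$cds_start, cds_end = df$cds_end, strand = df$strand,
    frame = df$frame, full_orf = df$full_orf)
  out
}

#' @noRd
.orfsOneSeq <- function(seq, id, species, minAA, requireFull) {
  L <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revComp(seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < 2L) next
      starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      gc <- Biostrings::GENETIC_CODE
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"
      isStop <- aa == "*"
      isMet <- aa == "M"
      prevStop <- 0L  # codon index of the last stop seen
      i <- 1L
      while (i <= ncod) {
        if (isStop[i]) {
          m <- if (i > prevStop + 1L)
            which(isMet[(prevStop + 1L):(i - 1L)])[1L] else NA_integer_
          if (!is.na(m) && i - (prevStop + m) >= minAA) {
            mi <- prevStop + m
            hits[[length(hits) + 1L]] <- .orfRow(
              s, L, id, species, strand, frame, mi, i, aa, TRUE)
          }
          prevStop <- i
        }
        i <- i + 1L
      }
      if (!requireFull && prevStop < ncod) {
        m <- which(isMet[(prevStop + 1L):ncod])[1L]
        if (!is.na(m) && ncod - (prevStop + m) + 1L >= minAA) {
          mi <- prevStop + m
          hits[[length(hits) + 1L]] <- .orfRow(
            s, L, id, species, strand, frame, mi, ncod + 1L, aa, FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, hits)
  df <- df[order(-nchar(df$aa), df$cds_start), , drop = FALSE]
  df$id <- sprintf("%s|orf%d", id, seq_len(nrow(df)))
  df
}

# Build one ORF record. mi = codon index of the ATG, si = codon index of
# the stop (or ncod+1 when running off the end without a stop). Codon
# indices are on the scanned strand; coordinates are mapped back to the
# forward strand, half-open, stop codon included.
#' @noRd
.orfRow <- function(s, L, id, species, strand, frame, mi, si, aa, hasStop) {
  aaStr <- paste(aa[mi:(si - 1L)], collapse = "")
  ntStart <- frame + 3L * (mi - 1L)          # 0-based on scanned strand
  ntEnd <- frame + 3L * si                   # half-open; includes stop codon
  if (!hasStop) ntEnd <- frame + 3L * (si - 1L)
  if (strand == "+") {
    cs <- ntStart; ce <- ntEnd
  } else {
    cs <- L - ntEnd; ce <- L - ntStart
  }
  data.frame(id = NA_character_, species = species, source_id = id,
             aa = aaStr, cds_start = cs, cds_end = ce, strand = strand,
             frame = frame, full_orf = hasStop && substr(aaStr, 1, 1) == "M",
             stringsAsFactors = FALSE)
}

#' Extract the CDS nucleotide sequence of an ORF record
#'
#' @param transcript the source nucleotide string.
#' @param cdsStart,cdsEnd 0-based half-open forward-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @return the coding-strand nucleotide sequence (ATG..stop).
#' @export
orfCds <- function(transcript, cdsStart, cdsEnd, strand = "+") {
  s <- substr(toupper(transcript[[1L]]), cdsStart + 1L, cdsEnd)
  if (strand == "-") s <- revComp(s)
  unname(s)
}
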