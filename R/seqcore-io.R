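# FASTA and Newick I/O. Parsing of the formats themselves is delegated
# to Biostrings and ape; these wrappers add the contracts the rest of
# the package relies on (unique ids, uppercasing, id/description split,
# parse diagnostics with a character offset).

#' Read a FASTA file
#'
#' Records are returned in file order as an XStringSet. Sequence ids are
#' the header up to the first whitespace; any remainder is kept in
#' `mcols(x)$desc`. Sequences are uppercased on read.
#'
#' @param path path to a FASTA file.
#' @param type `"dna"` (alphabet ACGTN) or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet];
#'   empty (with a warning) for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some description", "ac", "gt"), f)
#' readFasta(f)  # one record, seq "ACGT"
#' @export
readFasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(if (type == "dna") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet())
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  out <- if (type == "dna") {
    if (!all(grepl("^[ACGTN]+$", seqs)))
      stop("non-ACGTN characters in DNA FASTA: ", path)
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(desc = desc)
  out
}

#' Write sequences to FASTA
#'
#' 80-column wrapped.
#'
#' @param x an XStringSet or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# Quick structural scan so parse failures report a character offset,
# which ape's reader does not.
#' @noRd
.checkNewickString <- function(s) {
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error: %d unclosed '(' at end of string (character %d)",
      depth, length(chars)))
  if (!grepl(";\\s*$", s))
    stop(sprintf("Newick parse error: missing terminal ';' (character %d)",
                 nchar(s)))
  invisible(TRUE)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that
#' round-trip tip labels, internal-node support labels and branch
#' lengths, allow polytomies, and report malformed input with a
#' character offset.
#'
#' @param path path to a Newick file (one or more trees).
#' @return `readNewickTree`: an [ape::phylo] object (or `multiPhylo` if
#'   the file holds several trees).
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  for (s in strsplit(txt, "(?<=;)", perl = TRUE)[[1L]]) {
    if (grepl("[^[:space:]]", s)) .checkNewickString(trimws(s))
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname readNewickTree
#' @param tree an [ape::phylo] or `multiPhylo` object.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code. A terminal stop codon is consumed (not
#' reported in the protein); internal stops are flagged rather than
#' silently translated. Codons containing N translate to X.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return list with `aa` (amino-acid string; internal stops appear as
#'   `*`), `has_stop` (sequence ends in a stop codon), `internal_stop`
#'   (a stop occurs before the last codon), and `full_orf` (starts with
#'   M, ends with a stop, no internal stop).
#' @examples
#' translateCDS("ATGAAATAA")$aa   # "MK"
#' translateCDS("ATGGCC")$aa      # "MA", full_orf FALSE (no stop)
#' @export
translateCDS <- function(cds) {
  cds <- toupper(cds[[1L]])
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop("CDS length must be a positive multiple of 3 (got ", n, ")")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # codons with N or other ambiguity
  hasStop <- aa[length(aa)] == "*"
  if (hasStop) aa <- aa[-length(aa)]
  internalStop <- any(aa == "*")
  list(aa = paste(aa, collapse = ""), has_stop = hasStop,
       internal_stop = internalStop,
       full_orf = length(aa) > 0L && aa[1L] == "M" && hasStop && !internalStop)
}

#' Reverse complement
#' @param x nucleotide string(s).
#' @return reverse-complemented string(s).
#' @export
revComp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTN", "TGCAN", toupper(s))
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = !is.null(names(x)))
}
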