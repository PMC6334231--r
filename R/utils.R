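# Internal helpers shared across modules.

#' @noRd
.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Sequence input normalisation: accept a named character vector or an
# XStringSet; always return an uppercased named character vector.
#' @noRd
.asSeqChar <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- names(x)
    return(out)
  }
  if (!is.character(x)) stop(sprintf("'%s' must be a character vector or XStringSet", what))
  toupper(x)
}

#' @noRd
.isDnaAlphabet <- function(seqs) {
  all(grepl("^[ACGTN-]*$", seqs))
}

# Deterministic unordered species-pair key.
#' @noRd
.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

# Character matrix (rows = sequences) from aligned strings of equal width.
#' @noRd
.alnMatrix <- function(strings) {
  if (length(strings) == 0L) return(matrix(character(0), 0, 0))
  w <- unique(nchar(strings))
  if (length(w) > 1L) stop("aligned strings differ in width")
  if (w == 0L) return(matrix(character(0), length(strings), 0,
                             dimnames = list(names(strings), NULL)))
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
              nrow = length(strings), byrow = TRUE)
  rownames(m) <- names(strings)
  m
}

#' @noRd
.collapseRows <- function(mat) {
  if (ncol(mat) == 0L) return(setNames(rep("", nrow(mat)), rownames(mat)))
  setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
}
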