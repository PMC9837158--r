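#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the A/C/G/T alphabet, via
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length; names are preserved.
#' @examples
#' reverseComplementStrings(c("ACGT", "GAATTC", "AAA"))
#' @export
reverseComplementStrings <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Decode Sanger (Phred+33) quality strings to integer scores
#'
#' @param qual character vector of ASCII quality strings.
#' @return list of integer vectors, one per input string.
#' @examples
#' phredScores("IIII")[[1]]  # 40 40 40 40
#' @export
phredScores <- function(qual) {
  lapply(qual, function(q) {
    if (!nzchar(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

# Encode integer Phred scores back to an ASCII string (offset 33).
phredString <- function(scores) {
  if (length(scores) == 0L) return("")
  intToUtf8(as.integer(scores) + 33L)
}

# Open a text connection that transparently decompresses plain, gzip and
# bz2 input (gzfile() inspects magic bytes, not the file extension).
openReadConnection <- function(path) {
  if (!file.exists(path))
    ioError(sprintf("file not found: %s", path))
  gzfile(path, open = "rt")
}

# Open a write connection for 'none', 'gzip' or 'bz2' compression.
openWriteConnection <- function(path, compress = c("none", "gzip", "bz2")) {
  compress <- match.arg(compress)
  switch(compress,
    none = file(path, open = "wt"),
    gzip = gzfile(path, open = "wt"),
    bz2  = bzfile(path, open = "wt")
  )
}
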