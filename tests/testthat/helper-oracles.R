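# Independent oracles used to cross-check the package. These deliberately
# avoid the code paths of the implementation: edit distance is a
# hand-written DP (the package delegates to utils::adist), and the
# segmentation oracle finds occurrences by naive substring comparison
# (the package uses Biostrings::matchPattern).

# Quadratic DP Levenshtein distance, row-wise. The within-row insertion
# recurrence cur[j] = min(m[j], cur[j-1] + 1) is resolved with the exact
# closed form cur[j] = min_{k<=j} (v[k] + (j - k)) via cummin.
oracleLevenshtein <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    subCost <- prev[1:m] + (A[i] != B)
    delCost <- prev[2:(m + 1L)] + 1L
    v <- c(i, pmin(subCost, delCost))
    prev <- cummin(v - 0:m) + 0:m
  }
  as.integer(prev[m + 1L])
}

oracleRevComp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# All 1-based start positions of pat in seq, overlapping included.
oracleOccurrences <- function(pat, seq) {
  L <- nchar(pat); n <- nchar(seq)
  if (L > n || L == 0L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - L + 1L))
    if (substring(seq, i, i + L - 1L) == pat) hits <- c(hits, i)
  hits
}

# Brute-force segmentation: enumerate all occurrences per pattern/strand
# and replay the claiming order naively (user pattern order, F before R,
# leftmost-first, skip anything touching a claimed base), then label the
# gaps. Returns the canonical structure string.
oracleStructure <- function(seq, patterns, maxKmerSize = NULL) {
  # patterns: named character vector of forward sequences, in user order
  nm <- names(patterns)
  rc <- vapply(patterns, oracleRevComp, character(1))
  if (is.null(maxKmerSize)) maxKmerSize <- max(nchar(patterns)) + 1L
  n <- nchar(seq)
  claimed <- rep(FALSE, n)
  found <- list()
  for (i in seq_along(patterns)) {
    pal <- patterns[[i]] == rc[[i]]
    strands <- if (pal) "F" else c("F", "R")
    for (strand in strands) {
      pat <- if (strand == "F") patterns[[i]] else rc[[i]]
      L <- nchar(pat)
      for (s in oracleOccurrences(pat, seq)) {
        if (any(claimed[s:(s + L - 1L)])) next
        claimed[s:(s + L - 1L)] <- TRUE
        found[[length(found) + 1L]] <-
          list(start = s, end = s + L,
               token = if (pal) sprintf("{%s}", nm[i])
                       else sprintf("{%s:%s}", nm[i], strand))
      }
    }
  }
  segs <- found
  # gaps
  inGap <- FALSE; gapStart <- 0L
  for (p in seq_len(n + 1L)) {
    open <- p <= n && !claimed[p]
    if (open && !inGap) { inGap <- TRUE; gapStart <- p }
    if (!open && inGap) {
      inGap <- FALSE
      len <- p - gapStart
      segs[[length(segs) + 1L]] <-
        list(start = gapStart, end = p,
             token = if (len <= maxKmerSize) sprintf("{kmer:%dbp}", len)
                     else "{unknown}")
    }
  }
  ord <- order(vapply(segs, `[[`, numeric(1), "start"))
  paste(vapply(segs[ord], `[[`, character(1), "token"), collapse = "")
}

randomDNAString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# The worked pattern dictionary used across tests.
fooBarBazJSON <- '{"foo":"CTGTCTCTTATACAC","bar":"CCGAAAACACG","baz":"TCGTCGGG"}'
fooBarBazSet <- function() parsePatternSet(fooBarBazJSON)

# Random reads of length 50-150 with 0-3 pattern copies overwritten at
# random positions (either strand). Both the implementation and the
# oracle see the same final sequence, so accidental extra occurrences
# are harmless for equivalence checks.
makePlantedReads <- function(nReads, patterns) {
  rc <- vapply(patterns, oracleRevComp, character(1))
  vapply(seq_len(nReads), function(i) {
    len <- sample(50:150, 1L)
    read <- randomDNAString(len)
    for (k in seq_len(sample(0:3, 1L))) {
      j <- sample(length(patterns), 1L)
      pat <- if (sample(c(TRUE, FALSE), 1L)) patterns[[j]] else rc[[j]]
      L <- nchar(pat)
      if (L > len) next
      pos <- sample(len - L + 1L, 1L)
      substr(read, pos, pos + L - 1L) <- pat
    }
    read
  }, character(1))
}
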