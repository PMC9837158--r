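#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

#' PatternSet: an ordered dictionary of service-sequence patterns
#'
#' Holds the user's named nucleotide patterns in the order they were
#' supplied, together with precomputed reverse complements, palindrome
#' flags, and any diagnostic warnings accumulated by the pattern checks.
#' Search order is significant: patterns are matched in dictionary order,
#' forward strand before reverse strand, so earlier patterns claim read
#' bases first.
#'
#' @slot sequences named character vector of uppercase A/C/G/T sequences,
#'   in user order.
#' @slot revcomp named character vector, reverse complement of each
#'   sequence.
#' @slot palindromic named logical vector; `TRUE` when a sequence equals
#'   its own reverse complement (necessarily even length).
#' @slot warnings data.frame with columns `kind` (one of `not-sorted`,
#'   `near-match`, `nested`, `palindrome`, `near-palindrome`), `members`
#'   (comma-joined pattern names), `distance` (integer or `NA`), and
#'   `message`.
#'
#' @seealso [parsePatternSet()], [checkPatternOrder()],
#'   [patternDistances()], [analyzePalindromes()]
#' @export
setClass("PatternSet",
  representation(
    sequences   = "character",
    revcomp     = "character",
    palindromic = "logical",
    warnings    = "data.frame"
  )
)

setValidity("PatternSet", function(object) {
  msgs <- character(0)
  nm <- names(object@sequences)
  if (length(object@sequences) == 0L)
    msgs <- c(msgs, "pattern set is empty")
  if (is.null(nm) || any(!nzchar(nm)))
    msgs <- c(msgs, "all patterns must be named")
  if (anyDuplicated(nm))
    msgs <- c(msgs, sprintf("duplicate pattern name(s): %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  bad <- grepl("[^ACGT]", object@sequences)
  if (any(bad))
    msgs <- c(msgs, sprintf("pattern(s) with non-ACGT characters: %s",
                            paste(nm[bad], collapse = ", ")))
  if (any(!nzchar(object@sequences)))
    msgs <- c(msgs, "empty pattern sequence(s)")
  if (length(object@revcomp) != length(object@sequences) ||
      length(object@palindromic) != length(object@sequences))
    msgs <- c(msgs, "revcomp/palindromic slots out of step with sequences")
  else {
    if (!identical(unname(object@revcomp),
                   unname(reverseComplementStrings(object@sequences))))
      msgs <- c(msgs, "revcomp slot does not match reverse complements")
    if (!identical(unname(object@palindromic),
                   unname(object@sequences == object@revcomp)))
      msgs <- c(msgs, "palindromic flags inconsistent")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReadStructure: the segmentation of one read
#'
#' The ordered decomposition of a single read into exact pattern matches,
#' short unknown segments (K-mers, labelled with their length), and longer
#' unrecognized stretches. Segments tile the read exactly. Coordinates are
#' 0-based, half-open.
#'
#' @slot readId character scalar.
#' @slot sequence the read sequence (uppercase).
#' @slot segments data.frame with columns `kind` (`match`/`kmer`/`unknown`),
#'   `start`, `end` (0-based half-open), `pattern` (name or `NA`), `strand`
#'   (`"F"`/`"R"`, `NA` for non-matches and palindromic patterns), and
#'   `sequence` (the read substring).
#' @slot structureString the canonical token rendering, e.g.
#'   `"{unknown}{foo:F}{kmer:14bp}"`.
#'
#' @seealso [segmentRead()], [renderStructure()]
#' @export
setClass("ReadStructure",
  representation(
    readId          = "character",
    sequence        = "character",
    segments        = "data.frame",
    structureString = "character"
  )
)

setValidity("ReadStructure", function(object) {
  seg <- object@segments
  msgs <- character(0)
  need <- c("kind", "start", "end", "pattern", "strand", "sequence")
  if (!all(need %in% names(seg)))
    return(sprintf("segments must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L) return("segments must be non-empty")
  n <- nchar(object@sequence)
  if (seg$start[1L] != 0L || seg$end[nrow(seg)] != n)
    msgs <- c(msgs, "segments do not span the read")
  if (nrow(seg) > 1L && !all(seg$end[-nrow(seg)] == seg$start[-1L]))
    msgs <- c(msgs, "segments do not abut")
  if (any(seg$start >= seg$end))
    msgs <- c(msgs, "segment with non-positive width")
  if (paste(seg$sequence, collapse = "") != object@sequence)
    msgs <- c(msgs, "segment sequences do not reassemble the read")
  if (length(msgs)) msgs else TRUE
})

#' StructureTable: frequency table of read-structure strings
#'
#' Exact multiset counts of structure strings over all reads (single-end)
#' or pairs (paired-end), with rates summing to one. A display rate floor
#' hides low-frequency rows from rendered summaries without touching
#' counts or totals.
#'
#' @slot rows data.frame with columns `structure`, `count`, `rate`; sorted
#'   by count descending, ties broken lexicographically.
#' @slot totalReads integer; number of structure units counted.
#' @slot rateFloor numeric in `[0, 1]`; display threshold only.
#'
#' @seealso [aggregateStructures()], [applyRateFloor()], [shownRows()],
#'   [hiddenSummary()]
#' @export
setClass("StructureTable",
  representation(
    rows       = "data.frame",
    totalReads = "integer",
    rateFloor  = "numeric"
  )
)

setValidity("StructureTable", function(object) {
  msgs <- character(0)
  r <- object@rows
  if (!all(c("structure", "count", "rate") %in% names(r)))
    return("rows must have columns structure, count, rate")
  if (sum(r$count) != object@totalReads)
    msgs <- c(msgs, "counts do not sum to totalReads")
  if (abs(sum(r$rate) - 1) > 1e-9)
    msgs <- c(msgs, "rates do not sum to 1")
  if (is.unsorted(rev(r$count)))
    msgs <- c(msgs, "rows not sorted by count descending")
  if (object@rateFloor < 0 || object@rateFloor > 1)
    msgs <- c(msgs, "rateFloor must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
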