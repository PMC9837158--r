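#' Template tokens for the synthetic-read generator
#'
#' `patternToken()` plants one exact copy of a named pattern on the given
#' strand; `fillerToken()` inserts a random stretch whose length is drawn
#' uniformly from `[min, max]` bp. Fillers are rejection-sampled to be
#' free of any pattern occurrence on either strand, so the expected
#' structure of an error-free template is exact.
#'
#' @param name pattern name (must exist in the pattern set at generation
#'   time).
#' @param strand `"F"` (forward sequence) or `"R"` (reverse complement).
#' @param min,max inclusive filler length bounds in bp.
#' @return a token object for [structureTemplate()].
#' @export
patternToken <- function(name, strand = c("F", "R")) {
  strand <- match.arg(strand)
  structure(list(type = "pattern", name = name, strand = strand),
            class = "rcToken")
}

#' @rdname patternToken
#' @export
fillerToken <- function(min = 20L, max = 30L) {
  stopifnot(min >= 1L, max >= min)
  structure(list(type = "filler", min = as.integer(min), max = as.integer(max)),
            class = "rcToken")
}

#' Define a read template for the synthetic-read generator
#'
#' A template is an ordered list of tokens (planted pattern copies and
#' random fillers) plus a sampling weight, an optional per-base
#' substitution error rate, and an optional +/-1 bp indel applied to a
#' named pattern token (emulating A-tailing and oligo-synthesis length
#' errors). The expected structure string is computable exactly only for
#' error-free templates; templates with `errorRate > 0` get `NA` truth.
#'
#' @param tokens list of tokens from [patternToken()] / [fillerToken()]
#'   (mate 1 in paired mode).
#' @param tokens2 optional token list for mate 2 (required in paired
#'   mode).
#' @param weight sampling proportion; weights over a template set must
#'   sum to 1.
#' @param errorRate per-base substitution probability applied after
#'   assembly. Default 0.
#' @param indel optional `list(pattern = <name>, delta = -1L or +1L)`:
#'   truncate (delta -1) or extend (delta +1) every planted copy of that
#'   pattern by one base at its 3' end; the modified copy is no longer an
#'   exact match and is expected to surface as a length-labelled K-mer.
#' @param id template identifier used in the truth table.
#' @return a template object for [generateReads()].
#' @export
structureTemplate <- function(tokens, tokens2 = NULL, weight = 1,
                              errorRate = 0, indel = NULL, id = NULL) {
  stopifnot(is.list(tokens), length(tokens) >= 1L,
            all(vapply(tokens, inherits, logical(1), "rcToken")))
  if (!is.null(tokens2))
    stopifnot(is.list(tokens2), length(tokens2) >= 1L,
              all(vapply(tokens2, inherits, logical(1), "rcToken")))
  if (!is.null(indel))
    stopifnot(is.list(indel), !is.null(indel$pattern),
              indel$delta %in% c(-1L, 1L))
  structure(list(tokens = tokens, tokens2 = tokens2, weight = weight,
                 errorRate = errorRate, indel = indel, id = id),
            class = "rcTemplate")
}

# All start positions (1-based) of an exact occurrence of pat in seq,
# including overlapping ones. Naive vectorized scan.
allOccurrences <- function(pat, seq) {
  L <- nchar(pat); n <- nchar(seq)
  if (L > n) return(integer(0))
  which(substring(seq, seq_len(n - L + 1L), L:n) == pat)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Assemble one mate from a token list. Returns pieces (seq, isMatch,
# pattern, strand) with the read verified to contain pattern occurrences
# exactly at the intact planted positions.
assembleMate <- function(tokens, ps, indel, maxAttempts = 200L) {
  nm <- patternNames(ps)
  for (attempt in seq_len(maxAttempts)) {
    pieceSeq <- character(0); pieceMatch <- logical(0)
    piecePat <- character(0); pieceStrand <- character(0)
    for (tok in tokens) {
      if (tok$type == "pattern") {
        if (!(tok$name %in% nm))
          stop(sprintf("template references unknown pattern '%s'", tok$name),
               call. = FALSE)
        s <- if (tok$strand == "F") patternSequences(ps)[[tok$name]]
             else patternRevcomp(ps)[[tok$name]]
        intact <- TRUE
        if (!is.null(indel) && identical(indel$pattern, tok$name)) {
          s <- if (indel$delta == -1L) substr(s, 1L, nchar(s) - 1L)
               else paste0(s, randomDNA(1L))
          intact <- FALSE
        }
        pieceSeq <- c(pieceSeq, s)
        pieceMatch <- c(pieceMatch, intact)
        piecePat <- c(piecePat, if (intact) tok$name else NA_character_)
        pieceStrand <- c(pieceStrand,
                         if (intact && !isPalindromic(ps)[[tok$name]])
                           tok$strand else NA_character_)
      } else {
        len <- sample(seq(tok$min, tok$max), 1L)
        pieceSeq <- c(pieceSeq, randomDNA(len))
        pieceMatch <- c(pieceMatch, FALSE)
        piecePat <- c(piecePat, NA_character_)
        pieceStrand <- c(pieceStrand, NA_character_)
      }
    }
    read <- paste(pieceSeq, collapse = "")
    if (nchar(read) == 0L)
      stop("template produces empty reads", call. = FALSE)
    ends <- cumsum(nchar(pieceSeq))
    starts <- c(1L, utils::head(ends, -1L) + 1L)

    # verify: every pattern occurs exactly at the intact planted spots
    ok <- TRUE
    for (i in seq_along(nm)) {
      fwd <- patternSequences(ps)[[i]]
      rc <- patternRevcomp(ps)[[i]]
      planted <- which(pieceMatch & piecePat == nm[i])
      if (isPalindromic(ps)[[i]]) {
        expect <- sort(starts[planted])
        if (!identical(allOccurrences(fwd, read), as.integer(expect))) ok <- FALSE
      } else {
        expF <- sort(starts[planted[pieceStrand[planted] == "F"]])
        expR <- sort(starts[planted[pieceStrand[planted] == "R"]])
        if (!identical(allOccurrences(fwd, read), as.integer(expF))) ok <- FALSE
        if (!identical(allOccurrences(rc, read), as.integer(expR))) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok)
      return(list(read = read,
                  pieces = data.frame(
                    sequence = pieceSeq, isMatch = pieceMatch,
                    pattern = piecePat, strand = pieceStrand,
                    start = starts - 1L, end = ends,
                    stringsAsFactors = FALSE)))
  }
  stop(sprintf("could not assemble a pattern-free read in %d attempts; check template/filler design",
               maxAttempts), call. = FALSE)
}

# Expected structure string of an assembled mate (error-free case):
# intact pieces render as matches, maximal runs of non-match pieces merge
# and are labelled kmer/unknown by length.
expectedMateStructure <- function(pieces, ps, maxKmerSize) {
  tokens <- character(0)
  i <- 1L
  n <- nrow(pieces)
  while (i <= n) {
    if (pieces$isMatch[i]) {
      p <- pieces$pattern[i]
      tokens <- c(tokens, if (isPalindromic(ps)[[p]]) sprintf("{%s}", p)
                          else sprintf("{%s:%s}", p, pieces$strand[i]))
      i <- i + 1L
    } else {
      j <- i
      while (j < n && !pieces$isMatch[j + 1L]) j <- j + 1L
      len <- pieces$end[j] - pieces$start[i]
      tokens <- c(tokens, if (len <= maxKmerSize) sprintf("{kmer:%dbp}", len)
                          else "{unknown}")
      i <- j + 1L
    }
  }
  paste(tokens, collapse = "")
}

applySubstitutions <- function(read, errorRate) {
  if (errorRate <= 0) return(read)
  bases <- strsplit(read, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(bases)) < errorRate)
  for (i in hit)
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  paste(bases, collapse = "")
}

#' Generate synthetic FastQ reads with exact truth labels
#'
#' Draws `nReads` reads (or pairs) from weighted [structureTemplate()]s,
#' plants exact pattern copies separated by rejection-sampled
#' pattern-free fillers, and records for each read its template and — for
#' error-free templates — the exact structure string the segmentation
#' must produce. Qualities are constant Phred 37. Deterministic for a
#' given seed.
#'
#' @param templates list of [structureTemplate()]s; weights must sum
#'   to 1.
#' @param patterns a [PatternSet-class], or JSON text / file path.
#' @param nReads number of reads (pairs) to generate.
#' @param seed integer RNG seed.
#' @param paired logical; when `TRUE` every template must carry `tokens2`
#'   and two synchronized FastQ files are produced.
#' @param r1Path,r2Path,truthPath optional output paths (FastQ and a TSV
#'   truth table `read_id`, `template_id`, `expected_structure`); when
#'   omitted, results are only returned in memory.
#' @param compress `"none"`, `"gzip"` or `"bz2"` for the FastQ outputs.
#' @param maxKmerSize used for the expected kmer/unknown labels; default
#'   longest pattern + 1 (must match the analysis setting).
#' @return list with `reads1` (data.frame `id`, `sequence`, `quality`),
#'   `reads2` (or `NULL`), `truth` (data.frame), and `pieces`
#'   (data.frame of planted fragments with 0-based half-open `start`,
#'   `end`, `isMatch`, `pattern`, `strand`, `mate`, `read_id`).
#' @examples
#' ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC"}')
#' tpl <- structureTemplate(list(fillerToken(20, 30), patternToken("foo"),
#'                               fillerToken(20, 30)))
#' g <- generateReads(list(tpl), ps, nReads = 5, seed = 1)
#' g$truth$expected_structure[1]
#' @export
generateReads <- function(templates, patterns, nReads, seed,
                          paired = FALSE, r1Path = NULL, r2Path = NULL,
                          truthPath = NULL,
                          compress = c("none", "gzip", "bz2"),
                          maxKmerSize = NULL) {
  compress <- match.arg(compress)
  stopifnot(nReads >= 1L)
  ps <- if (is(patterns, "PatternSet")) patterns else parsePatternSet(patterns)
  if (is.null(maxKmerSize)) maxKmerSize <- defaultMaxKmerSize(ps)
  stopifnot(is.list(templates), length(templates) >= 1L,
            all(vapply(templates, inherits, logical(1), "rcTemplate")))
  w <- vapply(templates, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("template weights must sum to 1", call. = FALSE)
  if (paired && any(vapply(templates, function(t) is.null(t$tokens2), logical(1))))
    stop("paired mode requires tokens2 in every template", call. = FALSE)
  tplIds <- vapply(seq_along(templates), function(i) {
    id <- templates[[i]]$id
    if (is.null(id)) sprintf("template%02d", i) else id
  }, character(1))

  set.seed(as.integer(seed))
  pick <- sample.int(length(templates), nReads, replace = TRUE, prob = w)

  ids <- sprintf("read%06d", seq_len(nReads))
  seq1 <- character(nReads); seq2 <- character(nReads)
  expected <- character(nReads)
  piecesAcc <- vector("list", 2L * nReads)

  for (i in seq_len(nReads)) {
    tpl <- templates[[pick[i]]]
    a1 <- assembleMate(tpl$tokens, ps, tpl$indel)
    e1 <- expectedMateStructure(a1$pieces, ps, maxKmerSize)
    p1 <- a1$pieces; p1$mate <- "R1"; p1$read_id <- ids[i]
    piecesAcc[[2L * i - 1L]] <- p1
    if (paired) {
      a2 <- assembleMate(tpl$tokens2, ps, tpl$indel)
      e2 <- expectedMateStructure(a2$pieces, ps, maxKmerSize)
      p2 <- a2$pieces; p2$mate <- "R2"; p2$read_id <- ids[i]
      piecesAcc[[2L * i]] <- p2
      seq2[i] <- applySubstitutions(a2$read, tpl$errorRate)
      expected[i] <- if (tpl$errorRate > 0) NA_character_
                     else sprintf("R1:%s R2:%s", e1, e2)
    } else {
      expected[i] <- if (tpl$errorRate > 0) NA_character_ else e1
    }
    seq1[i] <- applySubstitutions(a1$read, tpl$errorRate)
  }

  reads1 <- data.frame(
    id = if (paired) paste0(ids, "/1") else ids,
    sequence = seq1, quality = strrep("F", nchar(seq1)),
    stringsAsFactors = FALSE)
  reads2 <- if (paired) data.frame(
    id = paste0(ids, "/2"),
    sequence = seq2, quality = strrep("F", nchar(seq2)),
    stringsAsFactors = FALSE) else NULL
  truth <- data.frame(read_id = ids, template_id = tplIds[pick],
                      expected_structure = expected,
                      stringsAsFactors = FALSE)
  pieces <- do.call(rbind, piecesAcc[!vapply(piecesAcc, is.null, logical(1))])
  rownames(pieces) <- NULL

  if (!is.null(r1Path)) writeFastq(reads1, r1Path, compress)
  if (!is.null(r2Path) && paired) writeFastq(reads2, r2Path, compress)
  if (!is.null(truthPath))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  list(reads1 = reads1, reads2 = reads2, truth = truth, pieces = pieces)
}

#' Write a read table as 4-line FastQ
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path output path.
#' @param compress `"none"`, `"gzip"` or `"bz2"`.
#' @return invisibly, the path.
#' @export
writeFastq <- function(reads, path, compress = c("none", "gzip", "bz2")) {
  compress <- match.arg(compress)
  con <- openWriteConnection(path, compress)
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, con)
  invisible(path)
}
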