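ioError <- function(msg) {
  stop(errorCondition(msg, class = c("rcIOError", "error", "condition")))
}

#' Read a FastQ file (plain, gzip, or bz2)
#'
#' Streams 4-line Sanger-dialect FastQ records. Compression is detected
#' from the file's magic bytes, not its extension, so mislabelled files
#' still work. Qualities are kept as the raw Phred+33 string; decode with
#' [phredScores()].
#'
#' @param path FastQ file path.
#' @param maxReads maximum number of records to read (default unlimited).
#' @return data.frame with columns `id` (without the leading `@`),
#'   `sequence` (uppercased) and `quality`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path, maxReads = Inf) {
  con <- openReadConnection(path)
  on.exit(close(con))
  chunkRecords <- 10000L
  ids <- character(0); seqs <- character(0); quals <- character(0)
  total <- 0L
  repeat {
    want <- if (is.finite(maxReads)) min(chunkRecords, maxReads - total) else chunkRecords
    if (want <= 0L) break
    lines <- tryCatch(readLines(con, n = 4L * want),
                      error = function(e) ioError(sprintf(
                        "failed to read '%s': %s", path, conditionMessage(e))))
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      ioError(sprintf("truncated FastQ record %d in '%s' (%d trailing line(s))",
                      total + length(lines) %/% 4L + 1L, path,
                      length(lines) %% 4L))
    m <- matrix(lines, nrow = 4L)
    hdr <- m[1L, ]; sq <- toupper(m[2L, ]); plus <- m[3L, ]; ql <- m[4L, ]
    badHdr <- which(!startsWith(hdr, "@"))
    if (length(badHdr))
      ioError(sprintf("malformed FastQ record %d in '%s': header does not start with '@'",
                      total + badHdr[1L], path))
    badPlus <- which(!startsWith(plus, "+"))
    if (length(badPlus))
      ioError(sprintf("malformed FastQ record %d in '%s': separator line is not '+'",
                      total + badPlus[1L], path))
    badLen <- which(nchar(sq) != nchar(ql))
    if (length(badLen))
      ioError(sprintf("sequence/quality length mismatch for read '%s' in '%s'",
                      sub("^@", "", hdr[badLen[1L]]), path))
    ids <- c(ids, sub("^@", "", hdr))
    seqs <- c(seqs, sq)
    quals <- c(quals, ql)
    total <- total + ncol(m)
    if (length(lines) < 4L * want) break
  }
  data.frame(id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Pair two synchronized FastQ record streams
#'
#' Zips the two mate files positionally and validates that read IDs agree
#' after stripping a trailing mate designator (`/1`, `/2`) or a
#' space-delimited comment.
#'
#' @param s1,s2 data.frames from [readFastq()] for mate 1 and mate 2.
#' @return invisibly, a list with elements `r1` and `r2` (the validated
#'   inputs).
#' @export
pairReads <- function(s1, s2) {
  if (nrow(s1) != nrow(s2)) {
    k <- min(nrow(s1), nrow(s2)) + 1L
    stop(sprintf("paired files differ in length: record %d has no mate (%d vs %d reads)",
                 k, nrow(s1), nrow(s2)), call. = FALSE)
  }
  stem1 <- readIdStem(s1$id)
  stem2 <- readIdStem(s2$id)
  bad <- which(stem1 != stem2)
  if (length(bad))
    stop(sprintf("mate ID mismatch at record %d: '%s' vs '%s'",
                 bad[1L], s1$id[bad[1L]], s2$id[bad[1L]]), call. = FALSE)
  invisible(list(r1 = s1, r2 = s2))
}

htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

htmlTable <- function(df, caption = NULL) {
  head <- paste0("<tr>", paste0("<th>", htmlEscape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, , drop = FALSE], function(v) {
      v <- if (is.na(v)) "" else format(v)
      paste0("<td>", htmlEscape(v), "</td>")
    }, character(1))
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0(if (!is.null(caption)) sprintf("<h3>%s</h3>", htmlEscape(caption)) else "",
         "<table border='1' cellspacing='0' cellpadding='4'>",
         head, paste(body, collapse = ""), "</table>")
}

#' Write the self-contained HTML summary
#'
#' One HTML page, no external assets: the run options, the pattern list
#' with both strand sequences, all pattern diagnostics (sort order,
#' pairwise Levenshtein distances per strand combination and their
#' minimum, nesting, palindromes), and the structure frequency table with
#' the rate floor applied and a residual line accounting for hidden rows.
#' Percentages are shown with 4 significant digits.
#'
#' @param config named list of run options to echo.
#' @param diag result of [diagnosePatterns()] (pattern set + distances).
#' @param table a [StructureTable-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSummary <- function(config, diag, table, path) {
  ps <- diag$patternSet
  parts <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
             "<title>ReadContext summary</title></head><body>",
             "<h1>ReadContext run summary</h1>")

  cfg <- data.frame(option = names(config),
                    value = vapply(config, function(v)
                      paste(format(v), collapse = " "), character(1)),
                    stringsAsFactors = FALSE)
  parts <- c(parts, htmlTable(cfg, "Run options"))

  pat <- data.frame(name = patternNames(ps),
                    length_bp = unname(patternLengths(ps)),
                    forward = unname(patternSequences(ps)),
                    reverse_complement = unname(patternRevcomp(ps)),
                    palindromic = unname(isPalindromic(ps)),
                    stringsAsFactors = FALSE)
  parts <- c(parts, htmlTable(pat, "Patterns"))

  if (length(patternNames(ps)) >= 2L) {
    nm <- patternNames(ps)
    pairs <- utils::combn(nm, 2L)
    dd <- diag$distances
    pairDf <- data.frame(
      pair = apply(pairs, 2L, paste, collapse = " / "),
      fwd_fwd = apply(pairs, 2L, function(p) dd$ff[p[1L], p[2L]]),
      fwd_rc  = apply(pairs, 2L, function(p) dd$fr[p[1L], p[2L]]),
      rc_fwd  = apply(pairs, 2L, function(p) dd$rf[p[1L], p[2L]]),
      rc_rc   = apply(pairs, 2L, function(p) dd$rr[p[1L], p[2L]]),
      minimum = apply(pairs, 2L, function(p) dd$min[p[1L], p[2L]]),
      stringsAsFactors = FALSE)
    parts <- c(parts, htmlTable(pairDf,
      "Pairwise Levenshtein distances (per strand combination)"))
  }

  warn <- patternWarnings(ps)
  if (nrow(warn)) {
    parts <- c(parts, htmlTable(warn[, c("kind", "members", "distance", "message")],
                                "Pattern warnings"))
  } else {
    parts <- c(parts, "<h3>Pattern warnings</h3><p>none</p>")
  }

  shown <- shownRows(table)
  tabDf <- data.frame(structure = shown$structure, count = shown$count,
                      percent = signif(shown$rate * 100, 4),
                      stringsAsFactors = FALSE)
  parts <- c(parts, htmlTable(tabDf,
    sprintf("Read structures (%d units, rate floor %g)",
            totalReads(table), table@rateFloor)))
  hid <- hiddenSummary(table)
  parts <- c(parts, sprintf(
    "<p>%d structure(s) below the rate floor, cumulative %s%%.</p>",
    hid$n, format(signif(hid$cumulativeRate * 100, 4))))
  parts <- c(parts, "</body></html>")

  ok <- tryCatch({ writeLines(paste(parts, collapse = "\n"), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ioError(sprintf("cannot write summary to '%s'", path))
  invisible(path)
}

#' Write per-read detail records as gzip-compressed NDJSON
#'
#' One JSON object per read (or read pair) per line, inside a gzip
#' stream. Each record carries the read ID, the structure string, and
#' per-mate sequence, Phred scores, segment table, and (when read
#' analysis was enabled) segment-vs-pattern edit distances. Records
#' round-trip losslessly through [readDetail()].
#'
#' @param records list of detail records (see [readDetail()] for shape).
#' @param path output path; the stream is always gzip-compressed.
#' @return invisibly, the path.
#' @export
writeDetail <- function(records, path) {
  con <- tryCatch(gzfile(path, open = "wt"),
                  error = function(e) ioError(sprintf(
                    "cannot write detail file to '%s'", path)))
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null"), con)
  }
  invisible(path)
}

#' Read a gzip NDJSON detail file back into R
#'
#' @param path path written by [writeDetail()].
#' @return list of records; each has `read_id`, `structure`, and `mates`
#'   (a list of per-mate entries with `mate`, `sequence`, `phred`,
#'   `structure`, `segments`, and optionally `similarity`).
#' @export
readDetail <- function(path) {
  con <- openReadConnection(path)
  on.exit(close(con))
  lines <- readLines(con)
  lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}
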