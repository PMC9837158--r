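buildMateEntry <- function(rs, quality, mateLabel, ps, readAnalysis) {
  entry <- list(
    mate = mateLabel,
    sequence = rs@sequence,
    phred = I(phredScores(quality)[[1L]]),
    structure = rs@structureString,
    segments = rs@segments
  )
  if (readAnalysis)
    entry$similarity <- analyzeReadSegments(rs, ps)
  entry
}

processChunk <- function(idx, reads1, reads2, ps, maxKmerSize,
                         readAnalysis, wantDetail) {
  paired <- !is.null(reads2)
  structures <- character(length(idx))
  details <- if (wantDetail) vector("list", length(idx)) else NULL
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (paired) {
      pair <- segmentPair(
        list(id = reads1$id[i], sequence = reads1$sequence[i]),
        list(id = reads2$id[i], sequence = reads2$sequence[i]),
        ps, maxKmerSize)
      structures[k] <- pair$structureString
      if (wantDetail)
        details[[k]] <- list(
          read_id = readIdStem(reads1$id[i]),
          structure = pair$structureString,
          mates = list(
            buildMateEntry(pair$r1, reads1$quality[i], "R1", ps, readAnalysis),
            buildMateEntry(pair$r2, reads2$quality[i], "R2", ps, readAnalysis)))
    } else {
      rs <- segmentRead(reads1$sequence[i], ps, maxKmerSize,
                        readId = reads1$id[i])
      structures[k] <- rs@structureString
      if (wantDetail)
        details[[k]] <- list(
          read_id = reads1$id[i],
          structure = rs@structureString,
          mates = list(buildMateEntry(rs, reads1$quality[i], "single",
                                      ps, readAnalysis)))
    }
  }
  list(structures = structures, details = details)
}

#' Run the full read-structure analysis
#'
#' End-to-end pipeline: parse and diagnose the pattern dictionary, stream
#' the FastQ input (single- or paired-end), segment every read (pair)
#' into its structure string, aggregate the structure frequency table,
#' and optionally write the HTML summary and the gzip NDJSON detail file.
#' Work is split into chunks that may be processed by several worker
#' processes; results are merged in input order, so all outputs are
#' independent of `workers`.
#'
#' @param r1 path to the mate-1 (or single-end) FastQ file; plain, gzip
#'   or bz2.
#' @param r2 optional path to the mate-2 FastQ file; presence switches on
#'   paired-end mode (one structure unit per pair).
#' @param patterns pattern dictionary: JSON text or a JSON file path (see
#'   [parsePatternSet()]), or an already-built [PatternSet-class].
#' @param maxKmerSize see [segmentRead()]; default longest pattern + 1.
#' @param rateFloor display rate floor for the summary table, in
#'   `[0, 1]`. Default 0.001.
#' @param readAnalysis logical; compute per-segment Levenshtein
#'   similarities against the patterns ([analyzeReadSegments()]) and
#'   store them in the detail records. Off by default (it is expensive
#'   and only changes detail-file content).
#' @param confusionThreshold see [patternDistances()].
#' @param palindromeRiskThreshold see [analyzePalindromes()].
#' @param workers number of worker processes (forked; 1 = serial).
#' @param maxReads cap on records read per file (default unlimited).
#' @param summaryPath optional HTML summary output path.
#' @param detailPath optional gzip NDJSON detail output path.
#' @param quiet suppress progress messages (default `TRUE`).
#' @return invisibly, a list with `patternSet`, `distances`, `table` (a
#'   [StructureTable-class] with the rate floor applied), `structures`
#'   (per-unit strings in input order), `details` (when a detail path or
#'   read analysis was requested), `nReads`, `paired`, and `config`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "CTGTCTCTTATACAC", "+", strrep("F", 15)), fq)
#' res <- runReadContext(fq, patterns = '{"foo":"CTGTCTCTTATACAC"}')
#' structureRows(res$table)
#' @export
runReadContext <- function(r1, r2 = NULL, patterns,
                           maxKmerSize = NULL, rateFloor = 0.001,
                           readAnalysis = FALSE,
                           confusionThreshold = 2L,
                           palindromeRiskThreshold = 2L,
                           workers = 1L, maxReads = Inf,
                           summaryPath = NULL, detailPath = NULL,
                           quiet = TRUE) {
  ps <- if (is(patterns, "PatternSet")) patterns else parsePatternSet(patterns)
  diag <- diagnosePatterns(ps, confusionThreshold, palindromeRiskThreshold)
  ps <- diag$patternSet
  if (!quiet)
    message(sprintf("patterns validated: %d pattern(s), %d warning(s)",
                    length(patternNames(ps)), nrow(patternWarnings(ps))))
  if (is.null(maxKmerSize)) maxKmerSize <- defaultMaxKmerSize(ps)

  reads1 <- readFastq(r1, maxReads)
  reads2 <- if (!is.null(r2)) readFastq(r2, maxReads) else NULL
  paired <- !is.null(reads2)
  if (paired) pairReads(reads1, reads2)
  n <- nrow(reads1)
  if (n == 0L) stop("no reads in input", call. = FALSE)

  wantDetail <- !is.null(detailPath) || readAnalysis
  workers <- max(1L, as.integer(workers))
  chunkSize <- max(1L, ceiling(n / max(workers * 4L, 1L)))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunkSize))
  apply_fun <- if (workers > 1L && .Platform$OS.type == "unix") {
    function(x, f) parallel::mclapply(x, f, mc.cores = workers)
  } else {
    function(x, f) lapply(x, f)
  }
  pieces <- apply_fun(chunks, function(idx)
    processChunk(idx, reads1, reads2, ps, maxKmerSize,
                 readAnalysis, wantDetail))
  structures <- unlist(lapply(pieces, `[[`, "structures"), use.names = FALSE)
  details <- if (wantDetail)
    do.call(c, lapply(pieces, `[[`, "details")) else NULL
  if (!quiet)
    message(sprintf("%d %s processed", n, if (paired) "read pairs" else "reads"))

  table <- applyRateFloor(aggregateStructures(structures), rateFloor)

  config <- list(
    r1 = r1, r2 = if (paired) r2 else NA,
    paired = paired, maxKmerSize = maxKmerSize, rateFloor = rateFloor,
    readAnalysis = readAnalysis, confusionThreshold = confusionThreshold,
    palindromeRiskThreshold = palindromeRiskThreshold,
    workers = workers,
    maxReads = if (is.finite(maxReads)) maxReads else "unlimited",
    nReads = n)

  if (!is.null(summaryPath)) writeSummary(config, diag, table, summaryPath)
  if (!is.null(detailPath)) writeDetail(details, detailPath)
  if (!quiet && (!is.null(summaryPath) || !is.null(detailPath)))
    message(sprintf("outputs written: %s",
                    paste(c(summaryPath, detailPath), collapse = ", ")))

  invisible(list(patternSet = ps, distances = diag$distances, table = table,
                 structures = structures, details = details, nReads = n,
                 paired = paired, config = config,
                 summaryPath = summaryPath, detailPath = detailPath))
}

#' Command-line interface
#'
#' Parses POSIX-style flags and runs [runReadContext()]. Used by the
#' `inst/scripts/fastcontext.R` wrapper; callable directly for testing.
#' Progress goes to standard error; machine output only to the named
#' files. Exit codes: 0 success, 1 validation/usage error, 2 I/O error.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return integer exit code.
#' @export
readContextCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  optionList <- list(
    optparse::make_option(c("-1", "--r1"), type = "character",
      help = "FastQ file, mate 1 or single-end (plain/gzip/bz2)"),
    optparse::make_option(c("-2", "--r2"), type = "character",
      default = NULL, help = "FastQ file, mate 2 (enables paired mode)"),
    optparse::make_option(c("-p", "--patterns"), type = "character",
      help = "pattern dictionary: JSON text or path to a JSON file"),
    optparse::make_option(c("-s", "--summary"), type = "character",
      help = "HTML summary output path"),
    optparse::make_option(c("-j", "--json"), type = "character",
      default = NULL, help = "gzip NDJSON per-read detail output path"),
    optparse::make_option(c("-k", "--max-kmer-size"), type = "integer",
      default = NULL, help = "max K-mer length label [longest pattern + 1]"),
    optparse::make_option(c("-f", "--rate-floor"), type = "double",
      default = 0.001, help = "display rate floor [default %default]"),
    optparse::make_option(c("-l", "--levenshtein"), action = "store_true",
      default = FALSE, help = "enable per-read Levenshtein analysis"),
    optparse::make_option(c("-t", "--threads"), type = "integer",
      default = 1L, help = "worker processes [default %default]"),
    optparse::make_option(c("-m", "--max-reads"), type = "integer",
      default = NA_integer_, help = "cap on reads per file [unlimited]"),
    optparse::make_option("--confusion-threshold", type = "integer",
      default = 2L, help = "pattern confusability distance [default %default]"),
    optparse::make_option("--palindrome-threshold", type = "integer",
      default = 2L, help = "near-palindrome distance [default %default]")
  )
  parser <- optparse::OptionParser(
    usage = "fastcontext.R --r1 reads.fastq[.gz|.bz2] --patterns '{\"name\":\"SEQ\"}' --summary out.html [options]",
    option_list = optionList)
  if (length(args) == 0L) {
    optparse::print_help(parser)
    return(1L)
  }
  opt <- tryCatch(optparse::parse_args(parser, args = args),
                  error = function(e) {
                    message("argument error: ", conditionMessage(e))
                    NULL
                  })
  if (is.null(opt)) return(1L)
  missing <- c(if (is.null(opt$r1)) "--r1",
               if (is.null(opt$patterns)) "--patterns",
               if (is.null(opt$summary)) "--summary")
  if (length(missing)) {
    message("missing required flag(s): ", paste(missing, collapse = ", "))
    return(1L)
  }
  if (opt$levenshtein && is.null(opt$json))
    message("note: --levenshtein results are only stored in the detail file; consider --json")
  status <- tryCatch({
    runReadContext(
      r1 = opt$r1, r2 = opt$r2, patterns = opt$patterns,
      maxKmerSize = opt$`max-kmer-size`, rateFloor = opt$`rate-floor`,
      readAnalysis = opt$levenshtein, workers = opt$threads,
      maxReads = if (is.na(opt$`max-reads`)) Inf else opt$`max-reads`,
      confusionThreshold = opt$`confusion-threshold`,
      palindromeRiskThreshold = opt$`palindrome-threshold`,
      summaryPath = opt$summary, detailPath = opt$json,
      quiet = FALSE)
    0L
  },
  rcIOError = function(e) { message("I/O error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
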