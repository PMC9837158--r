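#' Aggregate structure strings into a ranked frequency table
#'
#' Exact multiset counting of the canonical structure strings over all
#' reads (single-end) or read pairs (paired-end; one unit per pair).
#' Rows are sorted by count descending with lexicographic tie-breaking so
#' reports are reproducible; rates are `count / totalReads` and sum to 1.
#'
#' @param structures character vector of structure strings, one per
#'   structure unit.
#' @return a [StructureTable-class] with rate floor 0 (everything shown).
#' @examples
#' tab <- aggregateStructures(c("{foo:F}", "{foo:F}", "{unknown}"))
#' structureRows(tab)
#' @export
aggregateStructures <- function(structures) {
  stopifnot(is.character(structures))
  if (length(structures) == 0L)
    stop("cannot aggregate an empty structure stream", call. = FALSE)
  counts <- table(structures)
  df <- data.frame(structure = names(counts),
                   count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$structure), , drop = FALSE]
  rownames(df) <- NULL
  df$rate <- df$count / length(structures)
  new("StructureTable", rows = df,
      totalReads = length(structures), rateFloor = 0)
}

#' Set the display rate floor of a structure table
#'
#' The rate floor hides low-frequency structures from rendered summaries.
#' It is display-only: counts, rates and the total are never modified, and
#' hidden rows are reported in aggregate by [hiddenSummary()] so shown +
#' hidden rates always sum to 1.
#'
#' @param table a [StructureTable-class].
#' @param floor numeric in `[0, 1]`.
#' @return the table with its rate floor set.
#' @export
applyRateFloor <- function(table, floor) {
  stopifnot(is(table, "StructureTable"), floor >= 0, floor <= 1)
  table@rateFloor <- as.numeric(floor)
  validObject(table)
  table
}

#' @describeIn StructureTable-accessors all rows (floor ignored)
#' @export
structureRows <- function(table) table@rows

#' Accessors for StructureTable
#'
#' @param table a [StructureTable-class].
#' @name StructureTable-accessors
NULL

#' @describeIn StructureTable-accessors total structure units counted
#' @export
totalReads <- function(table) table@totalReads

#' @describeIn StructureTable-accessors rows at or above the rate floor
#' @export
shownRows <- function(table) {
  table@rows[table@rows$rate >= table@rateFloor, , drop = FALSE]
}

#' @describeIn StructureTable-accessors count and cumulative rate of rows
#'   hidden by the rate floor
#' @export
hiddenSummary <- function(table) {
  hid <- table@rows[table@rows$rate < table@rateFloor, , drop = FALSE]
  list(n = nrow(hid), cumulativeRate = sum(hid$rate))
}

setMethod("show", "StructureTable", function(object) {
  cat(sprintf("StructureTable: %d distinct structure(s) over %d unit(s), rate floor %g\n",
              nrow(object@rows), object@totalReads, object@rateFloor))
  shown <- shownRows(object)
  out <- utils::head(shown, 10L)
  out$percent <- signif(out$rate * 100, 4)
  print(out[, c("structure", "count", "percent")], row.names = FALSE)
  if (nrow(shown) > 10L) cat(sprintf("... and %d more shown row(s)\n", nrow(shown) - 10L))
  hid <- hiddenSummary(object)
  if (hid$n > 0L)
    cat(sprintf("%d row(s) below the rate floor (cumulative rate %.6f)\n",
                hid$n, hid$cumulativeRate))
})
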