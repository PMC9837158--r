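---
title: "Read-structure analysis with ReadContext"
author: "ReadContext maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-structure analysis with ReadContext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReadContext)
```

## The problem

During NGS library preparation a molecule accumulates service sequences:
adapters ligated to its ends, primers, sample- and molecule-specific
barcodes, enrichment oligos. When a new protocol underperforms, the
distribution, orientation and *linkage* of those sequences inside the
raw reads is often the most direct evidence of what went wrong — an
adapter on the wrong strand, a barcode fused to the wrong end, a
truncated oligo from a failed synthesis batch. ReadContext makes that
evidence legible: every read (or read pair) is decomposed into an
ordered token string, its *read structure*, and the frequency of each
structure across the file is tabulated.

## The segmentation model

The user supplies an **ordered** dictionary of named patterns as a JSON
object. Order is part of the model: patterns are searched one at a time
in dictionary order, and within each pattern the forward strand (the
sequence itself) before the reverse strand (its reverse complement).
Each pass scans the still-unclaimed portions of the read left to right
and claims every **exact** occurrence greedily; an occurrence that
overlaps any already-claimed base is skipped entirely. This is the
sequential find-and-mask semantics a user would get by masking the read
once per pattern, and it makes earlier patterns strictly higher
priority — which is why the package warns when patterns are not sorted
long-to-short: a short pattern listed first can claim the core of a
longer pattern's occurrence and split it.

Matching is deliberately full-match only. A pattern copy carrying a
single sequencing error is *not* matched; it falls through to the
unrecognized classes below. This biases long patterns downwards (their
per-copy error probability is higher), which is the price of never
reporting a spurious match; the per-read Levenshtein diagnostics below
are the escape hatch.

After all passes, each maximal unclaimed run becomes one segment:

* a **K-mer** `{kmer:Nbp}` when its length `N` is at most
  `maxKmerSize`, or
* `{unknown}` otherwise.

Match tokens render as `{name:F}` / `{name:R}`; reverse-complement
palindromic patterns (sequence equal to its own reverse complement,
necessarily even-length) are searched once and render without a strand
suffix, `{name}`, because their orientation is undefined. Segments tile
the read exactly — concatenating segment sequences reproduces the read
— and this invariant is enforced by the `ReadStructure` validity method.

Coordinates in segment tables and detail records are 0-based and
half-open. This is the package's serialization contract; the 1-based
closed convention of IRanges is confined to the internal matching step.

## Tunable parameters

* `maxKmerSize` (bp; default: longest pattern length + 1). The point of
  the K-mer class is to make ±1 bp pattern variants visible: A-tailing
  and oligo-synthesis errors produce copies one base shorter or longer
  than designed, and a `{kmer:14bp}` token next to a 15 bp pattern is a
  strong hint. The default guarantees those variants are always
  labelled; raising it labels longer unknowns too, at some loss of
  contrast.
* `confusionThreshold` (edits; default 2). Pattern pairs whose minimum
  Levenshtein distance over the four strand combinations is at or below
  this value are flagged `near-match`: a few sequencing errors could
  interconvert them. Two is a pragmatic reading of "a few errors" for
  typical 8–35 bp service sequences; it is CLI-configurable.
* `palindromeRiskThreshold` (edits; default 2). A non-palindromic
  pattern within this distance of its own reverse complement is flagged
  `near-palindrome`, since errors can make it effectively strandless and
  distort forward/reverse statistics.
* `rateFloor` (fraction; default 0.001). Display-only: structures below
  the floor are hidden from the summary table and reported in aggregate
  (count and cumulative rate), never removed from counts or totals, so
  shown + hidden rates always sum to 1.
* `workers` (default 1). Reads are partitioned into chunks processed by
  forked workers and merged in input order; all outputs are identical
  for any worker count.

## Pattern diagnostics

Before any read is processed the dictionary itself is analyzed: sort
order (`not-sorted`), pairwise Levenshtein distances reported per strand
combination with per-pair minima (`near-match`), exact substring nesting
on either strand (`nested`), and palindromes (`palindrome`,
`near-palindrome`). Near-nesting (substring up to an edit distance) is
deliberately not checked — there is no principled threshold for it, and
the pairwise distance matrix already exposes the relevant pairs.

The pattern-pair distance is taken as the minimum over the four strand
combinations, because two patterns confusable on opposite strands are
just as damaging to the claiming order as two confusable forward
sequences; the summary reports all four values so the user can see which
combination drives the minimum.

## Per-read Levenshtein analysis

With `readAnalysis = TRUE` (CLI `--levenshtein`), every `kmer` and
`unknown` segment is compared to every pattern on both strands by plain
Levenshtein distance, and the results are stored in the per-read detail
records. Whole-segment against whole-pattern is a crude similarity — it
ignores where inside a long unknown the pattern-like stretch sits — but
it is cheap, monotone in the obvious bounds
(`|len(seg) − len(pat)| ≤ d ≤ max(len(seg), len(pat))`), and usually
enough to suggest the true structure of a near-miss read. Match segments
are excluded as uninformative (distance trivially 0). The flag changes
detail-file content only; structure strings and counts are unaffected,
which the test suite verifies differentially. It is off by default
because it dominates runtime on large inputs.

## Input, output, and numerical conventions

FastQ input (single-end, or two synchronized files in paired-end mode)
may be plain, gzip- or bz2-compressed; compression is detected from
magic bytes so mislabelled extensions still work. Qualities are
Sanger/Illumina-1.8 Phred+33; they are carried through to the detail
records untouched. Pairing is positional, with read IDs validated after
stripping `/1`, `/2` or a space-delimited comment; a pair is **one**
structure unit (`R1:… R2:…`), and the reverse mate is analyzed in
machine orientation — strand suffixes, not reverse-complementing, carry
orientation information.

The summary is one self-contained HTML page: run options, the pattern
table with both strands, the diagnostics above, and the structure table
(counts and percentages at 4 significant digits) with a residual line
for rows hidden by the rate floor. The detail file is gzip-compressed
NDJSON — one object per read or pair — chosen over a single JSON array
so it can be written and parsed as a stream; it round-trips losslessly.

Tie-breaking and degenerate inputs: structure rows with equal counts are
ordered lexicographically; empty reads, empty pattern sets, non-ACGT
pattern characters (IUPAC codes included), duplicate names and malformed
JSON are rejected with specific errors. Aggregation is exact integer
counting, so the only floating-point quantity is the rate, checked to
1e-9 conservation in the tests.

## The synthetic-read generator

`generateReads()` draws reads from weighted `structureTemplate()`s —
ordered lists of planted pattern copies and random fillers with a
per-base substitution rate and an optional ±1 bp indel on a named
pattern token (emulating A-tailing / synthesis-length errors). Fillers
are rejection-sampled so that the assembled read contains pattern
occurrences *exactly* at the planted positions; the expected structure
string of every error-free read is therefore computable in closed form,
and the generator emits it as a truth table. Qualities are constant
Phred 37, since qualities are pass-through data in this tool.

What the generator does **not** emulate: platform-specific quality
decay, indels outside the single ±1 bp token event, chimeric inserts,
and genomic sequence composition (fillers are i.i.d. uniform ACGT).
Passing tests on generator data therefore demonstrate the correctness of
the segmentation, counting and I/O machinery under the model's own
assumptions, not recall on any particular instrument's error profile —
on real data, full-match semantics means match rates are lower bounds.

## Problem sizes and verification

The test suite cross-checks the implementation against two independent
oracles: a quadratic dynamic-programming edit distance (the package
itself delegates to `utils::adist`) and a brute-force segmentation
oracle that enumerates occurrences by naive substring comparison and
replays the claiming order. Default verification sizes are 1,000 planted
reads for oracle equivalence, 10,000 random string pairs (length ≤ 40)
for the distance check, 10,000 random odd-length strings for the
palindrome property, and a 1,000-read 70/20/10 template mix for
end-to-end recovery; these sizes give the properties thousands of
chances to fail while keeping the whole suite under two minutes on one
core. `scripts/acceptance.R` re-runs the same checks from a single seed
against the installed package.

## Known limitations

* No mismatch-tolerant or quality-weighted matching; one error, no
  match. The Levenshtein diagnostics are descriptive, not corrective.
* No IUPAC wildcards in patterns.
* No SAM/BAM/uBAM or interleaved-FastQ input, and no read trimming —
  the tool annotates, it never modifies reads.
* Whole-segment Levenshtein similarity is not a local alignment; for a
  long unknown segment the distance to a short pattern is dominated by
  the length difference.
* Structure frequencies are reported without statistical tests; the
  table is descriptive QC output.
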