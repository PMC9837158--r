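# ReadContext

Read-structure segmentation for NGS protocol debugging.

NGS library preparation incorporates *service sequences* — sequencing
adapters, primers, sample/cell/molecule barcodes — and when a protocol
misbehaves, the fastest diagnostic is often to look at **where those
sequences actually sit inside the reads**. ReadContext decomposes every
read (or read pair) into an ordered, strand-annotated token string, the
*read structure*, and tabulates how often each structure occurs across a
FastQ file.

Given an ordered pattern dictionary such as

```json
{"foo": "CTGTCTCTTATACAC", "bar": "CCGAAAACACG", "baz": "TCGTCGGG"}
```

each read is scanned pattern by pattern (in dictionary order, forward
strand before reverse complement), claiming exact occurrences greedily
from the left; matching is full-match only, so one sequencing error
removes a match. Whatever remains unclaimed becomes either a short
length-labelled unknown (*K-mer*, e.g. `{kmer:14bp}` — the signature of a
pattern copy one base shorter or longer than expected, as produced by
A-tailing or oligo-synthesis errors) or an `{unknown}` stretch. A read
that carries adapter `foo` on the forward strand after 60 unrecognized
bases and ends in a 14 bp remnant renders as

```
{unknown}{foo:F}{kmer:14bp}
```

Reverse-complement palindromic patterns render without a strand suffix
(`{pal}`), since their orientation is undefined. Before any read is
processed the dictionary itself is diagnosed: long-to-short ordering,
pairwise Levenshtein distances over all four strand combinations
(confusable pairs), exact nesting, and palindromes / near-palindromes.

Outputs are a self-contained HTML summary (run options, pattern
diagnostics, and the structure frequency table with a display-only rate
floor) and, optionally, a gzip-compressed NDJSON detail file with one
record per read or pair (sequence, Phred scores, segment table, and —
with `--levenshtein` — per-segment edit distances to every pattern).

## Worked example

```r
library(ReadContext)

ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC","bar":"CCGAAAACACG","baz":"TCGTCGGG"}')

structureString(segmentRead("CTGTCTCTTATACAC", ps))
#> [1] "{foo:F}"
structureString(segmentRead("GTGTATAAGAGACAG", ps))   # reverse complement
#> [1] "{foo:R}"
structureString(segmentRead(paste0(strrep("A", 60), "CTGTCTCTTATACAC", strrep("G", 14)), ps))
#> [1] "{unknown}{foo:F}{kmer:14bp}"

patternDistances(ps)$min
#>     foo bar baz
#> foo   0   7  10
#> bar   7   0   7
#> baz  10   7   0

tab <- aggregateStructures(c("{foo:F}", "{foo:F}", "{unknown}"))
structureRows(tab)
#>   structure count      rate
#> 1   {foo:F}     2 0.6666667
#> 2 {unknown}     1 0.3333333
```

The minimum pairwise edit distance here is 7, comfortably above the
default confusability threshold of 2, so no `near-match` warning is
raised: a couple of sequencing errors cannot turn one of these patterns
into another. The structure table says two thirds of the reads carry
`foo` forward and one third match nothing.

From a shell, the same pipeline runs as:

```sh
Rscript inst/scripts/fastcontext.R \
  --r1 reads_R1.fastq.gz --r2 reads_R2.fastq.gz \
  --patterns '{"foo":"CTGTCTCTTATACAC","bar":"CCGAAAACACG","baz":"TCGTCGGG"}' \
  --summary summary.html --json details.json.gz --threads 4
```

FastQ input may be plain, gzip- or bz2-compressed (detected from magic
bytes, not the extension). In paired mode each pair is one structure
unit: `R1:{foo:F}{unknown} R2:{unknown}{foo:R}`.

The package also ships a truth-labelled synthetic-read generator
(`generateReads()` with `structureTemplate()` / `patternToken()` /
`fillerToken()`): fillers are rejection-sampled to be pattern-free, so
the expected structure string of every error-free read is known exactly.
All test fixtures are built with it at run time.

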