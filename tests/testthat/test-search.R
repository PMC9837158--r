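test_that("single full-length matches are found on both strands", {
  ps <- fooBarBazSet()
  rs <- segmentRead("CTGTCTCTTATACAC", ps)
  expect_identical(structureString(rs), "{foo:F}")
  seg <- readSegments(rs)
  expect_identical(seg$start, 0L)
  expect_identical(seg$end, 15L)
  expect_identical(structureString(segmentRead("GTGTATAAGAGACAG", ps)), "{foo:R}")
})

test_that("structure rendering follows the token conventions", {
  ps <- fooBarBazSet()
  read <- paste0(strrep("A", 60), "CTGTCTCTTATACAC", strrep("G", 14))
  expect_identical(structureString(segmentRead(read, ps)),
                   "{unknown}{foo:F}{kmer:14bp}")
  # palindromic patterns carry no strand suffix
  psPal <- parsePatternSet('{"p":"GAATTC"}')
  expect_identical(structureString(segmentRead("GAATTC", psPal)), "{p}")
  expect_identical(structureString(segmentRead(strrep("A", 100), psPal)),
                   "{unknown}")
})

test_that("degenerate inputs are rejected", {
  ps <- fooBarBazSet()
  expect_error(segmentRead("", ps), "empty read")
  psEmpty <- ps
  psEmpty@sequences <- character(0)
  expect_error(segmentRead("ACGT", psEmpty), "empty pattern set")
})

test_that("segments always tile the read exactly", {
  ps <- fooBarBazSet()
  set.seed(303)
  reads <- makePlantedReads(50, patternSequences(ps))
  for (read in reads) {
    seg <- readSegments(segmentRead(read, ps))
    expect_identical(seg$start[1L], 0L)
    expect_identical(seg$end[nrow(seg)], nchar(read))
    if (nrow(seg) > 1L)
      expect_identical(seg$end[-nrow(seg)], seg$start[-1L])
    expect_identical(paste(seg$sequence, collapse = ""), read)
  }
})

test_that("earlier patterns claim bases and block overlapping later patterns", {
  # A = first 10 bases; B overlaps A's tail, so B must be absent
  ps <- parsePatternSet('{"A":"ACGTACGTAC","B":"GTACTTTT"}')
  read <- "ACGTACGTACTTTTGGGGGGGGGGGGGGGG"   # B would start inside A at pos 7
  rs <- segmentRead(read, ps)
  expect_false("B" %in% readSegments(rs)$pattern)
  expect_true("A" %in% readSegments(rs)$pattern)
})

test_that("forward occurrences beat overlapping reverse occurrences of the same pattern", {
  # p = AACCG, revcomp = CGGTT; in AACCGGTT they overlap at the CG core
  ps <- parsePatternSet('{"p":"AACCG"}')
  rs <- segmentRead("AACCGGTT", ps)
  seg <- readSegments(rs)
  expect_identical(seg$strand[seg$kind == "match"], "F")
  expect_identical(structureString(rs), "{p:F}{kmer:3bp}")
})

test_that("matching is full-match only: one substitution kills the match", {
  ps <- fooBarBazSet()
  read <- paste0(strrep("T", 30), "CTGTCTCTTATACAC", strrep("G", 30))
  expect_identical(structureString(segmentRead(read, ps)),
                   "{unknown}{foo:F}{unknown}")
  mutated <- sub("CTGTCTCTTATACAC", "CTGTCTCTAATACAC", read, fixed = TRUE)
  rs <- segmentRead(mutated, ps)
  expect_false("foo" %in% readSegments(rs)$pattern)
  expect_identical(structureString(rs), "{unknown}")
})

test_that("one-base-truncated pattern copies surface as length-labelled K-mers", {
  ps <- fooBarBazSet()  # maxKmerSize defaults to 16
  # unclaimed regions merge, so the 14 bp remnant is isolated between
  # claimed baz matches to surface as its own K-mer token
  read <- paste0("TCGTCGGG", substr("CTGTCTCTTATACAC", 1, 14), "TCGTCGGG")
  expect_identical(structureString(segmentRead(read, ps)),
                   "{baz:F}{kmer:14bp}{baz:F}")
  # one base beyond maxKmerSize stays {unknown}
  rs <- segmentRead(strrep("A", 17), ps)
  expect_identical(structureString(rs), "{unknown}")
  expect_identical(structureString(segmentRead(strrep("A", 16), ps)),
                   "{kmer:16bp}")
})

test_that("segmentation agrees with the brute-force claiming oracle", {
  ps <- fooBarBazSet()
  pats <- patternSequences(ps)
  set.seed(404)
  reads <- makePlantedReads(150, pats)
  for (read in reads) {
    expect_identical(structureString(segmentRead(read, ps)),
                     oracleStructure(read, pats))
  }
})

test_that("read pairs are segmented independently and render as one unit", {
  ps <- fooBarBazSet()
  p <- segmentPair(list(id = "a/1", sequence = "CTGTCTCTTATACAC"),
                   list(id = "a/2", sequence = "GTGTATAAGAGACAG"), ps)
  expect_identical(p$structureString, "R1:{foo:F} R2:{foo:R}")
  p2 <- segmentPair(list(id = "b 1:N:0:ACGT", sequence = strrep("A", 100)),
                    list(id = "b 2:N:0:ACGT", sequence = strrep("C", 100)), ps)
  expect_identical(p2$structureString, "R1:{unknown} R2:{unknown}")
  expect_error(
    segmentPair(list(id = "a/1", sequence = "ACGTACGT"),
                list(id = "b/2", sequence = "ACGTACGT"), ps),
    "a/1.*b/2")
})
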