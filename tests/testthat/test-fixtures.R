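test_that("a bare pattern template reproduces the pattern exactly", {
  ps <- fooBarBazSet()
  g <- generateReads(list(structureTemplate(list(patternToken("foo")))),
                     ps, nReads = 10, seed = 1)
  expect_identical(unique(g$reads1$sequence), "CTGTCTCTTATACAC")
  expect_identical(unique(g$truth$expected_structure), "{foo:F}")
  expect_identical(unique(nchar(g$reads1$quality)), 15L)
  expect_true(all(phredScores(g$reads1$quality[1L])[[1L]] == 37L))
})

test_that("filler tokens produce pattern-free flanks with exact truth labels", {
  ps <- fooBarBazSet()
  tpl <- structureTemplate(list(fillerToken(20, 30), patternToken("foo", "R"),
                                fillerToken(20, 30)))
  g <- generateReads(list(tpl), ps, nReads = 40, seed = 2)
  expect_identical(unique(g$truth$expected_structure),
                   "{unknown}{foo:R}{unknown}")
  # short fillers get kmer labels instead
  tplShort <- structureTemplate(list(fillerToken(5, 10), patternToken("foo")))
  g2 <- generateReads(list(tplShort), ps, nReads = 20, seed = 2)
  expect_true(all(grepl("^\\{kmer:(5|6|7|8|9|10)bp\\}\\{foo:F\\}$",
                        g2$truth$expected_structure)))
  # rejection sampling: no filler contains any pattern on either strand
  fillers <- g$pieces[!g$pieces$isMatch, "sequence"]
  for (f in fillers)
    for (p in c(patternSequences(ps), patternRevcomp(ps)))
      expect_length(oracleOccurrences(p, f), 0L)
})

test_that("generated reads match their truth structures when segmented", {
  ps <- fooBarBazSet()
  templates <- list(
    structureTemplate(list(fillerToken(20, 30), patternToken("foo"),
                           fillerToken(20, 30), patternToken("baz", "R")),
                      weight = 0.5),
    structureTemplate(list(patternToken("bar"), fillerToken(20, 30)),
                      weight = 0.5))
  g <- generateReads(templates, ps, nReads = 60, seed = 33)
  got <- vapply(g$reads1$sequence, function(s)
    structureString(segmentRead(s, ps)), character(1), USE.NAMES = FALSE)
  expect_identical(got, g$truth$expected_structure)
})

test_that("generation is byte-identical for the same seed", {
  ps <- fooBarBazSet()
  tpl <- structureTemplate(list(fillerToken(20, 30), patternToken("foo"),
                                fillerToken(20, 30)))
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  generateReads(list(tpl), ps, nReads = 30, seed = 99, r1Path = f1)
  generateReads(list(tpl), ps, nReads = 30, seed = 99, r1Path = f2)
  generateReads(list(tpl), ps, nReads = 30, seed = 100, r1Path = f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("paired generation writes synchronized mates with pair-level truth", {
  ps <- fooBarBazSet()
  tpl <- structureTemplate(
    list(patternToken("foo"), fillerToken(20, 30)),
    tokens2 = list(fillerToken(20, 30), patternToken("foo", "R")))
  r1 <- tempfile(); r2 <- tempfile(); tt <- tempfile()
  g <- generateReads(list(tpl), ps, nReads = 15, seed = 8, paired = TRUE,
                     r1Path = r1, r2Path = r2, truthPath = tt)
  expect_identical(unique(g$truth$expected_structure),
                   "R1:{foo:F}{unknown} R2:{unknown}{foo:R}")
  fq1 <- readFastq(r1); fq2 <- readFastq(r2)
  pairReads(fq1, fq2)
  truth <- utils::read.delim(tt, stringsAsFactors = FALSE)
  expect_identical(truth$expected_structure, g$truth$expected_structure)
  got <- vapply(seq_len(nrow(fq1)), function(i)
    segmentPair(as.list(fq1[i, ]), as.list(fq2[i, ]), ps)$structureString,
    character(1))
  expect_identical(got, g$truth$expected_structure)
})

test_that("error-rate templates carry NA truth and invalid templates error", {
  ps <- fooBarBazSet()
  noisy <- structureTemplate(list(fillerToken(20, 30), patternToken("foo")),
                             errorRate = 0.1)
  g <- generateReads(list(noisy), ps, nReads = 5, seed = 4)
  expect_true(all(is.na(g$truth$expected_structure)))
  expect_error(
    generateReads(list(structureTemplate(list(patternToken("nope")))),
                  ps, nReads = 2, seed = 1),
    "unknown pattern")
  expect_error(
    generateReads(list(structureTemplate(list(patternToken("foo")),
                                         weight = 0.5)),
                  ps, nReads = 2, seed = 1),
    "sum to 1")
})

test_that("indel templates relabel the affected copy as a K-mer", {
  ps <- fooBarBazSet()
  tpl <- structureTemplate(
    list(fillerToken(20, 30), patternToken("foo"), fillerToken(20, 30)),
    indel = list(pattern = "foo", delta = -1L))
  g <- generateReads(list(tpl), ps, nReads = 20, seed = 6)
  expect_identical(unique(g$truth$expected_structure), "{unknown}")
  # the truncated copy merges into its flanking fillers; with tight
  # flanks the whole read becomes one labelled K-mer run
  tpl2 <- structureTemplate(list(patternToken("foo")),
                            indel = list(pattern = "foo", delta = -1L))
  g2 <- generateReads(list(tpl2), ps, nReads = 20, seed = 6)
  expect_identical(unique(g2$truth$expected_structure), "{kmer:14bp}")
  got <- vapply(g2$reads1$sequence, function(s)
    structureString(segmentRead(s, ps)), character(1), USE.NAMES = FALSE)
  expect_identical(got, g2$truth$expected_structure)
})
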