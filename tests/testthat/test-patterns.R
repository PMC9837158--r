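test_that("pattern JSON parses in key order with lengths and revcomps", {
  ps <- fooBarBazSet()
  expect_identical(patternNames(ps), c("foo", "bar", "baz"))
  expect_identical(unname(patternLengths(ps)), c(15L, 11L, 8L))
  expect_identical(unname(patternRevcomp(ps)[1L]), "GTGTATAAGAGACAG")
  expect_false(any(isPalindromic(ps)))
  expect_identical(nrow(patternWarnings(ps)), 0L)
})

test_that("palindromic single pattern is recognized and revcomp is an involution", {
  ps <- parsePatternSet('{"p":"ACGT"}')
  expect_identical(unname(patternRevcomp(ps)), "ACGT")
  expect_true(isPalindromic(ps)[["p"]])
})

test_that("lowercase input is canonicalized and file-path input is accepted", {
  ps <- parsePatternSet('{"p":"acgtt"}')
  expect_identical(unname(patternSequences(ps)), "ACGTT")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(fooBarBazJSON, f)
  expect_identical(patternNames(parsePatternSet(f)), c("foo", "bar", "baz"))
})

test_that("invalid pattern input is rejected with informative errors", {
  expect_error(parsePatternSet('{"a":"AAAN"}'), "'a'.*'N'")
  expect_error(parsePatternSet('{"a":"ACGT","a":"GGGG"}'), "duplicate")
  expect_error(parsePatternSet("{}"), "non-empty")
  expect_error(parsePatternSet('{"a": bad}'), "parse error")
  expect_error(parsePatternSet('{"a": 5}'), "strings")
  expect_error(parsePatternSet('{"a": ""}'), "empty")
})

test_that("order check warns only on the first length increase", {
  expect_identical(nrow(checkPatternOrder(fooBarBazSet())), 0L)
  ps <- parsePatternSet('{"short":"TCGTCGGG","long":"CTGTCTCTTATACAC"}')
  w <- checkPatternOrder(ps)
  expect_identical(w$kind, "not-sorted")
  expect_identical(w$members, "short,long")
  tied <- parsePatternSet('{"a":"ACGTACGTAC","b":"TTTTTTTTTT","c":"GGGG"}')
  expect_identical(nrow(checkPatternOrder(tied)), 0L)
})

test_that("pattern-pair distances match the DP oracle and flag confusable pairs", {
  ps <- parsePatternSet('{"a":"ACGTACGT","b":"ACGTACGA"}')
  d <- patternDistances(ps, confusionThreshold = 2L)
  expect_identical(d$min["a", "b"], 1L)
  expect_true("near-match" %in% d$warnings$kind)

  d3 <- patternDistances(fooBarBazSet(), confusionThreshold = 2L)
  # frozen from the brute-force DP oracle over all four strand combinations
  expect_identical(d3$min["foo", "bar"], 7L)
  expect_identical(d3$min["foo", "baz"], 10L)
  expect_identical(d3$min["bar", "baz"], 7L)
  expect_false("near-match" %in% d3$warnings$kind)
})

test_that("nesting is detected as exact substring containment on either strand", {
  ps <- parsePatternSet('{"long":"AACCGGTTAA","short":"CCGGTT"}')
  w <- patternDistances(ps)$warnings
  expect_true(any(w$kind == "nested" & w$members == "short,long"))
  # revcomp nesting: revcomp(GGAATT) = AATTCC sits inside the long pattern
  ps2 <- parsePatternSet('{"long":"CAATTCCG","rcnested":"GGAATT"}')
  w2 <- patternDistances(ps2)$warnings
  expect_true(any(w2$kind == "nested"))
})

test_that("palindrome diagnostics flag palindromes and near-palindromes only", {
  ps <- parsePatternSet('{"ecoRI":"GAATTC","risky":"GAATTA","far":"AAAAA"}')
  w <- analyzePalindromes(ps, palindromeRiskThreshold = 2L)
  expect_identical(w$kind[w$members == "ecoRI"], "palindrome")
  expect_identical(w$kind[w$members == "risky"], "near-palindrome")
  expect_identical(w$distance[w$members == "risky"], 2L)  # DP oracle: GAATTA vs TAATTC
  expect_false("far" %in% w$members)
})

test_that("reverse complement is an involution and odd lengths are never palindromic", {
  set.seed(101)
  for (k in 1:50) {
    s <- randomDNAString(sample(1:40, 1L))
    expect_identical(reverseComplementStrings(reverseComplementStrings(s)), s)
    expect_identical(reverseComplementStrings(s), oracleRevComp(s))
  }
  for (k in 1:50) {
    s <- randomDNAString(2L * sample(1:15, 1L) - 1L)  # odd length
    ps <- parsePatternSet(sprintf('{"p":"%s"}', s))
    expect_false(isPalindromic(ps)[["p"]])
    w <- analyzePalindromes(ps)
    expect_false("palindrome" %in% w$kind)
  }
})

test_that("distance matrix is symmetric, zero-diagonal, and triangle-consistent", {
  set.seed(202)
  for (k in 1:20) {
    seqs <- vapply(1:3, function(i) randomDNAString(sample(5:20, 1L)), character(1))
    ps <- parsePatternSet(jsonlite::toJSON(
      as.list(setNames(seqs, c("x", "y", "z"))), auto_unbox = TRUE))
    m <- patternDistances(ps)$min
    expect_identical(m, t(m))
    expect_identical(unname(diag(m)), rep(0L, 3L))
    expect_true(m["x", "z"] <= m["x", "y"] + m["y", "z"])
  }
})
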