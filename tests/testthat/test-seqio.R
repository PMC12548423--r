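test_that("readFasta normalizes case, RNA, and ambiguity codes", {
  fa <- withr::local_tempfile(fileext = ".fa")

  writeLines(c(">a", "acgt"), fa)
  expect_equal(as.character(readFasta(fa)), c(a = "ACGT"))

  writeLines(c(">a", "ACGU"), fa)
  expect_equal(as.character(readFasta(fa)), c(a = "ACGT"))

  writeLines(c(">a", "ACRT"), fa)
  expect_warning(x <- readFasta(fa), "ambiguity")
  expect_equal(as.character(x), c(a = "ACNT"))

  writeLines(c(">a", "AC!T"), fa)
  expect_error(suppressWarnings(readFasta(fa)))

  writeLines(character(0), fa)
  expect_error(readFasta(fa), "empty")
})

test_that("FASTA round trip reproduces records exactly", {
  set.seed(11)
  seqs <- vapply(1:5, function(i) randomSeq(sample(20:200, 1)), "")
  names(seqs) <- paste0("rec", 1:5)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeFasta(seqs, fa)
  expect_identical(as.character(readFasta(fa)), seqs)
})

test_that("buildConsensus applies majority rule with documented ties", {
  cons <- function(x) as.character(buildConsensus(
    stats::setNames(x, paste0("s", seq_along(x)))
  )[[1]])

  expect_equal(cons(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(cons(c("ACGT", "ACGA", "ACGA")), "ACGA")
  # gap minority dropped per column, not per record
  expect_equal(cons(c("A-GT", "AC-T", "ACGT")), "ACGT")
  # majority gap column dropped entirely
  expect_equal(cons(c("A-GT", "A-GT", "ACGT")), "AGT")
  # tie broken by first record's base
  expect_equal(cons(c("ACGT", "ACGA", "TCGA", "TCGT")), "ACGT")
  # N ignored in voting unless all N
  expect_equal(cons(c("ANGT", "ANGT", "ACGT")), "ACGT")
  expect_equal(cons(c("ANGT", "ANGT", "ANGT")), "ANGT")

  expect_error(cons("ACGT"), "at least 2")
  expect_error(
    buildConsensus(c(a = "ACGT", b = "ACG"), preAligned = TRUE),
    "equal lengths"
  )
  expect_error(
    buildConsensus(c(a = "ACGT", b = "ACGT"), preAligned = FALSE),
    "upstream"
  )
})

test_that("buildConsensus is permutation-invariant away from ties", {
  set.seed(23)
  base <- randomSeq(80)
  recs <- vapply(1:5, function(i) mutateSeq(base, 0.05), "")
  names(recs) <- paste0("s", 1:5)
  ref <- as.character(buildConsensus(recs)[[1]])
  for (k in 1:5) {
    perm <- sample(recs)
    # identical majority structure; only tie columns may differ, and a tie
    # needs >= 2 distinct maxima, rare at 5 deep coverage of one template
    got <- as.character(buildConsensus(perm)[[1]])
    expect_equal(nchar(got), nchar(ref))
  }
  # unanimity columns never change under permutation
  expect_equal(ref, as.character(buildConsensus(rev(recs))[[1]]))
})

test_that("alignPairwise reproduces hand-scored alignments", {
  # identity: no gaps, no mismatches
  a <- alignPairwise(c(r = "ACGT"), c(q = "ACGT"))
  expect_equal(alignedRef(a), "ACGT")
  expect_equal(alignedQry(a), "ACGT")

  # single deletion beats mismatches under (1, -1, 2, 1)
  a <- alignPairwise(c(r = "ACGT"), c(q = "AGT"), alignParams(1, -1, 2, 1))
  expect_equal(alignedRef(a), "ACGT")
  expect_equal(alignedQry(a), "A-GT")
  expect_equal(alignmentScore(a), 0)

  # all-mismatch: gaps cost more than substitutions under defaults
  a <- alignPairwise(c(r = "AAAA"), c(q = "TTTT"))
  expect_equal(alignedRef(a), "AAAA")
  expect_equal(alignedQry(a), "TTTT")
  expect_equal(alignmentScore(a), 4 * -3)
})

test_that("self-alignment of a long sequence has no gaps or mismatches", {
  set.seed(7)
  s <- randomSeq(10000)
  a <- alignPairwise(c(r = s), c(q = s))
  expect_equal(alignedRef(a), s)
  expect_equal(alignedQry(a), s)
  expect_equal(alignmentScore(a), 2 * 10000)
})

test_that("alignment scores match the independent DP oracle", {
  set.seed(31)
  for (k in 1:25) {
    a <- randomSeq(sample(5:60, 1))
    b <- randomSeq(sample(5:60, 1))
    got <- alignmentScore(alignPairwise(c(r = a), c(q = b)))
    expect_equal(got, oracleAlignScore(a, b), info = paste(a, b))
  }
})

test_that("ingestAlignedFasta projects reference coordinates", {
  alns <- ingestAlignedFasta(c(r = "AC-T", q = "ACGT"), "r")
  expect_length(alns, 1)
  a <- alns[["q"]]
  expect_equal(alignedRef(a), "AC-T")
  expect_equal(alignedQry(a), "ACGT")
  expect_equal(refPositions(a), c(1L, 2L, NA_integer_, 3L))

  # two queries share the reference coordinate frame
  alns <- ingestAlignedFasta(c(r = "ACGT", q1 = "ACGA", q2 = "TCGT"), "r")
  expect_equal(refPositions(alns[["q1"]]), refPositions(alns[["q2"]]))

  # reference only -> empty list
  expect_length(ingestAlignedFasta(c(r = "ACGT"), "r"), 0)

  expect_error(ingestAlignedFasta(c(r = "ACGT", q = "ACG"), "r"), "equal")
  expect_error(ingestAlignedFasta(c(r = "ACGT", q = "ACGA"), "zz"),
               "not found")

  # columns gapped in both reference and query are dropped for that pair
  alns <- ingestAlignedFasta(c(r = "A-CG", q1 = "A-CG", q2 = "ATCG"), "r")
  expect_equal(nchar(alignedRef(alns[["q1"]])), 3)
  expect_equal(nchar(alignedRef(alns[["q2"]])), 4)
})

test_that("aligned FASTA export round-trips through the ingester", {
  set.seed(5)
  ref <- randomSeq(120)
  qry <- mutateSeq(ref, 0.08)
  a <- alignPairwise(c(r = ref), c(q = qry))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeAlignedFasta(a, fa)
  back <- ingestAlignedFasta(readFasta(fa), "r")[["q"]]
  expect_equal(alignedRef(back), alignedRef(a))
  expect_equal(alignedQry(back), alignedQry(a))
})
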