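gaRecords <- function(aln) {
  r <- classifyMismatches(aln)
  r[r$klass == "G>A", , drop = FALSE]
}

test_that("extractContexts reads minus-strand 3-mers", {
  # plus-strand GAA -> minus-strand TTC (the canonical preferred target)
  a <- gaplessAln("TTGAATT", "TTAAATT")
  sites <- extractContexts(gaRecords(a), a)
  expect_equal(sites$minusContext, "TTC")
  expect_equal(sites$refPos, 3L)

  # plus-strand GAT -> minus ATC
  a <- gaplessAln("TTGATTT", "TTAATTT")
  expect_equal(extractContexts(gaRecords(a), a)$minusContext, "ATC")

  # contemporaneous source reads edited neighbors from the query:
  # ref GGG / qry AAA -> first site sees minus TTC at edit time
  a <- gaplessAln("TTGGGTT", "TTAAATT")
  recs <- gaRecords(a)
  ref <- extractContexts(recs, a, source = "reference")
  cont <- extractContexts(recs, a, source = "contemporaneous")
  expect_equal(ref$minusContext[ref$refPos == 3], "CCC")
  expect_equal(cont$minusContext[cont$refPos == 3], "TTC")

  # non-G>A input is an error
  a <- gaplessAln("CCC", "TTT")
  expect_error(extractContexts(classifyMismatches(a), a), "G>A")
})

test_that("sites at edges or beside gaps are dropped with a message", {
  # G>A at the last position: no +1/+2 context
  a <- gaplessAln("TTG", "TTA")
  expect_message(sites <- extractContexts(gaRecords(a), a), "dropped 1")
  expect_equal(nrow(sites), 0)

  # insertion column between the site and its neighbor
  a <- ingestAlignedFasta(c(r = "TTG-AAT", q = "TTACAAT"), "r")[["q"]]
  expect_message(sites <- extractContexts(gaRecords(a), a), "dropped 1")
  expect_equal(nrow(sites), 0)

  # deletion at a neighbor
  a <- ingestAlignedFasta(c(r = "TTGAATT", q = "TTA-ATT"), "r")[["q"]]
  expect_message(sites <- extractContexts(gaRecords(a), a), "dropped 1")
  expect_equal(nrow(sites), 0)
})

test_that("reference-source contexts always end in C and account for drops", {
  set.seed(61)
  for (k in 1:10) {
    ref <- randomSeq(400)
    qry <- mutateSeq(ref, 0.1)
    a <- gaplessAln(ref, qry)
    recs <- gaRecords(a)
    sites <- suppressMessages(extractContexts(recs, a))
    expect_true(all(substr(sites$minusContext, 3, 3) == "C"))
    expect_lte(nrow(sites), nrow(recs))
    # reference context equals revcomp of the plus-strand triplet
    for (i in seq_len(nrow(sites))) {
      p <- sites$refPos[i]
      expect_equal(sites$minusContext[i],
                   revcompStr(substr(ref, p, p + 2)))
    }
  }
})

test_that("standaloneFilter drops sites with mutated -1/-2 neighbors", {
  # run of three G>A: only the 3'-most site has unmutated neighbors
  a <- gaplessAln("TTGGGTTTT", "TTAAATTTT")
  recs <- classifyMismatches(a)
  sites <- extractContexts(gaRecords(a), a)
  kept <- standaloneFilter(sites, recs)
  expect_equal(kept$refPos, 5L)

  # isolated site passes through; filter is idempotent and a subset
  a <- gaplessAln("TTGAATTTT", "TTAAATTTT")
  recs <- classifyMismatches(a)
  sites <- extractContexts(gaRecords(a), a)
  kept <- standaloneFilter(sites, recs)
  expect_equal(nrow(kept), 1)
  expect_identical(standaloneFilter(kept, recs), kept)

  # a non-G>A neighbor excludes under "any" but not under "GA"
  a <- gaplessAln("TTGCATTTT", "TTATATTTT")  # G>A at 3, C>T at 4
  recs <- classifyMismatches(a)
  sites <- extractContexts(gaRecords(a), a)
  expect_equal(nrow(standaloneFilter(sites, recs, exclude = "any")), 0)
  expect_equal(nrow(standaloneFilter(sites, recs, exclude = "GA")), 1)
})

test_that("sharedSites intersects profiles at a minimum share", {
  lv <- levels(classifyMismatches(gaplessAln("G", "A"))$klass)
  mk <- function(pos) {
    data.frame(refPos = as.integer(pos),
               refBase = rep("G", length(pos)),
               qryBase = rep("A", length(pos)),
               klass = factor(rep("G>A", length(pos)), levels = lv))
  }
  profs <- list(a = mk(c(100, 200)), b = mk(c(100, 300)), c = mk(400))
  expect_equal(sharedSites(profs, 2), 100L)
  expect_equal(sharedSites(profs, 3), integer(0))
  expect_equal(sharedSites(profs[1], 2), integer(0))
  expect_error(sharedSites(profs, 1), ">= 2")
})

test_that("buildLogo computes frequencies and information content", {
  mkSites <- function(ctx) {
    data.frame(refPos = seq_along(ctx), minusContext = ctx,
               source = "reference", stringsAsFactors = FALSE)
  }
  logo <- buildLogo(mkSites(rep("TTC", 10)))
  expect_equal(unname(infoBits(logo)), c(2, 2, 2))
  expect_equal(logoFreqs(logo)[["T", "-2"]], 1)

  # -2 split evenly over four bases: zero information
  logo <- buildLogo(mkSites(c("ATC", "CTC", "GTC", "TTC")))
  expect_equal(infoBits(logo)[["-2"]], 0)
  expect_equal(infoBits(logo)[["-1"]], 2)

  # 50/50 T/A at -2: one bit
  logo <- buildLogo(mkSites(c("TTC", "ATC")))
  expect_equal(infoBits(logo)[["-2"]], 1)

  expect_error(buildLogo(mkSites("TTC")[0, , drop = FALSE]), "at least one")
})

test_that("classifyPreference separates the two allele signatures", {
  mkSites <- function(ctx) {
    data.frame(refPos = seq_along(ctx), minusContext = ctx,
               source = "reference", stringsAsFactors = FALSE)
  }
  # T(T/C)C-dominated edits: strong T at -2
  b6 <- mkSites(c(rep("TTC", 12), rep("TCC", 9), "ATC", "GTC", "CCC"))
  callB6 <- classifyPreference(b6)
  expect_equal(callB6$label, "B6-like")
  expect_gt(callB6$score, 0.5)

  # XTC edits: -2 uniform, T required at -1
  balb <- mkSites(rep(c("ATC", "CTC", "GTC", "TTC"), 6))
  callBalb <- classifyPreference(balb)
  expect_equal(callBalb$label, "BALB-like")

  # below the sample-size gate: indeterminate
  expect_equal(classifyPreference(b6[1:10, ])$label, "indeterminate")

  # LogoMatrix input is accepted as-is
  expect_equal(classifyPreference(buildLogo(b6))$label, "B6-like")
})
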