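test_that("generateProvirus builds identical LTRs and a seeded CDS", {
  t <- generateProvirus(seed = 3)
  expect_equal(ltr5Range(t), c(1L, 1300L))
  expect_equal(ltr3Range(t), c(6701L, 8000L))
  s <- templateSeq(t)
  expect_equal(substr(s, 1, 1300), substr(s, 6701, 8000))

  cds <- cdsTable(t)
  cdsSeq <- substr(s, cds$start, cds$end)
  expect_equal(substr(cdsSeq, 1, 3), "ATG")
  codons <- substring(cdsSeq, seq(1, nchar(cdsSeq) - 2, 3),
                      seq(3, nchar(cdsSeq), 3))
  expect_gte(sum(codons == "TGG"), 20)
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))

  # determinism
  expect_identical(templateSeq(generateProvirus(seed = 3)), s)
  expect_false(identical(templateSeq(generateProvirus(seed = 4)), s))

  expect_error(generateProvirus(totalLen = 2000, ltrLen = 1300),
               "ltrLen")
})

test_that("simulateEditing realizes every event as plus-strand G>A", {
  t <- generateProvirus(totalLen = 4000, ltrLen = 500, seed = 13)
  cfg <- editConfig(baseRate = 0.1, seed = 13)
  sim <- simulateEditing(t, cfg)
  ref <- strsplit(templateSeq(t), "")[[1]]
  ed <- strsplit(as.character(sim$edited[[1]]), "")[[1]]
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ref[ev$pos] == "G"))
  expect_true(all(ed[ev$pos] == "A"))
  expect_false(any(duplicated(ev$pos)))
  # positions not in the truth are unchanged (no background configured)
  expect_equal(which(ref != ed), sort(ev$pos))
  # determinism, byte for byte
  sim2 <- simulateEditing(t, cfg)
  expect_identical(as.character(sim2$edited[[1]]),
                   as.character(sim$edited[[1]]))
  expect_identical(sim2$truth, sim$truth)
})

test_that("zero base rate edits nothing; background stays non-G>A", {
  t <- generateProvirus(totalLen = 4000, ltrLen = 500, seed = 17)
  sim <- simulateEditing(t, editConfig(baseRate = 0,
                                       backgroundSubRate = 0.01, seed = 17))
  expect_equal(nrow(sim$truth$events), 0)
  bg <- sim$truth$background
  expect_gt(nrow(bg), 0)
  expect_false(any(bg$fromBase == "G" & bg$toBase == "A"))
  # sequence differs from the template exactly at background positions
  ref <- strsplit(templateSeq(t), "")[[1]]
  ed <- strsplit(as.character(sim$edited[[1]]), "")[[1]]
  expect_equal(which(ref != ed), sort(bg$pos))
})

test_that("weights restrict editing to their contexts", {
  # exactly one minus-strand TTC (plus GAA) and no other editable context
  t <- tinyTemplate("TTAGAATATT", c(1, 2), c(9, 10))
  cfg <- editConfig(baseRate = 1, contextWeights = c(TTC = 1),
                    defaultWeight = 0, seed = 1)
  sim <- simulateEditing(t, cfg)
  expect_equal(sim$truth$events$pos, 4L)
  expect_equal(sim$truth$events$context, "TTC")
  expect_equal(as.character(sim$edited[[1]]), "TTAAAATATT")
})

test_that("3'-LTR extra exposure multiplies Bernoulli trials there", {
  t <- generateProvirus(totalLen = 4000, ltrLen = 600, seed = 19)
  cfg <- editConfig(baseRate = 0.02, passes = 1, ltr3ExtraExposure = 2,
                    seed = 19)
  sim <- simulateEditing(t, cfg)
  ev <- sim$truth$events
  ltr3 <- ltr3Range(t)
  inside <- ev$pos >= ltr3[1] & ev$pos <= ltr3[2]
  # passes beyond the first global pass only ever touch the 3' LTR
  expect_true(all(ev$pass[!inside] == 1))
  expect_true(any(ev$pass[inside] > 1))
  expect_true(all(ev$pass <= 3))
})

test_that("cascade reads contexts from the live sequence", {
  # plus GGG (minus CCC): with cascade off nothing is editable under
  # TTC/CTC-only weights; with cascade on and a minus5to3 scan, editing the
  # 3'-most G (enabled here by weight on its own context) converts the
  # tract step by step
  s <- "TTGGGAATT"
  # reference contexts: site 5 TTC (plus GAA), site 4 TCC, site 3 CCC;
  # weights cover TTC only, so only site 5 is a pre-existing target
  t <- tinyTemplate(s, c(1, 2), c(8, 9))
  wOn <- c(TTC = 1)
  off <- simulateEditing(t, editConfig(baseRate = 1, contextWeights = wOn,
                                       defaultWeight = 0, cascade = FALSE,
                                       scanDirection = "minus5to3",
                                       seed = 2))
  expect_equal(off$truth$events$pos, 5L)  # only the pre-existing target
  on <- simulateEditing(t, editConfig(baseRate = 1, contextWeights = wOn,
                                      defaultWeight = 0, cascade = TRUE,
                                      scanDirection = "minus5to3",
                                      seed = 2))
  # editing 5 turns site 4's live context into TTC, then site 3 follows
  expect_equal(sort(on$truth$events$pos), c(3L, 4L, 5L))
  expect_equal(on$truth$events$context[on$truth$events$pos == 4L], "TTC")
})

test_that("edit fractions follow the analytic site census", {
  t <- generateProvirus(seed = 23)
  cfg <- editConfig(baseRate = 0.15,
                    contextWeights = c(ATC = 5, CTC = 5, GTC = 5, TTC = 5),
                    defaultWeight = 0.2, seed = 23)
  census <- contextCensus(t, cfg)
  pr <- pmin(1, cfg$baseRate * census$weight)
  tAt1 <- substr(census$context, 2, 2) == "T"
  expected <- sum(pr[tAt1]) / sum(pr)
  sim <- simulateEditing(t, cfg)
  ev <- sim$truth$events
  got <- mean(substr(ev$context, 2, 2) == "T")
  n <- nrow(ev)
  expect_gt(n, 300)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(got - expected), 3 * se + 1e-12)
})

test_that("tuneEditRate hits its expected count", {
  t <- generateProvirus(seed = 27)
  cfg <- editConfig(seed = 27)
  r <- tuneEditRate(t, cfg, 500)
  census <- contextCensus(t, cfg)
  expect_equal(sum(pmin(1, r * census$weight)), 500, tolerance = 1e-6)
  # realized counts scatter around the target over a few seeds
  counts <- vapply(1:5, function(s) {
    cfg2 <- editConfig(baseRate = r, seed = 1000 + s)
    nrow(simulateEditing(t, cfg2)$truth$events)
  }, 0)
  expect_gt(mean(counts), 400)
  expect_lt(mean(counts), 600)
})

test_that("simulateLtrCopy duplicates the 3' LTR and is idempotent", {
  t <- generateProvirus(totalLen = 4000, ltrLen = 500, seed = 29)
  cfg <- editConfig(baseRate = 0.05, ltr3ExtraExposure = 2, seed = 29)
  sim <- simulateEditing(t, cfg)
  edited <- as.character(sim$edited[[1]])
  copy <- as.character(simulateLtrCopy(edited, ltr5Range(t),
                                       ltr3Range(t))[[1]])
  l5 <- ltr5Range(t); l3 <- ltr3Range(t)
  expect_equal(substr(copy, l5[1], l5[2]), substr(edited, l3[1], l3[2]))
  expect_equal(substr(copy, l5[2] + 1, nchar(copy)),
               substr(edited, l5[2] + 1, nchar(edited)))
  # idempotent on already-identical LTRs
  copy2 <- as.character(simulateLtrCopy(copy, l5, l3)[[1]])
  expect_identical(copy2, copy)
  # template method: unedited template already has identical LTRs
  expect_identical(as.character(simulateLtrCopy(t)[[1]]), templateSeq(t))
})
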