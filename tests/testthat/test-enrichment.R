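test_that("the independence expectation follows its closed form", {
  expect_equal(expectedOverlap(38909, 4641652, 109330), 916.4671,
               tolerance = 1e-6)
  expect_equal(expectedOverlap(0, 1e6, 5000), 0)
  # a genome-spanning target recovers the element length
  expect_equal(expectedOverlap(1234, 50000, 50000), 1234)
  expect_error(expectedOverlap(10, 0, 10), "positive")
  expect_warning(expectedOverlap(2e6, 1e6, 100), "multiplicity")
})

test_that("observed overlap distinguishes multiplicity from union", {
  target <- grIv(100, 200)
  inside <- grIv(120, 132)          # a 13-bp footprint inside the target
  expect_equal(observedOverlap(inside, target, "multiplicity"), 13)
  expect_equal(observedOverlap(grIv(500, 512), target), 0)
  twice <- c(inside, inside)
  expect_equal(observedOverlap(twice, target, "multiplicity"), 26)
  expect_equal(observedOverlap(twice, target, "union"), 13)
})

test_that("observed overlap matches the indicator-vector oracle", {
  for (seed in 1:6) {
    set.seed(seed + 60)
    G <- 5000L
    es <- sample(G - 60, 40)
    ee <- es + sample(10:50, 40, replace = TRUE)
    ts <- sample(G - 400, 8)
    te <- ts + sample(50:400, 8, replace = TRUE)
    el <- grIv(es, ee)
    tg <- grIv(ts, te)
    for (mult in c(TRUE, FALSE)) {
      conv <- if (mult) "multiplicity" else "union"
      expect_equal(observedOverlap(el, tg, conv),
                   indicatorOverlap(es, ee, ts, te, G, mult))
    }
  }
})

test_that("K reproduces the worked ratio and handles degenerate E", {
  e <- expectedOverlap(38909, 4641652, 109330)
  expect_equal(round(kRatio(1134, e), 2), 1.24)
  expect_equal(kRatio(10, 10), 1)
  expect_warning(expect_true(is.na(kRatio(5, 0))), "undefined")
})

test_that("fold enrichment is symmetric and exact on closed forms", {
  G <- 10000
  a <- grIv(c(1001, 5001), c(2000, 5500))    # 1500 bp: f = 0.15
  res <- foldEnrichment(a, a, G)
  expect_equal(res@k, 1 / 0.15)
  dis <- foldEnrichment(grIv(1, 100), grIv(201, 400), G)
  expect_equal(dis@k, 0)
  set.seed(71)
  bs <- sample(9000, 5)
  b <- grIv(bs, bs + 300)
  ab <- foldEnrichment(a, b, G)
  ba <- foldEnrichment(b, a, G)
  expect_equal(ab@observed, ba@observed)
  expect_equal(ab@k, ba@k)
  expect_equal(ab@observed,
               indicatorOverlap(GenomicRanges::start(a),
                                GenomicRanges::end(a),
                                GenomicRanges::start(b),
                                GenomicRanges::end(b), G,
                                multiplicity = FALSE))
})

test_that("K is invariant under joint coordinate shift", {
  G <- 8000
  set.seed(72)
  as <- sample(3000, 10)
  bs <- sample(3000, 6)
  a <- grIv(as, as + 150)
  b <- grIv(bs, bs + 400)
  k0 <- foldEnrichment(a, b, G)@k
  shiftBy <- 2500L
  k1 <- foldEnrichment(GenomicRanges::shift(a, shiftBy),
                       GenomicRanges::shift(b, shiftBy), G)@k
  expect_equal(k1, k0)
})

test_that("K distribution comparison detects shifts and degeneracy", {
  set.seed(73)
  kUr <- runif(9, 0.8, 1.2)
  same <- compareKDistributions(kUr, kUr)
  expect_gt(same$p.value, 0.9)
  shifted <- compareKDistributions(kUr + 10, kUr)
  expect_lt(shifted$p.value, 0.01)
  expect_warning(res <- compareKDistributions(rep(1, 5), rep(1, 5)),
                 "equal")
  expect_equal(res$p.value, 1)
  expect_error(compareKDistributions(1:2, 1:9), "at least 3")
  tt <- compareKDistributions(kUr + 10, kUr, method = "t")
  expect_match(tt$method, "t-test")
})

test_that("probe selection is inclusive at 2-fold and merges overlaps", {
  probes <- data.frame(start = c(100, 300, 330, 900),
                       ratio = c(2.0, 2.5, 3.1, 1.99))
  gr <- probesToIntervals(probes, minFold = 2, width = 60)
  expect_equal(GenomicRanges::start(gr), c(100, 300))
  expect_equal(GenomicRanges::width(gr), c(60, 90))  # 300+330 merged
  expect_length(probesToIntervals(data.frame(start = 1, ratio = 1.5)), 0)
})

test_that("point expansion is centred, merged, and degenerate at width 1", {
  gr <- pointsToIntervals(100, 36)
  expect_equal(GenomicRanges::start(gr), 82)
  expect_equal(GenomicRanges::width(gr), 36)
  two <- pointsToIntervals(c(100, 110), 36)
  expect_length(two, 1)
  expect_equal(GenomicRanges::width(two), 46)
  one <- pointsToIntervals(c(5, 50), 1)
  expect_equal(GenomicRanges::width(one), c(1, 1))
})

test_that("repeat enrichment combines catalog totals with the target", {
  set.seed(74)
  g <- randomGenome(6000)
  cat <- scanRepeats(g, "inverted", iRange = 5, jRange = 3:6,
                     circular = FALSE)
  target <- grIv(c(1001, 4001), c(1600, 4400))
  enr <- repeatEnrichment(cat, target)
  s <- summary(cat)
  expect_equal(enr$expected, (s$L / 6000) *
                 sum(GenomicRanges::width(target)))
  fp5 <- repeatFootprints(cat, i = 5, j = 3)
  expect_equal(enr$observed[enr$j == 3],
               observedOverlap(fp5, target, "multiplicity"))
})
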