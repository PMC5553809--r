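test_that("flat and rectangular tracks call the expected peaks", {
  p <- peakParams()
  # R == 1 everywhere: nothing to call
  expect_length(callPeaks(toyTrack(rep(1, 500)), p), 0)
  # R = 1.6 on exactly 60 positions: a single boundary-length peak
  r <- rep(1, 500); r[101:160] <- 1.6
  pk <- callPeaks(toyTrack(r), p)
  expect_equal(GenomicRanges::start(pk), 101)
  expect_equal(GenomicRanges::end(pk), 160)
  # one position short of 60
  r2 <- rep(1, 500); r2[101:159] <- 1.6
  expect_length(callPeaks(toyTrack(r2), p), 0)
})

test_that("the 50% fraction is inclusive", {
  # 60-bp stretch with exactly 30 above-threshold positions -> eligible
  r <- rep(0.5, 300)
  r[101:115] <- 1.6; r[146:160] <- 1.6          # 15 + 15 above
  r[116:145] <- 0.9                             # 30 below in between
  pk <- callPeaks(toyTrack(r), peakParams())
  expect_equal(GenomicRanges::start(pk), 101)
  expect_equal(GenomicRanges::end(pk), 160)
  # 29 of 60 -> rejected everywhere
  r2 <- rep(0.5, 300)
  r2[101:115] <- 1.6; r2[147:160] <- 1.6        # 15 + 14 above
  r2[116:146] <- 0.9
  expect_length(callPeaks(toyTrack(r2), peakParams()), 0)
})

test_that("every emitted peak passes the position-wise predicate", {
  p <- peakParams(minLen = 20L)
  for (seed in 1:8) {
    set.seed(seed)
    r <- exp(stats::filter(rnorm(2000, 0, 0.6), rep(1 / 5, 5),
                           circular = TRUE))
    rt <- toyTrack(as.numeric(r), circular = seed %% 2 == 0)
    pk <- callPeaks(rt, p)
    expect_true(verifyPeaks(pk, rt, p))
  }
})

test_that("raising the threshold never lengthens the called set", {
  for (seed in 1:5) {
    set.seed(seed)
    r <- exp(as.numeric(stats::filter(rnorm(1500, 0.2, 0.7),
                                      rep(1 / 7, 7), circular = TRUE)))
    lens <- vapply(c(1.2, 1.5, 1.8, 2.2), function(th) {
      pk <- callPeaks(toyTrack(r), peakParams(rMin = th, minLen = 20L))
      sum(GenomicRanges::width(pk))
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("peaks and unbound regions are disjoint", {
  set.seed(12)
  r <- exp(as.numeric(stats::filter(rnorm(1500, 0, 0.8), rep(1 / 5, 5),
                                    circular = TRUE)))
  rt <- toyTrack(r)
  p <- peakParams(minLen = 20L)
  pk <- callPeaks(rt, p)
  ur <- callUnbound(rt, rt, params = p)
  expect_length(GenomicRanges::intersect(
    GenomicRanges::reduce(pk), GenomicRanges::reduce(ur)), 0)
})

test_that("unbound regions require R < 1 in both tracks", {
  p <- peakParams()
  # both flat at 0.8 on a circular genome: one genome-spanning region
  rt <- toyTrack(rep(0.8, 400), circular = TRUE)
  ur <- callUnbound(rt, rt, params = p)
  expect_equal(sum(GenomicRanges::width(ur)), 400)
  # a single boundary R = 1.0 position splits; fragments < 60 bp are lost
  r1 <- rep(0.8, 400); r1[150] <- 1.0
  ur2 <- callUnbound(toyTrack(r1, circular = FALSE),
                     toyTrack(rep(0.8, 400), circular = FALSE),
                     params = p, merge = FALSE)
  expect_equal(GenomicRanges::start(ur2), c(1, 151))
  expect_equal(GenomicRanges::end(ur2), c(149, 400))
  # split fragments survive only if still >= 60 bp
  r3 <- rep(1.2, 400); r3[100:190] <- 0.9; r3[165] <- 1.0
  ur3 <- callUnbound(toyTrack(r3, circular = FALSE),
                     toyTrack(rep(0.8, 400), circular = FALSE),
                     params = p, merge = FALSE)
  expect_equal(GenomicRanges::start(ur3), 100)
  expect_equal(GenomicRanges::end(ur3), 164)
})

test_that("unbound calling matches the position-wise oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    r1 <- runif(1200, 0.5, 1.6)
    r2 <- runif(1200, 0.5, 1.6)
    ur <- callUnbound(toyTrack(r1, circular = FALSE),
                      toyTrack(r2, circular = FALSE),
                      params = peakParams(minLen = 10L), merge = FALSE)
    o <- bruteUnbound(r1, r2, 1.0, 10)
    expect_equal(GenomicRanges::start(ur), unname(o[, 1]))
    expect_equal(GenomicRanges::end(ur), unname(o[, 2]))
  }
})

test_that("exclusion sets remove whole overlapping unbound regions", {
  r <- rep(1.2, 500); r[101:200] <- 0.8; r[301:400] <- 0.8
  rt <- toyTrack(r, circular = FALSE)
  ur <- callUnbound(rt, rt, exclusions = grIv(200, 210),
                    params = peakParams())
  expect_equal(GenomicRanges::start(ur), 301)
})

test_that("the gap-merge rule follows its strict and inclusive bounds", {
  base <- rep(0.9, 400)
  s <- grIv(c(51, 140), c(110, 200))
  # 29-bp gap (111..139), intermediate max 1.05 -> merged
  r <- base; r[111:139] <- 1.05
  m <- mergeRegions(s, toyTrack(r), 30, 1.1)
  expect_equal(GenomicRanges::start(m), 51)
  expect_equal(GenomicRanges::end(m), 200)
  # gap of exactly 30 bp -> not merged
  s30 <- grIv(c(51, 141), c(110, 200))
  m30 <- mergeRegions(s30, toyTrack(base), 30, 1.1)
  expect_length(m30, 2)
  # one intermediate position at 1.2 -> not merged
  r2 <- base; r2[125] <- 1.2
  expect_length(mergeRegions(s, toyTrack(r2), 30, 1.1), 2)
  # intermediate exactly 1.1 -> merged (inclusive)
  r3 <- base; r3[111:139] <- 1.1
  expect_length(mergeRegions(s, toyTrack(r3), 30, 1.1), 1)
  # chains merge to a fixed point
  s3 <- grIv(c(51, 120, 180), c(110, 170, 230))
  expect_length(mergeRegions(s3, toyTrack(base), 30, 1.1), 1)
})

test_that("replicate combination removes unbound-overlapping peaks whole", {
  peaks2 <- grIv(c(100, 300, 500), c(180, 360, 590))
  # 1-bp overlap with an unbound region removes the whole peak
  unbound1 <- grIv(360, 420)
  cs <- combineExperiments(peaks2, unbound1)
  expect_equal(GenomicRanges::start(cs), c(100, 500))
  # empty unbound set: identity
  expect_length(combineExperiments(peaks2, GenomicRanges::GRanges()), 3)
  # peak-support mode keeps only peaks overlapping replicate-1 peaks
  ps <- combineExperiments(peaks2, mode = "peak-support",
                           peaks1 = grIv(550, 560))
  expect_equal(GenomicRanges::start(ps), 500)
})

test_that("peak extraction agrees with exhaustive interval enumeration", {
  p <- peakParams(minLen = 15L)
  for (seed in 1:10) {
    set.seed(100 + seed)
    n <- sample(300:900, 1)
    r <- exp(as.numeric(stats::filter(rnorm(n, 0, 0.8), rep(1 / 5, 5),
                                      circular = TRUE)))
    pk <- callPeaks(toyTrack(r, circular = FALSE), p)
    o <- brutePeaks(r, 1.5, 0.5, 15)
    expect_equal(GenomicRanges::start(pk), unname(o[, 1]))
    expect_equal(GenomicRanges::end(pk), unname(o[, 2]))
  }
})

test_that("circular peak calling is rotation invariant in total length", {
  set.seed(33)
  r <- exp(as.numeric(stats::filter(rnorm(1000, 0, 0.8), rep(1 / 5, 5),
                                    circular = TRUE)))
  p <- peakParams(minLen = 15L)
  tot <- sum(GenomicRanges::width(callPeaks(toyTrack(r, circular = TRUE),
                                            p)))
  for (shift in c(100, 450, 800)) {
    rs <- c(r[(shift + 1):1000], r[1:shift])
    tots <- sum(GenomicRanges::width(
      callPeaks(toyTrack(rs, circular = TRUE), p)))
    expect_equal(tots, tot)
  }
})
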