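test_that("constructed repeat pairs are found at their positions", {
  # AATTC (positions 9..13) = revcomp(GAATT): inverted i=5, j=3 at 1
  inv <- scanRepeats("GAATTCCCAATTC", "inverted", iRange = 5, jRange = 3,
                     circular = FALSE)
  expect_equal(repeatPairs(inv), data.frame(i = 5L, j = 3L, start = 1L))
  dir <- scanRepeats("ACGTGTTACGTG", "direct", iRange = 5, jRange = 2,
                     circular = FALSE)
  expect_equal(repeatPairs(dir), data.frame(i = 5L, j = 2L, start = 1L))
})

test_that("catalog totals obey the multiplicative identity", {
  inv <- scanRepeats("GAATTCCCAATTC", "inverted", iRange = 5, jRange = 3,
                     circular = FALSE)
  expect_equal(unname(catalogTotals(inv, 5, 3)), c(1, 13))
  expect_equal(unname(catalogTotals(inv, 7, 4)), c(0, 0))
  set.seed(21)
  g <- randomGenome(4000)
  cat <- scanRepeats(g, "inverted", iRange = 5:7, jRange = 3:8)
  s <- summary(cat)
  expect_equal(s$L, s$n * (2 * s$i + s$j))
})

test_that("scanning matches the quadruple-loop brute force", {
  for (seed in 1:4) {
    set.seed(seed + 40)
    G <- sample(300:900, 1)
    g <- randomGenome(G, gc = 0.5)
    for (type in c("direct", "inverted")) {
      got <- repeatPairs(scanRepeats(g, type, iRange = 5:8, jRange = 0:6,
                                     circular = FALSE))
      exp <- bruteRepeatScan(g, type, 5:8, 0:6, circular = FALSE)
      expect_equal(sortPairs(got), sortPairs(exp))
    }
  }
})

test_that("circular scanning honours origin-spanning pairs", {
  set.seed(50)
  g <- randomGenome(400)
  for (type in c("direct", "inverted")) {
    got <- repeatPairs(scanRepeats(g, type, iRange = 5:6, jRange = 0:4,
                                   circular = TRUE))
    exp <- bruteRepeatScan(g, type, 5:6, 0:4, circular = TRUE)
    expect_equal(sortPairs(got), sortPairs(exp))
  }
})

test_that("inverted scanning is strand symmetric", {
  set.seed(22)
  g <- randomGenome(2000)
  a <- summary(scanRepeats(g, "inverted", iRange = 5:6, jRange = 3:6,
                           circular = FALSE))
  b <- summary(scanRepeats(revcompStr(g), "inverted", iRange = 5:6,
                           jRange = 3:6, circular = FALSE))
  expect_equal(a$n, b$n)
})

test_that("homopolymer direct-repeat counts follow the closed form", {
  G <- 200L
  g <- strrep("A", G)
  cat <- scanRepeats(g, "direct", iRange = 5:7, jRange = 0:3,
                     circular = FALSE)
  s <- summary(cat)
  # every window position qualifies: n = G - (2i + j) + 1
  expect_equal(s$n, G - (2L * s$i + s$j) + 1L)
  # and a homopolymer has no inverted pairs at all (A vs comp(A) = T)
  expect_equal(nrow(repeatPairs(scanRepeats(g, "inverted", iRange = 5:6,
                                            jRange = 3:4,
                                            circular = FALSE))), 0L)
})

test_that("arm-maximal mode suppresses sub-pairs of a longer palindrome", {
  # ACGTAC TTT GTACGT: a clean (6,3) palindrome in a repeat-free poly-C
  # background (C flanks cannot extend it: comp(C) = G)
  g <- paste0(strrep("C", 300), "ACGTACTTTGTACGT", strrep("C", 300))
  all <- repeatPairs(scanRepeats(g, "inverted", iRange = 5:6,
                                 jRange = 3:5, circular = FALSE,
                                 maximality = "none"))
  mx <- repeatPairs(scanRepeats(g, "inverted", iRange = 5:6,
                                jRange = 3:5, circular = FALSE,
                                maximality = "arm-maximal"))
  # the (6,3) pair and its interior (5,3) sub-pair are both present raw
  expect_true(any(all$i == 6 & all$j == 3 & all$start == 301))
  expect_true(any(all$i == 5 & all$j == 3 & all$start == 302))
  # arm-maximal keeps the full pair, suppresses the sub-pair
  expect_true(any(mx$i == 6 & mx$j == 3 & mx$start == 301))
  expect_false(any(mx$i == 5 & mx$j == 3 & mx$start == 302))
})

test_that("footprints carry the holistic-unit span and wrap the origin", {
  g <- paste0("AATTC", randomGenome(300), "GAATT")  # wraps: GAATT..AATTC
  cat <- scanRepeats(g, "inverted", iRange = 5, jRange = 3,
                     circular = TRUE)
  fp <- repeatFootprints(cat)
  expect_true(all(GenomicRanges::width(fp) <= 13))
  # a wrapped footprint splits into two arcs totalling 2i + j
  p <- repeatPairs(cat)
  wrapped <- p$start + 12 > nchar(g)
  if (any(wrapped)) {
    tot <- sum(GenomicRanges::width(fp))
    expect_equal(tot, 13 * nrow(p))
  }
})

test_that("empty ranges are rejected", {
  expect_error(scanRepeats("ACGTACGT", "direct", iRange = integer(),
                           jRange = 0:2), "non-empty")
})
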