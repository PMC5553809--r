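test_that("index lookup finds genomic substrings on both strands", {
  set.seed(7)
  g <- randomGenome(800)
  idx <- buildIndex(g, 20, circular = FALSE)
  p <- 101L
  kmer <- substr(g, p, p + 19L)
  expect_true(p %in% lookupKmer(idx, kmer))
  # strand collapse: the reverse complement maps to the same left position
  expect_true(p %in% lookupKmer(idx, revcompStr(kmer)))
  # absent sequence -> empty
  expect_length(lookupKmer(idx, strrep("A", 20)), 0)
})

test_that("circular indexing includes origin-spanning k-mers", {
  g <- randomGenome(300)
  idx <- buildIndex(g, 30, circular = TRUE)
  wrap <- paste0(substr(g, 291, 300), substr(g, 1, 20))
  expect_true(291L %in% lookupKmer(idx, wrap))
  idxLin <- buildIndex(g, 30, circular = FALSE)
  expect_false(291L %in% lookupKmer(idxLin, wrap))
})

test_that("a single mismatch leaves a read unanchored", {
  set.seed(8)
  g <- randomGenome(500)
  read <- substr(g, 101, 150)
  bad <- read
  mid <- substr(bad, 25, 25)
  substr(bad, 25, 25) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  idx <- buildIndex(g, 50, circular = FALSE)
  prof <- anchorReads(makeLib(c(read, bad)), idx)
  expect_equal(unname(anchorStats(prof)["anchored"]), 1L)
  expect_equal(unname(anchorStats(prof)["unanchored"]), 1L)
  expect_equal(counts(prof)[101], 1)
})

test_that("multi-locus reads follow the counting policy", {
  set.seed(9)
  core <- randomGenome(60)
  # the same 50-mer is planted at two loci
  g <- paste0(randomGenome(150), core, randomGenome(200), core,
              randomGenome(120))
  read <- substr(core, 1, 50)
  idx <- buildIndex(g, 50, circular = FALSE)
  lib <- makeLib(read)
  all <- anchorReads(lib, idx, "all-occurrences")
  expect_equal(counts(all)[151], 1)
  expect_equal(counts(all)[151 + 60 + 200], 1)
  expect_equal(sum(counts(all)), 2)
  expect_equal(unname(anchorStats(all)["multi"]), 1L)
  uni <- anchorReads(lib, idx, "unique-only")
  expect_equal(sum(counts(uni)), 0)
  expect_equal(unname(anchorStats(uni)["multi"]), 1L)
  expect_equal(unname(anchorStats(uni)["anchored"]), 0L)
})

test_that("anchoring matches a brute-force sliding scan on toy genomes", {
  for (seed in 1:5) {
    set.seed(seed)
    G <- sample(400:2000, 1)
    L <- 25L
    g <- randomGenome(G, gc = 0.4)
    doubled <- paste0(g, g)
    idx <- buildIndex(g, L, circular = TRUE)
    reads <- c(
      vapply(sample(G, 15), function(p)
        substr(doubled, p, p + L - 1L), character(1)),
      vapply(sample(G, 10), function(p)
        revcompStr(substr(doubled, p, p + L - 1L)), character(1)),
      vapply(1:5, function(k) randomGenome(L), character(1))
    )
    prof <- anchorReads(makeLib(reads), idx)
    # oracle: slide read and revcomp along the doubled genome
    expCounts <- numeric(G)
    nAnch <- 0L
    for (rd in reads) {
      subs <- substring(doubled, 1:G, 1:G + L - 1L)
      hits <- which(subs == rd | subs == revcompStr(rd))
      if (length(hits)) nAnch <- nAnch + 1L
      expCounts[hits] <- expCounts[hits] + 1
    }
    expect_equal(counts(prof), expCounts)
    expect_equal(unname(anchorStats(prof)["anchored"]), nAnch)
  }
})

test_that("anchoring tallies partition the library", {
  set.seed(10)
  g <- randomGenome(1000)
  idx <- buildIndex(g, 30, circular = TRUE)
  doubled <- paste0(g, g)
  reads <- c(vapply(sample(1000, 30), function(p)
    substr(doubled, p, p + 29L), character(1)),
    vapply(1:10, function(k) randomGenome(30), character(1)))
  for (pol in c("all-occurrences", "unique-only")) {
    prof <- anchorReads(makeLib(reads), idx, pol)
    st <- anchorStats(prof)
    if (pol == "all-occurrences")
      expect_equal(unname(st["anchored"] + st["unanchored"]),
                   length(reads))
    else
      expect_equal(unname(st["anchored"] + st["unanchored"] + st["multi"]),
                   length(reads))
  }
})

test_that("the complete k-mer library covers a circular genome", {
  set.seed(11)
  g <- randomGenome(400)
  L <- 15L
  doubled <- paste0(g, g)
  every <- substring(doubled, 1:400, 1:400 + L - 1L)
  idx <- buildIndex(g, L, circular = TRUE)
  prof <- anchorReads(makeLib(every), idx)
  expect_true(all(counts(prof) >= 1))
})

test_that("a self-complementary read counts once", {
  pal <- "ACGCGT"  # its own reverse complement
  g <- paste0("TTTTTT", pal, "TTTTTT")
  idx <- buildIndex(g, 6, circular = FALSE)
  prof <- anchorReads(makeLib(pal), idx)
  expect_equal(counts(prof)[7], 1)
  expect_equal(sum(counts(prof)), 1)
})

test_that("length mismatches and bad genomes are rejected", {
  g <- randomGenome(200)
  idx <- buildIndex(g, 20, circular = FALSE)
  expect_error(anchorReads(makeLib("ACGT"), idx), "length")
  expect_error(buildIndex("ACGTN", 3), "A,C,G,T")
})
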