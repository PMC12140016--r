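# Window extraction, filtering/balancing, stratified splitting, the
# site-centered interpretation set, and subregion ground-truth labels.

test_that("window starts enumerate template offsets", {
  g <- manualGenome(c(c1 = randomDNA(1, 30, 1)))
  ws <- extractWindows(g, "whole_genome", window = 10, step = 5)
  expect_equal(length(ws), 5)
  expect_equal(windowInfo(ws)$start, c(0L, 5L, 10L, 15L, 20L))
  expect_equal(as.character(windowSeqs(ws))[2],
               substr(randomDNA(1, 30, 1), 6, 15))
})

test_that("a genome without sites yields no positive candidates", {
  g <- smallGenome(seed = 2, density = 0)
  ws <- extractWindows(g, "whole_genome", window = 200, step = 50)
  expect_true(all(windowLabels(ws) == 0L))
})

test_that("window labels follow site overlap exactly", {
  g <- manualGenome(c(c1 = randomDNA(1, 30, 3)),
                    sites = data.frame(contig = "c1", pos = 12L))
  ws <- extractWindows(g, "whole_genome", window = 10, step = 5)
  expect_equal(windowLabels(ws), c(0L, 1L, 1L, 0L, 0L))
  expect_equal(as.integer(siteOffsets(ws)[[2]]), 7L)  # 12 - 5
  expect_equal(as.integer(siteOffsets(ws)[[3]]), 2L)  # 12 - 10
})

test_that("coding-only template slides within intervals and needs annotation", {
  g <- manualGenome(c(c1 = randomDNA(1, 100, 4)),
                    coding = data.frame(contig = "c1", start = 20L, end = 55L))
  ws <- extractWindows(g, "coding_only", window = 20, step = 5)
  expect_equal(windowInfo(ws)$start, c(20L, 25L, 30L, 35L))
  gNo <- manualGenome(c(c1 = randomDNA(1, 100, 4)))
  expect_error(extractWindows(gNo, "coding_only", 20, 5), "annotation")
})

test_that("window extraction is shift-equivariant", {
  s <- randomDNA(1, 400, 5)
  g1 <- manualGenome(c(c1 = s), sites = data.frame(contig = "c1", pos = 150L))
  pad <- paste(rep("A", 30), collapse = "")
  g2 <- manualGenome(c(c1 = paste0(pad, s)),
                     sites = data.frame(contig = "c1", pos = 180L))
  w1 <- extractWindows(g1, "whole_genome", window = 100, step = 10)
  w2 <- extractWindows(g2, "whole_genome", window = 100, step = 10)
  # windows of g2 starting at 30 + k*10 match windows of g1 at k*10
  sel2 <- which(windowInfo(w2)$start >= 30 &
                windowInfo(w2)$start <= 30 + max(windowInfo(w1)$start))
  expect_equal(as.character(windowSeqs(w2))[sel2],
               as.character(windowSeqs(w1)))
  expect_equal(windowLabels(w2)[sel2], windowLabels(w1))
})

test_that("filterAndBalance drops N windows and balances classes", {
  seqs <- randomDNA(30, 50, 6)
  # windows come from one contig holding sites at known spots
  contig <- paste0(paste(seqs, collapse = ""), paste(rep("A", 100), collapse = ""))
  substr(contig, 101, 101) <- "N"   # corrupt the 3rd window (pos 100..149)
  g <- manualGenome(c(c1 = contig),
                    sites = data.frame(contig = "c1",
                                       pos = as.integer(seq(10, 700, by = 50))),
                    coding = data.frame(contig = "c1", start = 800L,
                                        end = 1600L))
  pos <- extractWindows(g, "whole_genome", window = 50, step = 50)
  neg <- extractWindows(g, "coding_only", window = 50, step = 50)
  nPosN <- sum(Biostrings::vcountPattern("N", windowSeqs(pos)) > 0 &
               windowLabels(pos) == 1)
  expect_gt(nPosN, 0)
  bal <- filterAndBalance(pos, neg, nPerClass = 5, seed = 1)
  expect_equal(length(bal), 10)
  expect_equal(sum(windowLabels(bal)), 5)
  expect_true(all(Biostrings::vcountPattern("N", windowSeqs(bal)) == 0))
  # determinism
  bal2 <- filterAndBalance(pos, neg, nPerClass = 5, seed = 1)
  expect_identical(windowInfo(bal)$start, windowInfo(bal2)$start)
  # shortage is handled by taking all, with a warning
  expect_warning(filterAndBalance(pos, neg, nPerClass = 1000, seed = 1),
                 "available")
})

test_that("splits are disjoint, exhaustive, ratio-sized and stratified", {
  g <- smallGenome(seed = 7, density = 0.01, len = 30000)
  pos <- extractWindows(g, "whole_genome", 200, 10)
  neg <- extractWindows(g, "coding_only", 200, 10)
  ws <- filterAndBalance(pos, neg, nPerClass = 250, seed = 2)
  sp <- splitDataset(ws, seed = 3)
  expect_equal(length(sp@train), 400)
  expect_equal(length(sp@validation), 50)
  expect_equal(length(sp@test), 50)
  key <- function(w) paste(windowInfo(w)$contig, windowInfo(w)$start,
                           windowLabels(w))
  ks <- c(key(sp@train), key(sp@validation), key(sp@test))
  expect_equal(sort(ks), sort(key(ws)))
  # class ratio preserved within one sample
  for (w in list(sp@train, sp@validation, sp@test))
    expect_lte(abs(sum(windowLabels(w)) - length(w) / 2), 1)
  expect_error(splitDataset(ws, ratios = c(0, 0, 0)), "positive sum")
  expect_error(splitDataset(ws[1:5]), "at least 10")
})

test_that("interpretation sequences are exact 201 nt slices around sites", {
  s <- randomDNA(1, 400, 8)
  g <- manualGenome(c(c1 = s),
                    sites = data.frame(contig = "c1", pos = c(150L, 50L)),
                    coding = data.frame(contig = "c1", start = 0L, end = 400L))
  ws <- suppressWarnings(
    buildInterpretationSet(g, nPos = 10, nNeg = 0, flank = 100, seed = 1))
  # the site at 50 is closer than flank to the edge and must be excluded
  expect_equal(sum(windowLabels(ws) == 1), 1)
  expect_equal(as.character(windowSeqs(ws))[1], substr(s, 51, 251))
  expect_equal(nchar(as.character(windowSeqs(ws))[1]), 201)
  expect_true(100L %in% as.integer(siteOffsets(ws)[[1]]))
})

test_that("interpretation negatives avoid sites; nPos = 0 gives none", {
  g <- smallGenome(seed = 9, density = 0.005, len = 30000)
  ws <- buildInterpretationSet(g, nPos = 0, nNeg = 50, flank = 100, seed = 2)
  expect_equal(sum(windowLabels(ws)), 0)
  expect_equal(length(ws), 50)
  # brute-force: no negative window intersects any site
  sitePos <- GenomicRanges::start(infidelitySites(g)) - 1L
  siteCt <- as.character(GenomicRanges::seqnames(infidelitySites(g)))
  inf <- windowInfo(ws)
  for (i in seq_len(length(ws))) {
    hit <- siteCt == inf$contig[i] & sitePos >= inf$start[i] &
      sitePos < inf$start[i] + 201L
    expect_false(any(hit))
  }
})

test_that("subregion labels follow span/site overlap and PAD validity", {
  # 3 tokens covering [0,21); site at nt 7 in the second token
  spans <- cbind(start = c(0L, 5L, 12L), end = c(5L, 12L, 21L))
  sl <- subregionLabels(spans, siteOffsets = 7L, m = 1L, nT = 6L)
  expect_equal(sl$V, c(1L, 1L, 1L, 0L, 0L))  # tokens, then SEP/PAD
  expect_equal(sl$y, c(0L, 1L, 0L, 0L, 0L))
  # one subregion covering nt [0,21) -> overlap
  sl2 <- subregionLabels(spans, 7L, m = 5L, nT = 6L)
  expect_equal(sl2$y, 1L)
  expect_equal(sl2$V, 1L)
  # label-0 sample: all subregion labels 0
  sl3 <- subregionLabels(spans, integer(0), m = 2L, nT = 6L)
  expect_true(all(sl3$y == 0L))
  expect_error(subregionLabels(cbind(c(0L, 6L), c(5L, 10L)), integer(0), 1, 6),
               "partition")
})

test_that("sequence label equals OR of valid subregion labels for all m", {
  g <- smallGenome(seed = 10, density = 0.01, len = 8000)
  pos <- extractWindows(g, "whole_genome", 200, 40)
  vocab <- tinyVocab()
  sel <- pos[seq_len(min(40, length(pos)))]
  tk <- encodeSequences(as.character(windowSeqs(sel)), vocab, nT = 120)
  for (m in c(1L, 7L, 20L, 119L)) {
    for (i in seq_len(length(sel))) {
      sl <- subregionLabels(tk@spans[[i]], as.integer(siteOffsets(sel)[[i]]),
                            m, nT = 120L)
      expect_equal(max(sl$y[sl$V == 1L]), windowLabels(sel)[i])
    }
  }
})
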