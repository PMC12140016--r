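# Attribution stack: closed-form perturbation oracle, JASPAR I/O, the PWM
# conversion/scan, window means, aggregation, smoothing, composition, and
# consensus calling.

makeStubSeq <- function(motifStart = 90, seed = 91) {
  # one CACCTG occurrence, none elsewhere
  repeat {
    s <- randomDNA(1, 201, seed)
    substr(s, motifStart, motifStart + 5) <- "CACCTG"
    if (length(gregexpr("CACCTG", s, fixed = TRUE)[[1]]) == 1) return(s)
    seed <- seed + 1
  }
}

test_that("hexamer importance matches the closed-form stub oracle", {
  s <- makeStubSeq(90)
  tr <- hexamerImportance(stubScorer(), s, C = 100, seed = 1)
  expect_equal(tr$valid, 1L)
  expect_length(tr$values, 196)
  delta <- logitClamped(0.9) - logitClamped(0.1)   # 2 ln 9 ~ 4.394
  expect_equal(delta, 4.394449, tolerance = 1e-6)
  overlap <- 85:90                            # hexamer windows j..j+5 hit 90:95
  expect_equal(unname(tr$values[overlap]), rep(delta, 6), tolerance = 1e-9)
  expect_true(all(tr$values[setdiff(1:196, 85:95)] == 0))
})

test_that("perturbation medians are robust to the perturbation count", {
  s <- makeStubSeq(90)
  t100 <- hexamerImportance(stubScorer(), s, C = 100, seed = 2)
  t1001 <- hexamerImportance(stubScorer(), s, C = 1001, seed = 3)
  expect_equal(t100$values, t1001$values, tolerance = 1e-12)
})

test_that("sequences predicted negative get an all-zero track", {
  s <- gsub("CACCTG", "CACCTA", randomDNA(1, 201, 95))  # stub predicts negative
  tr <- hexamerImportance(stubScorer(), s, C = 20, seed = 4)
  expect_equal(tr$valid, 0L)
  expect_true(all(tr$values == 0))
})

test_that("a constant scorer yields an exactly zero track", {
  tr <- hexamerImportance(function(x) rep(0.8, length(x)),
                          randomDNA(1, 201, 96), C = 20, seed = 5)
  expect_true(all(tr$values == 0))
  expect_error(hexamerImportance(stubScorer(), "ACGT", C = 10), "201 nt")
})

test_that("JASPAR dialects parse and motifs round-trip", {
  td <- withr::local_tempdir()
  f <- file.path(td, "pfm.txt")
  writeLines(c(">MA0004.1 Arnt",
               "A  [ 4 19  0  0 13 ]",
               "C  [16  0 20  0  0 ]",
               "G  [ 0  1  0 20  7 ]",
               "T  [ 0  0  0  0  0 ]",
               ">MA0006.1 Ahr::Arnt",
               "3 0 0 0",
               "8 0 23 0",
               "2 23 0 23",
               "11 1 1 1"), f)
  mot <- readJASPAR(f)
  expect_length(mot, 2)
  expect_equal(mot[[1]]@id, "MA0004.1")
  expect_equal(mot[[1]]@name, "Arnt")
  expect_equal(unname(motifPFM(mot[[1]])["C", 1]), 16)
  expect_equal(motifLength(mot[[2]]), 4)
  expect_equal(tfFamily(mot[[1]]), "unknown")
  # metadata attaches family/class
  meta <- data.frame(tf_id = "MA0004.1", family = "bHLH-ZIP", class = "bHLH")
  mot2 <- readJASPAR(f, meta)
  expect_equal(tfFamily(mot2[[1]]), "bHLH-ZIP")
  expect_equal(tfClass(mot2[[1]]), "bHLH")
  # round trip
  f2 <- file.path(td, "pfm2.txt")
  writeJASPAR(mot, f2)
  mot3 <- readJASPAR(f2)
  expect_equal(motifPFM(mot3[[1]]), motifPFM(mot[[1]]))
  expect_equal(motifPFM(mot3[[2]]), motifPFM(mot[[2]]))
  # empty file and malformed rows
  fe <- file.path(td, "empty.txt"); file.create(fe)
  expect_length(readJASPAR(fe), 0)
  fb <- file.path(td, "bad.txt")
  writeLines(c(">X x", "A [ 1 z ]", "C [ 1 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"), fb)
  expect_error(readJASPAR(fb), "malformed")
})

test_that("PFM -> PPM -> PWM follows the pseudocount formula", {
  pfm <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T"), NULL))
  conv <- pfmToPwm(pfm)
  expect_equal(unname(conv$ppm["A", 1]), 10.5 / 12)
  expect_equal(unname(conv$ppm["A", 1]), 0.875)
  expect_equal(unname(conv$pwm["A", 1]), log(3.5))
  expect_equal(round(unname(conv$pwm["A", 1]), 5), 1.25276)
  # uniform column: PPM 0.25 everywhere, PWM 0
  u <- pfmToPwm(matrix(7, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
  expect_true(all(abs(u$ppm - 0.25) < 1e-12))
  expect_true(all(abs(u$pwm) < 1e-12))
  withr::with_seed(97, {
    r <- pfmToPwm(matrix(rpois(40, 5), 4, 10,
                         dimnames = list(c("A","C","G","T"), NULL)))
    expect_equal(colSums(r$ppm), rep(1, 10))
  })
  expect_error(pfmToPwm(matrix(0, 4, 1, dimnames = list(c("A","C","G","T"),
                                                        NULL)), alpha = 0),
               "zero pseudocount")
})

test_that("PWM scanning matches the brute-force oracle and the cutoff algebra", {
  # a sharp 8-mer: consensus scores 8 ln 3.5 ~ 10.02 >= ln(999) -> hit
  m8 <- consensusMotifModel("M8", "CACGTGAC")
  s <- paste0(randomDNA(1, 50, 98), "CACGTGAC", randomDNA(1, 50, 99))
  hits <- scanMotif(m8, s)
  expect_equal(hits$start, 51)
  expect_equal(hits$score, 8 * log(3.5), tolerance = 1e-9)
  expect_true(all(hits$score >= log(999)))
  # uniform PWM: all scores 0, sigmoid 0.5, no hits
  mu <- new("MotifModel", id = "U", name = "U", family = "u", tfclass = "u",
            pfm = matrix(5, 4, 6, dimnames = list(c("A","C","G","T"), NULL)),
            ppm = matrix(0.25, 4, 6), pwm = matrix(0, 4, 6))
  all6 <- scanMotif(mu, s, keepAll = TRUE)
  expect_true(all(all6$score == 0) && all(all6$sigmoidScore == 0.5))
  expect_equal(nrow(scanMotif(mu, s)), 0)
  # oracle equivalence on random motif/sequence pairs
  withr::with_seed(100, {
    for (r in 1:100) {
      Ln <- sample(6:10, 1)
      pfm <- matrix(rpois(4 * Ln, 3), 4, Ln,
                    dimnames = list(c("A","C","G","T"), NULL))
      cv <- pfmToPwm(pfm)
      mo <- new("MotifModel", id = "R", name = "R", family = "f", tfclass = "c",
                pfm = pfm, ppm = cv$ppm, pwm = cv$pwm)
      sq <- randomDNA(1, 60, 1000 + r)
      a <- scanMotif(mo, sq, threshold = 0.6)
      b <- scanOracle(mo, sq, threshold = 0.6)
      expect_equal(a$start, b$start)
      expect_equal(a$score, b$score, tolerance = 1e-9)
    }
  })
  expect_error(scanMotif(m8, "ACGTNACGTT"), "outside ACGT")
})

test_that("TF importance is the mean over in-footprint hexamer windows", {
  vals <- numeric(196)
  vals[10:12] <- c(1, 2, 3)
  expect_equal(tfImportance(vals, 10, 8), 2.0)     # L_n=8 -> mean of 3 windows
  expect_equal(tfImportance(vals, 10, 6), vals[10])  # L_n=6 -> single term
  expect_warning(out <- tfImportance(vals, 10, 5), "skipped")
  expect_true(is.na(out))
  expect_error(tfImportance(vals, 196, 8), "outside")
})

test_that("family/class aggregation is the binding-weighted mean", {
  hits <- data.frame(seqIndex = c(1, 2, 1, 1), tfId = c("a", "a", "b", "c"),
                     family = c("F1", "F1", "F1", "F2"),
                     class = c("C1", "C1", "C1", "C2"),
                     start = c(5, 5, 9, 9), score = 8,
                     isTF = c(1, 3, 7, 2), valid = c(1, 1, 1, 1))
  agg <- aggregateImportance(hits, by = "family", nPositions = 20)
  f1 <- agg[agg$group == "F1", ]
  expect_equal(f1$value[5], 2.0)        # two hits, values 1 and 3
  expect_equal(f1$value[9], 7)
  expect_true(is.na(f1$value[3]))       # never bound -> missing, not zero
  expect_equal(unique(f1$nBindings), 3)
  # single TF, single hit: the aggregate equals that IS^TF
  f2 <- agg[agg$group == "F2", ]
  expect_equal(f2$value[9], 2)
  # invalid sequences are excluded
  hits$valid <- 0
  expect_error(aggregateImportance(hits), "no valid")
})

test_that("triangular smoothing: identity, constant, impulse kernel", {
  v <- rnorm(50)
  expect_identical(smoothTrack(v, 1), v)
  expect_equal(smoothTrack(rep(3, 30), 10), rep(3, 30))
  imp <- numeric(21); imp[11] <- 1
  sm <- smoothTrack(imp, 10)
  w <- 6 - abs(-5:5)
  expect_equal(sm[6:16], w / sum(w))    # interior: kernel / total weight
  expect_equal(sm[11], 6 / 36)
  expect_true(all(sm[c(1:5, 17:21)] == 0))
  # NA positions are excluded from numerator and weight sum
  v2 <- c(1, NA, 1, 1, 1)
  expect_equal(smoothTrack(v2, 2)[1], 1)
})

test_that("composition features match hand-counted proportions", {
  cf <- compositionFeatures("AATT", "AATT")
  mono <- cf$mono
  expect_equal(mono$propA[mono$kmer == "A"], 0.5)
  expect_equal(mono$propA[mono$kmer == "T"], 0.5)
  expect_equal(mono$propA[mono$kmer == "G"], 0)
  di <- cf$di
  expect_equal(di$propA[di$kmer %in% c("AA", "AT", "TT")], rep(1/3, 3))
  expect_true(all(cf$mono$rankChange == 0))
  expect_true(all(cf$di$rankChange == 0))
  expect_true(all(cf$tri$rankChange == 0))
  expect_error(compositionFeatures(character(0), "A"), "empty")
})

test_that("consensus calling honors the degeneracy threshold", {
  m1 <- consensusMotifModel("S", "CACCTG", counts = 100)
  expect_equal(motifConsensus(m1), "CACCTG")
  ppm <- matrix(c(0.97, 0.01, 0.01, 0.01,
                  0.45, 0.44, 0.05, 0.06), 4, 2,
                dimnames = list(c("A","C","G","T"), NULL))
  mo <- new("MotifModel", id = "D", name = "D", family = "f", tfclass = "c",
            pfm = ppm * 100, ppm = ppm, pwm = log(ppm / 0.25))
  expect_equal(motifConsensus(mo), "A[A/C]")
})
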