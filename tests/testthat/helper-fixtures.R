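# Shared fixtures. Heavy objects (the planted-motif benchmark genome, its
# vocabulary and datasets, trained models) are built lazily on first use and
# cached for the rest of the run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

randomDNA <- function(n, len, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)))
}

# small deterministic genome for unit tests
smallGenome <- function(seed = 5, density = 0.005, n = 2, len = 4000, ...) {
  simulateGenome(simConfig(nContigs = n, contigLength = len,
                           siteDensity = density, seed = seed, ...))
}

# hand-built genome from explicit parts (0-based half-open coords)
manualGenome <- function(seqs, sites = NULL, coding = NULL) {
  contigs <- Biostrings::DNAStringSet(seqs)
  siteGR <- if (is.null(sites) || nrow(sites) == 0)
    GenomicRanges::GRanges() else
    GenomicRanges::GRanges(sites$contig,
                           IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  codGR <- if (is.null(coding) || nrow(coding) == 0)
    GenomicRanges::GRanges() else
    GenomicRanges::GRanges(coding$contig,
                           IRanges::IRanges(start = coding$start + 1L,
                                            end = coding$end))
  new("SyntheticGenome", contigs = contigs, coding = codGR, sites = siteGR,
      simConfig = list())
}

tinyVocab <- function(vocabSize = 64, seed = 9) {
  cached(sprintf("vocab_%d_%d", vocabSize, seed),
         trainBPE(randomDNA(1, 20000, seed = seed), vocabSize = vocabSize))
}

## ---- planted-motif benchmark (shared by the acceptance tests) -------------

benchGenome <- function() cached("benchGenome",
  simulateGenome(plantedMotifBenchmark(seed = 101)))

benchVocab <- function() cached("benchVocab",
  trainBPE(as.character(contigSeqs(benchGenome())), vocabSize = 4096))

benchSplit <- function() cached("benchSplit", {
  g <- benchGenome()
  pos <- extractWindows(g, "whole_genome", window = 200, step = 10)
  neg <- extractWindows(g, "coding_only", window = 200, step = 10)
  ws <- filterAndBalance(pos, neg, nPerClass = 10000, seed = 7)
  splitDataset(ws, seed = 8)
})

benchModel <- function() cached("benchModel", {
  cfg <- modelConfig("tiny", nT = 60, m = 20, seed = 21)
  trainTTIRI(benchSplit(), benchVocab(), cfg,
             trainingRecipe(epochs = 2, batchSize = 32, patience = 2,
                            seed = 22))
})

# 201 nt site-centered set and the sequence-level-only interpretation model
benchInterpSet <- function() cached("benchInterpSet",
  buildInterpretationSet(benchGenome(), nPos = 10000, nNeg = 10000,
                         flank = 100, seed = 31))

benchInterpModel <- function() cached("benchInterpModel", {
  ws <- benchInterpSet()
  sp <- splitDataset(ws, seed = 32)
  cfg <- modelConfig("tiny", nT = 64, m = 20, seed = 33)
  trainTTIRI(sp, benchVocab(), cfg,
             trainingRecipe(epochs = 2, batchSize = 32, patience = 1,
                            seed = 34), level = "sequence")
})

## ---- independent scalar-loop oracles --------------------------------------

# Eq.-1 weighted token loss, written as plain nested loops
tokenLossOracle <- function(y, p, V) {
  y <- as.numeric(y); p <- as.numeric(p); V <- as.numeric(V)
  p <- pmin(1 - 1e-7, pmax(1e-7, p))
  npos <- 0; nneg <- 0
  for (i in seq_along(y)) {
    if (V[i] == 1 && y[i] == 1) npos <- npos + 1
    if (V[i] == 1 && y[i] == 0) nneg <- nneg + 1
  }
  w <- if (npos > 0) nneg / npos else nneg
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    if (V[i] != 1) next
    num <- num - (w * y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
    den <- den + 1
  }
  num / den
}

# quadratic-time pairwise AUROC
aurocOracle <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# average precision recomputed from scratch at each unique threshold
auprcOracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  nP <- sum(labels == 1)
  ap <- 0; prevR <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / nP
    ap <- ap + (rec - prevR) * prec
    prevR <- rec
  }
  ap
}

# brute-force PWM scan: score every substring independently
scanOracle <- function(motif, sequence, threshold = 0.999) {
  Ln <- motifLength(motif)
  pwm <- motifPWM(motif)
  out <- data.frame(start = integer(0), score = numeric(0))
  for (j in seq_len(nchar(sequence) - Ln + 1)) {
    sub <- strsplit(substr(sequence, j, j + Ln - 1), "")[[1]]
    sc <- 0
    for (k in seq_len(Ln)) sc <- sc + pwm[match(sub[k], c("A","C","G","T")), k]
    if (1 / (1 + exp(-sc)) >= threshold)
      out <- rbind(out, data.frame(start = j, score = sc))
  }
  out
}

# presence/absence stub scorer used for the closed-form attribution oracle
stubScorer <- function(motif = "CACCTG", pHit = 0.9, pMiss = 0.1) {
  function(seqs) ifelse(grepl(motif, seqs, fixed = TRUE), pHit, pMiss)
}
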