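# ALiBi biases, token merging, the three losses (against hand arithmetic and
# a scalar-loop oracle), forward-pass contracts, and analytic gradients
# against central finite differences.

test_that("ALiBi biases have zero diagonal, symmetry, geometric slopes", {
  B <- alibiBias(6, 12)
  expect_length(B, 12)
  for (i in c(1, 5, 12)) {
    expect_true(all(diag(B[[i]]) == 0))
    expect_identical(B[[i]], t(B[[i]]))
  }
  expect_equal(B[[1]][1, 2], -2^(-8 / 12))
  expect_equal(B[[1]][1, 2], -0.63, tolerance = 1e-3)
  expect_equal(B[[3]][2, 5], -3 * 2^(-24 / 12))
})

test_that("mergeTokens reproduces hand matrix arithmetic", {
  Mt <- rbind(c(1, 2), c(3, 4))
  Wc <- rbind(diag(2), matrix(0, 2, 2))  # picks out the mean block
  expect_equal(mergeTokens(Mt, 2, Wc), matrix(c(2, 3), 1))
  # m = 1: each output row is [token || token] %*% Wc
  WcR <- matrix(rnorm(4 * 2), 4, 2)
  out1 <- mergeTokens(Mt, 1, WcR)
  expect_equal(nrow(out1), 2)
  expect_equal(out1[1, ], as.numeric(c(1, 2, 1, 2) %*% WcR))
  # m = nrow: a single subregion
  expect_equal(nrow(mergeTokens(Mt, 2, WcR)), 1)
  # all-equal rows in a window: Mean = Max, so output = [r || r] %*% Wc
  Mt2 <- rbind(c(5, -1), c(5, -1), c(5, -1))
  expect_equal(mergeTokens(Mt2, 3, WcR),
               matrix(as.numeric(c(5, -1, 5, -1) %*% WcR), 1))
  expect_error(mergeTokens(Mt, 5, WcR), "out of range")
})

test_that("sequence loss matches hand computation and is order-invariant", {
  expect_lt(sequenceLoss(1, 1 - 1e-12), 1e-5)
  expect_equal(sequenceLoss(c(1, 0), c(0.9, 0.1)), -(log(0.9) + log(0.9)) / 2)
  expect_equal(round(sequenceLoss(c(1, 0), c(0.9, 0.1)), 5), 0.10536)
  y <- c(1, 1, 0, 0, 1); p <- c(0.8, 0.4, 0.3, 0.6, 0.9)
  o <- c(3, 1, 5, 2, 4)
  expect_equal(sequenceLoss(y, p), sequenceLoss(y[o], p[o]))
  expect_error(sequenceLoss(numeric(0), numeric(0)), "empty")
})

test_that("weighted token loss reproduces the hand-computed examples", {
  l1 <- tokenLoss(c(1, 0, 0), c(0.8, 0.2, 0.6), c(1, 1, 1))
  expect_equal(l1, -(2 * log(0.8) + log(0.8) + log(0.4)) / 3)
  expect_equal(round(l1, 5), 0.52857)
  # all-negative batch forces the 'otherwise' weight branch
  expect_equal(round(tokenLoss(0, 0.5, 1), 5), 0.69315)
  # equal valid class counts: w = 1, so the loss is plain masked BCE
  y <- c(1, 1, 0, 0, 1, 0); p <- runif(6, 0.1, 0.9); V <- rep(1, 6)
  expect_equal(tokenLoss(y, p, V), -mean(y * log(p) + (1 - y) * log(1 - p)))
  expect_error(tokenLoss(c(1, 0), c(0.5, 0.5), c(0, 0)), "no valid")
})

test_that("combined loss is the exact convex combination", {
  expect_equal(combinedLoss(1.0, 0.5, 0.2), 0.6)
  expect_equal(combinedLoss(2, 7, 0.999), 0.999 * 2 + 0.001 * 7)
  expect_gt(combinedLoss(1.1, 0.5, 0.3), combinedLoss(1.0, 0.5, 0.3))
  expect_gt(combinedLoss(1.0, 0.6, 0.3), combinedLoss(1.0, 0.5, 0.3))
  expect_error(combinedLoss(1, 1, 0), "lambda")
  expect_error(combinedLoss(1, 1, 1), "lambda")
})

test_that("token loss matches the scalar-loop oracle on random tensors", {
  withr::with_seed(44, {
    for (r in 1:100) {
      n <- sample(3:40, 1)
      y <- rbinom(n, 1, 0.3)
      p <- runif(n, 0.01, 0.99)
      V <- rbinom(n, 1, 0.8)
      if (sum(V) == 0) V[1] <- 1
      expect_equal(tokenLoss(y, p, V), tokenLossOracle(y, p, V),
                   tolerance = 1e-6)
    }
  })
})

test_that("forward pass obeys shape, determinism and PAD-masking contracts", {
  vocab <- tinyVocab(64)
  cfg <- modelConfig("custom", dH = 16, nLayers = 1, heads = 2, nT = 40,
                     m = 13, seed = 2)
  mdl <- initTTIRI(cfg, vocab)
  mdl@params$w_seq[] <- rnorm(16, sd = 0.5)
  mdl@params$w_sub[] <- rnorm(16, sd = 0.5)
  s <- randomDNA(3, 40, 51)
  pr <- predictTTIRI(mdl, s)
  expect_length(pr$pSeq, 3)
  expect_equal(dim(pr$pSub), c(3, ceiling(39 / 13)))
  expect_true(all(pr$pSeq > 0 & pr$pSeq < 1))
  # determinism
  pr2 <- predictTTIRI(mdl, s)
  expect_identical(pr$pSeq, pr2$pSeq)
  expect_identical(pr$pSub, pr2$pSub)
  # changing PAD ids never changes p_seq or valid-subregion p_sub
  tk <- encodeSequences(s, vocab, nT = 40)
  ids2 <- tk@ids
  for (i in 1:3) {
    padAt <- which(tk@mask[i, ] == 0)
    ids2[i, padAt] <- sample(4:60, length(padAt), replace = TRUE)
  }
  pr3 <- predictTTIRI(mdl, list(ids = ids2, mask = tk@mask))
  expect_equal(pr3$pSeq, pr$pSeq, tolerance = 1e-12)
  valid <- vapply(1:3, function(i)
    subregionLabels(tk@spans[[i]], integer(0), 13, 40)$V, integer(3))
  expect_equal(pr3$pSub[t(valid) == 1L], pr$pSub[t(valid) == 1L],
               tolerance = 1e-12)
})

test_that("without positional biases, identical tokens give identical outputs", {
  vocab <- tinyVocab(64)
  cfg <- modelConfig("custom", dH = 16, nLayers = 2, heads = 2, nT = 12,
                     m = 2, alibi = FALSE, seed = 3)
  mdl <- initTTIRI(cfg, vocab)
  mdl@params$w_sub[] <- rnorm(16, sd = 0.5)
  ids <- matrix(7L, 1, 12); mask <- matrix(1L, 1, 12)
  pr <- predictTTIRI(mdl, list(ids = ids, mask = mask))
  expect_lt(diff(range(pr$pSub)), 1e-12)
})

test_that("a random-init model scores balanced random labels at chance", {
  vocab <- tinyVocab(256)
  cfg <- modelConfig("custom", dH = 16, nLayers = 1, heads = 2, nT = 70,
                     m = 20, seed = 4)
  mdl <- initTTIRI(cfg, vocab)
  mdl@params$w_seq[] <- rnorm(16, sd = 0.5)
  s <- randomDNA(400, 120, 52)
  lab <- rep(c(0, 1), 200)
  auc <- aurocScore(lab, predictTTIRI(mdl, s)$pSeq)
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)
})

test_that("analytic gradients match central finite differences", {
  vocab <- tinyVocab(16)
  cfg <- modelConfig("custom", dH = 8, nLayers = 2, heads = 2, nT = 8,
                     m = 3, seed = 5, dropout = 0)
  p0 <- modelParams(initTTIRI(cfg, vocab))
  withr::with_seed(53, {
    for (nm in c("w_seq", "b_seq", "w_sub", "b_sub", "Wc", "bq_1", "bo_2"))
      p0[[nm]][] <- rnorm(length(p0[[nm]]), sd = 0.5)
    V <- 4 + length(vocabTokens(vocab))
    ids <- matrix(sample(0:(V - 1), 24, TRUE), 3, 8); ids[, 1] <- 2L
    mask <- matrix(1L, 3, 8); mask[1, 7:8] <- 0L
    y <- c(1, 0, 1)
    ysub <- matrix(rbinom(9, 1, 0.4), 3, 3)
    vsub <- matrix(1L, 3, 3); vsub[2, 3] <- 0L
    cl <- ttiri:::.cppCfg(cfg, V)
    res <- ttiri:::.cpp_loss_grads(ids, mask, y, ysub, vsub, p0, cl, 0.3)
    h <- 1e-5
    for (nm in names(p0)) {
      for (ii in sample(length(p0[[nm]]), min(3, length(p0[[nm]])))) {
        pp <- p0; pp[[nm]][ii] <- pp[[nm]][ii] + h
        pm <- p0; pm[[nm]][ii] <- pm[[nm]][ii] - h
        num <- (ttiri:::.cpp_loss_grads(ids, mask, y, ysub, vsub, pp, cl, 0.3,
                                        want_grads = FALSE)$loss -
                ttiri:::.cpp_loss_grads(ids, mask, y, ysub, vsub, pm, cl, 0.3,
                                        want_grads = FALSE)$loss) / (2 * h)
        ana <- res$grads[[nm]][ii]
        expect_equal(ana, num, tolerance = 1e-3,
                     label = sprintf("grad %s[%d]", nm, ii))
      }
    }
  })
})

test_that("the C++ training losses equal the exported R loss functions", {
  vocab <- tinyVocab(64)
  cfg <- modelConfig("custom", dH = 16, nLayers = 1, heads = 2, nT = 36,
                     m = 10, seed = 6)
  mdl <- initTTIRI(cfg, vocab)
  mdl@params$w_seq[] <- rnorm(16, sd = 0.3)
  mdl@params$w_sub[] <- rnorm(16, sd = 0.3)
  g <- smallGenome(seed = 12, density = 0.02, len = 3000)
  ws <- extractWindows(g, "whole_genome", 60, 40)
  inp <- buildModelInputs(ws[1:8], vocab, nT = 36, m = 10)
  cl <- ttiri:::.cppCfg(cfg, 4 + length(vocabTokens(vocab)))
  res <- ttiri:::.cpp_loss_grads(inp$ids, inp$mask, inp$ySeq, inp$ySub,
                                 inp$vSub, modelParams(mdl), cl, 0.2,
                                 want_grads = FALSE)
  pr <- predictTTIRI(mdl, inp)
  expect_equal(res$loss_seq, sequenceLoss(inp$ySeq, pr$pSeq), tolerance = 1e-12)
  expect_equal(res$loss_tok,
               tokenLoss(inp$ySub[inp$vSub == 1], pr$pSub[inp$vSub == 1],
                         rep(1, sum(inp$vSub))), tolerance = 1e-12)
  expect_equal(res$loss, combinedLoss(res$loss_seq, res$loss_tok, 0.2),
               tolerance = 1e-12)
})

test_that("lambda gates the two heads' gradients", {
  vocab <- tinyVocab(16)
  cfg <- modelConfig("custom", dH = 8, nLayers = 1, heads = 2, nT = 8,
                     m = 3, seed = 7)
  p0 <- modelParams(initTTIRI(cfg, vocab))
  withr::with_seed(54, {
    for (nm in c("w_seq", "w_sub", "Wc"))
      p0[[nm]][] <- rnorm(length(p0[[nm]]), sd = 0.5)
    ids <- matrix(sample(4:19, 24, TRUE), 3, 8); ids[, 1] <- 2L
    mask <- matrix(1L, 3, 8)
    ysub <- matrix(rbinom(9, 1, 0.5), 3, 3)
    vsub <- matrix(1L, 3, 3)
    cl <- ttiri:::.cppCfg(cfg, 4 + length(vocabTokens(vocab)))
    # lambda = 1 (sequence-only override): subregion-head gradients exactly 0
    g1 <- ttiri:::.cpp_loss_grads(ids, mask, c(1, 0, 1), ysub, vsub, p0, cl, 1)
    expect_true(all(g1$grads$Wc == 0))
    expect_true(all(g1$grads$w_sub == 0))
    expect_true(all(g1$grads$b_sub == 0))
    expect_gt(max(abs(g1$grads$w_seq)), 0)
    # lambda -> 0+: sequence-head gradients vanish proportionally
    g0 <- ttiri:::.cpp_loss_grads(ids, mask, c(1, 0, 1), ysub, vsub, p0, cl, 1e-6)
    expect_lt(max(abs(g0$grads$w_seq)), 1e-4)
    expect_gt(max(abs(g0$grads$w_sub)), 1e-4)
  })
})
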