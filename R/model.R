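## Model configuration, parameter initialization, and reference R
## implementations of the pieces with closed contracts: ALiBi biases, the
## mean/max token-merging projection, and the three losses. The training-time
## forward/backward lives in src/transformer.cpp; the R losses double as the
## documented definition that the C++ path is tested against.

#' Architecture configuration
#'
#' The "paper" preset is the full-scale architecture (768 hidden units, 12
#' encoder blocks, 12 heads); the "tiny" preset (64/2/4) trains from scratch
#' in minutes on a CPU and is used throughout the examples and tests.
#'
#' @param preset "tiny", "paper", or "custom" (then supply dH/nLayers/heads).
#' @param dH hidden size; must be divisible by \code{heads}.
#' @param nLayers number of encoder blocks.
#' @param heads attention heads (per-head dim is \code{dH/heads}).
#' @param nT total tokens per sequence (CLS + effective + SEP + PAD).
#' @param m pooling window: tokens merged per subregion.
#' @param lambda loss mix in (0,1); the combined loss is
#'   \code{lambda * l_sequence + (1 - lambda) * l_token}.
#' @param dropout dropout rate applied to sublayer outputs during training.
#' @param alibi logical; use ALiBi positional biases (disable only for
#'   diagnostics).
#' @param seed seed for parameter initialization.
#' @return a configuration list of class \code{ModelConfig}.
#' @export
modelConfig <- function(preset = c("tiny", "paper", "custom"), dH = NULL,
                        nLayers = NULL, heads = NULL, nT = 60L, m = 20L,
                        lambda = 0.2, dropout = 0.1, alibi = TRUE,
                        seed = 1L) {
  preset <- match.arg(preset)
  dims <- switch(preset,
    tiny = list(d = 64L, l = 2L, h = 4L),
    paper = list(d = 768L, l = 12L, h = 12L),
    custom = list(d = as.integer(dH), l = as.integer(nLayers),
                  h = as.integer(heads)))
  if (preset != "custom" && (!is.null(dH) || !is.null(nLayers) || !is.null(heads)))
    dims <- list(d = as.integer(dH %||% dims$d),
                 l = as.integer(nLayers %||% dims$l),
                 h = as.integer(heads %||% dims$h))
  if (any(vapply(dims, function(z) length(z) != 1L || is.na(z), logical(1))))
    stop("custom preset requires dH, nLayers and heads")
  if (dims$d %% dims$h != 0) stop("dH must be divisible by heads")
  nT <- as.integer(nT); m <- as.integer(m)
  if (m < 1L || m > nT - 1L) stop("m must be in 1..nT-1")
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 1)
    stop("lambda must be in (0, 1)")
  .checkFraction(dropout, "dropout")
  structure(list(d = dims$d, n_layers = dims$l, h = dims$h, d_k = dims$d %/% dims$h,
                 n_t = nT, m = m, lambda = lambda, dropout = dropout,
                 alibi = isTRUE(alibi), ln_eps = 1e-5,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# configuration list handed to the C++ kernels
.cppCfg <- function(config, vocabTotal) {
  list(d = config$d, n_layers = config$n_layers, h = config$h,
       n_t = config$n_t, m = config$m, vocab_total = as.integer(vocabTotal),
       alibi = config$alibi, ln_eps = config$ln_eps)
}

.nSub <- function(config) ceiling((config$n_t - 1L) / config$m)

#' Initialize an untrained model
#'
#' Creates the parameter tensors (truncated-normal-free: plain N(0, 0.02)
#' matrices, zero biases, unit layer-norm gains) in the positional layout the
#' C++ kernels expect.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param vocab the \code{BPEVocabulary} the model will consume.
#' @return an untrained \code{\linkS4class{TTIRIModel}}.
#' @export
initTTIRI <- function(config, vocab) {
  if (!inherits(config, "ModelConfig")) stop("'config' must come from modelConfig()")
  d <- config$d
  V <- N_SPECIAL + length(vocab@tokens)
  mkW <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  zeros <- function(nr) matrix(0, nr, 1)
  ones <- function(nr) matrix(1, nr, 1)
  params <- withr::with_seed(config$seed, {
    p <- list(Emb = mkW(V, d))
    for (l in seq_len(config$n_layers)) {
      lp <- list(Wq = mkW(d, d), bq = zeros(d), Wk = mkW(d, d), bk = zeros(d),
                 Wv = mkW(d, d), bv = zeros(d), Wo = mkW(d, d), bo = zeros(d),
                 g1 = ones(d), be1 = zeros(d),
                 W1 = mkW(d, 4 * d), b1 = zeros(4 * d),
                 W2 = mkW(4 * d, d), b2 = zeros(d),
                 g2 = ones(d), be2 = zeros(d))
      names(lp) <- paste0(names(lp), "_", l)
      p <- c(p, lp)
    }
    c(p, list(Wc = mkW(2 * d, d), w_seq = zeros(d), b_seq = zeros(1),
              w_sub = zeros(d), b_sub = zeros(1)))
  })
  new("TTIRIModel", params = params, config = unclass(config), vocab = vocab,
      history = data.frame(), recipe = list())
}

#' ALiBi linear attention biases
#'
#' Position is injected through the attention scores: head i receives the
#' bias \eqn{B_i[q,k] = -2^{-8i/h} |q-k|}, a symmetric (non-causal)
#' distance penalty with geometrically decreasing slopes. The diagonal is 0
#' and the matrices depend only on position offsets, never on content.
#'
#' @param nT number of token positions.
#' @param h number of attention heads.
#' @return list of \code{h} \code{nT x nT} bias matrices.
#' @examples
#' B <- alibiBias(4, 12)
#' B[[1]][1, 2]  # -2^(-8/12)
#' @export
alibiBias <- function(nT, h) {
  if (nT < 1 || h < 1) stop("nT and h must be positive")
  D <- abs(outer(seq_len(nT), seq_len(nT), `-`))
  lapply(seq_len(h), function(i) -2^(-8 * i / h) * D)
}

#' Merge adjacent token representations into subregions
#'
#' Non-overlapping mean- and max-pooling over windows of \code{m} rows of the
#' non-CLS hidden states, concatenated and projected back to the hidden size:
#' \deqn{M^m = Concat(Mean(M^t, m), Max(M^t, m)) W^C.}
#' The final window may be partial. When \code{mask} is supplied, PAD rows
#' are excluded from both poolings (a window with no unmasked rows yields a
#' zero row); this keeps subregion scores independent of PAD content.
#'
#' @param Mt (nT-1) x d matrix of non-CLS token states.
#' @param m pooling window size.
#' @param Wc 2d x d projection matrix.
#' @param mask optional logical/0-1 vector of length \code{nrow(Mt)}; TRUE
#'   rows participate in pooling.
#' @return \code{ceiling(nrow(Mt)/m) x d} matrix of subregion states.
#' @export
mergeTokens <- function(Mt, m, Wc, mask = NULL) {
  m <- as.integer(m)
  if (m < 1L || m > nrow(Mt)) stop("m out of range")
  if (ncol(Wc) * 2L != nrow(Wc)) stop("Wc must be 2d x d")
  if (is.null(mask)) mask <- rep(TRUE, nrow(Mt))
  nSub <- ceiling(nrow(Mt) / m)
  out <- matrix(0, nSub, ncol(Mt))
  for (t in seq_len(nSub)) {
    rows <- (((t - 1L) * m + 1L):min(t * m, nrow(Mt)))
    rows <- rows[as.logical(mask[rows])]
    if (length(rows) == 0) next
    blk <- Mt[rows, , drop = FALSE]
    out[t, ] <- c(colMeans(blk), apply(blk, 2, max)) %*% Wc
  }
  out
}

#' Sequence-level binary cross-entropy loss
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities (clamped to [1e-7, 1-1e-7]).
#' @return mean binary cross-entropy, natural log.
#' @export
sequenceLoss <- function(y, p) {
  if (length(y) == 0) stop("empty batch")
  if (length(y) != length(p)) stop("y and p lengths differ")
  p <- .clampProb(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Class-weighted subregion (token) loss
#'
#' The subregion labels are heavily imbalanced, so valid positive subregions
#' are up-weighted by the batch ratio of valid negatives to valid positives
#' (or, when the batch holds no valid positive, by the count of valid
#' negatives):
#' \deqn{\ell_{token} = \frac{-\sum_i \sum_t V_{i,t}\,(w\, y_{i,t} \log p_{i,t}
#'   + (1-y_{i,t}) \log(1-p_{i,t}))}{\sum_i \sum_t V_{i,t}}.}
#' Invalid subregions (all merged tokens PAD) contribute nothing.
#'
#' @param y 0/1 subregion labels (vector or matrix).
#' @param p predicted subregion probabilities, same shape.
#' @param V 0/1 validity indicators, same shape.
#' @return the weighted loss (scalar).
#' @export
tokenLoss <- function(y, p, V) {
  if (length(y) != length(p) || length(y) != length(V))
    stop("y, p and V must have the same shape")
  V <- as.numeric(V)
  if (sum(V) == 0) stop("no valid subregions")
  y <- as.numeric(y); p <- .clampProb(as.numeric(p))
  nPos <- sum(V * (y == 1)); nNeg <- sum(V * (y == 0))
  w <- if (nPos > 0) nNeg / nPos else nNeg
  -sum(V * (w * y * log(p) + (1 - y) * log(1 - p))) / sum(V)
}

#' Combined two-layer training objective
#'
#' @param lSeq sequence-level loss.
#' @param lTok subregion-level loss.
#' @param lambda mix in (0,1); 0.2 by default, weighting the subregion term
#'   4:1.
#' @return \code{lambda * lSeq + (1 - lambda) * lTok}.
#' @export
combinedLoss <- function(lSeq, lTok, lambda = 0.2) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("lambda must be in (0, 1)")
  lambda * lSeq + (1 - lambda) * lTok
}

#' Score sequences with a model
#'
#' Runs the full forward pass and returns the sequence-level probability and
#' the per-subregion probabilities for each input.
#'
#' @param model a trained (or initialized) \code{TTIRIModel}.
#' @param x character vector, \code{DNAStringSet}, \code{TokenizedSequences},
#'   or an input list from \code{\link{buildModelInputs}}.
#' @return list with \code{pSeq} (numeric vector) and \code{pSub} (matrix,
#'   one column per subregion).
#' @export
predictTTIRI <- function(model, x) {
  if (length(model@params) == 0) stop("model has uninitialized parameters")
  cfg <- model@config
  if (is.list(x) && !is.null(x$ids)) {
    ids <- x$ids; mask <- x$mask
  } else if (is(x, "TokenizedSequences")) {
    ids <- x@ids; mask <- x@mask
  } else {
    tk <- encodeSequences(.asCharacter(x), model@vocab, nT = cfg$n_t)
    ids <- tk@ids; mask <- tk@mask
  }
  V <- N_SPECIAL + length(model@vocab@tokens)
  res <- .cpp_predict(ids, mask, model@params, .cppCfg(cfg, V))
  list(pSeq = as.numeric(res$p_seq), pSub = res$p_sub)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding parameters, configuration, vocabulary and
#' history.
#'
#' @param model a \code{TTIRIModel}.
#' @param path file path.
#' @return \code{loadModel} returns the \code{TTIRIModel}.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
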