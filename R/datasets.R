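## Dataset construction: sliding-window extraction, N-filtering and class
## balancing, stratified splitting, the 201 nt site-centered interpretation
## set, and subregion ground-truth labels derived from token spans.

.emptyWindowSet <- function(width = 0L) {
  new("WindowSet",
      info = DataFrame(contig = character(0), start = integer(0),
                       label = integer(0)),
      seqs = Biostrings::DNAStringSet(),
      siteOffsets = IRanges::IntegerList())
}

# windows: data.frame(contig, start0) -> WindowSet with labels/offsets
.makeWindowSet <- function(g, contig, start0, window) {
  if (length(contig) == 0) return(.emptyWindowSet(window))
  winGR <- GRanges(contig, IRanges(start = start0 + 1L, width = window))
  hits <- findOverlaps(winGR, g@sites)
  off <- integer(0)
  offFac <- factor(integer(0), levels = seq_along(winGR))
  if (length(hits)) {
    off <- start(g@sites)[S4Vectors::subjectHits(hits)] -
      start(winGR)[S4Vectors::queryHits(hits)]   # 0-based within-window
    offFac <- factor(S4Vectors::queryHits(hits), levels = seq_along(winGR))
  }
  siteOffsets <- IRanges::IntegerList(split(off, offFac))
  label <- as.integer(S4Vectors::elementNROWS(siteOffsets) > 0L)

  # extract sequences contig by contig via Views
  seqs <- vector("list", length(winGR))
  for (ct in unique(contig)) {
    sel <- which(contig == ct)
    v <- IRanges::Views(g@contigs[[ct]],
                        start = start0[sel] + 1L, width = window)
    seqs[sel] <- as.list(as.character(v))
  }
  new("WindowSet",
      info = DataFrame(contig = contig, start = as.integer(start0),
                       label = label),
      seqs = Biostrings::DNAStringSet(unlist(seqs)),
      siteOffsets = siteOffsets)
}

#' Extract sliding windows from a genome
#'
#' Slides a fixed window across either the whole genome (the positive-sample
#' template) or across each coding interval (the negative-sample template),
#' labeling each window by whether it contains at least one infidelity site.
#' Windows start at offsets 0, step, 2*step, ... of their template.
#'
#' Positive training samples are conventionally drawn from the whole-genome
#' template (coding regions are often shorter than the window, and sites
#' inside them must not be lost), while negative samples come from the
#' coding-only template; \code{\link{filterAndBalance}} applies that
#' asymmetry.
#'
#' @param g a \code{SyntheticGenome}.
#' @param template "whole_genome" or "coding_only".
#' @param window window width in nt (default 200).
#' @param step step size in nt (default 10).
#' @return a \code{\linkS4class{WindowSet}} of all candidate windows (both
#'   labels).
#' @examples
#' g <- simulateGenome(simConfig(nContigs = 1, contigLength = 2000, seed = 1))
#' extractWindows(g, "whole_genome", window = 200, step = 100)
#' @export
extractWindows <- function(g, template = c("whole_genome", "coding_only"),
                           window = 200L, step = 10L) {
  template <- match.arg(template)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be positive")
  contig <- character(0); start0 <- integer(0)
  if (template == "whole_genome") {
    for (ct in names(g@contigs)) {
      len <- length(g@contigs[[ct]])
      if (len < window) next
      st <- seq.int(0L, len - window, by = step)
      contig <- c(contig, rep(ct, length(st))); start0 <- c(start0, st)
    }
  } else {
    if (length(g@coding) == 0)
      stop("coding_only template requires a coding annotation")
    for (k in seq_along(g@coding)) {
      ct <- as.character(seqnames(g@coding))[k]
      s0 <- start(g@coding)[k] - 1L
      ilen <- width(g@coding)[k]
      if (ilen < window) next
      st <- s0 + seq.int(0L, ilen - window, by = step)
      contig <- c(contig, rep(ct, length(st))); start0 <- c(start0, st)
    }
  }
  .makeWindowSet(g, contig, start0, window)
}

.dropN <- function(ws) {
  keep <- Biostrings::vcountPattern("N", ws@seqs) == 0L
  ws[keep]
}

.concatWindowSets <- function(a, b) {
  new("WindowSet", info = rbind(a@info, b@info), seqs = c(a@seqs, b@seqs),
      siteOffsets = c(a@siteOffsets, b@siteOffsets))
}

#' Filter and balance positive/negative candidate windows
#'
#' Removes every window containing an undetermined base ('N'), restricts the
#' positive pool to label-1 windows and the negative pool to label-0 windows,
#' then samples the same number from each class uniformly without
#' replacement.
#'
#' @param pos candidate positives (whole-genome template windows).
#' @param neg candidate negatives (coding-only template windows).
#' @param nPerClass target per class (default 10000); if a class has fewer
#'   usable windows, all are taken with a warning.
#' @param seed integer seed for the sampling.
#' @return a balanced \code{WindowSet} (positives first).
#' @export
filterAndBalance <- function(pos, neg, nPerClass = 10000L, seed = 1L) {
  pos <- .dropN(pos[windowLabels(pos) == 1L])
  neg <- .dropN(neg[windowLabels(neg) == 0L])
  if (length(pos) == 0) stop("no usable positive windows")
  if (length(neg) == 0) stop("no usable negative windows")
  n <- min(nPerClass, length(pos), length(neg))
  if (n < nPerClass)
    warning(sprintf("only %d windows available per class (requested %d)",
                    n, nPerClass))
  withr::with_seed(as.integer(seed), {
    pi <- sample.int(length(pos), n)
    ni <- sample.int(length(neg), n)
  })
  .concatWindowSets(pos[pi], neg[ni])
}

#' Stratified train/validation/test split
#'
#' Shuffles each label class independently and allocates ratio-proportional
#' counts (rounded; the test set absorbs the remainder), so the class balance
#' of every split matches the global balance within one sample.
#'
#' @param ws a \code{WindowSet}.
#' @param ratios numeric(3) split ratios, default \code{c(8, 1, 1)}.
#' @param seed integer seed.
#' @return a \code{\linkS4class{DatasetSplit}}.
#' @export
splitDataset <- function(ws, ratios = c(8, 1, 1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be three non-negative numbers with a positive sum")
  if (length(ws) < 10L) stop("need at least 10 samples to split")
  rs <- ratios / sum(ratios)
  idxTr <- idxVa <- idxTe <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (lb in unique(windowLabels(ws))) {
      idx <- which(windowLabels(ws) == lb)
      idx <- idx[sample.int(length(idx))]
      nTr <- round(length(idx) * rs[1])
      nVa <- round(length(idx) * rs[2])
      nTe <- length(idx) - nTr - nVa
      if (nTe < 0) { nVa <- nVa + nTe; nTe <- 0 }
      idxTr <- c(idxTr, idx[seq_len(nTr)])
      idxVa <- c(idxVa, idx[nTr + seq_len(nVa)])
      idxTe <- c(idxTe, idx[nTr + nVa + seq_len(nTe)])
    }
  })
  new("DatasetSplit", train = ws[idxTr], validation = ws[idxVa],
      test = ws[idxTe], ratios = as.numeric(ratios), seed = as.integer(seed))
}

#' Build the 201 nt site-centered interpretation set
#'
#' Positives are the 100 nt of flanking sequence on each side of a sampled
#' infidelity site (201 nt total, site at 0-based offset 100); sites closer
#' than \code{flank} to a contig edge are excluded so every sequence is fully
#' real. Negatives are site-free coding-template windows of the same width,
#' built with the same sliding method as the training dataset.
#'
#' @param g a \code{SyntheticGenome}.
#' @param nPos,nNeg target counts (all available taken, with a warning, if
#'   fewer).
#' @param flank flank width in nt (default 100).
#' @param seed integer seed.
#' @return a \code{WindowSet} of width \code{2*flank + 1} (positives first).
#' @export
buildInterpretationSet <- function(g, nPos = 10000L, nNeg = 10000L,
                                   flank = 100L, seed = 1L) {
  width <- 2L * flank + 1L
  len <- setNames(Biostrings::width(g@contigs), names(g@contigs))
  ct <- as.character(seqnames(g@sites))
  pos0 <- start(g@sites) - 1L
  keep <- pos0 >= flank & pos0 <= len[ct] - flank - 1L
  posWS <- .dropN(.makeWindowSet(g, ct[keep], pos0[keep] - flank, width))
  if (nPos > 0 && length(posWS) == 0) stop("no usable centered positives")

  negAll <- extractWindows(g, "coding_only", window = width, step = 10L)
  negWS <- .dropN(negAll[windowLabels(negAll) == 0L])
  if (nNeg > 0 && length(negWS) == 0) stop("no usable centered negatives")

  nP <- min(nPos, length(posWS)); nN <- min(nNeg, length(negWS))
  if (nP < nPos || nN < nNeg)
    warning(sprintf("interpretation set reduced to %d positives / %d negatives",
                    nP, nN))
  withr::with_seed(as.integer(seed), {
    pi <- if (nP > 0) sample.int(length(posWS), nP) else integer(0)
    ni <- if (nN > 0) sample.int(length(negWS), nN) else integer(0)
  })
  .concatWindowSets(posWS[pi], negWS[ni])
}

#' Subregion ground-truth labels and validity
#'
#' Maps token character spans to subregions of \code{m} merged tokens and
#' derives, for each subregion, the true label (does the union of its real
#' tokens' spans overlap an infidelity site?) and the validity flag (does it
#' contain at least one real sequence token, as opposed to SEP/PAD only?).
#' The token stream mirrors the model layout: CLS, the real tokens, SEP,
#' PAD...; subregion t merges stream positions (t-1)m+1 .. tm (CLS excluded).
#'
#' @param spans k x 2 integer matrix of 0-based half-open character spans of
#'   the real tokens; must partition [0, width).
#' @param siteOffsets integer vector of 0-based site offsets in the window.
#' @param m pooling window size in tokens.
#' @param nT total token count (model input length).
#' @return list with integer vectors \code{y} and \code{V} of length
#'   \code{ceiling((nT - 1) / m)}.
#' @export
subregionLabels <- function(spans, siteOffsets, m, nT = 60L) {
  m <- as.integer(m); nT <- as.integer(nT)
  if (m < 1L) stop("m must be >= 1")
  k <- nrow(spans)
  if (k > 0) {
    if (spans[1, 1] != 0L || (k > 1 && any(spans[-1, 1] != spans[-k, 2])))
      stop("token spans must partition the sequence")
  }
  nSub <- ceiling((nT - 1L) / m)
  y <- integer(nSub); V <- integer(nSub)
  for (t in seq_len(nSub)) {
    qs <- ((t - 1L) * m + 1L):min(t * m, nT - 1L)  # stream positions
    real <- qs[qs <= k]                             # real-token indices
    if (length(real) == 0) next
    V[t] <- 1L
    if (length(siteOffsets) > 0) {
      lo <- spans[real[1], 1]; hi <- spans[real[length(real)], 2]
      if (any(siteOffsets >= lo & siteOffsets < hi)) y[t] <- 1L
    }
  }
  list(y = y, V = V)
}

#' Assemble model input tensors from a window set
#'
#' Encodes every window, pads to the model length, and derives sequence and
#' subregion labels plus validity masks.
#'
#' @param ws a \code{WindowSet}.
#' @param vocab a \code{BPEVocabulary}.
#' @param nT model input length in tokens.
#' @param m pooling window size in tokens.
#' @return list with \code{ids}, \code{mask} (N x nT integer matrices),
#'   \code{ySeq}, \code{ySub}, \code{vSub}, \code{spans}, \code{nT},
#'   \code{m}.
#' @export
buildModelInputs <- function(ws, vocab, nT = 60L, m = 20L) {
  tk <- encodeSequences(as.character(windowSeqs(ws)), vocab, nT = nT)
  n <- length(ws)
  nSub <- ceiling((nT - 1L) / m)
  ySub <- matrix(0L, n, nSub); vSub <- matrix(0L, n, nSub)
  offs <- as.list(siteOffsets(ws))
  for (i in seq_len(n)) {
    sl <- subregionLabels(tk@spans[[i]], offs[[i]], m, nT)
    ySub[i, ] <- sl$y; vSub[i, ] <- sl$V
  }
  list(ids = tk@ids, mask = tk@mask, ySeq = as.numeric(windowLabels(ws)),
       ySub = ySub, vSub = vSub, spans = tk@spans, nT = nT, m = m)
}
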