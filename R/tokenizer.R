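## Byte-pair encoding over DNA. Training and greedy encoding are implemented
## in C++ (src/bpe.cpp); this layer owns the special-token scheme, padding,
## span bookkeeping, and the plain-text vocabulary format.

SPECIALS <- c(PAD = 0L, UNK = 1L, CLS = 2L, SEP = 3L)
N_SPECIAL <- 4L

#' Train a byte-pair-encoding vocabulary on a DNA corpus
#'
#' Starts from the unique characters of the corpus and repeatedly merges the
#' most frequent adjacent token pair into a new token until the vocabulary
#' size is reached or no pair occurs at least twice. Frequency ties are
#' broken on the lexicographically smallest merged string, so training is
#' fully deterministic.
#'
#' @param corpus character vector or \code{DNAStringSet} of sequences over
#'   \{A,C,G,T\}.
#' @param vocabSize target number of (non-special) tokens, default 4096.
#' @return a \code{\linkS4class{BPEVocabulary}}.
#' @examples
#' v <- trainBPE("ATATATAT", vocabSize = 4)
#' vocabTokens(v)  # "A" "T" "AT" "ATAT"
#' @export
trainBPE <- function(corpus, vocabSize = 4096L) {
  corpus <- .asCharacter(corpus)
  corpus <- corpus[nchar(corpus) > 0]
  if (length(corpus) == 0) stop("empty corpus")
  if (any(grepl("[^ACGT]", corpus)))
    stop("corpus must contain only A, C, G, T")
  res <- .cpp_bpe_train(corpus, as.integer(vocabSize))
  tokens <- res$tokens
  merges <- data.frame(left = tokens[res$merge_left + 1L],
                       right = tokens[res$merge_right + 1L],
                       stringsAsFactors = FALSE)
  new("BPEVocabulary", tokens = tokens, merges = merges, specials = SPECIALS)
}

# 0-based merge pair indices for the C++ encoder
.mergeIds <- function(vocab) {
  list(left = match(vocab@merges$left, vocab@tokens) - 1L,
       right = match(vocab@merges$right, vocab@tokens) - 1L)
}

#' Encode sequences into fixed-length token-id matrices
#'
#' Applies the learned merges greedily in rank order, then frames each token
#' sequence as CLS + tokens + SEP and pads with PAD to \code{nT}. Sequences
#' whose token count exceeds \code{nT - 2} raise an error rather than being
#' truncated (truncation would silently drop labeled nucleotides).
#' Characters outside the learned alphabet map to UNK.
#'
#' @param seqs character vector or \code{DNAStringSet}.
#' @param vocab a \code{BPEVocabulary}.
#' @param nT total token count per sequence (default 60).
#' @return a \code{\linkS4class{TokenizedSequences}}.
#' @export
encodeSequences <- function(seqs, vocab, nT = 60L) {
  seqs <- .asCharacter(seqs)
  nT <- as.integer(nT)
  mi <- .mergeIds(vocab)
  enc <- .cpp_bpe_encode(seqs, vocab@tokens, mi$left, mi$right)
  n <- length(seqs)
  ids <- matrix(SPECIALS[["PAD"]], n, nT)
  mask <- matrix(0L, n, nT)
  spans <- vector("list", n)
  nTokens <- integer(n)
  for (i in seq_len(n)) {
    e <- enc[[i]]
    k <- length(e$ids)
    if (k + 2L > nT)
      stop(sprintf("sequence %d tokenizes to %d tokens; %d exceeds n_t = %d",
                   i, k, k + 2L, nT))
    row <- e$ids + N_SPECIAL          # vocab ids start after specials
    row[e$ids < 0L] <- SPECIALS[["UNK"]]
    ids[i, seq_len(k + 2L)] <- c(SPECIALS[["CLS"]], row, SPECIALS[["SEP"]])
    mask[i, seq_len(k + 2L)] <- 1L
    spans[[i]] <- cbind(start = e$start, end = e$end)
    nTokens[i] <- k
  }
  storage.mode(ids) <- "integer"
  new("TokenizedSequences", ids = ids, mask = mask, spans = spans,
      nTokens = nTokens)
}

#' Decode token ids back to sequence
#'
#' Inverse of \code{\link{encodeSequences}} on the real tokens: CLS, SEP and
#' PAD are dropped, UNK decodes to 'N', and any id outside the vocabulary is
#' an error.
#'
#' @param x a \code{TokenizedSequences} or an integer vector of token ids.
#' @param vocab the \code{BPEVocabulary} used for encoding.
#' @return character vector of decoded sequences.
#' @export
decodeTokens <- function(x, vocab) {
  rows <- if (is(x, "TokenizedSequences"))
    lapply(seq_len(nrow(x@ids)), function(i) x@ids[i, ]) else list(as.integer(x))
  vapply(rows, function(idv) {
    if (any(idv < 0L | idv >= N_SPECIAL + length(vocab@tokens)))
      stop("unknown token id")
    out <- character(0)
    for (id in idv) {
      if (id == SPECIALS[["UNK"]]) out <- c(out, "N")
      else if (id >= N_SPECIAL) out <- c(out, vocab@tokens[id - N_SPECIAL + 1L])
    }
    paste0(out, collapse = "")
  }, character(1))
}

#' Save / load a vocabulary as plain text
#'
#' Two text files: one token per line, and one merge per line as
#' "left<TAB>right" in learned order. The format is editor-friendly so an
#' externally derived DNA vocabulary can be substituted.
#'
#' @param vocab a \code{BPEVocabulary}.
#' @param tokensFile,mergesFile file paths.
#' @return \code{saveVocabulary} returns the paths invisibly;
#'   \code{loadVocabulary} returns a \code{BPEVocabulary}.
#' @export
saveVocabulary <- function(vocab, tokensFile, mergesFile) {
  writeLines(vocab@tokens, tokensFile)
  writeLines(paste(vocab@merges$left, vocab@merges$right, sep = "\t"),
             mergesFile)
  invisible(c(tokensFile, mergesFile))
}

#' @rdname saveVocabulary
#' @export
loadVocabulary <- function(tokensFile, mergesFile) {
  tokens <- readLines(tokensFile)
  ml <- readLines(mergesFile)
  merges <- if (length(ml)) {
    parts <- strsplit(ml, "\t", fixed = TRUE)
    data.frame(left = vapply(parts, `[`, "", 1),
               right = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  } else data.frame(left = character(0), right = character(0))
  new("BPEVocabulary", tokens = tokens, merges = merges, specials = SPECIALS)
}
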