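## Attribution stack: hexamer perturbation importance, JASPAR PFM I/O, the
## PFM -> PPM -> PWM conversion, PWM scanning with the sigmoid-standardized
## score cutoff, TF-level window means, family/class aggregation, triangular
## smoothing, consensus calling, and the k-mer composition report.

BASES <- c("A", "C", "G", "T")

# all 4096 hexamers in base-4 order (A<C<G<T), built once at load
.hexamerTable <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      g <- expand.grid(BASES, BASES, BASES, BASES, BASES, BASES,
                       stringsAsFactors = FALSE)[, 6:1]
      tbl <<- do.call(paste0, g)
    }
    tbl
  }
})

.hexamerIndex <- function(hex) {
  # 1-based index into the base-4 enumeration
  v <- match(strsplit(hex, "")[[1]], BASES) - 1L
  sum(v * 4L^(5:0)) + 1L
}

#' Build a probability scorer from a model
#'
#' Wraps a trained sequence-level model as a plain
#' \code{function(sequences) -> probabilities}, the interface the
#' perturbation machinery consumes (any such function, e.g. a closed-form
#' stub, can be used in its place).
#'
#' @param model a trained \code{TTIRIModel}.
#' @return function mapping a character vector to sequence-level
#'   probabilities.
#' @export
ttiriScorer <- function(model) {
  force(model)
  function(seqs) predictTTIRI(model, seqs)$pSeq
}

#' Position-specific hexamer importance by in-silico perturbation
#'
#' For each of the L-5 hexamer positions of a 201 nt sequence, the hexamer is
#' replaced \code{C} times by hexamers drawn uniformly from the 4095
#' alternatives, and the importance score is the validity-gated median change
#' in predicted log-odds:
#' \deqn{IS^{hexamer}_{j} = V \cdot median_k(logit(P(S)) - logit(P(S^{(k)}_{j})))}
#' with \eqn{V = 1} iff the unperturbed sequence is predicted positive
#' (\eqn{P(S) \ge 0.5}); sequences predicted negative get an all-zero track.
#' Probabilities are clamped before the logit so scores stay finite.
#'
#' @param scorer \code{function(character vector) -> probabilities} (see
#'   \code{\link{ttiriScorer}}).
#' @param sequence a single 201 nt sequence over ACGT.
#' @param C perturbations per position (default 100).
#' @param seed integer seed for the replacement draws.
#' @param L expected sequence length (default 201).
#' @return list with \code{values} (length L-5), \code{valid} (0/1),
#'   \code{pBase}, and \code{sequence}.
#' @export
hexamerImportance <- function(scorer, sequence, C = 100L, seed = 1L,
                              L = 201L) {
  sequence <- .asCharacter(sequence)
  if (length(sequence) != 1L || nchar(sequence) != L)
    stop(sprintf("sequence must be a single %d nt string", L))
  nPos <- L - 5L
  pBase <- as.numeric(scorer(sequence))
  valid <- as.integer(pBase >= 0.5)
  if (valid == 0L)
    return(list(values = numeric(nPos), valid = 0L, pBase = pBase,
                sequence = sequence))
  tbl <- .hexamerTable()
  reps <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(4095L, nPos * C, replace = TRUE), nPos, C)
  })
  pert <- character(nPos * C)
  for (j in seq_len(nPos)) {
    k0 <- .hexamerIndex(substr(sequence, j, j + 5L))
    idx <- reps[j, ]
    idx[idx >= k0] <- idx[idx >= k0] + 1L   # skip the original hexamer
    pert[(j - 1L) * C + seq_len(C)] <-
      paste0(substr(sequence, 1L, j - 1L), tbl[idx],
             substr(sequence, j + 6L, L))
  }
  p <- as.numeric(scorer(pert))
  dl <- logitClamped(pBase) - logitClamped(p)
  vals <- vapply(seq_len(nPos),
                 function(j) median(dl[(j - 1L) * C + seq_len(C)]),
                 numeric(1))
  list(values = vals, valid = 1L, pBase = pBase, sequence = sequence)
}

## ---- JASPAR PFM I/O -------------------------------------------------------

.parsePFMRow <- function(line, motifId) {
  # accepts "A [ 4 19 0 ]", "A 4 19 0", and bare "4 19 0"
  line <- gsub("\\[|\\]", " ", line)
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(parts) > 0 && parts[1] %in% BASES) parts <- parts[-1]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) == 0 || anyNA(vals))
    stop(sprintf("malformed matrix row in motif '%s': %s", motifId, line))
  vals
}

#' Read JASPAR-format PFM files
#'
#' Parses the JASPAR flat text format (">ID name" headers followed by four
#' count rows, with or without base letters and brackets) and attaches
#' family/class metadata. Each motif's PPM and PWM are derived immediately
#' with \code{\link{pfmToPwm}} at the standard pseudocount.
#'
#' @param file PFM text file.
#' @param metadata optional data.frame (or TSV path) with columns
#'   \code{tf_id}, \code{family}, \code{class}; missing ids get "unknown".
#' @return list of \code{\linkS4class{MotifModel}}.
#' @export
readJASPAR <- function(file, metadata = NULL) {
  if (is.character(metadata)) {
    metadata <- read.table(metadata, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  }
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    hl <- sub("^>\\s*", "", lines[hdr[k]])
    parts <- strsplit(trimws(hl), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    rowLines <- lines[(hdr[k] + 1L):(if (k < length(hdr)) hdr[k + 1] - 1L
                                     else length(lines))]
    if (length(rowLines) != 4L)
      stop(sprintf("motif '%s' needs exactly 4 count rows", id))
    rows <- lapply(rowLines, .parsePFMRow, motifId = id)
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("ragged count rows in motif '%s'", id))
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- BASES
    fam <- cls <- "unknown"
    if (!is.null(metadata)) {
      hit <- match(id, metadata$tf_id)
      if (!is.na(hit)) {
        fam <- as.character(metadata$family[hit])
        cls <- as.character(metadata$class[hit])
      }
    }
    conv <- pfmToPwm(pfm)
    out[[k]] <- new("MotifModel", id = id, name = name, family = fam,
                    tfclass = cls, pfm = pfm, ppm = conv$ppm, pwm = conv$pwm)
  }
  out
}

#' @rdname readJASPAR
#' @param motifs list of \code{MotifModel} to write.
#' @export
writeJASPAR <- function(motifs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m@id, m@name), con)
    for (b in BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m@pfm[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(file)
}

#' Convert a position frequency matrix to probability and weight matrices
#'
#' \deqn{PPM_{i,j} = (PFM_{i,j} + \alpha) / \sum_k (PFM_{k,j} + \alpha)}
#' \deqn{PWM_{i,j} = \ln(PPM_{i,j} / p_i)}
#' with pseudocount \eqn{\alpha = 0.5} and uniform background
#' \eqn{p_i = 0.25}.
#'
#' @param pfm 4 x L non-negative count matrix (rows A, C, G, T).
#' @param alpha pseudocount.
#' @param background background base probability.
#' @return list with \code{ppm} and \code{pwm}.
#' @examples
#' pfmToPwm(matrix(c(10, 0, 0, 0), 4, 1,
#'                 dimnames = list(c("A","C","G","T"), NULL)))$pwm[1, 1]
#' # log(3.5)
#' @export
pfmToPwm <- function(pfm, alpha = 0.5, background = 0.25) {
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  if (alpha == 0 && any(colSums(pfm) == 0))
    stop("all-zero PFM column with zero pseudocount")
  ppm <- sweep(pfm + alpha, 2, colSums(pfm + alpha), "/")
  list(ppm = ppm, pwm = log(ppm / background))
}

#' Scan a sequence with a PWM
#'
#' Slides the motif with stride 1 and scores each start as
#' \eqn{Score(PWM, s) = \sum_j PWM_{s_j, j}}. Scores are standardized with a
#' sigmoid and starts with \eqn{sigmoid(score) \ge threshold} are kept as
#' binding hits; at the default 0.999 this is equivalent to a raw-score
#' cutoff of \eqn{\ln(999) \approx 6.907} regardless of motif length (which
#' favors long motifs; see the vignette).
#'
#' @param motif a \code{MotifModel}.
#' @param sequence sequence over ACGT, at least as long as the motif.
#' @param threshold sigmoid-score cutoff.
#' @param keepAll return every start instead of hits only.
#' @return data.frame with \code{start} (1-based), \code{score},
#'   \code{sigmoidScore}.
#' @export
scanMotif <- function(motif, sequence, threshold = 0.999, keepAll = FALSE) {
  sequence <- .asCharacter(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains characters outside ACGT")
  Ln <- motifLength(motif)
  L <- nchar(sequence)
  if (Ln > L) stop("motif longer than sequence")
  base <- match(strsplit(sequence, "")[[1]], BASES)
  nStart <- L - Ln + 1L
  scores <- numeric(nStart)
  pwm <- motif@pwm
  for (j in seq_len(Ln))
    scores <- scores + pwm[cbind(base[seq_len(nStart) + j - 1L], j)]
  sg <- 1 / (1 + exp(-scores))
  df <- data.frame(start = seq_len(nStart), score = scores,
                   sigmoidScore = sg)
  if (keepAll) df else df[df$sigmoidScore >= threshold, , drop = FALSE]
}

#' TF-level importance of a binding hit
#'
#' Averages the hexamer importance scores whose windows lie inside the motif
#' footprint starting at \code{j}:
#' \deqn{IS^{TF}_{j} = \frac{1}{L_n - 5} \sum_{k=0}^{L_n - 6}
#'   IS^{hexamer}_{j+k}.}
#'
#' @param values hexamer importance track (length L - 5).
#' @param j 1-based hit start.
#' @param Ln motif length (>= 6; shorter motifs are skipped with a warning
#'   and return NA).
#' @return the TF-level importance score.
#' @export
tfImportance <- function(values, j, Ln) {
  if (Ln < 6L) {
    warning("motif shorter than 6 nt skipped (window mean undefined)")
    return(NA_real_)
  }
  if (j < 1L || j + Ln - 6L > length(values))
    stop("hit footprint outside the importance track")
  mean(values[j + 0:(Ln - 6L)])
}

#' Scan and attribute a set of sequences
#'
#' Runs \code{\link{hexamerImportance}} on each sequence, scans every motif
#' over every sequence, and tabulates per-hit TF-level importance. The
#' per-sequence perturbation seed is derived from \code{seed} so results are
#' reproducible sequence by sequence.
#'
#' @param scorer probability scorer (see \code{\link{ttiriScorer}}).
#' @param sequences character vector of 201 nt sequences.
#' @param motifs list of \code{MotifModel}.
#' @param C perturbations per position.
#' @param seed base seed.
#' @param threshold sigmoid cutoff for binding hits.
#' @return list with \code{tracks} (per-sequence importance lists) and
#'   \code{hits} (data.frame: seqIndex, tfId, family, class, start, score,
#'   isTF, valid).
#' @export
interpretSequences <- function(scorer, sequences, motifs, C = 100L,
                               seed = 1L, threshold = 0.999) {
  sequences <- .asCharacter(sequences)
  L <- nchar(sequences[1])
  tracks <- lapply(seq_along(sequences), function(i)
    hexamerImportance(scorer, sequences[i], C = C, seed = seed + i, L = L))
  hits <- list()
  for (i in seq_along(sequences)) {
    tr <- tracks[[i]]
    for (mo in motifs) {
      Ln <- motifLength(mo)
      if (Ln < 6L) next
      hh <- scanMotif(mo, sequences[i], threshold = threshold)
      if (nrow(hh) == 0) next
      keep <- hh$start + Ln - 6L <= length(tr$values)
      hh <- hh[keep, , drop = FALSE]
      if (nrow(hh) == 0) next
      isv <- vapply(hh$start, function(j) tfImportance(tr$values, j, Ln),
                    numeric(1))
      hits[[length(hits) + 1L]] <-
        data.frame(seqIndex = i, tfId = mo@id, family = mo@family,
                   class = mo@tfclass, start = hh$start, score = hh$score,
                   isTF = isv, valid = tr$valid)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(seqIndex = integer(0), tfId = character(0),
                          family = character(0), class = character(0),
                          start = integer(0), score = numeric(0),
                          isTF = numeric(0), valid = integer(0))
  list(tracks = tracks, hits = hits)
}

#' Aggregate TF-level importance by family or class
#'
#' Per group and position, the binding-count-weighted mean over all valid
#' sequences and member TFs:
#' \deqn{IS^{Family/Class}_{j} = \frac{\sum_i \sum_{n \in g} V_{i,j,n}
#'   IS^{TF}_{i,j,n}}{\sum_i \sum_{n \in g} V_{i,j,n}}.}
#' Positions with no binding are reported as NA, never zero-filled.
#'
#' @param hits hit table from \code{\link{interpretSequences}}.
#' @param by "family" or "class".
#' @param nPositions track length (L - 5; default 196).
#' @return data.frame with \code{group}, \code{pos} (1-based), \code{value},
#'   \code{nBindings} (the group's total binding count).
#' @export
aggregateImportance <- function(hits, by = c("family", "class"),
                                nPositions = 196L) {
  by <- match.arg(by)
  if (nrow(hits) == 0 || all(hits$valid == 0))
    stop("no valid bindings to aggregate")
  g <- hits[hits$valid == 1L, , drop = FALSE]
  groups <- unique(g[[by]])
  if (length(groups) == 0 || all(is.na(groups)))
    stop("empty grouping metadata")
  out <- lapply(groups, function(gr) {
    sub <- g[g[[by]] == gr, , drop = FALSE]
    val <- rep(NA_real_, nPositions)
    agg <- tapply(sub$isTF, sub$start, mean)
    val[as.integer(names(agg))] <- as.numeric(agg)
    data.frame(group = gr, pos = seq_len(nPositions), value = val,
               nBindings = nrow(sub))
  })
  do.call(rbind, out)
}

#' Rank aggregate tracks the way the reports do
#'
#' Three selection rules over family/class tracks: the best single position
#' ("top_site", max), the cumulative importance over all bound positions
#' ("cumulative", sum), and groups positive everywhere they bind
#' ("positive_all", minimum bound value > 0).
#'
#' @param agg output of \code{\link{aggregateImportance}}.
#' @param method selection rule.
#' @return data.frame of groups with the ranking statistic, ordered best
#'   first ("positive_all" returns only qualifying groups).
#' @export
rankAggregates <- function(agg, method = c("top_site", "cumulative",
                                           "positive_all")) {
  method <- match.arg(method)
  stat <- tapply(agg$value, agg$group, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    switch(method, top_site = max(v), cumulative = sum(v),
           positive_all = min(v))
  })
  df <- data.frame(group = names(stat), stat = as.numeric(stat))
  if (method == "positive_all") df <- df[!is.na(df$stat) & df$stat > 0, ]
  df[order(-df$stat), ]
}

#' Triangular weighted smoothing of a positional track
#'
#' Centered triangular-weighted moving average with half-width
#' \code{floor(window/2)}; edge windows renormalize over the available
#' positions and missing values are excluded from both the numerator and the
#' weight sum. \code{window = 1} is the identity.
#'
#' @param values numeric track (NA for undefined positions).
#' @param window window size (default 10).
#' @return smoothed track of the same length.
#' @export
smoothTrack <- function(values, window = 10L) {
  if (window < 1L) stop("window must be >= 1")
  hw <- floor(window / 2)
  if (hw == 0) return(values)
  n <- length(values)
  out <- rep(NA_real_, n)
  w0 <- hw + 1 - abs(-hw:hw)
  for (i in seq_len(n)) {
    idx <- (i - hw):(i + hw)
    ok <- idx >= 1 & idx <= n & !is.na(values[pmax(pmin(idx, n), 1)])
    if (!any(ok)) next
    out[i] <- sum(w0[ok] * values[idx[ok]]) / sum(w0[ok])
  }
  out
}

#' k-mer composition comparison between two sequence sets
#'
#' Mono-, di- and tri-nucleotide frequency proportions (overlapping k-mers)
#' per set, with per-k rank tables and the signed rank change from set B to
#' set A (positive = the k-mer ranks higher, i.e. has a smaller rank number,
#' in B than in A).
#'
#' @param a,b \code{DNAStringSet} or character vectors (e.g. infidelity vs
#'   normal sequences).
#' @return list of data.frames (\code{mono}, \code{di}, \code{tri}) with
#'   columns kmer, propA, propB, rankA, rankB, rankChange.
#' @export
compositionFeatures <- function(a, b) {
  a <- .asDNAStringSet(a); b <- .asDNAStringSet(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sequence set")
  one <- function(x, k) {
    ct <- colSums(Biostrings::oligonucleotideFrequency(x, k))
    ct / sum(ct)
  }
  out <- lapply(1:3, function(k) {
    pa <- one(a, k); pb <- one(b, k)
    ra <- rank(-pa, ties.method = "min")
    rb <- rank(-pb, ties.method = "min")
    data.frame(kmer = names(pa), propA = as.numeric(pa),
               propB = as.numeric(pb), rankA = as.integer(ra),
               rankB = as.integer(rb),
               rankChange = as.integer(rb - ra))
  })
  names(out) <- c("mono", "di", "tri")
  out
}

#' Degenerate consensus of a motif
#'
#' Per column, the maximum-probability base; bases within
#' \code{degeneracyThreshold} of the maximum are joined as "[X/Y]" (ordered
#' by decreasing probability).
#'
#' @param motif a \code{MotifModel}.
#' @param degeneracyThreshold probability slack below the column maximum.
#' @return consensus string.
#' @export
motifConsensus <- function(motif, degeneracyThreshold = 0.25) {
  ppm <- motif@ppm
  cols <- vapply(seq_len(ncol(ppm)), function(j) {
    p <- ppm[, j]
    keep <- which(p >= max(p) - degeneracyThreshold)
    keep <- keep[order(-p[keep], BASES[keep])]
    if (length(keep) == 1) BASES[keep]
    else paste0("[", paste(BASES[keep], collapse = "/"), "]")
  }, character(1))
  paste0(cols, collapse = "")
}

#' Build a motif model from a consensus string
#'
#' Sharp synthetic PFM: \code{counts} at the consensus base per column, zero
#' elsewhere. Useful for planted-motif benchmarks and decoy panels.
#'
#' @param id motif identifier.
#' @param consensus string over ACGT.
#' @param counts per-column consensus count (default 10; with the standard
#'   pseudocount each matching base contributes ln(3.5) to the PWM score).
#' @param family,class annotation strings.
#' @return a \code{MotifModel}.
#' @export
consensusMotifModel <- function(id, consensus, counts = 10,
                                family = "unknown", class = "unknown") {
  bs <- strsplit(consensus, "")[[1]]
  if (any(!bs %in% BASES)) stop("consensus must be over ACGT")
  pfm <- matrix(0, 4, length(bs), dimnames = list(BASES, NULL))
  pfm[cbind(match(bs, BASES), seq_along(bs))] <- counts
  conv <- pfmToPwm(pfm)
  new("MotifModel", id = id, name = id, family = family, tfclass = class,
      pfm = pfm, ppm = conv$ppm, pwm = conv$pwm)
}

#' Panel of decoy motifs
#'
#' Random sharp consensus motifs (distinct, excluding a given motif) for
#' ranking benchmarks.
#'
#' @param n number of decoys.
#' @param length motif length.
#' @param exclude consensus string to exclude (e.g. the planted motif).
#' @param seed integer seed.
#' @return list of \code{MotifModel}.
#' @export
decoyMotifs <- function(n = 20L, length = 6L, exclude = "CACCTG", seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    while (base::length(out) < n) {
      cand <- paste0(sample(BASES, length, replace = TRUE), collapse = "")
      if (cand != exclude && !cand %in% out) out <- c(out, cand)
    }
    lapply(seq_along(out), function(i)
      consensusMotifModel(sprintf("DECOY%03d", i), out[i],
                          family = sprintf("decoy_family_%02d", i),
                          class = "decoy"))
  })
}
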