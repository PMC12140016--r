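#' Synthetic genome with infidelity sites and coding annotation
#'
#' Container for a simulated multi-contig genome: contig sequences, the
#' coding-region annotation used as the negative-sampling template, and the
#' single-nucleotide transcriptional-infidelity sites. All interval slots use
#' the usual Bioconductor 1-based closed convention; the simulator and the BED
#' writers convert from/to 0-based half-open coordinates.
#'
#' @slot contigs \code{DNAStringSet} of contig sequences.
#' @slot coding \code{GRanges} of coding intervals (disjoint per contig).
#' @slot sites \code{GRanges} of width-1 infidelity sites.
#' @slot simConfig list; the \code{\link{simConfig}} the object was built from
#'   (may be empty for genomes read from files).
#'
#' @aliases SyntheticGenome
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
  representation(contigs = "DNAStringSet", coding = "GRanges",
                 sites = "GRanges", simConfig = "list"))

setValidity("SyntheticGenome", function(object) {
  msg <- NULL
  len <- setNames(Biostrings::width(object@contigs), names(object@contigs))
  for (gr in list(object@sites, object@coding)) {
    if (length(gr) == 0) next
    ct <- as.character(seqnames(gr))
    if (!all(ct %in% names(len)))
      return("interval on unknown contig")
    if (any(start(gr) < 1L) || any(end(gr) > len[ct]))
      msg <- c(msg, "interval outside contig bounds")
  }
  if (length(object@coding) > 0 &&
      !all(vapply(split(IRanges::ranges(object@coding),
                        as.character(seqnames(object@coding))),
                  IRanges::isDisjoint, logical(1))))
    msg <- c(msg, "coding intervals overlap within a contig")
  if (is.null(msg)) TRUE else msg
})

#' Labeled sequence windows
#'
#' A set of fixed-width genomic windows with binary infidelity labels and the
#' 0-based within-window offsets of any infidelity sites they contain (the
#' sparse form of the per-nucleotide site mask).
#'
#' @slot info \code{DataFrame} with columns \code{contig}, \code{start}
#'   (0-based) and \code{label} (0/1).
#' @slot seqs \code{DNAStringSet}, one sequence per window.
#' @slot siteOffsets \code{IntegerList} of 0-based site offsets per window.
#'
#' @aliases WindowSet
#' @exportClass WindowSet
setClass("WindowSet",
  representation(info = "DataFrame", seqs = "DNAStringSet",
                 siteOffsets = "IntegerList"))

setValidity("WindowSet", function(object) {
  n <- nrow(object@info)
  if (length(object@seqs) != n || length(object@siteOffsets) != n)
    return("info, seqs and siteOffsets lengths differ")
  if (n > 0 && !all((object@info$label == 1L) ==
                    (S4Vectors::elementNROWS(object@siteOffsets) > 0L)))
    return("label must be 1 exactly when a window holds at least one site")
  TRUE
})

#' Train/validation/test partition of a window set
#'
#' @slot train,validation,test \code{WindowSet} partitions.
#' @slot ratios numeric(3) split ratios.
#' @slot seed integer seed used for the stratified shuffle.
#'
#' @aliases DatasetSplit
#' @exportClass DatasetSplit
setClass("DatasetSplit",
  representation(train = "WindowSet", validation = "WindowSet",
                 test = "WindowSet", ratios = "numeric", seed = "integer"))

#' Byte-pair-encoding vocabulary over DNA
#'
#' Learned by \code{\link{trainBPE}}: the ordered token list (alphabet first,
#' then one token per merge) and the ordered merge table. Special tokens are
#' not part of the vocabulary proper; their fixed ids are PAD=0, UNK=1, CLS=2,
#' SEP=3, and vocabulary tokens occupy ids 4 and up.
#'
#' @slot tokens character vector of tokens (non-special).
#' @slot merges data.frame with character columns \code{left}, \code{right},
#'   in learned order.
#' @slot specials named integer vector of special-token ids.
#'
#' @aliases BPEVocabulary
#' @exportClass BPEVocabulary
setClass("BPEVocabulary",
  representation(tokens = "character", merges = "data.frame",
                 specials = "integer"))

setValidity("BPEVocabulary", function(object) {
  if (!identical(sort(names(object@specials)), sort(c("PAD", "UNK", "CLS", "SEP"))))
    return("specials must name PAD, UNK, CLS, SEP")
  if (!all(c("left", "right") %in% names(object@merges)))
    return("merges needs 'left' and 'right' columns")
  ok <- paste0(object@merges$left, object@merges$right) %in% object@tokens
  if (!all(ok)) return("every merge must produce a vocabulary token")
  TRUE
})

#' Encoded sequences ready for the model
#'
#' Fixed-length token-id matrices plus the per-token character spans needed to
#' map subregions back to nucleotides. Row layout: CLS, the effective sequence
#' tokens, SEP, then PAD up to \code{n_t}.
#'
#' @slot ids integer matrix (sequences x n_t) of 0-based token ids.
#' @slot mask integer matrix; 1 for CLS/sequence/SEP tokens, 0 for PAD.
#' @slot spans list of k x 2 integer matrices of 0-based half-open character
#'   spans, one row per effective token.
#' @slot nTokens integer; effective (non-special) token count per sequence.
#'
#' @aliases TokenizedSequences
#' @exportClass TokenizedSequences
setClass("TokenizedSequences",
  representation(ids = "matrix", mask = "matrix", spans = "list",
                 nTokens = "integer"))

#' The two-layer infidelity-region classifier
#'
#' Holds the parameter tensors, the architecture configuration, the vocabulary
#' the model was trained with, and the training history.
#'
#' @slot params named list of parameter matrices (see \code{\link{initTTIRI}}).
#' @slot config \code{\link{modelConfig}} list.
#' @slot vocab \code{BPEVocabulary}.
#' @slot history data.frame of per-epoch losses and validation AUROC.
#' @slot recipe list; the training recipe used (empty if untrained).
#'
#' @aliases TTIRIModel
#' @exportClass TTIRIModel
setClass("TTIRIModel",
  representation(params = "list", config = "list", vocab = "BPEVocabulary",
                 history = "data.frame", recipe = "list"))

#' Transcription-factor binding motif (PFM/PPM/PWM triplet)
#'
#' @slot id,name character; motif identifier and TF name.
#' @slot family,class character; JASPAR family/class annotation ("unknown"
#'   when no metadata is supplied).
#' @slot pfm 4 x L count matrix (rows A, C, G, T).
#' @slot ppm probability matrix (pseudocount-normalized PFM).
#' @slot pwm natural-log odds matrix against the uniform 0.25 background.
#'
#' @aliases MotifModel
#' @exportClass MotifModel
setClass("MotifModel",
  representation(id = "character", name = "character", family = "character",
                 tfclass = "character", pfm = "matrix", ppm = "matrix",
                 pwm = "matrix"))

setValidity("MotifModel", function(object) {
  if (nrow(object@pfm) != 4 || !identical(rownames(object@pfm), c("A", "C", "G", "T")))
    return("pfm must have rows A, C, G, T")
  if (any(object@pfm < 0)) return("pfm counts must be non-negative")
  if (ncol(object@ppm) > 0 && any(abs(colSums(object@ppm) - 1) > 1e-8))
    return("ppm columns must sum to 1")
  TRUE
})

## ---- accessors ------------------------------------------------------------

#' @describeIn SyntheticGenome-accessors contig sequences
#' @export
contigSeqs <- function(x) x@contigs

#' Accessors for SyntheticGenome
#'
#' @param x a \code{SyntheticGenome}
#' @name SyntheticGenome-accessors
#' @aliases codingRegions infidelitySites
NULL

#' @describeIn SyntheticGenome-accessors coding intervals (GRanges)
#' @export
codingRegions <- function(x) x@coding

#' @describeIn SyntheticGenome-accessors infidelity sites (width-1 GRanges)
#' @export
infidelitySites <- function(x) x@sites

#' @describeIn WindowSet-accessors window metadata DataFrame
#' @export
windowInfo <- function(x) x@info

#' Accessors for WindowSet
#'
#' @param x a \code{WindowSet}
#' @name WindowSet-accessors
#' @aliases windowSeqs windowLabels siteOffsets
NULL

#' @describeIn WindowSet-accessors window sequences
#' @export
windowSeqs <- function(x) x@seqs

#' @describeIn WindowSet-accessors 0/1 labels
#' @export
windowLabels <- function(x) x@info$label

#' @describeIn WindowSet-accessors per-window 0-based site offsets
#' @export
siteOffsets <- function(x) x@siteOffsets

#' @describeIn BPEVocabulary-accessors vocabulary tokens (non-special)
#' @export
vocabTokens <- function(x) x@tokens

#' Accessors for BPEVocabulary
#'
#' @param x a \code{BPEVocabulary}
#' @name BPEVocabulary-accessors
#' @aliases vocabMerges specialTokens vocabSize
NULL

#' @describeIn BPEVocabulary-accessors ordered merge table
#' @export
vocabMerges <- function(x) x@merges

#' @describeIn BPEVocabulary-accessors named special-token ids
#' @export
specialTokens <- function(x) x@specials

#' @describeIn BPEVocabulary-accessors number of non-special tokens
#' @export
vocabSize <- function(x) length(x@tokens)

#' @describeIn TTIRIModel-accessors parameter list
#' @export
modelParams <- function(x) x@params

#' Accessors for TTIRIModel and MotifModel
#'
#' @param x a \code{TTIRIModel} or \code{MotifModel}
#' @name TTIRIModel-accessors
#' @aliases trainHistory motifPFM motifPPM motifPWM motifLength tfFamily tfClass
NULL

#' @describeIn TTIRIModel-accessors architecture configuration
#' @export
modelConfigOf <- function(x) x@config

#' @describeIn TTIRIModel-accessors per-epoch training history
#' @export
trainHistory <- function(x) x@history

#' @describeIn TTIRIModel-accessors count matrix
#' @export
motifPFM <- function(x) x@pfm

#' @describeIn TTIRIModel-accessors probability matrix
#' @export
motifPPM <- function(x) x@ppm

#' @describeIn TTIRIModel-accessors log-odds matrix
#' @export
motifPWM <- function(x) x@pwm

#' @describeIn TTIRIModel-accessors motif length in nt
#' @export
motifLength <- function(x) ncol(x@pfm)

#' @describeIn TTIRIModel-accessors TF family annotation
#' @export
tfFamily <- function(x) x@family

#' @describeIn TTIRIModel-accessors TF class annotation
#' @export
tfClass <- function(x) x@tfclass

## ---- basic methods --------------------------------------------------------

#' @export
setMethod("length", "WindowSet", function(x) nrow(x@info))

#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  new("WindowSet", info = x@info[i, , drop = FALSE], seqs = x@seqs[i],
      siteOffsets = x@siteOffsets[i])
})

setMethod("show", "SyntheticGenome", function(object) {
  cat(sprintf("SyntheticGenome: %d contig(s), %s nt total\n",
              length(object@contigs),
              format(sum(Biostrings::width(object@contigs)), big.mark = ",")))
  cat(sprintf("  %d infidelity site(s), %d coding interval(s)\n",
              length(object@sites), length(object@coding)))
})

setMethod("show", "WindowSet", function(object) {
  n <- length(object)
  w <- if (n) Biostrings::width(object@seqs)[1] else NA_integer_
  cat(sprintf("WindowSet: %d window(s) of %s nt (%d positive)\n", n, w,
              sum(object@info$label == 1L)))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (%s): train %d / validation %d / test %d\n",
              paste(object@ratios, collapse = ":"), length(object@train),
              length(object@validation), length(object@test)))
})

setMethod("show", "BPEVocabulary", function(object) {
  cat(sprintf("BPEVocabulary: %d tokens (+%d specials), %d merges\n",
              length(object@tokens), length(object@specials),
              nrow(object@merges)))
})

setMethod("show", "TokenizedSequences", function(object) {
  cat(sprintf("TokenizedSequences: %d sequence(s), n_t = %d, median %g effective tokens\n",
              nrow(object@ids), ncol(object@ids),
              stats::median(object@nTokens)))
})

setMethod("show", "TTIRIModel", function(object) {
  cfg <- object@config
  cat(sprintf("TTIRIModel: d_h=%d, %d layer(s), %d head(s), n_t=%d, m=%d, lambda=%g\n",
              cfg$d, cfg$n_layers, cfg$h, cfg$n_t, cfg$m, cfg$lambda))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); best validation AUROC %.4f\n",
                nrow(object@history),
                suppressWarnings(max(object@history$val_auroc, na.rm = TRUE))))
  else cat("  untrained (initialized parameters)\n")
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel %s (%s): %d nt, family '%s', class '%s'\n",
              object@id, object@name, ncol(object@pfm), object@family,
              object@tfclass))
})
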