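## shared numerical helpers

PROB_EPS <- 1e-7

#' Clamped log-odds transform
#'
#' Probabilities are clamped to [1e-7, 1 - 1e-7] before the logit so that
#' perturbation importance scores stay finite even for saturated predictions.
#'
#' @param p numeric vector of probabilities.
#' @return log(p / (1 - p)) after clamping, natural log.
#' @export
logitClamped <- function(p) {
  p <- pmin(1 - PROB_EPS, pmax(PROB_EPS, p))
  log(p / (1 - p))
}

.clampProb <- function(p) pmin(1 - PROB_EPS, pmax(PROB_EPS, p))

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x > 0

.checkFraction <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a fraction in [0, 1]", nm), call. = FALSE)
  x
}

# split a character vector of equal-width sequences into a DNAStringSet
.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

.asCharacter <- function(x) {
  if (is.character(x)) x else as.character(x)
}
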