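#' @useDynLib symtyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm quantile residuals rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over the DNA alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of FASTQ quality strings.
#' @return list of integer vectors, one per read.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer quality scores as a Phred+33 string
#'
#' @param q integer vector of per-base quality scores.
#' @return single quality string.
#' @export
int_to_phred <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

# Mean Phred score per read, vectorized over a character vector.
mean_quality <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

# Hamming mismatch counts between equal-length string vectors and one probe,
# comparing the first nchar(probe) characters.
prefix_mismatches <- function(x, probe) {
  n <- nchar(probe)
  mism <- integer(length(x))
  too_short <- nchar(x) < n
  for (i in seq_len(n)) {
    mism <- mism + (substr(x, i, i) != substr(probe, i, i))
  }
  mism[too_short] <- n
  mism
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
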