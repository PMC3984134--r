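# Pairwise alignment wrappers. Bulk read-vs-reference scoring uses the
# package's banded C++ aligner; single-pair operations (annotation, consensus
# building, haplotype distances) use Biostrings::pairwiseAlignment.

#' Align two sequences and return the aligned strings
#'
#' Needleman-Wunsch (or overlap) alignment with unit match/mismatch scores and
#' affine gaps, tuned to keep indels in contiguous runs.
#'
#' @param a,b sequences.
#' @param type "global" or "overlap" (free end gaps).
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @return list with `aligned_a`, `aligned_b`, `score`.
#' @export
align_pair <- function(a, b, type = c("global", "overlap"), match = 1,
                       mismatch = -1, gap_opening = 3, gap_extension = 1) {
  type <- match.arg(type)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension
  )
  list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

# Percent identity of an aligned pair: matches / aligned columns * 100.
# An empty alignment (nothing alignable) counts as identity 0.
aligned_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) == 0L) return(0)
  100 * sum(a == b & a != "-") / length(a)
}

#' Map clean reads against reference sequences
#'
#' Every read is aligned semi-globally (anchored at the 5' end, free trailing
#' gaps) to every reference with linear scoring (+1 match, -1 mismatch, -2
#' gap). A read is `mapped` when a unique best-scoring reference exists and
#' the alignment identity reaches `min_identity`; any score tie makes it
#' `ambiguous` (maximum discrimination: tied reads are discarded from
#' counting); reads below the identity floor are `unmapped`.
#'
#' @param clean_reads data.frame with `read_id`, `bases`.
#' @param references reference table with `reference_id`, `bases`.
#' @param match,mismatch,gap alignment scores.
#' @param min_identity minimum percent identity for a mapped call (default 90).
#' @param band half-width of the alignment band (default 12); widen for
#'   indel-rich data.
#' @return data.frame with `read_id`, `status` (mapped/ambiguous/unmapped),
#'   `reference_id` (NA unless mapped), `score`, `identity`.
#' @export
map_reads <- function(clean_reads, references, match = 1, mismatch = -1,
                      gap = -2, min_identity = 90, band = 12) {
  if (nrow(references) == 0L) stop("references must be non-empty", call. = FALSE)
  if (nrow(clean_reads) == 0L) {
    return(data.frame(read_id = character(0), status = character(0),
                      reference_id = character(0), score = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  ustr <- unique(clean_reads$bases)
  sm <- semiglobal_score_matrix(ustr, references$bases, match, mismatch, gap,
                                as.integer(band))
  score <- sm$score
  ident <- sm$identity
  best <- max.col(score, ties.method = "first")
  idx <- cbind(seq_along(ustr), best)
  best_score <- score[idx]
  n_best <- rowSums(score == best_score)
  best_ident <- ident[idx]
  status <- ifelse(n_best > 1L, "ambiguous",
                   ifelse(best_ident >= min_identity, "mapped", "unmapped"))
  ref_id <- ifelse(status == "mapped", references$reference_id[best], NA_character_)

  m <- match(clean_reads$bases, ustr)
  data.frame(
    read_id = clean_reads$read_id,
    status = status[m],
    reference_id = ref_id[m],
    score = best_score[m],
    identity = best_ident[m],
    stringsAsFactors = FALSE
  )
}

#' Percentage of a total, as printed in run accounting
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits rounding (default 1).
#' @return `100 * n / total`, rounded.
#' @export
percent_of <- function(n, total, digits = 1) {
  stopifnot_scalar_number(n, "n", min = 0)
  stopifnot_scalar_number(total, "total", min = 1)
  round(100 * n / total, digits)
}

#' Mapping efficiency
#'
#' Fraction of reads that mapped unambiguously, `mapped / (mapped + ambiguous
#' + unmapped)`, reported to two decimals as in run accounting tables. Can be
#' called either on an assignment table or on printed counts.
#'
#' @param x assignment data.frame from [map_reads()], or the number of mapped
#'   reads.
#' @param total when `x` is a count: total (cleaned) reads.
#' @param digits rounding for the reported value (default 2).
#' @return mapping efficiency as a number in `[0, 1]`.
#' @export
mapping_efficiency <- function(x, total = NULL, digits = 2) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("no assignments", call. = FALSE)
    round(sum(x$status == "mapped") / nrow(x), digits)
  } else {
    stopifnot_scalar_number(x, "x", min = 0)
    stopifnot_scalar_number(total, "total", min = 1)
    round(x / total, digits)
  }
}
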