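# Preprocessing: demultiplex by barcode, trim primers, filter on quality and
# length. Read accounting is conserved at every stage: every input read ends
# up in exactly one output bin.

#' Demultiplex reads by 5' barcode
#'
#' A read is assigned to a sample when exactly one manifest barcode matches
#' its 5' end with at most `max_mismatches` mismatches and strictly fewer
#' mismatches than any other barcode; the matched barcode prefix is removed.
#' All other reads go to the unassigned bin.
#'
#' @param reads data.frame with `read_id`, `bases` and optionally `qualities`.
#' @param manifest data.frame with `barcode` and `sample_id` (unique).
#' @param max_mismatches maximum barcode mismatches (default 1).
#' @return list with `samples` (named list of read data.frames, barcode
#'   stripped) and `unassigned` (data.frame).
#' @export
demultiplex <- function(reads, manifest, max_mismatches = 1) {
  validate_manifest(manifest)
  nb <- nrow(manifest)
  mism <- matrix(0L, nrow(reads), nb)
  for (b in seq_len(nb)) {
    mism[, b] <- prefix_mismatches(reads$bases, manifest$barcode[b])
  }
  best <- apply(mism, 1L, which.min)
  best_val <- mism[cbind(seq_len(nrow(reads)), best)]
  n_best <- rowSums(mism == best_val)
  assigned <- best_val <= max_mismatches & n_best == 1L
  if (nrow(reads) == 0L) assigned <- logical(0)

  samples <- lapply(seq_len(nb), function(b) {
    sel <- assigned & best == b
    out <- reads[sel, , drop = FALSE]
    blen <- nchar(manifest$barcode[b])
    out$bases <- substring(out$bases, blen + 1L)
    if (!is.null(out$qualities)) out$qualities <- substring(out$qualities, blen + 1L)
    rownames(out) <- NULL
    out
  })
  names(samples) <- manifest$sample_id
  unassigned <- reads[!assigned, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(samples = samples, unassigned = unassigned)
}

# Locate the reverse-complemented reverse primer near the 3' end; returns the
# 1-based start of the primer hit, or NA. Scans a window of end offsets to
# tolerate small indels upstream.
find_reverse_primer <- function(bases, primer_rc, max_mismatches, window = 8L) {
  np <- nchar(primer_rc)
  n <- length(bases)
  hit <- rep(NA_integer_, n)
  len <- nchar(bases)
  for (off in 0:window) {
    start <- len - np + 1L - off
    cand <- is.na(hit) & start >= 1L
    if (!any(cand)) next
    frag <- substring(bases[cand], start[cand], start[cand] + np - 1L)
    mm <- prefix_mismatches(frag, primer_rc)
    ok <- mm <= max_mismatches
    hit[which(cand)[ok]] <- start[cand][ok]
  }
  hit
}

#' Trim PCR primers from demultiplexed reads
#'
#' The leading forward primer (up to `max_mismatches` mismatches) is removed;
#' reads without it are rejected. If the reverse-complemented reverse primer
#' is found near the 3' end it is removed too; absence at the 3' end is
#' tolerated since truncated reads rarely reach it.
#'
#' @param reads data.frame with `bases` (and optionally `qualities`).
#' @param primer_forward,primer_reverse primer sequences (reverse given in
#'   primer orientation, matched as its reverse complement).
#' @param max_mismatches per-primer mismatch tolerance (default 2).
#' @return list with `trimmed` and `rejected` data.frames.
#' @export
trim_primers <- function(reads, primer_forward, primer_reverse = NULL,
                         max_mismatches = 2) {
  if (is.null(primer_forward) || nchar(primer_forward) == 0L) {
    stop("primer_forward must be non-empty", call. = FALSE)
  }
  mm <- prefix_mismatches(reads$bases, primer_forward)
  keep <- mm <= max_mismatches
  trimmed <- reads[keep, , drop = FALSE]
  npf <- nchar(primer_forward)
  trimmed$bases <- substring(trimmed$bases, npf + 1L)
  if (!is.null(trimmed$qualities)) {
    trimmed$qualities <- substring(trimmed$qualities, npf + 1L)
  }
  if (!is.null(primer_reverse) && nchar(primer_reverse) > 0L && nrow(trimmed) > 0L) {
    rc <- revcomp(primer_reverse)
    hit <- find_reverse_primer(trimmed$bases, rc, max_mismatches)
    cut <- !is.na(hit)
    trimmed$bases[cut] <- substring(trimmed$bases[cut], 1L, hit[cut] - 1L)
    if (!is.null(trimmed$qualities)) {
      trimmed$qualities[cut] <- substring(trimmed$qualities[cut], 1L, hit[cut] - 1L)
    }
  }
  rejected <- reads[!keep, , drop = FALSE]
  rownames(trimmed) <- NULL
  rownames(rejected) <- NULL
  list(trimmed = trimmed, rejected = rejected)
}

#' Filter reads on length and mean quality
#'
#' Reads shorter than `min_length` are discarded (strictly less than, so a
#' read of exactly `min_length` bases is kept), then reads with mean Phred
#' score below `min_mean_quality` are discarded. The log counts each
#' rejection under the first rule that fired.
#'
#' @param reads data.frame with `bases` and optionally `qualities`.
#' @param min_length minimum read length in bp (default 150).
#' @param min_mean_quality minimum mean Phred score (default 20); ignored when
#'   reads carry no qualities.
#' @return list with `kept`, `rejected`, and `log` (data.frame of reason,
#'   count).
#' @export
quality_length_filter <- function(reads, min_length = 150, min_mean_quality = 20) {
  stopifnot_scalar_number(min_length, "min_length", min = 1)
  short <- nchar(reads$bases) < min_length
  lowq <- if (!is.null(reads$qualities) && nrow(reads) > 0L) {
    !short & mean_quality(reads$qualities) < min_mean_quality
  } else rep(FALSE, nrow(reads))
  kept <- reads[!short & !lowq, , drop = FALSE]
  rejected <- reads[short | lowq, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(rejected) <- NULL
  list(
    kept = kept, rejected = rejected,
    log = data.frame(reason = c("too_short", "low_quality"),
                     count = c(sum(short), sum(lowq)),
                     stringsAsFactors = FALSE)
  )
}

#' Full preprocessing stage
#'
#' Demultiplexes, trims primers and applies the quality/length filter per
#' sample, returning clean reads plus a per-stage accounting report. The
#' accounting reconciles exactly: raw = unassigned + no-primer + filtered +
#' clean.
#'
#' @param reads raw read data.frame (`read_id`, `bases`, `qualities`).
#' @param manifest barcode manifest with `barcode`, `sample_id` and optional
#'   `fwd_primer`, `rev_primer` columns.
#' @param max_barcode_mismatches barcode tolerance (default 1).
#' @param max_primer_mismatches primer tolerance (default 2).
#' @param min_length,min_mean_quality filter thresholds.
#' @return list with `clean` (data.frame `read_id`, `sample_id`, `bases`) and
#'   `report` (per-sample and total counts).
#' @export
preprocess <- function(reads, manifest, max_barcode_mismatches = 1,
                       max_primer_mismatches = 2, min_length = 150,
                       min_mean_quality = 20) {
  dm <- demultiplex(reads, manifest, max_barcode_mismatches)
  per_sample <- lapply(manifest$sample_id, function(sid) {
    r <- dm$samples[[sid]]
    row <- manifest[manifest$sample_id == sid, ]
    fwd <- row$fwd_primer %||% NULL
    rev <- row$rev_primer %||% NULL
    if (!is.null(fwd) && !is.na(fwd) && nchar(fwd) > 0L) {
      tp <- trim_primers(r, fwd, rev, max_primer_mismatches)
    } else {
      tp <- list(trimmed = r, rejected = r[0, , drop = FALSE])
    }
    qf <- quality_length_filter(tp$trimmed, min_length, min_mean_quality)
    clean <- if (nrow(qf$kept) > 0L) {
      data.frame(read_id = qf$kept$read_id, sample_id = sid,
                 bases = qf$kept$bases, stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = character(0), sample_id = character(0),
                 bases = character(0), stringsAsFactors = FALSE)
    }
    list(clean = clean,
         counts = c(demultiplexed = nrow(r), no_primer = nrow(tp$rejected),
                    too_short = qf$log$count[1], low_quality = qf$log$count[2],
                    clean = nrow(clean)))
  })
  names(per_sample) <- manifest$sample_id
  clean <- do.call(rbind, lapply(per_sample, `[[`, "clean"))
  rownames(clean) <- NULL
  counts <- do.call(rbind, lapply(per_sample, `[[`, "counts"))
  report <- list(
    raw = nrow(reads),
    unassigned = nrow(dm$unassigned),
    per_sample = data.frame(sample_id = manifest$sample_id, counts,
                            row.names = NULL, stringsAsFactors = FALSE),
    clean = nrow(clean)
  )
  stopifnot(report$raw == report$unassigned + sum(counts[, "demultiplexed"]))
  list(clean = clean, report = report)
}
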