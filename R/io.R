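# Readers and writers for the plain-text formats flowing between stages:
# FASTQ/FASTA via Biostrings, tabular files as TSV.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `read_id`, `bases`, `qualities`
#'   (Phred+33 encoded string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  data.frame(
    read_id = ids,
    bases = as.character(x),
    qualities = as.character(Biostrings::quality(x)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `read_id`, `bases`, `qualities`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$read_id
  qs <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(reads$qualities)
  )
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTA file into a sequence table
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `bases`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)), bases = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write named sequences to FASTA
#'
#' @param ids sequence names.
#' @param bases sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, bases, path) {
  x <- Biostrings::DNAStringSet(bases)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path TSV path with a header row.
#' @return data.frame.
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Columns: `barcode`, `sample_id`, `fwd_primer`, `rev_primer`.
#'
#' @param path TSV path.
#' @return validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read_tsv_file(path)
  validate_manifest(m)
  m
}

validate_manifest <- function(manifest) {
  need <- c("barcode", "sample_id")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns `barcode` and `sample_id`", call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(manifest$barcode)) {
    stop("duplicate barcodes in manifest", call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_ids in manifest", call. = FALSE)
  }
  invisible(manifest)
}
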