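# 100%-identity clustering of clean reads and histogram-based selection of
# reference sequences.
#
# Pyrosequencing reads vary in length, so "100% identity" is exact identity
# with prefix containment: a read that is an exact prefix of a longer read
# belongs with it. Unique strings are processed longest-first and each joins
# the cluster, among those whose representative contains it as a prefix, with
# the most abundant founding string (greedy abundance-first dereplication, as
# in cd-hit-style clustering); a string matching no representative founds a
# new cluster. The greedy rule keeps near-identical templates that share a
# long prefix (e.g. two types separated by one late SNP) in separate
# clusters, while their genuinely ambiguous truncated reads are resolved
# later at the mapping stage.

#' Cluster reads at 100% identity with prefix containment
#'
#' @param clean_reads data.frame with `read_id` and `bases`.
#' @return list with `clusters` (data.frame `cluster_id`,
#'   `representative_id`, `representative_bases`, `size`, ordered by
#'   decreasing size) and `membership` (data.frame `read_id`, `cluster_id`).
#'   Cluster sizes sum to the number of input reads.
#' @export
cluster_identical <- function(clean_reads) {
  if (nrow(clean_reads) == 0L) stop("reads must be non-empty", call. = FALSE)
  ustr <- sort(unique(clean_reads$bases), method = "radix")
  nu <- length(ustr)
  nch <- nchar(ustr)
  ucount <- tabulate(match(clean_reads$bases, ustr), nu)
  proc <- order(-nch, seq_len(nu))  # longest first; ties keep lexicographic order
  cluster_of <- integer(nu)
  founder_count <- integer(nu)  # read multiplicity of each cluster's founder
  n_clusters <- 0L
  for (i in proc) {
    s <- ustr[i]
    best <- 0L
    best_fc <- -1L
    j <- i + 1L
    while (j <= nu && startsWith(ustr[j], s)) {
      cj <- cluster_of[j]  # longer, hence already assigned
      fc <- founder_count[cj]
      if (fc > best_fc || (fc == best_fc && cj < best)) {
        best <- cj
        best_fc <- fc
      }
      j <- j + 1L
    }
    if (best == 0L) {
      n_clusters <- n_clusters + 1L
      best <- n_clusters
      founder_count[best] <- ucount[i]
    }
    cluster_of[i] <- best
  }

  read_cluster <- cluster_of[match(clean_reads$bases, ustr)]
  size <- tabulate(read_cluster, n_clusters)

  # founding string of each cluster is its longest member (greedy order)
  founder <- integer(n_clusters)
  for (i in rev(proc)) founder[cluster_of[i]] <- i  # earliest processed wins
  rep_bases <- ustr[founder]
  rep_id <- vapply(seq_len(n_clusters), function(cl) {
    ids <- clean_reads$read_id[read_cluster == cl &
                                 clean_reads$bases == rep_bases[cl]]
    sort(ids, method = "radix")[1]
  }, character(1))

  ord <- order(-size, rep_id, method = "radix")
  clusters <- data.frame(
    cluster_id = sprintf("cluster_%04d", seq_len(n_clusters)),
    representative_id = rep_id[ord],
    representative_bases = rep_bases[ord],
    size = size[ord],
    stringsAsFactors = FALSE
  )
  relabel <- setNames(clusters$cluster_id, as.character(ord))
  membership <- data.frame(
    read_id = clean_reads$read_id,
    cluster_id = unname(relabel[as.character(read_cluster)]),
    stringsAsFactors = FALSE
  )
  list(clusters = clusters, membership = membership)
}

#' Cluster-size histogram
#'
#' For every size class s, the number of clusters of size >= s and the
#' fraction of all reads contained in clusters of size >= s. Both series are
#' non-increasing in s and the read fraction at s = 1 is exactly 1.
#'
#' @param clusters cluster table from [cluster_identical()].
#' @return data.frame with `size_class`, `n_clusters_geq`,
#'   `read_fraction_geq`.
#' @export
size_histogram <- function(clusters) {
  if (nrow(clusters) == 0L) stop("need >= 1 cluster", call. = FALSE)
  total <- sum(clusters$size)
  s <- sort(unique(c(1L, clusters$size)))
  data.frame(
    size_class = s,
    n_clusters_geq = vapply(s, function(x) sum(clusters$size >= x), integer(1)),
    read_fraction_geq = vapply(s, function(x) {
      sum(clusters$size[clusters$size >= x]) / total
    }, numeric(1))
  )
}

#' Select reference sequences by the histogram cut-off rule
#'
#' Size classes are scanned from largest to smallest; a class is admitted
#' while the marginal gain in total read fraction is at least
#' `asymptote_gain` (the asymptote rule: stop once admitting the next smaller
#' class adds less than that fraction of reads). If the scan completes
#' without reaching an asymptote, all clusters with size >= `min_cluster_size`
#' are kept instead (the fallback used when the read-fraction curve shows no
#' asymptote). Setting `asymptote_gain = 0` disables the stop rule and always
#' exercises the fallback. Representatives of kept clusters become the
#' reference sequences.
#'
#' @param clusters cluster table from [cluster_identical()].
#' @param histogram optional precomputed [size_histogram()].
#' @param min_cluster_size fallback minimum cluster size (default 10 reads).
#' @param asymptote_gain marginal read-fraction threshold (default 0.01).
#' @return data.frame with `reference_id`, `bases`, `source_cluster_size`;
#'   attribute `asymptote` records whether the stop rule fired. An empty
#'   selection (all clusters below the minimum size) returns a zero-row table
#'   with attribute `empty_selection = TRUE` and a warning.
#' @export
select_references <- function(clusters, histogram = NULL, min_cluster_size = 10,
                              asymptote_gain = 0.01) {
  if (is.null(histogram)) histogram <- size_histogram(clusters)
  total <- sum(clusters$size)
  cls <- sort(unique(clusters$size), decreasing = TRUE)
  asymptote <- FALSE
  min_admitted <- cls[1]
  if (length(cls) > 1L) {
    for (cc in cls[-1L]) {
      gain <- sum(clusters$size[clusters$size == cc]) / total
      if (gain < asymptote_gain) { asymptote <- TRUE; break }
      min_admitted <- cc
    }
  }
  keep_min <- if (asymptote) min_admitted else min_cluster_size
  kept <- clusters[clusters$size >= keep_min, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no clusters reach the minimum size; empty reference set",
            call. = FALSE)
    out <- data.frame(reference_id = character(0), bases = character(0),
                      source_cluster_size = integer(0), stringsAsFactors = FALSE)
    attr(out, "empty_selection") <- TRUE
    attr(out, "asymptote") <- asymptote
    return(out)
  }
  kept <- kept[order(-kept$size, kept$representative_id, method = "radix"), ]
  out <- data.frame(
    reference_id = sprintf("ref_%03d", seq_len(nrow(kept))),
    bases = kept$representative_bases,
    source_cluster_size = kept$size,
    stringsAsFactors = FALSE
  )
  attr(out, "asymptote") <- asymptote
  attr(out, "min_size_kept") <- keep_min
  out
}

# Is the difference between two aligned strings exactly one gap run whose
# inserted/deleted bases extend a homopolymer?
homopolymer_indel_only <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  gap <- a == "-" | b == "-"
  subs <- !gap & a != b
  if (any(subs)) return(FALSE)
  if (!any(gap)) return(FALSE)
  r <- rle(gap)
  if (sum(r$values) != 1L) return(FALSE)  # exactly one gap run
  ends <- cumsum(r$lengths)
  i <- which(r$values)
  run <- (ends[i] - r$lengths[i] + 1L):ends[i]
  other <- ifelse(a[run] == "-", b[run], a[run])
  ch <- unique(other)
  if (length(ch) != 1L) return(FALSE)
  before <- if (min(run) > 1L) a[min(run) - 1L] else NA
  after <- if (max(run) < length(a)) a[max(run) + 1L] else NA
  isTRUE(before == ch) || isTRUE(after == ch)
}

#' Screen selected references for homopolymer indel artifacts
#'
#' A reference that differs from a much larger reference (cluster at least
#' `min_ratio` times bigger) only by the length of one homopolymer run is the
#' signature of a pyrosequencing indel error and is dropped.
#'
#' @param references reference table from [select_references()].
#' @param min_ratio size ratio for the larger partner (default 10).
#' @return list with `kept` (reference table) and `dropped` (data.frame of
#'   `reference_id`, `matched_reference`).
#' @export
vet_references <- function(references, min_ratio = 10) {
  n <- nrow(references)
  drop <- logical(n)
  matched <- character(n)
  if (n > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || drop[i]) next
        if (references$source_cluster_size[j] <
            min_ratio * references$source_cluster_size[i]) next
        al <- align_pair(references$bases[i], references$bases[j])
        if (homopolymer_indel_only(al$aligned_a, al$aligned_b)) {
          drop[i] <- TRUE
          matched[i] <- references$reference_id[j]
        }
      }
    }
  }
  kept <- references[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "asymptote") <- attr(references, "asymptote")
  list(
    kept = kept,
    dropped = data.frame(reference_id = references$reference_id[drop],
                         matched_reference = matched[drop],
                         stringsAsFactors = FALSE)
  )
}
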