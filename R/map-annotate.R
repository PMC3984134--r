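# Annotation of reference sequences to symbiont type via a curated panel
# (with diagnostic-SNP tie-breaking), pruning of the reference library using
# known-dominant samples, and per-type consensus building.

#' Construct a curated type reference panel
#'
#' @param entries data.frame with `type_name` (unique) and `bases`, one
#'   curated sequence per type.
#' @param diagnostic_sites optional data.frame with `panel_id` (the panel
#'   type the position is counted on), `position` (1-based), `base`, and
#'   `type_name`: single-nucleotide states that discriminate otherwise
#'   near-identical types (e.g. C at 212 for C1, T for C3).
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(entries, diagnostic_sites = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("type_name", "bases") %in% names(entries)))
  if (nrow(entries) == 0L) stop("panel must be non-empty", call. = FALSE)
  if (anyDuplicated(entries$type_name)) {
    stop("panel type names must be unique", call. = FALSE)
  }
  if (!is.null(diagnostic_sites)) {
    stopifnot(all(c("panel_id", "position", "base", "type_name") %in%
                    names(diagnostic_sites)))
    for (key in unique(paste(diagnostic_sites$panel_id, diagnostic_sites$position))) {
      rows <- diagnostic_sites[paste(diagnostic_sites$panel_id,
                                     diagnostic_sites$position) == key, ]
      if (anyDuplicated(rows$base)) {
        stop("diagnostic-site bases must be distinct", call. = FALSE)
      }
    }
  }
  structure(list(entries = entries, diagnostic_sites = diagnostic_sites),
            class = "reference_panel")
}

#' Derive a reference panel from simulated type genomes
#'
#' Uses each genome's first (major) variant as the curated panel sequence and
#' carries over the simulator's diagnostic SNP, if any.
#'
#' @param genomes a panel from [build_type_panel()].
#' @return a `reference_panel`.
#' @export
panel_from_genomes <- function(genomes) {
  entries <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(type_name = g$type_name, bases = g$variants$bases[1],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  ds <- attr(genomes, "diagnostic_site")
  diagnostic_sites <- if (!is.null(ds)) {
    data.frame(panel_id = ds$bases[[1]], position = ds$position,
               base = names(ds$bases), type_name = unname(ds$bases),
               stringsAsFactors = FALSE)
  } else NULL
  reference_panel(entries, diagnostic_sites)
}

#' Write a reference panel to disk
#'
#' @param panel a `reference_panel`.
#' @param fasta_path FASTA path for panel sequences (named by type).
#' @param sites_path optional TSV path for diagnostic sites.
#' @return invisibly, the paths written.
#' @export
write_reference_panel <- function(panel, fasta_path, sites_path = NULL) {
  write_fasta(panel$entries$type_name, panel$entries$bases, fasta_path)
  if (!is.null(sites_path) && !is.null(panel$diagnostic_sites)) {
    write_tsv_file(panel$diagnostic_sites, sites_path)
  }
  invisible(list(fasta = fasta_path, sites = sites_path))
}

#' Read a reference panel from disk
#'
#' @param fasta_path panel FASTA (sequence names are type names).
#' @param sites_path optional diagnostic-site TSV.
#' @return a `reference_panel`.
#' @export
read_reference_panel <- function(fasta_path, sites_path = NULL) {
  fa <- read_fasta(fasta_path)
  sites <- if (!is.null(sites_path) && file.exists(sites_path)) {
    read_tsv_file(sites_path)
  } else NULL
  reference_panel(data.frame(type_name = fa$id, bases = fa$bases,
                             stringsAsFactors = FALSE), sites)
}

# Base of `aligned_other` at panel position `pos` of `aligned_panel`.
base_at_panel_position <- function(aligned_panel, aligned_other, pos) {
  p <- strsplit(aligned_panel, "")[[1]]
  o <- strsplit(aligned_other, "")[[1]]
  non_gap <- cumsum(p != "-")
  col <- which(non_gap == pos & p != "-")[1]
  if (is.na(col)) NA_character_ else o[col]
}

#' Annotate reference sequences to type
#'
#' Each reference is aligned to every panel sequence (free end gaps, so
#' truncated references are not penalized) and assigned the type of highest
#' percent identity. Hits within `tie_margin` percentage points of the best
#' are treated as tied and resolved, in order, by (1) the reference's base at
#' a configured diagnostic site when the tied types are covered by one (C at
#' position 212 means C1, T means C3 -- so every reference carrying the
#' diagnostic state is annotated by it even when sequencing errors shift raw
#' identity slightly), then (2) a unique best alignment score; references
#' still tied are flagged for manual review. References below
#' `floor_identity` against every panel entry are flagged unannotated.
#'
#' @param references reference table (`reference_id`, `bases`).
#' @param panel a `reference_panel`.
#' @param floor_identity minimum percent identity for any annotation
#'   (default 70).
#' @param tie_margin identity margin (percentage points) within which top
#'   hits count as tied (default 0.5, about one mismatch on a 300 bp
#'   amplicon).
#' @return data.frame with `reference_id`, `type_name`, `percent_identity`,
#'   `tie_break_used` (none/diagnostic_site/score) and `flag`
#'   (ok/manual_review/unannotated).
#' @export
annotate_references <- function(references, panel, floor_identity = 70,
                                tie_margin = 0.5) {
  stopifnot(inherits(panel, "reference_panel"))
  np <- nrow(panel$entries)
  out <- lapply(seq_len(nrow(references)), function(i) {
    alns <- lapply(panel$entries$bases, function(pb) {
      align_pair(references$bases[i], pb, type = "overlap")
    })
    ident <- vapply(alns, function(a) aligned_identity(a$aligned_a, a$aligned_b),
                    numeric(1))
    score <- vapply(alns, `[[`, numeric(1), "score")
    best_ident <- max(ident)
    if (best_ident < floor_identity) {
      return(data.frame(reference_id = references$reference_id[i],
                        type_name = NA_character_, percent_identity = best_ident,
                        tie_break_used = "none", flag = "unannotated",
                        stringsAsFactors = FALSE))
    }
    tied <- which(ident >= best_ident - tie_margin)
    tie_break <- "none"
    flag <- "ok"
    pick <- tied[1]
    if (length(tied) > 1L) {
      tied_types <- panel$entries$type_name[tied]
      resolved <- FALSE
      ds <- panel$diagnostic_sites
      if (!is.null(ds)) {
        for (key in unique(paste(ds$panel_id, ds$position))) {
          rows <- ds[paste(ds$panel_id, ds$position) == key, ]
          if (!all(tied_types %in% rows$type_name)) next
          anchor <- match(rows$panel_id[1], panel$entries$type_name)
          if (is.na(anchor)) next
          al <- alns[[anchor]]
          b <- base_at_panel_position(al$aligned_b, al$aligned_a, rows$position[1])
          hit <- match(b, rows$base)
          if (!is.na(hit)) {
            pick <- tied[match(rows$type_name[hit], tied_types)]
            tie_break <- "diagnostic_site"
            resolved <- TRUE
            break
          }
        }
      }
      if (!resolved) {
        sc <- score[tied]
        if (sum(sc == max(sc)) == 1L) {
          pick <- tied[which.max(sc)]
          tie_break <- "score"
        } else {
          flag <- "manual_review"
          pick <- tied[1]
        }
      }
    }
    data.frame(reference_id = references$reference_id[i],
               type_name = if (flag == "manual_review") NA_character_ else
                 panel$entries$type_name[pick],
               percent_identity = best_ident,
               tie_break_used = tie_break, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Normalize designs (list of mixture_design or long data.frame) to a long
# table sample_id / type_name / cell_fraction.
as_design_table <- function(designs) {
  if (is.data.frame(designs)) {
    stopifnot(all(c("sample_id", "type_name", "cell_fraction") %in% names(designs)))
    designs
  } else {
    design_table(designs)
  }
}

# Normalize counts (long data.frame or matrix) to a samples x references
# integer matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(all(c("sample_id", "reference_id", "count") %in% names(counts)))
  samples <- unique(counts$sample_id)
  refs <- unique(counts$reference_id)
  m <- matrix(0L, length(samples), length(refs),
              dimnames = list(samples, refs))
  m[cbind(match(counts$sample_id, samples),
          match(counts$reference_id, refs))] <- as.integer(counts$count)
  m
}

#' Prune the reference library using known-dominant samples
#'
#' A sample whose design places a type at >= `high_threshold` must contain
#' every genuine reference of that type. A reference with zero mapped reads
#' in any such sample of its own type is a false positive and is removed; the
#' log records the triggering sample. Types with no high-abundance sample in
#' the design keep all their references (with a warning).
#'
#' @param references reference table.
#' @param annotations annotation table from [annotate_references()].
#' @param counts mapped read counts: samples x references matrix, or long
#'   data.frame (`sample_id`, `reference_id`, `count`).
#' @param designs mixture designs (list or long table).
#' @param high_threshold design fraction defining a known-dominant sample
#'   (default 0.85).
#' @return list with `kept` (pruned reference table) and `removed`
#'   (data.frame `reference_id`, `type_name`, `sample_id`).
#' @export
prune_references <- function(references, annotations, counts, designs,
                             high_threshold = 0.85) {
  if (nrow(references) == 0L) {
    return(list(kept = references,
                removed = data.frame(reference_id = character(0),
                                     type_name = character(0),
                                     sample_id = character(0),
                                     stringsAsFactors = FALSE)))
  }
  dt <- as_design_table(designs)
  cm <- as_count_matrix(counts)
  ann_type <- annotations$type_name[match(references$reference_id,
                                          annotations$reference_id)]
  removed <- list()
  keep <- rep(TRUE, nrow(references))
  warned_types <- character(0)
  for (i in seq_len(nrow(references))) {
    ty <- ann_type[i]
    if (is.na(ty)) next
    high <- dt$sample_id[dt$type_name == ty & dt$cell_fraction >= high_threshold]
    high <- intersect(high, rownames(cm))
    if (length(high) == 0L) {
      if (!(ty %in% warned_types)) {
        warning("no high-abundance sample for type ", ty,
                "; its references are kept", call. = FALSE)
        warned_types <- c(warned_types, ty)
      }
      next
    }
    rid <- references$reference_id[i]
    cnt <- if (rid %in% colnames(cm)) cm[high, rid] else rep(0L, length(high))
    if (any(cnt == 0L)) {
      keep[i] <- FALSE
      removed[[length(removed) + 1L]] <- data.frame(
        reference_id = rid, type_name = ty,
        sample_id = high[which(cnt == 0L)[1]],
        stringsAsFactors = FALSE)
    }
  }
  kept <- references[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    kept = kept,
    removed = if (length(removed) > 0L) do.call(rbind, removed) else
      data.frame(reference_id = character(0), type_name = character(0),
                 sample_id = character(0), stringsAsFactors = FALSE)
  )
}

#' Per-type consensus sequence
#'
#' Builds a star alignment of a type's references around the reference from
#' the largest source cluster and takes the per-column majority. Columns
#' where gaps and bases tie are decided by majority presence, exact ties
#' resolved toward the anchor (largest-cluster) reference. The consensus is
#' for reporting and annotation; mapping continues against the original
#' references so haplotype resolution is preserved.
#'
#' @param bases character vector of the type's reference sequences.
#' @param source_cluster_size optional cluster sizes (defaults to equal).
#' @return consensus sequence (no gaps).
#' @export
type_consensus <- function(bases, source_cluster_size = NULL) {
  n <- length(bases)
  if (n == 0L) stop("need >= 1 reference", call. = FALSE)
  if (n == 1L) return(bases)
  sizes <- source_cluster_size %||% rep(1L, n)
  anchor <- which.max(sizes)
  anchor_seq <- bases[anchor]
  la <- nchar(anchor_seq)

  # per sequence: main-column chars over anchor positions + insertions keyed
  # by (anchor position after which they occur, offset)
  mains <- matrix("-", n, la)
  inserts <- list()
  for (s in seq_len(n)) {
    if (s == anchor) {
      mains[s, ] <- strsplit(anchor_seq, "")[[1]]
      next
    }
    al <- align_pair(anchor_seq, bases[s])
    a <- strsplit(al$aligned_a, "")[[1]]
    b <- strsplit(al$aligned_b, "")[[1]]
    pos <- 0L
    k <- 0L
    for (col in seq_along(a)) {
      if (a[col] != "-") {
        pos <- pos + 1L
        k <- 0L
        mains[s, pos] <- b[col]
      } else {
        k <- k + 1L
        key <- sprintf("%06d.%03d", pos, k)
        if (is.null(inserts[[key]])) inserts[[key]] <- rep("-", n)
        inserts[[key]][s] <- b[col]
      }
    }
  }

  pick_column <- function(chars, anchor_char) {
    n_base <- sum(chars != "-")
    n_gap <- sum(chars == "-")
    use_base <- n_base > n_gap || (n_base == n_gap && anchor_char != "-")
    if (!use_base) return("")
    tab <- table(chars[chars != "-"])
    top <- names(tab)[tab == max(tab)]
    if (anchor_char %in% top) anchor_char else sort(top)[1]
  }

  cols <- character(0)
  ins_keys <- if (length(inserts) > 0L) sort(names(inserts)) else character(0)
  for (p in 0:la) {
    if (p > 0L) {
      cols <- c(cols, pick_column(mains[, p], mains[anchor, p]))
    }
    here <- ins_keys[startsWith(ins_keys, sprintf("%06d.", p))]
    for (key in here) {
      cols <- c(cols, pick_column(inserts[[key]], "-"))
    }
  }
  paste(cols, collapse = "")
}
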