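# Mock-community amplicon read simulator.
#
# Emulates a dilution-series experiment: a small panel of symbiont types, each
# with intra-genomic rDNA variants carried at fixed copy fractions and a
# per-cell rDNA copy number, mixed at known cell fractions, amplified and
# sequenced with pyrosequencing-style errors (substitutions plus +/-1 indels
# in homopolymer runs) and variable read lengths. Every read carries a truth
# label (template type and variant) so downstream stages can be validated
# against known composition.

#' Construct a symbiont type genome
#'
#' A type genome is the simulator's ground truth for one symbiont type: its
#' intra-genomic rDNA variant sequences, the fraction of the genome's rDNA
#' copies carrying each variant, and the total rDNA copy number per cell.
#'
#' @param type_name type label (e.g. "C1").
#' @param variants data.frame with columns `variant_id`, `bases`,
#'   `copy_fraction`.
#' @param copy_number rDNA copies per cell (integer >= 1).
#' @return object of class `type_genome`.
#' @export
type_genome <- function(type_name, variants, copy_number) {
  stopifnot(is.character(type_name), length(type_name) == 1L)
  if (!is.data.frame(variants) ||
      !all(c("variant_id", "bases", "copy_fraction") %in% names(variants))) {
    stop("`variants` needs columns variant_id, bases, copy_fraction", call. = FALSE)
  }
  if (nrow(variants) < 1L) stop("need >= 1 variant", call. = FALSE)
  if (anyDuplicated(variants$variant_id)) stop("variant ids must be unique", call. = FALSE)
  if (any(nchar(variants$bases) == 0L)) stop("variant bases must be non-empty", call. = FALSE)
  if (any(variants$copy_fraction <= 0 | variants$copy_fraction > 1)) {
    stop("copy fractions must be in (0, 1]", call. = FALSE)
  }
  if (abs(sum(variants$copy_fraction) - 1) > 1e-9) {
    stop("variant copy fractions must sum to 1", call. = FALSE)
  }
  stopifnot_scalar_number(copy_number, "copy_number", min = 1)
  structure(
    list(type_name = type_name, variants = variants,
         copy_number = as.integer(copy_number)),
    class = "type_genome"
  )
}

#' @export
print.type_genome <- function(x, ...) {
  cat(sprintf("<type_genome> %s: %d variant(s), copy number %d\n",
              x$type_name, nrow(x$variants), x$copy_number))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_base <- function(chars, pos, to = NULL) {
  for (p in pos) {
    cur <- chars[p]
    chars[p] <- if (is.null(to)) sample(setdiff(c("A", "C", "G", "T"), cur), 1L) else to
  }
  chars
}

#' Build a panel of type genomes for simulation
#'
#' Generates `n_types` divergent type genomes from a common random root
#' sequence. With four or more types, the third and fourth types form a
#' near-identical pair separated by exactly one substitution at
#' `diagnostic_position` (C in the third type, T in the fourth), emulating
#' type pairs such as C1/C3 that differ by a single diagnostic SNP; all other
#' type pairs differ at >= `divergence_between_types` of positions. Within a
#' type, additional variants carry a small number of substitutions so that any
#' two variants differ by at most `divergence_within_type` substitutions.
#'
#' @param n_types number of types (default 4: A13, D1, C1, C3).
#' @param n_variants_per_type intra-genomic variants per type.
#' @param seq_length amplicon insert length (>= 200).
#' @param divergence_between_types minimum between-type divergence as a
#'   fraction of positions.
#' @param divergence_within_type maximum pairwise substitutions between
#'   variants of one type (0 only with a single variant per type).
#' @param copy_numbers per-type rDNA copy number vector (recycled; default
#'   1000 for every type).
#' @param diagnostic_position 1-based position of the diagnostic SNP.
#' @param seed RNG seed; runs are byte-identical for a fixed seed.
#' @return list of `type_genome` objects with attributes `diagnostic_site`
#'   (list of `position` and base-to-type `bases` map) and `seq_length`.
#' @export
build_type_panel <- function(n_types = 4, n_variants_per_type = 4,
                             seq_length = 300,
                             divergence_between_types = 0.10,
                             divergence_within_type = 2,
                             copy_numbers = NULL,
                             diagnostic_position = 212,
                             seed = 1) {
  stopifnot_scalar_number(n_types, "n_types", min = 1)
  stopifnot_scalar_number(n_variants_per_type, "n_variants_per_type", min = 1)
  stopifnot_scalar_number(seq_length, "seq_length", min = 200)
  k <- ceiling(divergence_between_types * seq_length)
  if (divergence_within_type >= k) {
    stop("divergence_within_type must be smaller than between-type divergence",
         call. = FALSE)
  }
  if (n_variants_per_type > 1L && divergence_within_type < 1) {
    stop("multiple variants per type require divergence_within_type >= 1", call. = FALSE)
  }
  if (n_variants_per_type > 2L && divergence_within_type < 2) {
    stop("more than two variants per type require divergence_within_type >= 2",
         call. = FALSE)
  }
  if (diagnostic_position < 1 || diagnostic_position > seq_length) {
    stop("diagnostic_position outside the sequence", call. = FALSE)
  }
  copy_numbers <- copy_numbers %||% 1000L
  copy_numbers <- rep_len(as.integer(copy_numbers), n_types)

  base_names <- c("A13", "D1", "C1", "C3")
  type_names <- if (n_types <= 4L) base_names[seq_len(n_types)] else {
    c(base_names, sprintf("T%d", seq(5L, n_types)))
  }
  has_diag_pair <- n_types >= 4L

  with_seed(seed, {
    root <- strsplit(random_dna(seq_length), "")[[1]]
    # positions reserved for between-type divergence, never used within types
    pool <- setdiff(seq_len(seq_length), diagnostic_position)
    non_diag <- if (has_diag_pair) setdiff(seq_len(n_types), c(3L, 4L)) else seq_len(n_types)
    sizes <- integer(n_types)
    if (length(non_diag) > 0L) {
      sizes[non_diag[1L]] <- 2L * k  # first (A13-like) type is most divergent
      if (length(non_diag) > 1L) sizes[non_diag[-1L]] <- k
    }
    if (sum(sizes) > length(pool)) {
      stop("sequence too short for the requested between-type divergence", call. = FALSE)
    }
    picked <- sample(pool, sum(sizes))
    offsets <- c(0L, cumsum(sizes))
    type_bases <- vector("list", n_types)
    used <- integer(0)
    for (i in seq_len(n_types)) {
      chars <- root
      if (sizes[i] > 0L) {
        pos <- picked[(offsets[i] + 1L):offsets[i + 1L]]
        chars <- substitute_base(chars, pos)
        used <- c(used, pos)
      }
      type_bases[[i]] <- chars
    }
    if (has_diag_pair) {
      type_bases[[3L]][diagnostic_position] <- "C"
      type_bases[[4L]][diagnostic_position] <- "T"
    }

    n_sub <- max(1L, divergence_within_type %/% 2L)
    within_pool <- setdiff(pool, used)
    genomes <- vector("list", n_types)
    for (i in seq_len(n_types)) {
      v <- n_variants_per_type
      bases <- character(v)
      bases[1L] <- paste(type_bases[[i]], collapse = "")
      if (v > 1L) {
        vpos <- sample(within_pool, n_sub * (v - 1L))
        for (j in 2:v) {
          pos <- vpos[((j - 2L) * n_sub + 1L):((j - 1L) * n_sub)]
          bases[j] <- paste(substitute_base(type_bases[[i]], pos), collapse = "")
        }
      }
      w <- rev(seq_len(v))
      genomes[[i]] <- type_genome(
        type_names[i],
        data.frame(
          variant_id = paste0(type_names[i], "_", letters[seq_len(v)]),
          bases = bases,
          copy_fraction = w / sum(w),
          stringsAsFactors = FALSE
        ),
        copy_numbers[i]
      )
    }
    names(genomes) <- type_names
    diag_site <- if (has_diag_pair) {
      list(position = as.integer(diagnostic_position),
           bases = c(C = type_names[3L], T = type_names[4L]))
    } else NULL
    structure(genomes, diagnostic_site = diag_site, seq_length = seq_length,
              class = c("type_panel", "list"))
  })
}

#' Flatten a genome panel into a variant table
#'
#' @param genomes list of `type_genome` objects.
#' @return data.frame with one row per variant: `type_name`, `variant_id`,
#'   `bases`, `copy_fraction`, `copy_number`.
#' @export
variant_table <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    data.frame(type_name = g$type_name, g$variants,
               copy_number = g$copy_number,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Construct a mixture design
#'
#' @param sample_id sample label.
#' @param cell_fractions named numeric vector of per-type cell fractions,
#'   summing to 1.
#' @param total_cells combined cell density per sample (default 1e6 cells).
#' @param read_depth requested number of reads.
#' @param pcr_cycles PCR cycle count, carried as metadata only.
#' @return object of class `mixture_design`.
#' @export
mixture_design <- function(sample_id, cell_fractions, total_cells = 1e6,
                           read_depth = 10000, pcr_cycles = 23) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (is.null(names(cell_fractions)) || any(names(cell_fractions) == "")) {
    stop("cell_fractions must be named by type", call. = FALSE)
  }
  if (any(cell_fractions < 0)) stop("cell fractions must be >= 0", call. = FALSE)
  if (abs(sum(cell_fractions) - 1) > 1e-9) {
    stop("cell fractions must sum to 1", call. = FALSE)
  }
  stopifnot_scalar_number(read_depth, "read_depth", min = 1)
  structure(
    list(sample_id = sample_id, cell_fractions = cell_fractions,
         total_cells = total_cells, read_depth = as.integer(read_depth),
         pcr_cycles = as.integer(pcr_cycles)),
    class = "mixture_design"
  )
}

#' Expected read fractions under copy-number weighting
#'
#' The fraction of reads expected from type t is
#' `f_t = c_t * n_t / sum_u(c_u * n_u)` where `c` is the cell fraction and `n`
#' the per-cell rDNA copy number: types with more rDNA copies contribute
#' disproportionately many amplicons, which is the mechanism invoked for
#' copy-number quantification bias.
#'
#' @param design a `mixture_design`.
#' @param genomes list of `type_genome` objects covering every design type.
#' @return named numeric vector of read fractions summing to 1.
#' @export
expected_read_fractions <- function(design, genomes) {
  types <- names(design$cell_fractions)
  gnames <- vapply(genomes, function(g) g$type_name, character(1))
  missing <- setdiff(types, gnames)
  if (length(missing) > 0L) {
    stop("design types absent from genomes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cn <- vapply(types, function(t) genomes[[match(t, gnames)]]$copy_number, numeric(1))
  w <- design$cell_fractions * cn
  if (sum(w) <= 0) stop("all template weights are zero", call. = FALSE)
  w / sum(w)
}

#' Pyrosequencing-style error model
#'
#' @param substitution_rate per-base substitution probability.
#' @param homopolymer_indel_rate per-homopolymer-run (length >= 2) probability
#'   of a +/-1 length change, the dominant 454 error class.
#' @param length_mean,length_sd read-length distribution (normal, rounded);
#'   `length_mean = Inf` disables truncation.
#' @param length_min minimum read length (reads are never truncated below it).
#' @param seed RNG seed for the simulation.
#' @return object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.001,
                        homopolymer_indel_rate = 0.002,
                        length_mean = 320, length_sd = 40, length_min = 150,
                        seed = 1) {
  stopifnot_scalar_number(substitution_rate, "substitution_rate", 0, 1)
  stopifnot_scalar_number(homopolymer_indel_rate, "homopolymer_indel_rate", 0, 1)
  stopifnot_scalar_number(length_min, "length_min", min = 1)
  structure(
    list(substitution_rate = substitution_rate,
         homopolymer_indel_rate = homopolymer_indel_rate,
         length_mean = length_mean, length_sd = length_sd,
         length_min = length_min, seed = as.integer(seed)),
    class = "error_model"
  )
}

#' Error-free, truncation-free model
#'
#' Convenience model for validation runs: reads are exact copies of their
#' template variants.
#'
#' @param seed RNG seed (template sampling remains stochastic).
#' @return an `error_model`.
#' @export
zero_error_model <- function(seed = 1) {
  error_model(0, 0, length_mean = Inf, length_sd = 0, seed = seed)
}

#' Amplicon PCR primers used by default in simulations
#'
#' The standard ITS-2 primer pair (ITS2-F/ITS2-R) targeting the ~350 bp ITS-2
#' region of Symbiodinium.
#'
#' @return list with `forward` and `reverse` primer sequences.
#' @export
its2_primers <- function() {
  list(forward = "GTGAATTGCAGAACTCCGTG", reverse = "CCTCCGCTTACTTATATGCTT")
}

# Homopolymer runs (length >= 2) of a character vector; data.frame of
# start, length, char in string coordinates.
homopolymer_runs <- function(chars) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 2L
  data.frame(start = starts[keep], length = r$lengths[keep],
             char = r$values[keep], stringsAsFactors = FALSE)
}

# Tail-degraded quality profile: constant high score with a linear decline
# over the final bases, encoded Phred+33.
quality_string <- function(len, high = 38L, low = 22L, tail = 60L) {
  n_tail <- min(tail, len)
  q <- c(rep(high, len - n_tail),
         round(seq(high, low, length.out = n_tail)))
  int_to_phred(q)
}

#' Simulate reads for one mixture sample
#'
#' Each read draws a template (type, variant) with probability proportional to
#' cell fraction x copy number x copy fraction, then acquires per-base
#' substitutions, +/-1 indels in homopolymer runs of the insert, and is
#' truncated to a sampled length (never below `length_min`). When a barcode
#' and primers are supplied the assembled read is
#' barcode + forward primer + insert + reverse-complemented reverse primer,
#' mirroring the library structure the preprocessing stage expects.
#' Substitutions apply across the whole assembled read; indels are confined to
#' the insert so that barcode/primer coordinates stay fixed.
#'
#' @param design a `mixture_design`.
#' @param genomes list of `type_genome` objects.
#' @param model an `error_model`; its `seed` makes the sample reproducible.
#' @param barcode sample barcode prepended to every read ("" for none).
#' @param primer_forward,primer_reverse PCR primers (NULL for none).
#' @return object of class `sim_sample`: list with `sample_id`, `reads`
#'   (read_id, bases, qualities, barcode), `truth` (read_id, type_name,
#'   variant_id) and the `design`.
#' @export
simulate_reads <- function(design, genomes, model = error_model(),
                           barcode = "", primer_forward = NULL,
                           primer_reverse = NULL) {
  if (length(design$cell_fractions) == 0L) stop("empty design", call. = FALSE)
  vt <- variant_table(genomes)
  cf <- design$cell_fractions[match(vt$type_name, names(design$cell_fractions))]
  cf[is.na(cf)] <- 0
  w <- cf * vt$copy_number * vt$copy_fraction
  if (sum(w) <= 0) stop("all template weights are zero", call. = FALSE)

  prefix <- paste0(barcode, primer_forward %||% "")
  suffix <- if (is.null(primer_reverse)) "" else revcomp(primer_reverse)
  templates <- paste0(prefix, vt$bases, suffix)
  n_prefix <- nchar(prefix)
  insert_len <- nchar(vt$bases)

  n <- design$read_depth
  with_seed(model$seed, {
    tpl <- sample.int(nrow(vt), n, replace = TRUE, prob = w)
    bases <- character(n)
    read_len <- integer(n)
    for (u in unique(tpl)) {
      idx <- which(tpl == u)
      full <- templates[u]
      lfull <- nchar(full)
      nt <- length(idx)
      lens <- if (!is.finite(model$length_mean)) rep(lfull, nt) else {
        pmin(lfull, pmax(model$length_min,
                         round(rnorm(nt, model$length_mean, model$length_sd))))
      }
      nsub <- rbinom(nt, lfull, model$substitution_rate)
      chars0 <- strsplit(full, "")[[1]]
      runs <- homopolymer_runs(chars0[(n_prefix + 1L):(n_prefix + insert_len[u])])
      if (nrow(runs) > 0L) runs$start <- runs$start + n_prefix
      nind <- if (nrow(runs) > 0L) {
        rbinom(nt, nrow(runs), model$homopolymer_indel_rate)
      } else integer(nt)
      plain <- nsub == 0L & nind == 0L
      if (any(plain)) bases[idx[plain]] <- substring(full, 1L, lens[plain])
      for (j in which(!plain)) {
        chars <- chars0
        if (nsub[j] > 0L) {
          chars <- substitute_base(chars, sample.int(lfull, nsub[j]))
        }
        if (nind[j] > 0L) {
          hit <- sort(sample.int(nrow(runs), nind[j]), decreasing = TRUE)
          for (h in hit) {
            if (runif(1) < 0.5 && runs$length[h] >= 2L) {
              chars <- chars[-runs$start[h]]                       # -1 base
            } else {
              chars <- append(chars, runs$char[h], after = runs$start[h])  # +1
            }
          }
        }
        seq_j <- paste(chars, collapse = "")
        bases[idx[j]] <- substring(seq_j, 1L, min(nchar(seq_j), lens[j]))
      }
      read_len[idx] <- nchar(bases[idx])
    }
    qual_by_len <- vapply(sort(unique(read_len)), quality_string, character(1))
    names(qual_by_len) <- sort(unique(read_len))
    reads <- data.frame(
      read_id = sprintf("%s_r%06d", design$sample_id, seq_len(n)),
      bases = bases,
      qualities = unname(qual_by_len[as.character(read_len)]),
      barcode = barcode,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      read_id = reads$read_id,
      type_name = vt$type_name[tpl],
      variant_id = vt$variant_id[tpl],
      stringsAsFactors = FALSE
    )
    structure(list(sample_id = design$sample_id, reads = reads, truth = truth,
                   design = design),
              class = "sim_sample")
  })
}

#' Sample barcodes with guaranteed pairwise separation
#'
#' Greedy draw of fixed-length barcodes with pairwise Hamming distance >=
#' `min_dist`, so single-error reads still demultiplex uniquely.
#'
#' @param n number of barcodes.
#' @param length barcode length.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed RNG seed.
#' @return character vector of barcodes.
#' @export
make_barcodes <- function(n, length = 8, min_dist = 3, seed = 1) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- random_dna(length)
      ok <- all(vapply(out, function(b) {
        sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]]) >= min_dist
      }, logical(1)))
      if (ok) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 10000L) stop("could not find enough separated barcodes", call. = FALSE)
    }
    out
  })
}

#' The 15-sample dilution-series design
#'
#' Four types (A13, D1, C1, C3) mixed so that each type appears as the
#' dominant member at 99.7%, 97% and 85% against the other three at 0.1%, 1%
#' and 5% respectively, plus pure (100%) samples of the first three types.
#' Combined density is 1e6 cells per sample.
#'
#' @param read_depth requested reads per sample.
#' @param total_cells combined cell count per sample.
#' @return list of 15 `mixture_design` objects.
#' @export
dilution_designs <- function(read_depth = 10000, total_cells = 1e6) {
  types <- c("A13", "D1", "C1", "C3")
  rows <- list(
    c(99.7, 0.1, 0.1, 0.1), c(0.1, 99.7, 0.1, 0.1),
    c(0.1, 0.1, 99.7, 0.1), c(0.1, 0.1, 0.1, 99.7),
    c(97, 1, 1, 1), c(1, 97, 1, 1), c(1, 1, 97, 1), c(1, 1, 1, 97),
    c(85, 5, 5, 5), c(5, 85, 5, 5), c(5, 5, 85, 5), c(5, 5, 5, 85),
    c(100, 0, 0, 0), c(0, 100, 0, 0), c(0, 0, 100, 0)
  )
  cycles <- c(23, 23, 23, 23, 23, 22, 22, 23, 24, 22, 23, 23, 24, 23, 24)
  lapply(seq_along(rows), function(i) {
    mixture_design(sprintf("sample_%02d", i),
                   setNames(rows[[i]] / 100, types),
                   total_cells = total_cells, read_depth = read_depth,
                   pcr_cycles = cycles[i])
  })
}

#' Long-format design table
#'
#' @param designs list of `mixture_design` objects.
#' @return data.frame with `sample_id`, `type_name`, `cell_fraction`.
#' @export
design_table <- function(designs) {
  do.call(rbind, lapply(designs, function(d) {
    data.frame(sample_id = d$sample_id,
               type_name = names(d$cell_fractions),
               cell_fraction = unname(d$cell_fractions),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Simulate the full dilution series
#'
#' Emits one `sim_sample` per design row, each with its own barcode and the
#' default amplicon primers, plus the barcode manifest and a machine-readable
#' truth/design table. Per-sample seeds are derived as `model$seed + sample
#' index` so the series is reproducible end to end.
#'
#' @param genomes list of `type_genome` objects containing the four design
#'   types.
#' @param model an `error_model`.
#' @param depth_per_sample reads per sample.
#' @param barcoded prepend barcodes/primers (TRUE for pipeline input; FALSE
#'   yields bare insert reads).
#' @return object of class `dilution_series`: list with `samples`, `designs`,
#'   `design_table`, `manifest`.
#' @export
make_dilution_series <- function(genomes, model = error_model(),
                                 depth_per_sample = 10000, barcoded = TRUE) {
  gnames <- vapply(genomes, function(g) g$type_name, character(1))
  need <- c("A13", "D1", "C1", "C3")
  if (!all(need %in% gnames)) {
    stop("genomes must contain the four design types ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  designs <- dilution_designs(depth_per_sample)
  primers <- its2_primers()
  bcs <- if (barcoded) make_barcodes(length(designs), seed = model$seed) else
    rep("", length(designs))
  samples <- lapply(seq_along(designs), function(i) {
    m_i <- model
    m_i$seed <- model$seed + i
    simulate_reads(designs[[i]], genomes, m_i, barcode = bcs[i],
                   primer_forward = if (barcoded) primers$forward else NULL,
                   primer_reverse = if (barcoded) primers$reverse else NULL)
  })
  manifest <- data.frame(
    barcode = bcs,
    sample_id = vapply(designs, function(d) d$sample_id, character(1)),
    fwd_primer = primers$forward, rev_primer = primers$reverse,
    stringsAsFactors = FALSE
  )
  structure(
    list(samples = samples, designs = designs,
         design_table = design_table(designs), manifest = manifest),
    class = "dilution_series"
  )
}

#' Write a simulated series to disk
#'
#' Writes a combined FASTQ of all reads, the truth table, the design table and
#' the barcode manifest as TSV.
#'
#' @param series a `dilution_series`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_dilution_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reads <- do.call(rbind, lapply(series$samples, `[[`, "reads"))
  truth <- do.call(rbind, lapply(series$samples, function(s) {
    cbind(sample_id = s$sample_id, s$truth)
  }))
  paths <- list(
    fastq = file.path(dir, "reads.fastq"),
    truth = file.path(dir, "truth.tsv"),
    design = file.path(dir, "design.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_fastq(reads, paths$fastq)
  write_tsv_file(truth, paths$truth)
  write_tsv_file(series$design_table, paths$design)
  write_tsv_file(series$manifest, paths$manifest)
  invisible(paths)
}

#' Write panel variant sequences to FASTA
#'
#' @param genomes list of `type_genome` objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(genomes, path) {
  vt <- variant_table(genomes)
  write_fasta(vt$variant_id, vt$bases, path)
}
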