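# Pipeline orchestration: configuration, stage sequencing, on-disk outputs
# and the consolidated run report with per-stage read accounting.

#' Build and validate a pipeline configuration
#'
#' Either point `reads_path`/`manifest_path`/`panel_fasta`/`design_path` at
#' existing inputs, or set `simulate` to generate a dilution series in situ.
#' Every stage parameter is surfaced here with the standard defaults: 150 bp
#' minimum length, cluster size 10, 1000 permutations and bootstrap
#' resamples, 85% known-dominant threshold.
#'
#' @param out_dir output directory for all stage outputs and the report.
#' @param seed RNG seed; mandatory, drives every stochastic stage.
#' @param reads_path FASTQ of raw reads (ignored when `simulate` is set).
#' @param manifest_path barcode manifest TSV.
#' @param panel_fasta,panel_sites curated panel FASTA + diagnostic-site TSV.
#' @param design_path mixture-design TSV (`sample_id`, `type_name`,
#'   `cell_fraction`).
#' @param simulate NULL, or a list with optional `depth` (reads/sample),
#'   `model` (an [error_model()]), `genomes` (a [build_type_panel()] result).
#' @param min_length,min_mean_quality,max_barcode_mismatches,max_primer_mismatches
#'   preprocessing parameters.
#' @param min_cluster_size,asymptote_gain reference selection parameters.
#' @param min_identity,band mapping parameters.
#' @param high_threshold known-dominant design fraction for pruning.
#' @param alpha,n_perm,n_resamples,tolerance_r,outlier_k statistics parameters.
#' @param expected_basis "cells" validates observed percentages against cell
#'   fractions; "reads" against copy-number-weighted
#'   [expected_read_fractions()] (requires simulated genomes).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            reads_path = NULL, manifest_path = NULL,
                            panel_fasta = NULL, panel_sites = NULL,
                            design_path = NULL, simulate = NULL,
                            min_length = 150, min_mean_quality = 20,
                            max_barcode_mismatches = 1,
                            max_primer_mismatches = 2,
                            min_cluster_size = 10, asymptote_gain = 0.01,
                            min_identity = 90, band = 12,
                            high_threshold = 0.85,
                            alpha = 0.05, n_perm = 1000, n_resamples = 1000,
                            tolerance_r = 0, outlier_k = 5,
                            expected_basis = c("cells", "reads")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(min_length, "min_length", min = 1)
  stopifnot_scalar_number(min_identity, "min_identity", 0, 100)
  stopifnot_scalar_number(high_threshold, "high_threshold", 0, 1)
  stopifnot_scalar_number(alpha, "alpha", 0, 1)
  stopifnot_scalar_number(asymptote_gain, "asymptote_gain", 0, 1)
  expected_basis <- match.arg(expected_basis)
  if (is.null(simulate)) {
    for (p in c(reads_path, manifest_path, panel_fasta, design_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input path missing or not found: ",
             if (is.null(p)) "(unset)" else p, call. = FALSE)
      }
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), reads_path = reads_path,
         manifest_path = manifest_path, panel_fasta = panel_fasta,
         panel_sites = panel_sites, design_path = design_path,
         simulate = simulate, min_length = min_length,
         min_mean_quality = min_mean_quality,
         max_barcode_mismatches = max_barcode_mismatches,
         max_primer_mismatches = max_primer_mismatches,
         min_cluster_size = min_cluster_size, asymptote_gain = asymptote_gain,
         min_identity = min_identity, band = band,
         high_threshold = high_threshold, alpha = alpha, n_perm = n_perm,
         n_resamples = n_resamples, tolerance_r = tolerance_r,
         outlier_k = outlier_k, expected_basis = expected_basis),
    class = "pipeline_config"
  )
}

# Long count table (sample_id, reference_id, count) from per-read assignments
# joined to their samples.
assignment_counts <- function(assignments, clean, sample_ids) {
  sid <- clean$sample_id[match(assignments$read_id, clean$read_id)]
  mapped <- assignments$status == "mapped"
  agg <- stats::aggregate(
    list(count = rep(1L, sum(mapped))),
    by = list(sample_id = sid[mapped],
              reference_id = assignments$reference_id[mapped]),
    FUN = sum)
  refs <- unique(assignments$reference_id[mapped])
  m <- matrix(0L, length(sample_ids), length(refs),
              dimnames = list(sample_ids, refs))
  m[cbind(match(agg$sample_id, sample_ids), match(agg$reference_id, refs))] <-
    agg$count
  m
}

#' Run the full typing pipeline
#'
#' Stages: (optional) simulate, preprocess, cluster and select references,
#' map, annotate, prune with known-dominant samples, re-map against the
#' pruned library, quantify, validate (detection limit, gamma, bootstrap,
#' residuals), haplotype analysis. All stage outputs and a consolidated JSON
#' report are written under `config$out_dir`. Any stage failure raises an
#' error naming the stage and leaves a `FAILED` marker next to the partial
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly (class `run_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    # ---- inputs / simulation ----------------------------------------------
    genomes <- NULL
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim <- config$simulate
      genomes <- sim$genomes %||% build_type_panel(seed = config$seed)
      model <- sim$model %||% error_model(seed = config$seed)
      series <- make_dilution_series(genomes, model,
                                     depth_per_sample = sim$depth %||% 10000)
      write_dilution_series(series, file.path(out, "simulated"))
      reads <- do.call(rbind, lapply(series$samples, `[[`, "reads"))
      reads <- reads[, c("read_id", "bases", "qualities")]
      manifest <- series$manifest
      designs <- series$design_table
      panel <- panel_from_genomes(genomes)
    } else {
      stage <- "load_inputs"
      reads <- read_fastq(config$reads_path)
      manifest <- read_manifest(config$manifest_path)
      designs <- read_tsv_file(config$design_path)
      panel <- read_reference_panel(config$panel_fasta, config$panel_sites)
    }
    sample_ids <- manifest$sample_id

    # ---- preprocess -------------------------------------------------------
    stage <- "preprocess"
    pp <- preprocess(reads, manifest,
                     max_barcode_mismatches = config$max_barcode_mismatches,
                     max_primer_mismatches = config$max_primer_mismatches,
                     min_length = config$min_length,
                     min_mean_quality = config$min_mean_quality)
    clean <- pp$clean
    jsonlite::write_json(pp$report, file.path(out, "preprocess_report.json"),
                         auto_unbox = TRUE, digits = NA)

    # ---- cluster / select -------------------------------------------------
    stage <- "cluster"
    cl <- cluster_identical(clean)
    hist <- size_histogram(cl$clusters)
    write_tsv_file(hist, file.path(out, "cluster_histogram.tsv"))
    write_tsv_file(cl$membership, file.path(out, "cluster_membership.tsv"))
    refs0 <- select_references(cl$clusters, hist,
                               min_cluster_size = config$min_cluster_size,
                               asymptote_gain = config$asymptote_gain)
    vet <- vet_references(refs0)
    refs <- vet$kept
    if (nrow(refs) == 0L) stop("empty reference set after selection")
    write_fasta(refs$reference_id, refs$bases,
                file.path(out, "references.fasta"))

    # ---- map / annotate / prune / re-map ----------------------------------
    stage <- "map"
    asn1 <- map_reads(clean, refs, min_identity = config$min_identity,
                      band = config$band)
    counts1 <- assignment_counts(asn1, clean, sample_ids)

    stage <- "annotate"
    ann <- annotate_references(refs, panel)
    write_tsv_file(ann, file.path(out, "annotations.tsv"))

    stage <- "prune"
    pr <- prune_references(refs, ann, counts1, designs,
                           high_threshold = config$high_threshold)
    write_tsv_file(pr$removed, file.path(out, "pruning_log.tsv"))
    refs_final <- pr$kept
    if (nrow(refs_final) == 0L) stop("all references pruned")
    write_fasta(refs_final$reference_id, refs_final$bases,
                file.path(out, "references_pruned.fasta"))

    stage <- "remap"
    asn <- map_reads(clean, refs_final, min_identity = config$min_identity,
                     band = config$band)
    write_tsv_file(asn, file.path(out, "assignments.tsv"))
    counts <- assignment_counts(asn, clean, sample_ids)

    # ---- quantify ---------------------------------------------------------
    stage <- "quantify"
    ann_final <- ann[ann$reference_id %in% refs_final$reference_id, ]
    ab <- normalize_and_aggregate(counts, ann_final)
    write_tsv_file(
      data.frame(sample_id = rownames(ab$type_percent),
                 round(ab$type_percent, 4), check.names = FALSE),
      file.path(out, "abundance_types.tsv"))
    write_tsv_file(
      data.frame(sample_id = rownames(ab$ref_percent),
                 round(ab$ref_percent, 4), check.names = FALSE),
      file.path(out, "abundance_references.tsv"))

    # ---- validate ---------------------------------------------------------
    stage <- "validate"
    dtab <- as_design_table(designs)
    expected_pct <- if (config$expected_basis == "reads" && !is.null(genomes)) {
      do.call(rbind, lapply(split(dtab, dtab$sample_id), function(d) {
        des <- mixture_design(d$sample_id[1],
                              setNames(d$cell_fraction, d$type_name))
        f <- expected_read_fractions(des, genomes)
        data.frame(sample_id = d$sample_id[1], type_name = names(f),
                   expected = 100 * unname(f), stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(sample_id = dtab$sample_id, type_name = dtab$type_name,
                 expected = 100 * dtab$cell_fraction, stringsAsFactors = FALSE)
    }
    obs <- mapply(function(s, t) {
      if (s %in% rownames(ab$type_percent) && t %in% colnames(ab$type_percent))
        ab$type_percent[s, t] else NA_real_
    }, expected_pct$sample_id, expected_pct$type_name)
    val <- data.frame(expected_pct, observed = unname(obs))
    val <- val[!is.na(val$observed), ]
    bg <- val[val$expected <= 5, ]
    gamma_bg <- if (nrow(bg) >= 2L) {
      tryCatch(gamma_permutation_p(bg$expected, bg$observed,
                                   config$tolerance_r, config$n_perm,
                                   seed = config$seed),
               error = function(e) NULL)
    } else NULL
    cis <- lapply(split(bg$observed, bg$expected), function(v) {
      ci <- bootstrap_ci(v, config$n_resamples, seed = config$seed)
      list(mean = ci$mean, lower = ci$lower, upper = ci$upper)
    })
    resid <- if (nrow(bg) >= 3L && length(unique(bg$expected)) >= 2L) {
      residual_bias(bg$observed, bg$expected)
    } else NULL
    dl <- tryCatch(estimate_detection_limit(ab, designs, config$outlier_k),
                   error = function(e) NULL)
    write_tsv_file(val, file.path(out, "observed_vs_expected.tsv"))

    # ---- haplotypes -------------------------------------------------------
    stage <- "haplotypes"
    hap <- list()
    for (ty in colnames(ab$type_percent)) {
      ty_refs <- ann_final$reference_id[!is.na(ann_final$type_name) &
                                          ann_final$type_name == ty]
      ty_refs <- intersect(ty_refs, refs_final$reference_id)
      if (length(ty_refs) < 2L) next
      seqs <- setNames(refs_final$bases[match(ty_refs, refs_final$reference_id)],
                       ty_refs)
      totals <- colSums(counts[, ty_refs, drop = FALSE])
      net <- build_network(seqs, totals)
      write_tsv_file(net$edges, file.path(out, sprintf("network_%s.tsv", ty)))
      # correlate percent-of-sample (not within-type) proportions: variants of
      # one genome rise and fall together with their type across samples
      pm <- ab$ref_percent[, ty_refs, drop = FALSE]
      groups <- tryCatch(
        infer_intragenomic(pm, alpha = config$alpha, n_perm = config$n_perm,
                           seed = config$seed, tolerance_r = config$tolerance_r),
        error = function(e) NULL)
      hap[[ty]] <- list(network = net, groups = groups)
    }

    # ---- report -----------------------------------------------------------
    stage <- "report"
    sid <- clean$sample_id[match(asn$read_id, clean$read_id)]
    acc <- do.call(rbind, lapply(sample_ids, function(s) {
      st <- asn$status[sid == s]
      raw <- pp$report$per_sample$demultiplexed[pp$report$per_sample$sample_id == s]
      data.frame(sample_id = s, reads = raw,
                 cleaned = sum(clean$sample_id == s),
                 mapped = sum(st == "mapped"),
                 ambiguous = sum(st == "ambiguous"),
                 unmapped = sum(st == "unmapped"),
                 mapping_efficiency = if (length(st) > 0)
                   mapping_efficiency(sum(st == "mapped"), length(st)) else NA,
                 stringsAsFactors = FALSE)
    }))
    report <- list(
      package_version = as.character(utils::packageVersion("symtyper")),
      seed = config$seed,
      accounting = acc,
      raw_reads = pp$report$raw,
      unassigned = pp$report$unassigned,
      references_selected = nrow(refs),
      references_pruned = nrow(pr$removed),
      references_final = nrow(refs_final),
      detection_limit = if (!is.null(dl)) {
        list(mean_fp = dl$mean_fp, se_fp = dl$se_fp, cutoff = dl$cutoff,
             n_outliers = length(dl$outliers))
      } else NULL,
      gamma_background = if (!is.null(gamma_bg)) {
        list(gamma = gamma_bg$gamma, p_value = gamma_bg$p_value)
      } else NULL,
      bootstrap_cis = cis,
      residual_by_level = if (!is.null(resid)) resid$by_level else NULL
    )
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(structure(
      c(report, list(abundance = ab, assignments = asn, references = refs_final,
                     annotations = ann_final, haplotypes = hap,
                     observed_vs_expected = val, removed = pr$removed,
                     detection = dl)),
      class = "run_report"))
  }, error = on_fail)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d samples, %d raw reads, %d final references\n",
              nrow(x$accounting), x$raw_reads, x$references_final))
  print(x$accounting)
  invisible(x)
}
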