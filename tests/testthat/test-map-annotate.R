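# Read mapping with unique-best-hit semantics, type annotation with the
# diagnostic-SNP rule, reference pruning, consensus building.

test_that("map_reads distinguishes mapped, ambiguous and unmapped", {
  refA <- strrep("ACGT", 50)
  refB <- paste0(strrep("ACGT", 49), "TTTT")
  refs <- data.frame(reference_id = c("A", "B"), bases = c(refA, refB),
                     stringsAsFactors = FALSE)
  reads <- data.frame(
    read_id = c("exact", "tie", "junk"),
    bases = c(refA,
              substr(refA, 1, 150),          # prefix of both (differ at end)
              strrep("TGAC", 50)),
    stringsAsFactors = FALSE
  )
  asn <- map_reads(reads, refs)
  expect_equal(asn$status, c("mapped", "ambiguous", "unmapped"))
  expect_equal(asn$reference_id[1], "A")
  expect_true(is.na(asn$reference_id[2]))
  expect_error(map_reads(reads, refs[0, ]), "non-empty")
})

test_that("the banded aligner agrees with Biostrings on global alignments", {
  set.seed(7)
  for (i in 1:12) {
    ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
    chars <- strsplit(ref, "")[[1]]
    # a few substitutions and up to one small indel
    pos <- sample(120, 3)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    if (i %% 2 == 0) chars <- append(chars, "A", after = 60)
    read <- paste(chars, collapse = "")
    ours <- semiglobal_score_matrix(read, ref, 1, -1, -2, 12L)$score[1, 1]
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      scoreOnly = TRUE)
    expect_gte(ours, oracle)  # free trailing gaps can only help
    # with sequences of equal-ish length ending alike, scores coincide
    if (nchar(read) == nchar(ref)) expect_equal(ours, oracle)
  }
})

test_that("zero-error reads map back to their generating variants", {
  g <- test_panel()
  vt <- variant_table(g)
  refs <- data.frame(reference_id = vt$variant_id, bases = vt$bases,
                     stringsAsFactors = FALSE)
  d <- mixture_design("s", c(A13 = 0.25, D1 = 0.25, C1 = 0.25, C3 = 0.25),
                      read_depth = 500)
  sim <- simulate_reads(d, g, zero_error_model(seed = 10))
  asn <- map_reads(sim$reads[, c("read_id", "bases")], refs)
  expect_true(all(asn$status == "mapped"))
  expect_equal(asn$reference_id,
               sim$truth$variant_id[match(asn$read_id, sim$truth$read_id)])
  # accounting: every read gets exactly one status
  expect_equal(sum(table(asn$status)), nrow(sim$reads))
})

test_that("mapping efficiency reports to two decimals", {
  expect_equal(mapping_efficiency(1138, 1330), 0.86)
  expect_equal(mapping_efficiency(2186, 2410), 0.91)
  asn <- data.frame(status = c(rep("mapped", 9), "ambiguous"))
  expect_equal(mapping_efficiency(asn), 0.9)
  expect_equal(mapping_efficiency(data.frame(status = rep("mapped", 4))), 1.0)
})

test_that("annotation assigns the closest panel type and honors the SNP rule", {
  g <- test_panel()
  panel <- panel_from_genomes(g)
  vt <- variant_table(g)

  # exact panel sequence: that type at identity 100
  refs <- data.frame(reference_id = "r1",
                     bases = panel$entries$bases[panel$entries$type_name == "D1"],
                     stringsAsFactors = FALSE)
  ann <- annotate_references(refs, panel)
  expect_equal(ann$type_name, "D1")
  expect_equal(ann$percent_identity, 100)
  expect_equal(ann$flag, "ok")

  # truncated before the diagnostic site: equally close to C1 and C3,
  # unresolvable, flagged for review
  c1 <- panel$entries$bases[panel$entries$type_name == "C1"]
  refs2 <- data.frame(reference_id = "r2", bases = substr(c1, 1, 205),
                      stringsAsFactors = FALSE)
  ann2 <- annotate_references(refs2, panel)
  expect_equal(ann2$flag, "manual_review")

  # near-tied C1/C3 hit covering the site: the diagnostic base decides
  refs3 <- data.frame(reference_id = c("rC", "rT"),
                      bases = c(substr(c1, 1, 250),
                                sub("^(.{211}).", "\\1T", substr(c1, 1, 250))),
                      stringsAsFactors = FALSE)
  ann3 <- annotate_references(refs3, panel)
  expect_equal(ann3$type_name, c("C1", "C3"))
  expect_equal(ann3$tie_break_used, c("diagnostic_site", "diagnostic_site"))

  # divergent simulator variants still recover their source type
  refs4 <- data.frame(reference_id = vt$variant_id, bases = vt$bases,
                      stringsAsFactors = FALSE)
  ann4 <- annotate_references(refs4, panel)
  expect_equal(ann4$type_name, vt$type_name)

  # junk aligns to nothing above the floor
  refs5 <- data.frame(reference_id = "junk", bases = strrep("ATAT", 80),
                      stringsAsFactors = FALSE)
  expect_equal(annotate_references(refs5, panel)$flag, "unannotated")
})

test_that("annotation is invariant to panel entry order", {
  g <- test_panel()
  panel <- panel_from_genomes(g)
  vt <- variant_table(g)
  refs <- data.frame(reference_id = vt$variant_id, bases = vt$bases,
                     stringsAsFactors = FALSE)
  shuffled <- reference_panel(panel$entries[c(3, 1, 4, 2), ],
                              panel$diagnostic_sites)
  a1 <- annotate_references(refs, panel)
  a2 <- annotate_references(refs, shuffled)
  expect_equal(a1$type_name, a2$type_name)
})

test_that("pruning removes references absent from known-dominant samples", {
  refs <- data.frame(reference_id = c("x1", "x2", "y1"),
                     bases = c("AAA", "AAC", "GGG"),
                     source_cluster_size = c(100L, 50L, 80L),
                     stringsAsFactors = FALSE)
  ann <- data.frame(reference_id = c("x1", "x2", "y1"),
                    type_name = c("X", "X", "Y"), stringsAsFactors = FALSE)
  designs <- data.frame(
    sample_id = rep(c("hiX", "hiY", "mix"), each = 2),
    type_name = rep(c("X", "Y"), 3),
    cell_fraction = c(0.97, 0.03, 0.03, 0.97, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
  counts <- matrix(c(90, 0, 2,   3, 0, 95,  40, 0, 45), nrow = 3, byrow = TRUE,
                   dimnames = list(c("hiX", "hiY", "mix"), c("x1", "x2", "y1")))
  pr <- prune_references(refs, ann, counts, designs)
  expect_setequal(pr$kept$reference_id, c("x1", "y1"))
  expect_equal(pr$removed$reference_id, "x2")
  expect_equal(pr$removed$sample_id, "hiX")

  # no high-abundance sample for a type: kept with a warning
  designs2 <- designs[designs$sample_id != "hiX", ]
  expect_warning(pr2 <- prune_references(refs, ann, counts, designs2),
                 "no high-abundance")
  expect_true(all(c("x1", "x2") %in% pr2$kept$reference_id))

  # empty reference set passes through
  pr3 <- prune_references(refs[0, ], ann, counts, designs)
  expect_equal(nrow(pr3$kept), 0)
})

test_that("type consensus takes column majorities, anchored on the largest cluster", {
  expect_equal(type_consensus("ACGT"), "ACGT")

  seqs <- c("ACGTACGT", "ACGTACGT", "ACGAACGT")
  expect_equal(type_consensus(seqs), "ACGTACGT")

  # brute-force column-majority oracle on substitution-only variants
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  vars <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(60, 2)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  sizes <- c(40, 10, 5, 2)
  expect_equal(type_consensus(vars, sizes),
               brute_column_majority(vars, anchor = 1L))

  # an indel in a minority sequence does not enter the consensus
  with_del <- c(strrep("ACGT", 10), strrep("ACGT", 10),
                paste0(substr(strrep("ACGT", 10), 1, 20),
                       substr(strrep("ACGT", 10), 25, 40)))
  expect_equal(type_consensus(with_del, c(10, 10, 1)), strrep("ACGT", 10))
})
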