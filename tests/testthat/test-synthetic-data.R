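# Simulator: panel construction, copy-number weighting, read generation.

test_that("type_genome enforces its invariants", {
  v <- data.frame(variant_id = c("a", "b"), bases = c("ACGT", "ACGA"),
                  copy_fraction = c(0.6, 0.4))
  g <- type_genome("X", v, 1000)
  expect_s3_class(g, "type_genome")
  expect_error(type_genome("X", transform(v, copy_fraction = c(0.6, 0.6))),
               "sum to 1")
  expect_error(type_genome("X", transform(v, variant_id = c("a", "a")), 10),
               "unique")
  expect_error(type_genome("X", v, 0), "copy_number")
})

test_that("single-variant panels are the identity case", {
  g <- build_type_panel(n_variants_per_type = 1, divergence_within_type = 0,
                        seed = 5)
  for (tg in g) {
    expect_equal(nrow(tg$variants), 1L)
    expect_equal(tg$variants$copy_fraction, 1)
  }
})

test_that("default panel has the diagnostic SNP pair and divergent other pairs", {
  g <- test_panel()
  vt <- variant_table(g)
  base_of <- function(ty) vt$bases[vt$type_name == ty][1]
  ds <- attr(g, "diagnostic_site")
  expect_equal(ds$position, 212L)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(base_of("C1"), base_of("C3")), 1)
  expect_equal(substr(base_of("C1"), 212, 212), "C")
  expect_equal(substr(base_of("C3"), 212, 212), "T")
  pairs <- combn(c("A13", "D1", "C1", "C3"), 2, simplify = FALSE)
  for (p in pairs) {
    if (setequal(p, c("C1", "C3"))) next
    expect_gte(ham(base_of(p[1]), base_of(p[2])), 0.10 * 300)
  }
})

test_that("panel construction is deterministic and validates arguments", {
  expect_identical(build_type_panel(seed = 9), build_type_panel(seed = 9))
  expect_error(build_type_panel(n_types = 0), "n_types")
  expect_error(build_type_panel(divergence_within_type = 40,
                                divergence_between_types = 0.1),
               "smaller than")
  expect_error(build_type_panel(seq_length = 100), "seq_length")
})

test_that("expected_read_fractions implements copy-number weighting", {
  g <- test_panel()  # equal copy numbers
  d <- mixture_design("s", c(A13 = 0.997, D1 = 0.001, C1 = 0.001, C3 = 0.001))
  f <- expected_read_fractions(d, g)
  expect_equal(unname(f), c(0.997, 0.001, 0.001, 0.001))
  expect_equal(sum(f), 1, tolerance = 1e-12)

  two <- list(
    type_genome("A", data.frame(variant_id = "a", bases = strrep("ACGT", 60),
                                copy_fraction = 1), 1000),
    type_genome("B", data.frame(variant_id = "b", bases = strrep("TGCA", 60),
                                copy_fraction = 1), 3000)
  )
  d2 <- mixture_design("s2", c(A = 0.5, B = 0.5))
  expect_equal(unname(expected_read_fractions(d2, two)), c(0.25, 0.75))

  d3 <- mixture_design("s3", c(A = 1, B = 0))
  expect_equal(unname(expected_read_fractions(d3, two)), c(1, 0))
  d4 <- mixture_design("s4", c(A = 0.5, Z = 0.5))
  expect_error(expected_read_fractions(d4, two), "absent")
})

test_that("zero-error simulation reproduces panel variants exactly", {
  g <- test_panel()
  d <- mixture_design("s", c(A13 = 0.25, D1 = 0.25, C1 = 0.25, C3 = 0.25),
                      read_depth = 400)
  sim <- simulate_reads(d, g, zero_error_model(seed = 3))
  expect_true(all(sim$reads$bases %in% variant_table(g)$bases))
  expect_equal(nrow(sim$reads), 400)
  # truth covers every read exactly once
  expect_setequal(sim$truth$read_id, sim$reads$read_id)
  expect_false(anyDuplicated(sim$truth$read_id) > 0)
  # determinism
  sim2 <- simulate_reads(d, g, zero_error_model(seed = 3))
  expect_identical(sim, sim2)
})

test_that("template sampling matches the multinomial expectation", {
  g <- test_panel()
  d <- mixture_design("s5", c(A13 = 0.97, D1 = 0.01, C1 = 0.01, C3 = 0.01),
                      read_depth = 10000)
  sim <- simulate_reads(d, g, zero_error_model(seed = 8))
  counts <- table(factor(sim$truth$type_name, levels = names(d$cell_fractions)))
  f <- expected_read_fractions(d, g)
  for (ty in names(f)) {
    expected <- 10000 * f[[ty]]
    sd3 <- 3 * sqrt(10000 * f[[ty]] * (1 - f[[ty]]))
    expect_lt(abs(counts[[ty]] - expected), max(sd3, 1e-9) + 1e-9)
  }
})

test_that("read fractions converge at high depth", {
  g <- test_panel()
  d <- mixture_design("s", c(A13 = 0.4, D1 = 0.3, C1 = 0.2, C3 = 0.1),
                      read_depth = 1e5)
  sim <- simulate_reads(d, g, zero_error_model(seed = 4))
  obs <- table(sim$truth$type_name) / 1e5
  f <- expected_read_fractions(d, g)
  expect_true(all(abs(obs[names(f)] - f) < 0.005))
})

test_that("error model produces substitutions and homopolymer indels", {
  g <- test_panel()
  d <- mixture_design("s", c(A13 = 1, D1 = 0, C1 = 0, C3 = 0), read_depth = 2000)
  m <- error_model(substitution_rate = 0.005, homopolymer_indel_rate = 0.01,
                   length_mean = Inf, length_sd = 0, seed = 6)
  sim <- simulate_reads(d, g, m)
  vt <- variant_table(g)
  lens <- nchar(sim$reads$bases)
  expect_true(any(!sim$reads$bases %in% vt$bases))        # errors happened
  expect_true(any(lens != nchar(vt$bases[1])))            # indels change length
  expect_true(all(abs(lens - nchar(vt$bases[1])) <= 10))  # but only slightly
})

test_that("the dilution series encodes the standard 15-sample mixing design", {
  designs <- dilution_designs()
  expect_length(designs, 15)
  expect_equal(unname(designs[[1]]$cell_fractions),
               c(0.997, 0.001, 0.001, 0.001))
  expect_equal(names(designs[[1]]$cell_fractions), c("A13", "D1", "C1", "C3"))
  expect_equal(unname(designs[[13]]$cell_fractions), c(1, 0, 0, 0))
  for (d in designs) expect_equal(sum(d$cell_fractions), 1, tolerance = 1e-9)
})

test_that("make_dilution_series emits barcoded samples and exact depths", {
  g <- test_panel()
  ser <- make_dilution_series(g, error_model(seed = 2), depth_per_sample = 60)
  expect_length(ser$samples, 15)
  for (s in ser$samples) expect_equal(nrow(s$reads), 60)
  expect_equal(nrow(ser$manifest), 15)
  expect_false(anyDuplicated(ser$manifest$barcode) > 0)
  # barcodes pairwise separated
  bc <- ser$manifest$barcode
  for (i in 1:14) for (j in (i + 1):15) {
    expect_gte(sum(strsplit(bc[i], "")[[1]] != strsplit(bc[j], "")[[1]]), 3)
  }
})

test_that("identical seeds give byte-identical FASTQ output", {
  g <- test_panel()
  d1 <- tempfile()
  d2 <- tempfile()
  write_dilution_series(make_dilution_series(g, error_model(seed = 13),
                                             depth_per_sample = 40), d1)
  write_dilution_series(make_dilution_series(g, error_model(seed = 13),
                                             depth_per_sample = 40), d2)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
})
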