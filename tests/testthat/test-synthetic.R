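test_that("generate_genome is deterministic with the stated composition", {
  cfg <- cohort_config(seed = 5, n_contigs = 1, contig_length = 1000000L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  freq <- vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(unclass(g1)[[1]],
                       gregexpr(b, unclass(g1)[[1]], fixed = TRUE))) / 1e6, 0)
  expect_true(all(abs(freq - 0.25) < 0.005))
})

test_that("a degenerate all-C genome has no TCW sites", {
  cfg <- cohort_config(seed = 1, n_contigs = 1, contig_length = 5000L,
                       base_composition = c(A = 0, C = 1, G = 0, T = 0))
  g <- generate_genome(cfg)
  expect_equal(unique(strsplit(unclass(g)[[1]], "")[[1]]), "C")
  expect_length(enumerate_tcw_sites(g), 0L)
})

test_that("enumerate_tcw_sites finds exactly the strand-oriented TCW cytosines", {
  g <- genome_sequence(c(c1 = "ATCATGATCTAGA"))
  # plus strand TCA at 2-4 (C at 3), TCT at 8-10 (C at 9);
  # minus strand: TGA at 5-7 (G at 6), AGA at 11-13 (G at 12)
  expect_equal(enumerate_tcw_sites(g), c(3L, 6L, 9L, 12L))
})

test_that("planted APOBEC events are TCW-context C>T (or minus-strand G>A)", {
  g <- random_genome(1, 30000, seed = 12)
  r <- spawn_sbs(g, 200, apobec_fraction = 1, ct_cg_split = 1, seed = 3)
  expect_true(all((r$ref_allele == "C" & r$alt_allele == "T") |
                  (r$ref_allele == "G" & r$alt_allele == "A")))
  cls <- classify_sbs(r, g)
  expect_true(all(cls %in% c("T[C>T]A", "T[C>T]T")))
  # ct_cg_split = 0: pure C>G outcomes at the same motifs
  rg <- spawn_sbs(g, 200, apobec_fraction = 1, ct_cg_split = 0, seed = 3)
  expect_true(all((rg$ref_allele == "C" & rg$alt_allele == "G") |
                  (rg$ref_allele == "G" & rg$alt_allele == "C")))
})

test_that("spawned records are deterministic, sorted, and pass default filters", {
  g <- random_genome(2, 20000, seed = 6)
  r1 <- spawn_sbs(g, 300, 0.5, 1, seed = 77)
  r2 <- spawn_sbs(g, 300, 0.5, 1, seed = 77)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 300L)
  expect_false(is.unsorted(r1$position[r1$contig == "c1"]))
  kept <- suppressMessages(apply_filters(r1))
  expect_equal(nrow(kept), 300L)
  expect_true(all(r1$vaf > 0.05 & r1$vaf == r1$alt_depth / r1$total_depth))
  # distinct sites within a sample
  expect_equal(anyDuplicated(r1[c("contig", "position")]), 0L)
})

test_that("spawn_sbs errors when TCW sites cannot cover the request", {
  g <- genome_sequence(c(c1 = strrep("C", 2000)))
  expect_error(spawn_sbs(g, 10, apobec_fraction = 1, seed = 1),
               "insufficient TCW sites")
})

test_that("spawn_indels honours the length distribution and bounds", {
  g <- random_genome(1, 20000, seed = 8)
  r <- spawn_indels(g, 100, c("1" = 1, "2" = 0, "3" = 0, "4" = 0,
                              "5plus" = 0), seed = 2)
  expect_true(all(abs(nchar(r$ref_allele) - nchar(r$alt_allele)) == 1L))
  expect_equal(nrow(spawn_indels(g, 0, seed = 1)), 0L)
  # deletions never overrun the contig
  r2 <- spawn_indels(g, 300, seed = 3)
  del <- nchar(r2$ref_allele) > 1
  expect_true(all(r2$position[del] + nchar(r2$ref_allele[del]) - 1L <= 20000L))
})

test_that("generated timing tracks partition the genome exactly", {
  g <- random_genome(2, 25000, seed = 14)
  tr <- generate_timing_track(g, window = 1000, bias_ratio = 0.5, seed = 4)
  for (ctg in names(g)) {
    iv <- tr[tr$contig == ctg, ]
    iv <- iv[order(iv$start), ]
    expect_equal(iv$start[1], 0L)
    expect_equal(iv$end[nrow(iv)], 25000L)
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))
  }
  expect_true(all(tr$quintile %in% 1:5))
  expect_equal(attr(tr, "planted_bias_ratio"), 0.5)
  tr2 <- generate_timing_track(g, window = 1000, bias_ratio = 0.5, seed = 4)
  expect_identical(tr2$timing, tr$timing)
})

test_that("generate_cohort emits a complete, reproducible study", {
  cfg <- cohort_config(seed = 33, n_contigs = 2, contig_length = 20000L,
                       n_samples = 4, sbs_per_sample = 100,
                       apobec_fraction = c(0, 0, 0.6, 0.6),
                       indels_per_sample = 30, timing_window = 2000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  x1 <- generate_cohort(cfg, d1)
  x2 <- generate_cohort(cfg, d2)
  expect_equal(nrow(x1$truth), 4L)
  expect_equal(x1$truth$n_indels, c(30L, 30L, 66L, 66L))  # coupled mode
  expect_setequal(list.files(d1), c("genome.fa", "timing.bed", "manifest.tsv",
                                    "truth.tsv", paste0(x1$truth$sample_id,
                                                        ".vcf")))
  # byte-identical reproduction under the same seed
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # VCFs re-read to the same records
  r <- read_vcf_somatic(file.path(d1, "S03.vcf"), "S03")
  expect_equal(nrow(r), 100L + 66L)
})
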