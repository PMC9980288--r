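test_that("read_fasta normalizes case, concatenates lines, keys by first token", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), f)
  expect_equal(unclass(read_fasta(f)), c(c1 = "ACGT"))

  writeLines(c(">c1 some description", "AC", "GT"), f)
  expect_equal(unclass(read_fasta(f)), c(c1 = "ACGT"))
})

test_that("read_fasta rejects duplicates, uracil and bad characters by line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "AC", ">c1", "GG"), f)
  expect_error(read_fasta(f), "duplicate contig name")

  writeLines(c(">c1", "ACGU"), f)
  expect_error(read_fasta(f), "line 2.*RNA|uracil \\(U\\) base at line 2")

  writeLines(c(">c1", "ACGT", ">c2", "AXGT"), f)
  expect_error(read_fasta(f), "line 4")

  writeLines(c("ACGT", ">c1", "ACGT"), f)
  expect_error(read_fasta(f), "precedes any header")
})

test_that("fasta round trip preserves the genome", {
  g <- random_genome(2, 257, seed = 3)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f, width = 50)
  expect_identical(read_fasta(f), g)
})

test_that("genome_slice is total on valid ranges and clamps on request", {
  g <- genome_sequence(c(c1 = "ACGTACGT"))
  expect_equal(genome_slice(g, "c1", 2, 4), "CGT")
  expect_error(genome_slice(g, "c1", 0, 4), "out of bounds")
  expect_error(genome_slice(g, "c2", 1, 2), "not present")
  expect_equal(genome_slice(g, "c1", -3, 100, clamp = TRUE), "ACGTACGT")
})

test_that("mutation_records enforces the record invariants", {
  expect_error(rec("c1", 5, "C", "C"), "identical")
  expect_error(rec("c1", 5, "C", "X"), "outside A/C/G/T")
  expect_error(rec("c1", 0, "C", "T"), "1-based")
  expect_error(
    mutation_records("s", "c1", 5, "C", "T", 5L, 50L, vaf = 0.4),
    "vaf inconsistent")
  r <- mutation_records("s", "c1", 5, "C", "T", 5L, 50L)
  expect_equal(r$vaf, 0.1)
  expect_true(is_sbs(r))
  expect_false(is_indel(r))
  expect_true(is_indel(rec("c1", 5, "CA", "C")))
  mns <- rec("c1", 5, "CA", "TG")
  expect_false(is_sbs(mns) || is_indel(mns))
})

test_that("read_vcf_somatic maps AD fields, splits multi-allelics, honours FILTER", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "c1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:20,5",
    "c1\t150\t.\tA\tG\t.\tclustered_events\t.\tGT:AD\t0/1:20,9",
    "c1\t200\t.\tCA\tC\t.\tPASS\t.\tGT:AD\t0/1:30,10",
    "c1\t250\t.\tC\tT,G\t.\t.\t.\tGT:AD\t0/1:10,5,5"), f)
  r <- suppressMessages(read_vcf_somatic(f, "TUMOR"))
  expect_equal(nrow(r), 4L)  # FILTER row dropped, multiallelic split in two
  expect_equal(r$position[1], 100L)
  expect_equal(r$alt_depth[1], 5L)
  expect_equal(r$total_depth[1], 25L)
  expect_equal(r$vaf[1], 0.2)
  expect_false(150L %in% r$position)
  expect_equal(r$ref_allele[r$position == 200L], "CA")
  multi <- r[r$position == 250L, ]
  expect_setequal(multi$alt_allele, c("T", "G"))
  expect_equal(multi$total_depth, c(20L, 20L))
  expect_true(all(r$sample_id == "TUMOR"))
})

test_that("VCF write/read round trip preserves coordinates, alleles and depths", {
  g <- random_genome(2, 5000, seed = 11)
  r <- spawn_sbs(g, 60, 0.4, 1, seed = 5, sample_id = "T1")
  r <- rbind(r, spawn_indels(g, 20, seed = 6, sample_id = "T1"))
  r <- r[order(match(r$contig, names(g)), r$position), ]
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(r, f, g)
  r2 <- read_vcf_somatic(f, "T1")
  for (col in c("sample_id", "contig", "position", "ref_allele", "alt_allele",
                "alt_depth", "total_depth"))
    expect_equal(r2[[col]], r[[col]], info = col)
})

test_that("apply_filters enforces the read-support thresholds", {
  r <- mutation_records(
    "s", c("c1", "c1", "chrM", "c1", "c1"), 1:5,
    "C", "T",
    alt_depth = c(3L, 3L, 5L, 2L, 5L),
    total_depth = c(10L, 60L, 50L, 10L, 9L))
  # vaf: 0.30 (keep), 0.05 (strict removal), chrM (removal), alt<3, total<10
  kept <- suppressMessages(apply_filters(r))
  expect_equal(kept$position, 1L)
  log <- attr(kept, "filter_log")
  expect_equal(unname(log[c("input", "kept")]), c(5L, 1L))
  expect_equal(unname(log[["fail_vaf"]]), 1L)  # only the exact-0.05 record
  # idempotence
  again <- suppressMessages(apply_filters(kept))
  expect_equal(again$position, kept$position)
  expect_lte(nrow(kept), nrow(r))
})

test_that("apply_filters errors on records lacking required depths", {
  r <- mutation_records("s", "c1", 10L, "C", "T")
  expect_error(suppressMessages(apply_filters(r)), "lack depth fields")
  # a permissive policy accepts depthless records
  p <- filter_policy(min_alt_reads = 0, min_total_reads = 0, min_vaf = 0)
  expect_equal(nrow(suppressMessages(apply_filters(r, p))), 1L)
})

test_that("records TSV round trip", {
  r <- rec("c1", c(5L, 9L), c("C", "CA"), c("T", "C"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records_tsv(r, f)
  r2 <- read_records_tsv(f)
  expect_equal(r2$position, r$position)
  expect_equal(r2$ref_allele, r$ref_allele)
  expect_equal(r2$vaf, r$vaf)
})
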