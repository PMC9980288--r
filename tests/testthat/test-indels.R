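test_that("single-base indels are subtyped T/A vs C/G", {
  g <- genome_sequence(c(c1 = "GCAGGTTTTG"))
  del <- classify_indel(rec("c1", 2, "CA", "C"), g)   # deletes A
  expect_equal(del$kind, "deletion")
  expect_equal(del$size_category, "1")
  expect_equal(del$one_bp_subtype, "T/A")
  expect_false(del$microhomology)
  expect_equal(del$class, "del_1_TA")

  ins <- classify_indel(rec("c1", 2, "C", "CG"), g)
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$one_bp_subtype, "C/G")
  expect_equal(ins$class, "ins_1_CG")

  # the subtype is strand-symmetric by construction
  delT <- classify_indel(rec("c1", 5, "GT", "G"), g)
  expect_equal(delT$one_bp_subtype, "T/A")
})

test_that("microhomology is the junction common prefix of deleted and 3' flank", {
  # delete TAG at 3..5; reference continues TA at 6..7 -> MH length 2
  g <- genome_sequence(c(c1 = "GCTAGTACCCC"))
  d <- classify_indel(rec("c1", 2, "CTAG", "C"), g)
  expect_equal(d$size_category, "3")
  expect_true(d$microhomology)
  expect_equal(d$mh_length, 2L)
  expect_equal(d$class, "del_3_mh")

  # no junction identity -> no MH
  g2 <- genome_sequence(c(c1 = "GCTAGCCCCCC"))
  d2 <- classify_indel(rec("c1", 2, "CTAG", "C"), g2)
  expect_false(d2$microhomology)
  expect_equal(d2$class, "del_3")

  # insertions and 1 bp deletions never carry the MH flag
  i <- classify_indel(rec("c1", 2, "C", "CTAG"), g)
  expect_false(i$microhomology)
})

test_that("size categories cover 1-4, 5plus (to 200) and flag longer events", {
  set.seed(2)
  g <- genome_sequence(c(c1 = paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                                    collapse = "")))
  mk_del <- function(pos, len) {
    s <- unclass(g)[[1]]
    rec("c1", pos, substr(s, pos, pos + len), substr(s, pos, pos))
  }
  cl <- classify_indel(rbind(mk_del(10, 2), mk_del(40, 4), mk_del(80, 5),
                             mk_del(120, 200)), g)
  expect_equal(cl$size_category, c("2", "4", "5plus", "5plus"))
  expect_false(any(cl$out_of_spectrum))
  long <- suppressMessages(classify_indel(mk_del(300, 201), g))
  expect_true(long$out_of_spectrum)
  expect_equal(long$size_category, "5plus")
  # a balanced substitution is not an indel
  expect_error(classify_indel(rec("c1", 10, "AC", "CA"), g), "indel records")
})

test_that("summarize_indels counts classes and conserves the total", {
  g <- genome_sequence(c(c1 = "GATAGATACCCCGGGGACGTACGTACGT"))
  r <- rbind(rec("c1", 2, "AT", "A"),            # del 1 T/A
             rec("c1", 6, "AT", "A"),            # del 1 T/A
             rec("c1", 10, "C", "CGGTCGGA"))     # ins 7 (5plus)
  s <- summarize_indels(r, g, "s1")
  expect_equal(unname(unclass(s)["del_1_TA"]), 2L)
  expect_equal(unname(unclass(s)["ins_5plus"]), 1L)
  expect_equal(attr(s, "total_under_200"), 3L)
  expect_equal(sum(s), 3L)
  # permutation invariance of the total
  s2 <- summarize_indels(r[c(3, 1, 2), ], g, "s1")
  expect_equal(unclass(s2), unclass(s))
  # empty summary is valid
  s0 <- summarize_indels(r[0, ], g, "s0")
  expect_equal(sum(s0), 0L)
})

test_that("spawned indels always recover their drawn length category", {
  g <- random_genome(2, 30000, seed = 23)
  r <- spawn_indels(g, 1000, seed = 41)
  cl <- classify_indel(r, g)
  net <- abs(nchar(r$ref_allele) - nchar(r$alt_allele))
  expected <- ifelse(net >= 5, "5plus", as.character(net))
  expect_equal(cl$size_category, expected)
  expect_true(all(net >= 1 & net <= 200))
})

test_that("normalize_indels left-aligns shiftable deletions", {
  # TTTT run: deleting any T is representable at the leftmost anchor
  g <- genome_sequence(c(c1 = "GATTTTC"))
  shifted <- rec("c1", 4, "TT", "T")
  norm <- normalize_indels(shifted, g)
  expect_equal(norm$position, 2L)
  expect_equal(norm$ref_allele, "AT")
  expect_equal(norm$alt_allele, "A")
  # already left-aligned records are unchanged
  expect_equal(normalize_indels(norm, g), norm)
})

test_that("indel-enrichment association is monotone and flags degeneracy", {
  scores <- data.frame(sample_id = paste0("s", 1:6),
                       score = c(1, 1.5, 2, 2.5, 3, 3.5))
  summaries <- lapply(1:6, function(i) {
    x <- stats::setNames(integer(16), indel_classes())
    x["del_1_TA"] <- 2L * i          # proportional to score
    x["ins_2"] <- 3L                 # constant: degenerate
    structure(x, class = "indel_summary", sample_id = paste0("s", i),
              total_under_200 = sum(x), n_over_200 = 0L)
  })
  tab <- suppressMessages(indel_enrichment_association(summaries, scores))
  expect_equal(tab$rho[tab$class == "del_1_TA"], 1.0)
  expect_equal(tab$rho[tab$class == "total_under_200"], 1.0)
  expect_true(is.na(tab$rho[tab$class == "ins_2"]))
  expect_true(tab$degenerate[tab$class == "ins_2"])
  # sample mismatch errors
  bad <- scores
  bad$sample_id[1] <- "zz"
  expect_error(indel_enrichment_association(summaries, bad),
               "sample mismatch")
})
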