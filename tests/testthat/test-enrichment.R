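test_that("filter_for_enrichment applies the four rules in order", {
  g_ignore <- NULL
  r <- rbind(
    rec("c1", 10, "C", "T"),    # keep
    rec("c1", 20, "C", "A"),    # rule 4
    rec("c1", 30, "T", "G"),    # rule 2 (not C:G)
    rec("c1", 40, "G", "A"),    # keep
    rec("chrM", 50, "C", "T"),  # rule 3
    rec("c1", 60, "G", "T"),    # rule 4 on the minus strand
    rec("c1", 70, "CA", "C"))   # rule 1 (not SBS)
  f <- filter_for_enrichment(r)
  expect_equal(f$position, c(10L, 40L))
  log <- attr(f, "enrichment_filter_log")
  expect_equal(unname(log[c("fail_sbs", "fail_cg", "fail_mito",
                            "fail_c_to_a", "kept")]),
               c(1L, 1L, 1L, 2L, 2L))
  expect_equal(nrow(filter_for_enrichment(r[0, ])), 0L)
})

test_that("window_context extracts and orients 41-base windows", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  substr(s, 21, 21) <- "C"
  g <- genome_sequence(c(c1 = s))
  w <- window_context(rec("c1", 21, "C", "T"), g)
  expect_equal(nchar(w), 41L)
  expect_equal(w[1], substr(s, 1, 41))
  # left truncation at a contig edge
  substr(s, 5, 5) <- "C"
  g <- genome_sequence(c(c1 = s))
  w5 <- suppressMessages(window_context(rec("c1", 5, "C", "G"), g))
  expect_equal(nchar(w5), 25L)
  expect_equal(attr(w5, "n_truncated"), 1L)
  # G-site windows are the reverse complement of the plus-strand slice
  substr(s, 50, 50) <- "G"
  g <- genome_sequence(c(c1 = s))
  wg <- window_context(rec("c1", 50, "G", "A"), g)
  expect_equal(wg[1], revcomp(substr(s, 30, 70)))
})

test_that("count_motifs matches brute-force scanning and tcw <= c", {
  expect_equal(count_motifs("TCATCT")[1, ], c(tcw = 2L, c = 2L))
  expect_equal(count_motifs("GCCGG")[1, ], c(tcw = 0L, c = 2L))
  expect_equal(count_motifs("TCTCTCA")[1, "tcw"], c(tcw = 3L))  # overlapping
  expect_equal(count_motifs("NCANTCN")[1, ], c(tcw = 0L, c = 2L))
  set.seed(7)
  for (i in 1:60) {
    w <- paste(sample(c("A", "C", "G", "T", "N"), 41,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    cm <- count_motifs(w)
    expect_equal(cm[1, ], oracle_count_motifs(w))
    expect_lte(cm[1, "tcw"], cm[1, "c"])
  }
  # strict TCA mode
  expect_equal(count_motifs("TCATCT", motif = "TCA")[1, "tcw"], c(tcw = 1L))
})

test_that("enrichment_from_counts evaluates the ratio of ratios", {
  r <- enrichment_from_counts(5, 10, 10, 100, "x")
  expect_equal(r$score, 5.0)
  expect_equal(r$p_value, fisher_one_sided(5, 10, 10, 100))
  # identity case: mutation usage equals availability
  expect_equal(enrichment_from_counts(2, 10, 20, 100, "x")$score, 1.0)
  # undefined score is flagged and excluded from BH later
  r0 <- enrichment_from_counts(0, 0, 0, 0, "x")
  expect_true(r0$undefined)
  expect_true(is.na(r0$score))
  expect_error(enrichment_from_counts(3, 2, 10, 100), "invalid")
  expect_error(enrichment_from_counts(5, 10, 0, 100), "context bug")
})

test_that("enrichment_score aggregates per-site window counts", {
  # two C>T mutations on a hand-checkable genome
  g <- random_genome(1, 400, seed = 13)
  s <- unclass(g)[[1]]
  cpos <- which(strsplit(s, "")[[1]] == "C")
  cpos <- cpos[cpos > 40 & cpos < 360][1:2]
  r <- rec("c1", cpos, "C", "T")
  res <- enrichment_score(r, g)
  tri <- substring(s, cpos - 1, cpos + 1)
  exp_mut_tcw <- sum(tri %in% c("TCA", "TCT"))
  wins <- substring(s, cpos - 20, cpos + 20)
  om <- vapply(wins, oracle_count_motifs, c(tcw = 0L, c = 0L))
  expect_equal(unname(res$counts),
               c(exp_mut_tcw, 2L, sum(om["tcw", ]), sum(om["c", ])))
  expect_equal(res$score,
               (exp_mut_tcw / sum(om["tcw", ])) / (2 / sum(om["c", ])))
})

test_that("fisher_one_sided equals the hypergeometric tail", {
  # worked example: tail sum over the margins of [[5,5],[10,90]]
  expect_equal(fisher_one_sided(5, 10, 10, 100),
               oracle_fisher_greater(5, 5, 10, 90), tolerance = 1e-12)
  # observed minimum of the tail: p = 1
  expect_equal(fisher_one_sided(0, 7, 4, 20), 1)
  # monotone decreasing in mut_tcw at fixed margins
  ps <- vapply(0:8, function(a) fisher_one_sided(a, 8, 10, 40), 0)
  expect_true(all(diff(ps) < 0))
  # agreement with the standard exact test implementation
  set.seed(5)
  for (i in 1:25) {
    a <- rpois(1, 4); b <- rpois(1, 6); cc <- rpois(1, 5); d <- rpois(1, 20)
    ft <- stats::fisher.test(matrix(c(a, cc, b, d), 2),
                             alternative = "greater")$p.value
    expect_equal(fisher_one_sided(a, a + b, cc, cc + d), ft,
                 tolerance = 1e-12)
  }
  expect_error(fisher_one_sided(5, 4, 1, 10), "negative cell")
})

test_that("bh_adjust is the textbook step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("classify_es applies the strict q < threshold rule", {
  df <- data.frame(sample_id = c("a", "b", "c"), score = c(2, 1, NA),
                   q_value = c(0.05, 0.1, NA), es_class = NA_character_,
                   stringsAsFactors = FALSE)
  out <- suppressMessages(classify_es(df))
  expect_equal(out$es_class, c("high", "low", NA))
  df$q_value <- NA_real_
  expect_error(classify_es(df), "q_value unset")
})

test_that("apobec_enrichment applies one cohort-wide BH family", {
  g <- random_genome(1, 30000, seed = 21)
  r <- rbind(spawn_sbs(g, 150, 0.8, 1, seed = 1, sample_id = "hot"),
             spawn_sbs(g, 150, 0.0, 1, seed = 2, sample_id = "cold"))
  fit <- suppressMessages(apobec_enrichment(r, g))
  expect_s3_class(fit, "apobec_enrichment")
  expect_equal(fit$q_value, bh_adjust(fit$p_value))
  expect_gt(fit$score[fit$sample_id == "hot"],
            fit$score[fit$sample_id == "cold"])
  expect_equal(fit$es_class[fit$sample_id == "hot"], "high")
  # determinism: identical inputs give identical results
  fit2 <- suppressMessages(apobec_enrichment(r, g))
  expect_identical(as.data.frame(fit), as.data.frame(fit2))
})

test_that("associate handles both methods and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  a <- associate(x, 2 * x + 1, "pearson")
  expect_equal(a$coefficient, 1.0)
  b <- associate(x, exp(-x), "spearman")
  expect_equal(b$coefficient, -1.0)
  set.seed(3)
  y <- rnorm(5)
  perm <- sample(5)
  expect_equal(associate(x[perm], y[perm], "pearson")$coefficient,
               associate(x, y, "pearson")$coefficient)
  d <- suppressMessages(associate(x, rep(1, 5), "spearman"))
  expect_true(d$degenerate)
  expect_true(is.na(d$coefficient))
  expect_error(associate(1:2, 1:2), "at least 3")
  expect_error(associate(1:3, 1:4), "equal length")
})

test_that("compare_groups is an exact rank test on small groups", {
  sep <- compare_groups(c(10, 11, 12, 13, 14), c(1, 2, 3, 4, 5))
  expect_equal(sep$u_statistic, 25)
  expect_equal(sep$p_value, 2 / 252)
  ident <- compare_groups(rep(2, 4), rep(2, 4))
  expect_gte(ident$p_value, 0.99)
  # invariance under a common monotone transform
  a <- c(3, 9, 1, 7); b <- c(2, 8, 4, 12)
  expect_equal(compare_groups(exp(a), exp(b))$p_value,
               compare_groups(a, b)$p_value)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("null-sample scores match the site-enumeration expectation", {
  g <- random_genome(1, 200000, seed = 31)
  expected <- oracle_expected_score(g, 400, 0)
  scores <- vapply(1:30, function(i)
    enrichment_score(spawn_sbs(g, 400, 0, 1, seed = 1000 + i), g)$score, 0)
  expect_equal(mean(scores), expected, tolerance = 0.1)
})
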