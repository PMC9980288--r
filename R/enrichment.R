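# APOBEC TCW fold-enrichment over 41-base mutation contexts, with one-sided
# Fisher exact significance, cohort-wide BH correction, ES-high/low calls,
# and generic score-vs-covariate association helpers.
#
# The statistic: for each retained mutated cytosine, the site contributes to
# Mut_C (and to Mut_TCW when its strand-oriented trinucleotide is TCA/TCT),
# and its 41-base window contributes motif counts to Con_TCW / Con_C.
# Enrichment = (Mut_TCW / Con_TCW) / (Mut_C / Con_C).

motif_set <- function(motif = c("TCW", "TCA")) {
  motif <- match.arg(motif)
  if (motif == "TCW") c("TCA", "TCT") else "TCA"
}

#' Pre-filter mutations for the enrichment score
#'
#' Applies, in order: (1) keep single-base substitutions; (2) keep C:G
#' reference base pairs; (3) remove mitochondrial contigs; (4) remove
#' pyrimidine-strand C>A events (G>T on the reference G strand included).
#' The retained events are therefore C>T, C>G, G>A and G>C on the reference.
#' Per-rule removal counts are attached as the `"enrichment_filter_log"`
#' attribute.
#'
#' @param records a mutation record table (already read-support filtered).
#' @param exclude_contigs mitochondrial contig aliases to drop.
#' @return the retained records.
#' @export
filter_for_enrichment <- function(records,
                                  exclude_contigs = c("chrM", "MT", "M")) {
  n0 <- nrow(records)
  r1 <- is_sbs(records)
  r2 <- r1 & records$ref_allele %in% c("C", "G")
  r3 <- r2 & !(records$contig %in% exclude_contigs)
  ca <- (records$ref_allele == "C" & records$alt_allele == "A") |
        (records$ref_allele == "G" & records$alt_allele == "T")
  keep <- r3 & !ca
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "enrichment_filter_log") <- c(
    input = n0, fail_sbs = sum(!r1), fail_cg = sum(r1 & !r2),
    fail_mito = sum(r2 & !r3), fail_c_to_a = sum(r3 & ca), kept = sum(keep))
  out
}

#' Extract the strand-oriented sequence window around each mutation
#'
#' Returns the reference subsequence covering `position +/- half_width`,
#' truncated at contig edges (truncation counted in the `"n_truncated"`
#' attribute). Windows of purine-reference sites are reverse-complemented so
#' the mutated base is presented as a pyrimidine on the analyzed strand.
#'
#' @param records a mutation record table (rows retained by
#'   [filter_for_enrichment()]).
#' @param genome a [genome_sequence()].
#' @param half_width bases up- and downstream of the mutated position
#'   (default 20, i.e. a 41-base window).
#' @return character vector of windows with attribute `n_truncated`.
#' @export
window_context <- function(records, genome, half_width = 20L) {
  if (nrow(records) == 0L)
    return(structure(character(0), n_truncated = 0L))
  missing_ctg <- setdiff(unique(records$contig), names(genome))
  if (length(missing_ctg))
    stop(sprintf("contig '%s' not present in genome", missing_ctg[1L]),
         call. = FALSE)
  seqs <- unname(unclass(genome)[records$contig])
  lens <- nchar(seqs)
  lo <- pmax(1L, records$position - half_width)
  hi <- pmin(lens, records$position + half_width)
  win <- substring(seqs, lo, hi)
  purine <- records$ref_allele %in% c("A", "G")
  win[purine] <- revcomp(win[purine])
  n_trunc <- sum(lo > records$position - half_width |
                 hi < records$position + half_width)
  if (n_trunc) message(sprintf(
    "window_context: %d window(s) truncated at contig edges", n_trunc))
  structure(win, n_truncated = n_trunc)
}

#' Count TCW motifs and cytosines in sequence windows
#'
#' `c` is the number of C characters; `tcw` the number of positions whose
#' trinucleotide (within the window) is TCA or TCT (or TCA only in strict
#' mode). Counting is on the presented strand only; N never matches.
#'
#' @param window character vector of nucleotide windows.
#' @param motif `"TCW"` (TCA/TCT, default) or strict `"TCA"`.
#' @return integer matrix with one row per window, columns `tcw` and `c`.
#' @export
count_motifs <- function(window, motif = c("TCW", "TCA")) {
  motif <- match.arg(motif)
  pat <- if (motif == "TCW") "(?=TC[AT])" else "(?=TCA)"
  cbind(tcw = count_pattern(window, pat),
        c = count_pattern(window, "C", fixed = TRUE))
}

#' One-sided Fisher exact test for TCW enrichment
#'
#' Exact p-value (hypergeometric tail) of the one-sided "greater" test on
#' the 2x2 table `[[mut_tcw, mut_c - mut_tcw], [con_tcw, con_c - con_tcw]]`,
#' i.e. the probability of observing at least `mut_tcw` motif mutations
#' given the margins. Vectorised over its arguments.
#'
#' @param mut_tcw,mut_c,con_tcw,con_c the four enrichment counts.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_one_sided <- function(mut_tcw, mut_c, con_tcw, con_c) {
  a <- as.numeric(mut_tcw)
  b <- as.numeric(mut_c) - a
  cc <- as.numeric(con_tcw)
  d <- as.numeric(con_c) - cc
  if (any(c(a, b, cc, d) < 0, na.rm = TRUE))
    stop("negative cell in 2x2 table (check mut_tcw <= mut_c, con_tcw <= con_c)",
         call. = FALSE)
  # P(X >= a) for X ~ Hypergeom(white = a+c, black = b+d, drawn = a+b)
  stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; input order preserved, values clipped
#' at 1. Inputs outside `[0, 1]` (or missing) are an error.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment result from pre-aggregated counts
#'
#' Computes the fold-enrichment score `(mut_tcw/con_tcw) / (mut_c/con_c)`
#' and its one-sided Fisher p-value from the four aggregated counts.
#' With `mut_c = 0` the score is undefined (`NA`, flagged); such samples are
#' excluded from cohort-level BH correction.
#'
#' @param mut_tcw,mut_c,con_tcw,con_c aggregated counts.
#' @param sample_id sample label.
#' @return an object of class `enrichment_result`.
#' @export
enrichment_from_counts <- function(mut_tcw, mut_c, con_tcw, con_c,
                                   sample_id = NA_character_) {
  if (mut_tcw > mut_c || con_tcw > con_c || min(mut_tcw, con_tcw) < 0)
    stop("invalid enrichment counts", call. = FALSE)
  if (mut_c > 0 && con_c == 0)
    stop("con_c = 0 with mut_c > 0: windows missing", call. = FALSE)
  undefined <- mut_c == 0 || con_tcw == 0
  if (mut_tcw > 0 && con_tcw == 0)
    stop("con_tcw = 0 with mut_tcw > 0: window must contain the mutated site's own motif (context bug)",
         call. = FALSE)
  score <- if (undefined) NA_real_
           else (mut_tcw / con_tcw) / (mut_c / con_c)
  p <- if (mut_c == 0) NA_real_
       else fisher_one_sided(mut_tcw, mut_c, con_tcw, con_c)
  structure(list(sample_id = sample_id,
                 counts = c(mut_tcw = as.integer(mut_tcw),
                            mut_c = as.integer(mut_c),
                            con_tcw = as.integer(con_tcw),
                            con_c = as.integer(con_c)),
                 score = score, p_value = p, q_value = NA_real_,
                 es_class = NA_character_, undefined = undefined),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result '%s': score %.4g (mut %d/%d, con %d/%d), p = %.3g\n",
    x$sample_id, x$score, x$counts[["mut_tcw"]], x$counts[["mut_c"]],
    x$counts[["con_tcw"]], x$counts[["con_c"]], x$p_value))
  invisible(x)
}

#' APOBEC TCW enrichment score for one sample
#'
#' Applies the four enrichment pre-filters, orients every retained site to
#' present the mutated cytosine, aggregates motif counts over the 41-base
#' windows of all sites (overlapping windows counted independently), and
#' returns the fold-enrichment score with its one-sided Fisher p-value.
#' The q-value is left unset until cohort-level correction
#' (see [apobec_enrichment()]).
#'
#' @param records one sample's mutation record table (read-support filtered).
#' @param genome a [genome_sequence()].
#' @param sample_id sample label; defaults to the records' single sample id.
#' @param half_width context half-width (default 20 = 41-base window).
#' @param motif `"TCW"` (default) or strict `"TCA"`.
#' @param exclude_contigs mitochondrial aliases for rule 3.
#' @return an `enrichment_result`.
#' @export
enrichment_score <- function(records, genome, sample_id = NULL,
                             half_width = 20L, motif = c("TCW", "TCA"),
                             exclude_contigs = c("chrM", "MT", "M")) {
  motif <- match.arg(motif)
  if (is.null(sample_id)) {
    sid <- unique(records$sample_id)
    if (length(sid) > 1L)
      stop("records span multiple samples; supply `sample_id` or use apobec_enrichment()",
           call. = FALSE)
    sample_id <- if (length(sid)) sid else NA_character_
  }
  f <- filter_for_enrichment(records, exclude_contigs)
  if (nrow(f) == 0L) {
    res <- enrichment_from_counts(0L, 0L, 0L, 0L, sample_id)
    attr(res, "enrichment_filter_log") <- attr(f, "enrichment_filter_log")
    return(res)
  }
  tri <- oriented_trinucleotide(f, genome)
  mut_tcw <- sum(tri %in% motif_set(motif), na.rm = TRUE)
  win <- window_context(f, genome, half_width)
  cm <- count_motifs(win, motif)
  res <- enrichment_from_counts(mut_tcw, nrow(f), sum(cm[, "tcw"]),
                                sum(cm[, "c"]), sample_id)
  attr(res, "enrichment_filter_log") <- attr(f, "enrichment_filter_log")
  res
}

# Strand-oriented trinucleotide at each mutated site (NA at contig edges).
oriented_trinucleotide <- function(records, genome) {
  seqs <- unname(unclass(genome)[records$contig])
  lens <- nchar(seqs)
  at <- substring(seqs, records$position, records$position)
  bad <- at != records$ref_allele
  if (any(bad))
    stop(sprintf(
      "reference mismatch at %s:%d (genome has %s, record says %s); wrong genome build?",
      records$contig[bad][1L], records$position[bad][1L], at[bad][1L],
      records$ref_allele[bad][1L]), call. = FALSE)
  interior <- records$position >= 2L & records$position <= lens - 1L
  tri <- rep(NA_character_, nrow(records))
  tri[interior] <- substring(seqs[interior], records$position[interior] - 1L,
                             records$position[interior] + 1L)
  purine <- records$ref_allele %in% c("A", "G")
  tri[purine] <- revcomp(tri[purine])
  tri
}

#' Fit per-sample APOBEC enrichment across a cohort
#'
#' The cohort-level fitting function: splits records by sample, computes each
#' sample's enrichment score and one-sided Fisher p-value, applies a single
#' cohort-wide Benjamini-Hochberg correction over the defined p-values, and
#' dichotomises samples into ES-high (`q < q_threshold`) and ES-low.
#'
#' @param records mutation record table for the whole cohort (the
#'   `sample_id` column defines the BH family).
#' @param genome a [genome_sequence()].
#' @param q_threshold FDR threshold for the ES-high call (default 0.1).
#' @param half_width,motif,exclude_contigs passed to [enrichment_score()].
#' @return an object of class `apobec_enrichment`: a data frame with one row
#'   per sample (`sample_id`, the four counts, `score`, `p_value`, `q_value`,
#'   `es_class`).
#' @export
apobec_enrichment <- function(records, genome, q_threshold = 0.1,
                              half_width = 20L, motif = c("TCW", "TCA"),
                              exclude_contigs = c("chrM", "MT", "M")) {
  motif <- match.arg(motif)
  sids <- unique(records$sample_id)
  if (length(sids) == 0L) stop("no records supplied", call. = FALSE)
  fits <- lapply(sids, function(s)
    enrichment_score(records[records$sample_id == s, , drop = FALSE], genome,
                     sample_id = s, half_width = half_width, motif = motif,
                     exclude_contigs = exclude_contigs))
  df <- data.frame(
    sample_id = sids,
    mut_tcw = vapply(fits, function(f) f$counts[["mut_tcw"]], 0L),
    mut_c = vapply(fits, function(f) f$counts[["mut_c"]], 0L),
    con_tcw = vapply(fits, function(f) f$counts[["con_tcw"]], 0L),
    con_c = vapply(fits, function(f) f$counts[["con_c"]], 0L),
    score = vapply(fits, function(f) f$score, 0),
    p_value = vapply(fits, function(f) f$p_value, 0),
    q_value = NA_real_, es_class = NA_character_,
    stringsAsFactors = FALSE
  )
  defined <- !is.na(df$p_value)
  if (sum(!defined)) message(sprintf(
    "apobec_enrichment: %d sample(s) with undefined score excluded from BH",
    sum(!defined)))
  df$q_value[defined] <- bh_adjust(df$p_value[defined])
  out <- structure(df, class = c("apobec_enrichment", "data.frame"),
                   q_threshold = q_threshold, half_width = half_width,
                   motif = motif)
  classify_es(out, q_threshold)
}

#' Dichotomise samples into ES-high / ES-low
#'
#' `es_class` is `"high"` iff `q_value < q_threshold` (strict); samples with
#' undefined scores keep `NA`. A defined score with an unset q-value is an
#' error (run cohort-wide correction first).
#'
#' @param results an `apobec_enrichment` object (or data frame with `score`,
#'   `q_value` columns).
#' @param q_threshold FDR threshold (default 0.1).
#' @return `results` with `es_class` filled in.
#' @export
classify_es <- function(results, q_threshold = 0.1) {
  defined <- !is.na(results$score)
  if (any(defined & is.na(results$q_value)))
    stop("q_value unset; apply cohort-wide BH correction before classify_es",
         call. = FALSE)
  results$es_class[defined] <-
    ifelse(results$q_value[defined] < q_threshold, "high", "low")
  attr(results, "q_threshold") <- q_threshold
  message(sprintf("classify_es: %d high, %d low (q < %g)",
                  sum(results$es_class == "high", na.rm = TRUE),
                  sum(results$es_class == "low", na.rm = TRUE), q_threshold))
  results
}

#' @export
print.apobec_enrichment <- function(x, digits = 4, ...) {
  cat(sprintf(
    "APOBEC TCW enrichment: %d sample(s), motif %s, window %d bases, ES-high at q < %g\n",
    nrow(x), attr(x, "motif"), 2L * attr(x, "half_width") + 1L,
    attr(x, "q_threshold")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.apobec_enrichment <- function(object, ...) {
  cat(sprintf("APOBEC TCW enrichment over %d sample(s)\n", nrow(object)))
  cat(sprintf("  score: min %.3g, median %.3g, max %.3g\n",
              min(object$score, na.rm = TRUE),
              stats::median(object$score, na.rm = TRUE),
              max(object$score, na.rm = TRUE)))
  cat(sprintf("  ES-high: %d   ES-low: %d   undefined: %d\n",
              sum(object$es_class == "high", na.rm = TRUE),
              sum(object$es_class == "low", na.rm = TRUE),
              sum(is.na(object$score))))
  invisible(object)
}

#' @export
plot.apobec_enrichment <- function(x, ...) {
  ord <- order(x$score)
  cols <- ifelse(x$es_class[ord] == "high", "#E32926", "grey60")
  graphics::barplot(x$score[ord], names.arg = x$sample_id[ord], las = 2,
                    col = cols, border = NA, ylab = "TCW enrichment score",
                    ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Correlate an enrichment score with a covariate
#'
#' Pearson or Spearman correlation with two-sided p-value, after pairwise
#' deletion of missing values. Zero variance in either vector yields an
#' undefined coefficient (flagged, `NA`).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `p_value`, `n`, `method`, `degenerate`.
#' @export
associate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("associate: zero variance; coefficient undefined")
    return(list(coefficient = NA_real_, p_value = NA_real_, n = length(x),
                method = method, degenerate = TRUE))
  }
  ct <- if (method == "spearman")
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  else stats::cor.test(x, y, method = "pearson")
  list(coefficient = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method, degenerate = FALSE)
}

#' Compare a quantity between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie correction,
#' suited to the non-normal per-tumor totals being compared.
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @return list with `u_statistic` and `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied groups: no evidence against exchangeability
  list(u_statistic = unname(wt$statistic), p_value = min(p, 1))
}
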