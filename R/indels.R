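# Insertion/deletion classification into size and microhomology categories,
# per-sample indel spectra, and their association with APOBEC enrichment.
#
# Categories: {insertion, deletion} x {1 (split T/A vs C/G), 2, 3, 4,
# 5plus (5-200 bp)}, with a microhomology flag on deletions of 2+ bp.
# Events longer than 200 bp are classified but flagged out-of-spectrum.

#' All indel class labels
#'
#' @return character vector of the 16 class labels used by
#'   [summarize_indels()].
#' @export
indel_classes <- function() {
  c("ins_1_TA", "ins_1_CG", "ins_2", "ins_3", "ins_4", "ins_5plus",
    "del_1_TA", "del_1_CG",
    "del_2", "del_2_mh", "del_3", "del_3_mh", "del_4", "del_4_mh",
    "del_5plus", "del_5plus_mh")
}

#' Left-align indel records against the reference
#'
#' Defensive normalisation for callers that did not left-align: a simple
#' indel (one allele a prefix of the other) is shifted left while the base
#' preceding the anchor equals the last base of the inserted/deleted
#' sequence. Complex indels are returned unchanged.
#'
#' @param records a mutation record table.
#' @param genome a [genome_sequence()].
#' @return the records, possibly with shifted positions and alleles.
#' @export
normalize_indels <- function(records, genome) {
  idx <- which(is_indel(records))
  for (i in idx) {
    ref <- records$ref_allele[i]; alt <- records$alt_allele[i]
    long <- if (nchar(ref) > nchar(alt)) ref else alt
    short <- if (nchar(ref) > nchar(alt)) alt else ref
    if (!startsWith(long, short) || nchar(short) != 1L) next
    pos <- records$position[i]
    seqc <- unclass(genome)[[records$contig[i]]]
    ins <- substr(long, 2L, nchar(long))
    # shifting one base left is allowed while the anchor base equals the last
    # base of the inserted/deleted sequence (the event window slides)
    while (pos > 1L &&
           substr(seqc, pos, pos) == substr(ins, nchar(ins), nchar(ins))) {
      pos <- pos - 1L
      ins <- paste0(substr(seqc, pos + 1L, pos + 1L),
                    substr(ins, 1L, nchar(ins) - 1L))
    }
    if (pos != records$position[i]) {
      anchor <- substr(seqc, pos, pos)
      records$position[i] <- pos
      if (nchar(ref) > nchar(alt)) {
        records$ref_allele[i] <- paste0(anchor, ins)
        records$alt_allele[i] <- anchor
      } else {
        records$ref_allele[i] <- anchor
        records$alt_allele[i] <- paste0(anchor, ins)
      }
    }
  }
  records
}

#' Classify insertion/deletion records
#'
#' Net length is `|nchar(ref) - nchar(alt)|` (0 is an error: a balanced
#' substitution, not an indel). Size categories are 1-4 and `5plus`
#' (5-200 bp); longer events are classified but flagged out-of-spectrum.
#' Single-base events are subtyped T/A vs C/G by the inserted/deleted base.
#' A deletion of 2+ bp carries microhomology when the deleted sequence and
#' the reference immediately 3' of the deletion share a common prefix of at
#' least one base (scanned up to `mh_scan` bases).
#'
#' @param records a mutation record table; all rows must be indels in
#'   left-anchored (shared first base) representation.
#' @param genome a [genome_sequence()].
#' @param mh_scan bases of 3' flank examined for microhomology.
#' @return data frame with one row per record: `kind`, `size_category`,
#'   `one_bp_subtype`, `microhomology`, `mh_length`, `class`,
#'   `out_of_spectrum`.
#' @export
classify_indel <- function(records, genome, mh_scan = 10L) {
  if (nrow(records) == 0L)
    return(data.frame(kind = character(0), size_category = character(0),
                      one_bp_subtype = character(0),
                      microhomology = logical(0), mh_length = integer(0),
                      class = character(0), out_of_spectrum = logical(0),
                      stringsAsFactors = FALSE))
  if (!all(is_indel(records)))
    stop("classify_indel requires indel records only (net length > 0)",
         call. = FALSE)
  nr <- nchar(records$ref_allele)
  na_ <- nchar(records$alt_allele)
  net <- abs(nr - na_)
  kind <- ifelse(nr > na_, "deletion", "insertion")
  size_cat <- ifelse(net == 1L, "1",
              ifelse(net == 2L, "2",
              ifelse(net == 3L, "3",
              ifelse(net == 4L, "4", "5plus"))))
  out_of_spectrum <- net > 200L
  lcp <- lcp_length(records$ref_allele, records$alt_allele)
  lcp <- pmax(lcp, 1L)  # left-anchored representation shares the first base
  longer <- ifelse(nr > na_, records$ref_allele, records$alt_allele)
  indel_seq <- substr(longer, lcp + 1L, lcp + net)
  subtype <- rep("not_applicable", nrow(records))
  one <- net == 1L
  subtype[one] <- ifelse(indel_seq[one] %in% c("T", "A"), "T/A", "C/G")
  mh <- rep(FALSE, nrow(records))
  mh_len <- rep(0L, nrow(records))
  del2 <- which(kind == "deletion" & net >= 2L)
  for (i in del2) {
    flank_start <- records$position[i] + nr[i]
    seqc <- unclass(genome)[[records$contig[i]]]
    if (is.null(seqc))
      stop(sprintf("contig '%s' not present in genome", records$contig[i]),
           call. = FALSE)
    if (flank_start > nchar(seqc)) next
    flank <- substr(seqc, flank_start,
                    min(nchar(seqc), flank_start + mh_scan - 1L))
    d <- substr(indel_seq[i], 1L, mh_scan)
    mh_len[i] <- lcp_length(d, flank)
    mh[i] <- mh_len[i] >= 1L
  }
  cls <- ifelse(net == 1L,
                paste0(substr(kind, 1, 3), "_1_",
                       ifelse(subtype == "T/A", "TA", "CG")),
                paste0(substr(kind, 1, 3), "_", size_cat,
                       ifelse(mh, "_mh", "")))
  if (any(out_of_spectrum)) message(sprintf(
    "classify_indel: %d event(s) longer than 200 bp flagged out-of-spectrum",
    sum(out_of_spectrum)))
  data.frame(kind = kind, size_category = size_cat, one_bp_subtype = subtype,
             microhomology = mh, mh_length = mh_len, class = cls,
             out_of_spectrum = out_of_spectrum, stringsAsFactors = FALSE)
}

#' Summarise a sample's indels into the class spectrum
#'
#' Counts events per indel class; events longer than 200 bp are excluded
#' from the spectrum and tallied separately.
#'
#' @param records a mutation record table (any mix; only indels consumed).
#' @param genome a [genome_sequence()].
#' @param sample_id label; defaults to the records' single sample id.
#' @param mh_scan passed to [classify_indel()].
#' @return an object of class `indel_summary`: named integer vector over
#'   [indel_classes()] with attributes `sample_id`, `total_under_200`,
#'   `n_over_200`.
#' @export
summarize_indels <- function(records, genome, sample_id = NULL,
                             mh_scan = 10L) {
  if (is.null(sample_id)) {
    sid <- unique(records$sample_id)
    sample_id <- if (length(sid) == 1L) sid else "cohort"
  }
  ind <- records[is_indel(records), , drop = FALSE]
  cls <- classify_indel(ind, genome, mh_scan)
  in_spec <- !cls$out_of_spectrum
  counts <- table(factor(cls$class[in_spec], levels = indel_classes()))
  out <- stats::setNames(as.integer(counts), indel_classes())
  structure(out, class = "indel_summary", sample_id = sample_id,
            total_under_200 = sum(out), n_over_200 = sum(!in_spec))
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("indel_summary '%s': %d indels < 200 bp (%d longer excluded)\n",
              attr(x, "sample_id"), attr(x, "total_under_200"),
              attr(x, "n_over_200")))
  nz <- unclass(x)[unclass(x) > 0]
  if (length(nz))
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble indel summaries into a samples-by-class matrix
#'
#' @param summaries list of `indel_summary` objects.
#' @return integer matrix with a `total_under_200` final column.
#' @export
indel_matrix <- function(summaries) {
  m <- do.call(rbind, lapply(summaries, unclass))
  rownames(m) <- vapply(summaries, attr, "", "sample_id")
  cbind(m, total_under_200 = vapply(summaries, attr, 0L, "total_under_200"))
}

#' Associate indel class counts with APOBEC enrichment scores
#'
#' Spearman rank correlation of each indel class count (and of the total
#' under 200 bp) with the per-sample enrichment score. Samples must match
#' one-to-one between the two inputs.
#'
#' @param summaries list of `indel_summary` objects.
#' @param scores an `apobec_enrichment` object (or data frame with
#'   `sample_id` and `score`).
#' @param per_class also report one row per indel class (default `TRUE`;
#'   otherwise only the total).
#' @return data frame with `class`, `rho`, `p_value`, `n`, `degenerate`.
#' @export
indel_enrichment_association <- function(summaries, scores,
                                         per_class = TRUE) {
  m <- indel_matrix(summaries)
  ids <- rownames(m)
  missing <- setdiff(ids, scores$sample_id)
  extra <- setdiff(scores$sample_id, ids)
  if (length(missing) || length(extra))
    stop("sample mismatch between indel summaries and scores: ",
         paste(c(missing, extra), collapse = ", "), call. = FALSE)
  sc <- scores$score[match(ids, scores$sample_id)]
  cols <- if (per_class) colnames(m) else "total_under_200"
  rows <- lapply(cols, function(cl) {
    a <- associate(sc, m[, cl], method = "spearman")
    data.frame(class = cl, rho = a$coefficient, p_value = a$p_value,
               n = a$n, degenerate = a$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
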