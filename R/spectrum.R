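# 96-context single-base-substitution classification and per-sample spectra.
#
# Every substitution is reported on the pyrimidine strand: purine-reference
# events are reverse-complemented together with their flanks, so the 96
# classes are {C,T} reference x 3 alternates x 16 flank pairs.

PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution classes, in catalog order
#'
#' Substitution-major order (C>A, C>G, C>T, T>A, T>C, T>G), flanks
#' lexicographic (A, C, G, T; 5' outer), matching conventional signature
#' catalog serialization so spectra align with catalog matrices column by
#' column.
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs_classes <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(PYRIMIDINE_SUBS, function(s)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))))
}

#' Classify single-base substitutions into 96 trinucleotide classes
#'
#' Flanking bases are read from the reference genome (never from the VCF).
#' Purine-reference events are reverse-complemented, flanks included, so the
#' reported class always has a pyrimidine reference. A record whose reference
#' allele disagrees with the genome is an error (it signals a wrong genome
#' build). Records at contig edges (no flank) or whose context contains N are
#' unclassifiable and returned as `NA`, with counts in the `"n_excluded"`
#' attribute.
#'
#' @param records a mutation record table; all rows must be SBS.
#' @param genome a [genome_sequence()].
#' @return character vector of classes (NA = excluded), with attribute
#'   `n_excluded`.
#' @export
classify_sbs <- function(records, genome) {
  if (nrow(records) == 0L)
    return(structure(character(0), n_excluded = 0L))
  if (!all(is_sbs(records)))
    stop("classify_sbs requires single-base substitutions only", call. = FALSE)
  missing_ctg <- setdiff(unique(records$contig), names(genome))
  if (length(missing_ctg))
    stop(sprintf("contig '%s' not present in genome", missing_ctg[1L]),
         call. = FALSE)
  seqs <- unname(unclass(genome)[records$contig])
  lens <- nchar(seqs)
  if (any(records$position > lens))
    stop("record position beyond contig end", call. = FALSE)
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
  alt <- records$alt_allele
  purine <- records$ref_allele %in% c("A", "G")
  tri[purine] <- revcomp(tri[purine])
  alt[purine] <- complement_base(alt[purine])
  has_n <- !is.na(tri) & grepl("N", tri, fixed = TRUE)
  usable <- !is.na(tri) & !has_n
  cls <- rep(NA_character_, nrow(records))
  cls[usable] <- paste0(substr(tri[usable], 1L, 1L), "[",
                        substr(tri[usable], 2L, 2L), ">", alt[usable], "]",
                        substr(tri[usable], 3L, 3L))
  n_excl <- sum(!usable)
  if (n_excl) message(sprintf(
    "classify_sbs: %d record(s) excluded (contig edge or N in context)", n_excl))
  structure(cls, n_excluded = n_excl)
}

#' Build a per-sample 96-context spectrum
#'
#' Non-SBS records are skipped (count logged); unclassifiable SBS are
#' excluded. The spectrum total equals the number of classified SBS.
#'
#' @param records a mutation record table.
#' @param genome a [genome_sequence()].
#' @param sample_id label stored on the spectrum; defaults to the records'
#'   single sample id.
#' @return an object of class `spectrum96`: a named integer vector over
#'   [sbs_classes()] with attributes `sample_id`, `total`, `n_non_sbs`,
#'   `n_excluded`.
#' @export
build_spectrum <- function(records, genome, sample_id = NULL) {
  if (is.null(sample_id)) {
    sid <- unique(records$sample_id)
    sample_id <- if (length(sid) == 1L) sid else "cohort"
  }
  sbs <- records[is_sbs(records), , drop = FALSE]
  n_non_sbs <- nrow(records) - nrow(sbs)
  if (n_non_sbs) message(sprintf(
    "build_spectrum: %d non-SBS record(s) skipped", n_non_sbs))
  cls <- classify_sbs(sbs, genome)
  counts <- table(factor(cls, levels = sbs_classes()))
  out <- stats::setNames(as.integer(counts), sbs_classes())
  if (sum(out) == 0L) message("build_spectrum: empty spectrum (no classifiable SBS)")
  structure(out, class = "spectrum96", sample_id = sample_id,
            total = sum(out), n_non_sbs = n_non_sbs,
            n_excluded = attr(cls, "n_excluded"))
}

#' @export
print.spectrum96 <- function(x, ...) {
  cat(sprintf("spectrum96 for sample '%s': %d classified SBS\n",
              attr(x, "sample_id"), attr(x, "total")))
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  top <- top[top > 0]
  if (length(top))
    cat("  top classes:",
        paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a 96-context spectrum as the conventional profile barplot
#'
#' @param x a `spectrum96`.
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.spectrum96 <- function(x, main = attr(x, "sample_id"), ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16L)
  graphics::barplot(unclass(x), col = cols, border = NA, names.arg = FALSE,
                    main = main, ylab = "mutations", ...)
  graphics::mtext(PYRIMIDINE_SUBS, side = 3, line = 0,
                  at = seq(8, 96, by = 16) * 1.2, cex = 0.8)
  invisible(x)
}

#' Assemble spectra into a samples-by-96 matrix
#'
#' @param spectra a list of `spectrum96` objects.
#' @return integer matrix, rows = samples, columns = [sbs_classes()].
#' @export
spectra_matrix <- function(spectra) {
  m <- do.call(rbind, lapply(spectra, unclass))
  rownames(m) <- vapply(spectra, attr, "", "sample_id")
  m
}

#' Write spectra as a wide TSV (samples x 96)
#'
#' Column order matches signature-catalog matrices.
#'
#' @param spectra list of `spectrum96` objects or a matrix from
#'   [spectra_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  m <- if (is.matrix(spectra)) spectra else spectra_matrix(spectra)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of SBS that are TC->TT events
#'
#' The numerator counts SBS whose pyrimidine-strand class is `T[C>T]N`; the
#' denominator is all classifiable SBS. Returns 0 (flagged via the `"empty"`
#' attribute) when there are no SBS.
#'
#' @param records a mutation record table.
#' @param genome a [genome_sequence()].
#' @return a fraction in `[0, 1]` with attribute `empty`.
#' @export
tc_to_tt_fraction <- function(records, genome) {
  sbs <- records[is_sbs(records), , drop = FALSE]
  cls <- classify_sbs(sbs, genome)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L)
    return(structure(0, empty = TRUE))
  num <- sum(substr(cls, 1L, 1L) == "T" & substr(cls, 3L, 5L) == "C>T")
  structure(num / length(cls), empty = FALSE)
}
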