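# Reference genome container and FASTA input/output.

#' Construct a genome sequence object
#'
#' A genome is an ordered, named set of uppercase nucleotide strings over
#' the alphabet A/C/G/T/N. Contig names must be unique and sequences
#' non-empty.
#'
#' @param contigs named character vector, one element per contig.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(contigs) {
  if (!is.character(contigs) || length(contigs) == 0L)
    stop("`contigs` must be a non-empty named character vector", call. = FALSE)
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every contig must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate contig name: '%s'", nm[duplicated(nm)][1L]),
         call. = FALSE)
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L))
    stop(sprintf("contig '%s' is empty", nm[nchar(contigs) == 0L][1L]),
         call. = FALSE)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop(sprintf("contig '%s' contains characters outside A/C/G/T/N",
                 nm[bad][1L]), call. = FALSE)
  structure(contigs, class = "genome_sequence")
}

#' Read a reference genome from FASTA
#'
#' Contigs are keyed by the first whitespace-delimited token of each header
#' line; sequence is uppercased. Duplicate contig names, empty contigs,
#' uracil (U) bases and any character outside A/C/G/T/N are errors that name
#' the offending line.
#'
#' @param path path to a FASTA file.
#' @return a [genome_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file", call. = FALSE)
  is_header <- grepl("^>", lines)
  if (!is_header[nonblank[1L]])
    stop(sprintf("malformed FASTA: line %d precedes any header", nonblank[1L]),
         call. = FALSE)
  useq <- toupper(lines)
  for (i in nonblank) {
    if (is_header[i]) next
    if (grepl("U", useq[i], fixed = TRUE))
      stop(sprintf("malformed FASTA: uracil (U) base at line %d; RNA input is not supported", i),
           call. = FALSE)
    if (grepl("[^ACGTN[:space:]]", useq[i]))
      stop(sprintf("malformed FASTA: invalid sequence character at line %d", i),
           call. = FALSE)
  }
  grp <- cumsum(is_header)
  headers <- lines[is_header]
  nm <- sub("\\s.*$", "", sub("^>\\s*", "", headers))
  if (any(!nzchar(nm)))
    stop(sprintf("malformed FASTA: empty contig name at line %d",
                 which(is_header)[!nzchar(nm)][1L]), call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate contig name: '%s'", nm[duplicated(nm)][1L]),
         call. = FALSE)
  seqs <- vapply(seq_along(headers), function(k) {
    idx <- which(grp == k & !is_header)
    paste(gsub("[[:space:]]", "", useq[idx]), collapse = "")
  }, "")
  names(seqs) <- nm
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_sequence()].
#' @param path output path.
#' @param width line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract a reference subsequence
#'
#' 1-based, inclusive coordinates. When `clamp = TRUE` the range is truncated
#' at the contig edges; otherwise out-of-range coordinates are an error.
#'
#' @param genome a [genome_sequence()].
#' @param contig contig name.
#' @param start,end 1-based inclusive positions.
#' @param clamp truncate at contig boundaries instead of erroring.
#' @return a character scalar.
#' @export
genome_slice <- function(genome, contig, start, end, clamp = FALSE) {
  if (!contig %in% names(genome))
    stop(sprintf("contig '%s' not present in genome", contig), call. = FALSE)
  len <- nchar(genome[[contig]])
  if (clamp) {
    start <- max(1L, start)
    end <- min(len, end)
  } else if (start < 1L || end > len || start > end) {
    stop(sprintf("range %d-%d out of bounds for contig '%s' (length %d)",
                 start, end, contig, len), call. = FALSE)
  }
  substr(genome[[contig]], start, end)
}

contig_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' @export
print.genome_sequence <- function(x, ...) {
  lens <- contig_lengths(x)
  gc <- sum(count_pattern(unclass(x), "[GC]")) / sum(lens)
  cat(sprintf("genome_sequence: %d contig(s), %s bases, GC %.3f\n",
              length(x), format(sum(lens), big.mark = ","), gc))
  show <- utils::head(lens, 8L)
  for (nm in names(show)) cat(sprintf("  %s: %d bp\n", nm, show[[nm]]))
  if (length(lens) > 8L) cat(sprintf("  ... and %d more\n", length(lens) - 8L))
  invisible(x)
}
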