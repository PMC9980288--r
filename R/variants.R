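# Somatic variant ingestion, the internal mutation model, and the
# read-support filters applied before any downstream analysis.

#' Construct a table of mutation records
#'
#' The internal mutation model: one row per somatic substitution or indel,
#' with 1-based coordinates, explicit alleles over A/C/G/T, and read support.
#' `vaf` is checked against `alt_depth / total_depth` (tolerance 1e-9) when
#' depths are present, and derived from them when missing.
#'
#' @param sample_id,contig,position,ref_allele,alt_allele record fields.
#' @param alt_depth,total_depth,vaf read support; may be `NA`.
#' @return a `data.frame` with one row per record.
#' @export
mutation_records <- function(sample_id, contig, position, ref_allele,
                             alt_allele, alt_depth = NA_integer_,
                             total_depth = NA_integer_, vaf = NA_real_) {
  n <- length(position)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    contig = rep_len(as.character(contig), n),
    position = as.integer(position),
    ref_allele = toupper(rep_len(as.character(ref_allele), n)),
    alt_allele = toupper(rep_len(as.character(alt_allele), n)),
    alt_depth = rep_len(as.integer(alt_depth), n),
    total_depth = rep_len(as.integer(total_depth), n),
    vaf = rep_len(as.numeric(vaf), n),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

validate_records <- function(df) {
  need <- c("sample_id", "contig", "position", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("alt_depth", "total_depth"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  if (!"vaf" %in% names(df)) df[[col <- "vaf"]] <- NA_real_
  if (nrow(df) == 0L) return(df)
  if (any(is.na(df$position)) || any(df$position < 1L))
    stop("positions must be 1-based positive integers", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", df$ref_allele) | !grepl("^[ACGT]+$", df$alt_allele)
  if (any(bad))
    stop(sprintf("allele outside A/C/G/T at %s:%d",
                 df$contig[bad][1L], df$position[bad][1L]), call. = FALSE)
  same <- df$ref_allele == df$alt_allele
  if (any(same))
    stop(sprintf("ref and alt alleles identical at %s:%d",
                 df$contig[same][1L], df$position[same][1L]), call. = FALSE)
  have_depth <- !is.na(df$alt_depth) & !is.na(df$total_depth)
  derive <- have_depth & is.na(df$vaf)
  df$vaf[derive] <- df$alt_depth[derive] / df$total_depth[derive]
  chk <- have_depth & !is.na(df$vaf)
  off <- chk & abs(df$vaf - df$alt_depth / df$total_depth) > 1e-9
  if (any(off))
    stop(sprintf("vaf inconsistent with alt_depth/total_depth at %s:%d",
                 df$contig[off][1L], df$position[off][1L]), call. = FALSE)
  df
}

#' Classify records as single-base substitutions
#'
#' @param records a mutation record table.
#' @return logical vector.
#' @export
is_sbs <- function(records) {
  nchar(records$ref_allele) == 1L & nchar(records$alt_allele) == 1L
}

#' Classify records as insertions/deletions
#'
#' An indel has alleles of unequal length. Equal-length multi-base
#' substitutions are neither SBS nor indel and are excluded from both
#' analyses.
#'
#' @param records a mutation record table.
#' @return logical vector.
#' @export
is_indel <- function(records) {
  nchar(records$ref_allele) != nchar(records$alt_allele)
}

#' Read somatic variant calls from a VCF
#'
#' Emits one record per ALT allele of each FILTER-pass (`PASS` or `.`) row;
#' multi-allelic sites are split. Depths are taken from the tumor sample's
#' `AD` field (falling back to `AF` x `DP` when `AD` is absent); records with
#' neither are kept with missing depths and flagged when a depth-requiring
#' filter is later applied. Symbolic, spanning-deletion and non-ACGT alleles
#' are dropped with a message. Positions stay 1-based as in the VCF.
#'
#' @param path path to a VCF (v4.x, plain or gzipped).
#' @param sample_id sample identifier; used to pick the tumor genotype column
#'   when present, and stamped on every record.
#' @return a mutation record table.
#' @export
read_vcf_somatic <- function(path, sample_id) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(mutation_records(character(0), character(0), integer(0),
                            character(0), character(0)))
  gt <- v@gt
  scol <- NULL
  if (!is.null(gt) && ncol(gt) >= 2L) {
    scol <- if (sample_id %in% colnames(gt)) sample_id else colnames(gt)[2L]
  }
  pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  n_fail <- sum(!pass)
  if (n_fail) message(sprintf("read_vcf_somatic: %d record(s) removed by FILTER", n_fail))
  pos <- as.integer(fix$POS)
  if (is.unsorted(order(fix$CHROM, pos)[pass]) &&
      any(diff(pos[pass][!duplicated(fix$CHROM[pass])]) < 0))
    message("read_vcf_somatic: input not coordinate-sorted; accepted as-is")

  out <- vector("list", nrow(fix))
  n_dropped <- 0L
  for (i in which(pass)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    ref <- toupper(fix$REF[i])
    fmt <- ad <- af <- dp <- NULL
    if (!is.null(scol)) {
      fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
      val <- strsplit(gt[i, scol], ":", fixed = TRUE)[[1L]]
      pick <- function(key) {
        j <- match(key, fmt)
        if (is.na(j) || j > length(val) || val[j] %in% c(".", "")) NULL else val[j]
      }
      ad <- pick("AD"); af <- pick("AF"); dp <- pick("DP")
    }
    ad_v <- if (!is.null(ad)) suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1L]]))
    af_v <- if (!is.null(af)) suppressWarnings(as.numeric(strsplit(af, ",", fixed = TRUE)[[1L]]))
    dp_v <- if (!is.null(dp)) suppressWarnings(as.numeric(dp))
    rows <- lapply(seq_along(alts), function(k) {
      alt <- toupper(alts[k])
      if (!grepl("^[ACGT]+$", alt) || !grepl("^[ACGT]+$", ref)) {
        n_dropped <<- n_dropped + 1L
        return(NULL)
      }
      altd <- totd <- NA_integer_
      if (!is.null(ad_v) && length(ad_v) >= k + 1L && !anyNA(ad_v)) {
        altd <- as.integer(ad_v[k + 1L])
        totd <- as.integer(sum(ad_v))
      } else if (!is.null(af_v) && !is.null(dp_v) && length(af_v) >= k) {
        totd <- as.integer(dp_v)
        altd <- as.integer(round(af_v[k] * dp_v))
      }
      data.frame(sample_id = sample_id, contig = fix$CHROM[i],
                 position = pos[i], ref_allele = ref, alt_allele = alt,
                 alt_depth = altd, total_depth = totd,
                 vaf = if (is.na(altd) || is.na(totd) || totd == 0L) NA_real_
                       else altd / totd,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  if (n_dropped) message(sprintf(
    "read_vcf_somatic: %d symbolic/non-ACGT allele(s) dropped", n_dropped))
  res <- do.call(rbind, out)
  if (is.null(res))
    return(mutation_records(character(0), character(0), integer(0),
                            character(0), character(0)))
  rownames(res) <- NULL
  validate_records(res)
}

#' Write mutation records as a minimal VCF 4.2
#'
#' One tumor sample column carrying `GT:AD:DP`. Records are written in input
#' order; pass coordinate-sorted records for a spec-conformant file. The
#' header is deterministic (no timestamps).
#'
#' @param records a mutation record table for a single sample.
#' @param path output path.
#' @param genome optional [genome_sequence()] used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  sid <- unique(records$sample_id)
  if (length(sid) > 1L)
    stop("write_vcf expects records from a single sample", call. = FALSE)
  if (length(sid) == 0L) sid <- "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sigscan",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome), contig_lengths(genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid), collapse = "\t")
  )
  body <- if (nrow(records)) {
    ad <- ifelse(is.na(records$alt_depth) | is.na(records$total_depth), ".",
                 paste0(records$total_depth - records$alt_depth, ",",
                        records$alt_depth))
    dp <- ifelse(is.na(records$total_depth), ".", records$total_depth)
    paste(records$contig, records$position, ".", records$ref_allele,
          records$alt_allele, ".", "PASS", ".", "GT:AD:DP",
          paste0("0/1:", ad, ":", dp), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read mutation records from the TSV fallback format
#'
#' Columns: `sample`, `chrom`, `pos`, `ref`, `alt`, and optionally
#' `alt_depth`, `total_depth`, `vaf`.
#'
#' @param path input TSV path.
#' @return a mutation record table.
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("records TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mutation_records(df$sample, df$chrom, df$pos, df$ref, df$alt,
                   df$alt_depth %||% NA_integer_,
                   df$total_depth %||% NA_integer_,
                   df$vaf %||% NA_real_)
}

#' Write mutation records to the TSV fallback format
#'
#' @param records a mutation record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  out <- data.frame(sample = records$sample_id, chrom = records$contig,
                    pos = records$position, ref = records$ref_allele,
                    alt = records$alt_allele, alt_depth = records$alt_depth,
                    total_depth = records$total_depth, vaf = records$vaf,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read-support filter policy
#'
#' Defaults follow the study design: at least 3 variant-supporting reads,
#' at least 10 total reads, variant allele frequency strictly over 0.05,
#' and exclusion of the mitochondrial genome (common aliases).
#'
#' @param min_alt_reads minimum variant-supporting reads (kept if `>=`).
#' @param min_total_reads minimum total depth at the site (kept if `>=`).
#' @param min_vaf VAF threshold; records kept only if strictly greater.
#' @param exclude_contigs contig names removed outright.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_alt_reads = 3L, min_total_reads = 10L,
                          min_vaf = 0.05,
                          exclude_contigs = c("chrM", "MT", "M")) {
  if (min_alt_reads < 0L || min_total_reads < 0L)
    stop("read thresholds must be non-negative", call. = FALSE)
  if (min_vaf < 0 || min_vaf >= 1)
    stop("min_vaf must lie in [0, 1)", call. = FALSE)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_total_reads = as.integer(min_total_reads),
                 min_vaf = as.numeric(min_vaf),
                 exclude_contigs = as.character(exclude_contigs)),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf(
    "filter_policy: alt reads >= %d, total reads >= %d, VAF > %g, exclude {%s}\n",
    x$min_alt_reads, x$min_total_reads, x$min_vaf,
    paste(x$exclude_contigs, collapse = ", ")))
  invisible(x)
}

#' Apply read-support filters to mutation records
#'
#' Keeps records with `alt_depth >= min_alt_reads`, `total_depth >=
#' min_total_reads`, `vaf > min_vaf` (strict), and contig outside the
#' exclusion set. Input order is preserved; per-rule removal counts are
#' attached as the `"filter_log"` attribute and reported via [message()].
#' The operation is idempotent.
#'
#' @param records a mutation record table.
#' @param policy a [filter_policy()].
#' @return the retained records.
#' @export
apply_filters <- function(records, policy = filter_policy()) {
  records <- validate_records(records)
  if (nrow(records) == 0L) {
    attr(records, "filter_log") <- c(input = 0L, fail_alt_reads = 0L,
                                     fail_total_reads = 0L, fail_vaf = 0L,
                                     fail_contig = 0L, kept = 0L)
    return(records)
  }
  needs_depth <- policy$min_alt_reads > 0L || policy$min_total_reads > 0L
  no_depth <- is.na(records$alt_depth) | is.na(records$total_depth)
  if (needs_depth && any(no_depth))
    stop(sprintf(
      "record(s) lack depth fields required by the filter policy (first: %s:%d)",
      records$contig[no_depth][1L], records$position[no_depth][1L]),
      call. = FALSE)
  no_vaf <- is.na(records$vaf)
  if (policy$min_vaf > 0 && any(no_vaf))
    stop(sprintf(
      "record(s) lack a VAF required by the filter policy (first: %s:%d)",
      records$contig[no_vaf][1L], records$position[no_vaf][1L]), call. = FALSE)
  ok_alt <- !needs_depth | records$alt_depth >= policy$min_alt_reads
  ok_tot <- !needs_depth | records$total_depth >= policy$min_total_reads
  ok_vaf <- if (policy$min_vaf > 0) records$vaf > policy$min_vaf else TRUE
  ok_ctg <- !(records$contig %in% policy$exclude_contigs)
  keep <- ok_alt & ok_tot & ok_vaf & ok_ctg
  log <- c(input = nrow(records),
           fail_alt_reads = sum(!ok_alt),
           fail_total_reads = sum(!ok_tot),
           fail_vaf = sum(!ok_vaf),
           fail_contig = sum(!ok_ctg),
           kept = sum(keep))
  if (any(!is.na(records$vaf) & records$vaf == policy$min_vaf))
    message(sprintf(
      "apply_filters: %d record(s) at VAF exactly %g removed (strict threshold)",
      sum(!is.na(records$vaf) & records$vaf == policy$min_vaf), policy$min_vaf))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  message(sprintf("apply_filters: kept %d of %d record(s)", log[["kept"]],
                  log[["input"]]))
  out
}
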