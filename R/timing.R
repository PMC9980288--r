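# Replication-timing quintile assignment and mutation-density profiles.
#
# Tracks are plain interval tables (BED convention: 0-based, half-open),
# non-overlapping within a contig. Quintile 1 is the earliest-replicating
# fifth of tracked bases; mutation positions are 1-based internally and
# converted at the boundary.

validate_track <- function(track) {
  need <- c("contig", "start", "end")
  miss <- setdiff(need, names(track))
  if (length(miss))
    stop("timing track lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(track$end <= track$start))
    stop("track intervals must satisfy start < end", call. = FALSE)
  for (ctg in unique(track$contig)) {
    iv <- track[track$contig == ctg, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop(sprintf("overlapping track intervals on contig '%s'", ctg),
           call. = FALSE)
  }
  track
}

#' Read a replication-timing track from BED
#'
#' BED4/BED5, 0-based half-open. The timing value is taken from the 5th
#' (score) column when present, otherwise the 4th. If every value is an
#' integer in 1..5 the track is treated as pre-labelled quintiles;
#' otherwise values are continuous timing scores for [quintilize()].
#'
#' @param path BED path.
#' @return a track data frame with columns `contig`, `start`, `end`,
#'   `timing` and, when pre-labelled, `quintile`.
#' @export
read_timing_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("timing BED needs at least 4 columns (chrom, start, end, value)",
         call. = FALSE)
  val <- if (ncol(df) >= 5L && is.numeric(df[[5L]])) df[[5L]] else df[[4L]]
  val <- suppressWarnings(as.numeric(val))
  if (anyNA(val))
    stop("timing BED value column is not numeric", call. = FALSE)
  track <- data.frame(contig = as.character(df[[1L]]),
                      start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                      timing = val, stringsAsFactors = FALSE)
  track <- validate_track(track)
  if (all(val == round(val) & val >= 1 & val <= 5))
    track$quintile <- as.integer(val)
  track
}

#' Write a timing track to BED4
#'
#' @param track a track data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timing_bed <- function(track, path) {
  utils::write.table(
    data.frame(track$contig, track$start, track$end, track$timing),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Label track intervals with replication-timing quintiles
#'
#' Length-weighted quantile cut of the continuous timing values: intervals
#' are ranked by timing value (ascending; quintile 1 = earliest) and split
#' so each quintile covers ~20% of tracked bases. An interval is assigned by
#' the quintile containing its cumulative-coverage midpoint, so ties and
#' boundary-spanning intervals resolve toward the earlier quintile.
#'
#' @param track a track data frame with continuous `timing` values (at
#'   least 5 distinct values).
#' @return the track with a `quintile` column (1-5).
#' @export
quintilize <- function(track) {
  track <- validate_track(track)
  if (!"timing" %in% names(track))
    stop("track lacks a `timing` column", call. = FALSE)
  if (length(unique(track$timing)) < 5L)
    stop("need at least 5 distinct timing values to form quintiles",
         call. = FALSE)
  len <- track$end - track$start
  ord <- order(track$timing)
  cum <- cumsum(len[ord])
  total <- sum(len)
  mid <- cum - len[ord] / 2
  q <- pmin(5L, pmax(1L, floor(mid / total * 5) + 1L))
  track$quintile <- NA_integer_
  track$quintile[ord] <- as.integer(q)
  track
}

#' Assign mutations to replication-timing quintiles
#'
#' Each record lands in the quintile of the interval containing its
#' position (1-based position `p` is inside `[start, end)` iff
#' `start < p <= end` in 0-based half-open coordinates). Records outside
#' every interval are collected under `"untracked"`.
#'
#' @param records a mutation record table (filtered SBS recommended).
#' @param track a quintile-labelled track (see [quintilize()]).
#' @return named list of record tables: `"1"`..`"5"` and `"untracked"`.
#' @export
assign_quintiles <- function(records, track) {
  if (!"quintile" %in% names(track))
    stop("track is not quintile-labelled; run quintilize() first", call. = FALSE)
  validate_track(track)
  qq <- rep(NA_integer_, nrow(records))
  for (ctg in unique(records$contig)) {
    iv <- track[track$contig == ctg, , drop = FALSE]
    sel <- which(records$contig == ctg)
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv$start), , drop = FALSE]
    pos0 <- records$position[sel] - 1L  # 0-based
    idx <- findInterval(pos0, iv$start)
    inside <- idx >= 1L & pos0 < iv$end[pmax(idx, 1L)]
    qq[sel[inside]] <- iv$quintile[idx[inside]]
  }
  out <- lapply(1:5, function(k) {
    r <- records[!is.na(qq) & qq == k, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  names(out) <- as.character(1:5)
  out$untracked <- records[is.na(qq), , drop = FALSE]
  rownames(out$untracked) <- NULL
  if (nrow(out$untracked)) message(sprintf(
    "assign_quintiles: %d record(s) outside the track", nrow(out$untracked)))
  out
}

#' Quintile mutation-density profile for a group
#'
#' Per-quintile mutation counts, counts normalised to the largest quintile,
#' and the TC->TT percentage among each quintile's SBS.
#'
#' @param assignment output of [assign_quintiles()] (samples pooled per
#'   group before calling, when group profiles are wanted).
#' @param genome a [genome_sequence()].
#' @param group_id label for the profile.
#' @return an object of class `quintile_profile`: list with `group_id`,
#'   `counts`, `normalized`, `tc_tt_percent`, `n_untracked`.
#' @export
quintile_profile <- function(assignment, genome, group_id = "group") {
  counts <- vapply(as.character(1:5), function(k) nrow(assignment[[k]]), 0L)
  if (all(counts == 0L))
    stop("no mutations in tracked regions", call. = FALSE)
  tc_tt <- vapply(as.character(1:5), function(k) {
    r <- assignment[[k]]
    if (nrow(r) == 0L) return(0)
    100 * as.numeric(tc_to_tt_fraction(r, genome))
  }, 0)
  structure(list(group_id = group_id, counts = counts,
                 normalized = counts / max(counts), tc_tt_percent = tc_tt,
                 n_untracked = nrow(assignment$untracked)),
            class = "quintile_profile")
}

#' @export
print.quintile_profile <- function(x, ...) {
  cat(sprintf("quintile_profile '%s' (early -> late):\n", x$group_id))
  cat("  counts:     ", paste(x$counts, collapse = "  "), "\n")
  cat("  normalized: ", paste(sprintf("%.3f", x$normalized), collapse = "  "),
      "\n")
  cat("  %% TC->TT:   ", paste(sprintf("%.1f", x$tc_tt_percent),
                               collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.quintile_profile <- function(x, ...) {
  graphics::barplot(x$normalized, names.arg = paste0("Q", 1:5),
                    col = "grey40", border = NA,
                    ylab = "mutations (normalized to largest quintile)",
                    main = x$group_id, ...)
  invisible(x)
}
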