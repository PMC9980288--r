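# Synthetic-cohort generator: genomes, somatic SBS sets with a planted
# APOBEC component, indel sets, replication-timing tracks, and complete
# cohorts with a truth table, so every pipeline stage has a parameter-
# recovery test. All generators are deterministic given their seed.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the study design the pipeline targets: a two-group
#' cohort (10 control samples with no planted APOBEC signal, 10 samples
#' with a planted TCW fraction of 0.6), ~1 Mb genome of uniform base
#' composition, 2000 SBS per sample, C>T-only APOBEC outcomes
#' (`apobec_ct_cg_split = 1`, the SBS2-without-SBS13 pattern), an
#' early-replication mutation bias (geometric quintile weights, ratio 0.5),
#' and indel burdens coupled to the planted APOBEC fraction.
#'
#' @param seed master seed; all per-sample seeds derive from it.
#' @param n_contigs,contig_length genome shape.
#' @param base_composition probabilities of A, C, G, T (sum 1).
#' @param n_samples cohort size.
#' @param sbs_per_sample substitutions drawn per sample.
#' @param apobec_fraction scalar or per-sample vector in `[0, 1]`: fraction
#'   of SBS drawn from the APOBEC process (C at TCW), the rest uniform
#'   background.
#' @param apobec_ct_cg_split probability a planted APOBEC event is C>T
#'   rather than C>G.
#' @param indels_per_sample baseline indel count per sample.
#' @param indel_length_distribution probabilities over categories
#'   `"1"`, `"2"`, `"3"`, `"4"`, `"5plus"` (5plus drawn uniformly 5-200 bp).
#' @param timing_bias_ratio geometric ratio r of quintile mutation weights
#'   (1, r, r^2, r^3, r^4); 1 = unbiased, <1 = early-replication bias.
#' @param timing_window tile width of the generated timing track (bases).
#' @param indel_rate_couples_to_apobec when `TRUE`, a sample's indel count
#'   is `round(indels_per_sample * (1 + 2 * apobec_fraction))`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_contigs = 4L,
                          contig_length = 250000L,
                          base_composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                          n_samples = 20L,
                          sbs_per_sample = 2000L,
                          apobec_fraction = rep(c(0, 0.6), each = 10L),
                          apobec_ct_cg_split = 1.0,
                          indels_per_sample = 200L,
                          indel_length_distribution = c("1" = 0.40,
                                                        "2" = 0.15,
                                                        "3" = 0.10,
                                                        "4" = 0.05,
                                                        "5plus" = 0.30),
                          timing_bias_ratio = 0.5,
                          timing_window = 10000L,
                          indel_rate_couples_to_apobec = TRUE) {
  stopifnot(length(base_composition) == 4L)
  if (abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1", call. = FALSE)
  if (abs(sum(indel_length_distribution) - 1) > 1e-9)
    stop("indel_length_distribution must sum to 1", call. = FALSE)
  if (!setequal(names(indel_length_distribution),
                c("1", "2", "3", "4", "5plus")))
    stop("indel_length_distribution must be named 1, 2, 3, 4, 5plus",
         call. = FALSE)
  if (any(apobec_fraction < 0 | apobec_fraction > 1))
    stop("apobec_fraction must lie in [0, 1]", call. = FALSE)
  if (apobec_ct_cg_split < 0 || apobec_ct_cg_split > 1)
    stop("apobec_ct_cg_split must lie in [0, 1]", call. = FALSE)
  if (timing_bias_ratio <= 0)
    stop("timing_bias_ratio must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 base_composition = stats::setNames(as.numeric(base_composition),
                                                    c("A", "C", "G", "T")),
                 n_samples = as.integer(n_samples),
                 sbs_per_sample = as.integer(sbs_per_sample),
                 apobec_fraction = as.numeric(apobec_fraction),
                 apobec_ct_cg_split = as.numeric(apobec_ct_cg_split),
                 indels_per_sample = as.integer(indels_per_sample),
                 indel_length_distribution =
                   indel_length_distribution[c("1", "2", "3", "4", "5plus")],
                 timing_bias_ratio = as.numeric(timing_bias_ratio),
                 timing_window = as.integer(timing_window),
                 indel_rate_couples_to_apobec =
                   isTRUE(indel_rate_couples_to_apobec)),
            class = "cohort_config")
}

#' Generate a random genome
#'
#' I.i.d. bases per `base_composition`; deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return a [genome_sequence()].
#' @export
generate_genome <- function(config) {
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_contigs), function(i)
      paste(sample(c("A", "C", "G", "T"), config$contig_length,
                   replace = TRUE, prob = config$base_composition),
            collapse = ""), "")
    names(seqs) <- paste0("chr", seq_len(config$n_contigs))
    genome_sequence(seqs)
  })
}

# Global site index over a genome: contigs laid end to end.
site_index <- function(genome) {
  lens <- unname(contig_lengths(genome))
  list(contigs = names(genome), lens = lens,
       offsets = cumsum(c(0L, lens[-length(lens)])), total = sum(lens))
}

global_to_local <- function(idx, g) {
  k <- findInterval(g - 1L, idx$offsets)
  list(contig = idx$contigs[k], position = as.integer(g - idx$offsets[k]))
}

#' Enumerate strand-oriented TCW cytosine sites
#'
#' Global indices (contigs laid end to end) of every site presenting a
#' mutated-strand TCW cytosine: plus-strand C with context TCA/TCT, or G
#' whose reverse complement context is TCA/TCT (plus-strand TGA/AGA).
#' Precompute once per genome and pass to [spawn_sbs()] when simulating
#' many samples.
#'
#' @param genome a [genome_sequence()].
#' @return integer vector of global site indices.
#' @export
enumerate_tcw_sites <- function(genome) {
  idx <- site_index(genome)
  unlist(lapply(seq_along(idx$contigs), function(k) {
    s <- unclass(genome)[[k]]
    cpos <- gregexpr("(?=TC[AT])", s, perl = TRUE)[[1L]]
    gpos <- gregexpr("(?=[TA]GA)", s, perl = TRUE)[[1L]]
    cpos <- if (cpos[1L] == -1L) integer(0) else as.integer(cpos) + 1L
    gpos <- if (gpos[1L] == -1L) integer(0) else as.integer(gpos) + 1L
    sort(c(cpos, gpos)) + idx$offsets[k]
  }))
}

# Per-base quintile weights (bias_ratio^(quintile-1)) over the global index;
# positions outside the track get weight 1.
site_weights <- function(genome, track, bias_ratio) {
  idx <- site_index(genome)
  w <- rep(1, idx$total)
  for (k in seq_along(idx$contigs)) {
    iv <- track[track$contig == idx$contigs[k], , drop = FALSE]
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv$start), , drop = FALSE]
    for (j in seq_len(nrow(iv))) {
      lo <- idx$offsets[k] + iv$start[j] + 1L
      hi <- idx$offsets[k] + iv$end[j]
      w[lo:hi] <- bias_ratio^(iv$quintile[j] - 1L)
    }
  }
  w
}

synth_read_support <- function(n) {
  vaf0 <- stats::runif(n, 0.1, 0.5)
  alt <- as.integer(round(vaf0 * 50))
  list(alt_depth = alt, total_depth = rep(50L, n), vaf = alt / 50)
}

sort_records <- function(records, genome) {
  ord <- order(match(records$contig, names(genome)), records$position)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one sample's single-base substitutions
#'
#' `round(n * apobec_fraction)` events are drawn uniformly (or
#' timing-weighted, see below) without replacement from strand-oriented TCW
#' cytosine sites, mutated C>T with probability `ct_cg_split` and C>G
#' otherwise (reverse-complemented at minus-strand sites). The remaining
#' events are background: uniform over all genomic sites with a uniform
#' random non-reference alternate. Read support is synthesised (depth 50,
#' VAF ~ U(0.1, 0.5)) so downstream filters are exercised, not bypassed.
#' With a quintile-labelled `track`, site selection is weighted
#' `bias_ratio^(quintile - 1)`, planting an early-replication bias.
#'
#' @param genome a [genome_sequence()].
#' @param n total substitutions to draw.
#' @param apobec_fraction fraction of events from the APOBEC process.
#' @param ct_cg_split probability an APOBEC event is C>T rather than C>G.
#' @param seed RNG seed (deterministic output).
#' @param sample_id label stamped on the records.
#' @param track optional quintile-labelled timing track.
#' @param bias_ratio geometric quintile weight ratio used with `track`.
#' @param tcw_sites optional precomputed [enumerate_tcw_sites()] result.
#' @return a coordinate-sorted mutation record table.
#' @export
spawn_sbs <- function(genome, n, apobec_fraction, ct_cg_split = 1,
                      seed = 1L, sample_id = "S1", track = NULL,
                      bias_ratio = 1, tcw_sites = NULL) {
  stopifnot(n >= 0, apobec_fraction >= 0, apobec_fraction <= 1)
  if (n == 0L)
    return(mutation_records(character(0), character(0), integer(0),
                            character(0), character(0)))
  idx <- site_index(genome)
  n_apo <- round(n * apobec_fraction)
  n_bg <- n - n_apo
  if (is.null(tcw_sites) && n_apo > 0L) tcw_sites <- enumerate_tcw_sites(genome)
  if (n_apo > 0L && length(tcw_sites) < n_apo)
    stop(sprintf("insufficient TCW sites: need %d, genome has %d", n_apo,
                 length(tcw_sites)), call. = FALSE)
  with_seed(seed, {
    w <- if (!is.null(track) && bias_ratio != 1)
      site_weights(genome, track, bias_ratio) else NULL
    apo <- if (n_apo > 0L)
      sample_unique(tcw_sites, n_apo, weights = w[tcw_sites],
                    what = "TCW sites") else integer(0)
    bg <- if (n_bg > 0L)
      sample_unique(seq_len(idx$total), n_bg, weights = w,
                    exclude = apo, what = "sites") else integer(0)
    g <- c(apo, bg)
    loc <- global_to_local(idx, g)
    ref <- substring(unclass(genome)[loc$contig], loc$position, loc$position)
    alt <- character(length(g))
    if (n_apo > 0L) {
      ct <- stats::runif(n_apo) < ct_cg_split
      ref_a <- ref[seq_len(n_apo)]
      alt[seq_len(n_apo)] <- ifelse(ref_a == "C",
                                    ifelse(ct, "T", "G"),
                                    ifelse(ct, "A", "C"))
    }
    if (n_bg > 0L) {
      at <- n_apo + seq_len(n_bg)
      alt[at] <- vapply(ref[at], function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    }
    rs <- synth_read_support(length(g))
    rec <- mutation_records(sample_id, loc$contig, loc$position, ref, alt,
                            rs$alt_depth, rs$total_depth, rs$vaf)
    sort_records(rec, genome)
  })
}

#' Simulate one sample's insertions and deletions
#'
#' Lengths are drawn per `length_distribution` (category `"5plus"` uniform
#' over 5-200 bp), kinds insertion/deletion with equal probability,
#' positions uniform, inserted sequence i.i.d. per the genome's base
#' composition. Records use left-anchored VCF representation (shared first
#' base). Deletions that would overrun a contig are resampled (bounded).
#'
#' @param genome a [genome_sequence()].
#' @param n number of indels.
#' @param length_distribution probabilities over `"1"`..`"4"`, `"5plus"`.
#' @param seed RNG seed.
#' @param sample_id label stamped on the records.
#' @return a coordinate-sorted mutation record table.
#' @export
spawn_indels <- function(genome, n,
                         length_distribution = c("1" = 0.40, "2" = 0.15,
                                                 "3" = 0.10, "4" = 0.05,
                                                 "5plus" = 0.30),
                         seed = 1L, sample_id = "S1") {
  if (abs(sum(length_distribution) - 1) > 1e-9)
    stop("length_distribution must sum to 1", call. = FALSE)
  if (n == 0L)
    return(mutation_records(character(0), character(0), integer(0),
                            character(0), character(0)))
  idx <- site_index(genome)
  comp <- prop.table(vapply(c("A", "C", "G", "T"), function(b)
    sum(count_pattern(unclass(genome), b, fixed = TRUE)), 0))
  with_seed(seed, {
    cat_draw <- sample(names(length_distribution), n, replace = TRUE,
                       prob = length_distribution)
    len <- ifelse(cat_draw == "5plus", sample(5:200, n, replace = TRUE),
                  suppressWarnings(as.integer(cat_draw)))
    kind <- sample(c("insertion", "deletion"), n, replace = TRUE)
    contig <- character(n); pos <- integer(n)
    ref <- character(n); altv <- character(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:100) {
        k <- sample.int(length(idx$contigs), 1L, prob = idx$lens)
        L <- idx$lens[k]
        if (kind[i] == "deletion") {
          if (L <= len[i] + 1L) next
          p <- sample.int(L - len[i], 1L)
          s <- unclass(genome)[[k]]
          ref[i] <- substr(s, p, p + len[i])
          altv[i] <- substr(s, p, p)
        } else {
          p <- sample.int(L, 1L)
          anchor <- substr(unclass(genome)[[k]], p, p)
          ref[i] <- anchor
          altv[i] <- paste0(anchor,
                            paste(sample(c("A", "C", "G", "T"), len[i],
                                         replace = TRUE, prob = comp),
                                  collapse = ""))
        }
        contig[i] <- idx$contigs[k]; pos[i] <- p; ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("could not place a %d bp %s after bounded retries",
                     len[i], kind[i]), call. = FALSE)
    }
    rs <- synth_read_support(n)
    rec <- mutation_records(sample_id, contig, pos, ref, altv,
                            rs$alt_depth, rs$total_depth, rs$vaf)
    sort_records(rec, genome)
  })
}

#' Generate a replication-timing track over a genome
#'
#' Tiles the genome into fixed-width windows, assigns each tile a distinct
#' random timing value (a permutation, so labels are rank-based and
#' deterministic given the seed), and labels quintiles with [quintilize()].
#' The induced quintiles are intended to attract mutations with relative
#' weights `(1, r, r^2, r^3, r^4)` when passed to [spawn_sbs()] in biased
#' mode; the planted ratio is recorded in the `"planted_bias_ratio"`
#' attribute.
#'
#' @param genome a [genome_sequence()].
#' @param window tile width in bases.
#' @param bias_ratio planted geometric weight ratio.
#' @param seed RNG seed.
#' @return a quintile-labelled track data frame.
#' @export
generate_timing_track <- function(genome, window = 10000L, bias_ratio = 0.5,
                                  seed = 1L) {
  stopifnot(window >= 1L)
  lens <- contig_lengths(genome)
  tiles <- do.call(rbind, lapply(names(genome), function(nm) {
    starts <- seq(0L, lens[[nm]] - 1L, by = window)
    data.frame(contig = nm, start = starts,
               end = pmin(starts + window, lens[[nm]]),
               stringsAsFactors = FALSE)
  }))
  with_seed(seed, {
    tiles$timing <- sample.int(nrow(tiles))
  })
  out <- quintilize(tiles)
  attr(out, "planted_bias_ratio") <- bias_ratio
  out
}

#' Generate a complete synthetic study
#'
#' Emits a genome FASTA, one VCF per sample (SBS plus indels, synthesised
#' read support), a BED timing track, a cohort manifest and a truth table
#' of planted per-sample parameters, so the full pipeline runs end to end
#' with no external data. Per-sample seeds derive from the master seed;
#' re-running with the same config reproduces every file byte-identically.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `genome`, `track`, `truth`, `manifest`,
#'   `records` (per-sample tables) and file `paths`.
#' @export
generate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  fasta <- file.path(out_dir, "genome.fa")
  write_fasta(genome, fasta)
  track <- generate_timing_track(genome, config$timing_window,
                                 config$timing_bias_ratio,
                                 seed = config$seed + 101L)
  bed <- file.path(out_dir, "timing.bed")
  write_timing_bed(track, bed)
  tcw <- enumerate_tcw_sites(genome)
  fracs <- rep_len(config$apobec_fraction, config$n_samples)
  ids <- sprintf("S%02d", seq_len(config$n_samples))
  groups <- ifelse(fracs > 0, "A3B", "WT")
  biased <- config$timing_bias_ratio != 1
  records <- vector("list", config$n_samples)
  vcfs <- character(config$n_samples)
  n_ind <- integer(config$n_samples)
  seeds <- config$seed + 1000L + 7L * seq_len(config$n_samples)
  for (i in seq_len(config$n_samples)) {
    sbs <- spawn_sbs(genome, config$sbs_per_sample, fracs[i],
                     config$apobec_ct_cg_split, seed = seeds[i],
                     sample_id = ids[i], track = if (biased) track,
                     bias_ratio = config$timing_bias_ratio, tcw_sites = tcw)
    n_ind[i] <- if (config$indel_rate_couples_to_apobec)
      as.integer(round(config$indels_per_sample * (1 + 2 * fracs[i])))
    else config$indels_per_sample
    ind <- spawn_indels(genome, n_ind[i], config$indel_length_distribution,
                        seed = seeds[i] + 1L, sample_id = ids[i])
    records[[i]] <- sort_records(rbind(sbs, ind), genome)
    vcfs[i] <- paste0(ids[i], ".vcf")
    write_vcf(records[[i]], file.path(out_dir, vcfs[i]), genome)
  }
  manifest <- data.frame(sample_id = ids, group = groups, vcf = vcfs,
                         stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, group = groups,
                      apobec_fraction = fracs,
                      ct_cg_split = config$apobec_ct_cg_split,
                      n_sbs = config$sbs_per_sample, n_indels = n_ind,
                      timing_bias_ratio = config$timing_bias_ratio,
                      seed = seeds, stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.tsv")
  tpath <- file.path(out_dir, "truth.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = genome, track = track, truth = truth,
                 manifest = manifest, records = stats::setNames(records, ids),
                 paths = list(dir = out_dir, fasta = fasta, bed = bed,
                              manifest = mpath, truth = tpath,
                              vcfs = file.path(out_dir, vcfs))))
}
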