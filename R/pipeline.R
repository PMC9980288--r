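# Cohort orchestration: ingest -> spectra -> enrichment -> refit -> indels
# -> timing, with per-stage logging, association tables, group comparisons
# and a machine-readable report bundle.

#' Read a cohort manifest
#'
#' TSV with columns `sample_id`, `group`, `vcf`. Relative VCF paths are
#' resolved against the manifest's directory, keeping cohort directories
#' relocatable.
#'
#' @param path manifest TSV path.
#' @return data frame with absolute `vcf` paths.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "vcf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$vcf)
  df$vcf[rel] <- file.path(dirname(path), df$vcf[rel])
  df
}

#' Run the full analysis over a cohort
#'
#' For each manifest sample: read the VCF, apply read-support filters, build
#' the 96-context spectrum and the indel summary. Across the cohort: fit
#' APOBEC TCW enrichment with a single cohort-wide BH correction and the
#' ES-high/ES-low dichotomy, refit spectra against a signature catalog,
#' associate the enrichment score with mutation burden, indel classes,
#' the SBS2 percentage and any supplied covariates, compare per-sample
#' quantities between ES-high and ES-low (and between genotype groups)
#' by Mann-Whitney, and profile mutation density over replication-timing
#' quintiles per group. A failing sample is reported and skipped unless
#' `strict`.
#'
#' @param manifest data frame (`sample_id`, `group`, `vcf`) or manifest path.
#' @param genome a [genome_sequence()] or FASTA path.
#' @param track optional timing track (data frame or BED path).
#' @param catalog signature catalog matrix (default [toy_signature_catalog()];
#'   `NULL` skips refitting).
#' @param covariates optional data frame keyed by `sample_id`; every other
#'   numeric column is Pearson-associated with the enrichment score.
#' @param sv_counts optional data frame (`sample_id`, `count`) of per-sample
#'   structural-variation counts, compared across groups only.
#' @param policy a [filter_policy()].
#' @param q_threshold ES-high FDR threshold.
#' @param half_width,motif enrichment context parameters.
#' @param out_dir when given, TSV tables and a JSON summary are written here.
#' @param strict abort on the first failing sample.
#' @return an object of class `cohort_report`.
#' @export
run_cohort <- function(manifest, genome, track = NULL,
                       catalog = toy_signature_catalog(), covariates = NULL,
                       sv_counts = NULL, policy = filter_policy(),
                       q_threshold = 0.1, half_width = 20L,
                       motif = c("TCW", "TCA"), out_dir = NULL,
                       strict = FALSE) {
  motif <- match.arg(motif)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(genome) && !inherits(genome, "genome_sequence"))
    genome <- read_fasta(genome)
  if (is.character(track)) track <- read_timing_bed(track)
  if (!is.null(track) && !"quintile" %in% names(track))
    track <- quintilize(track)

  records <- list(); failures <- list()
  filter_logs <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      raw <- read_vcf_somatic(manifest$vcf[i], sid)
      apply_filters(raw, policy)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(sprintf("sample '%s' failed: %s", sid,
                               conditionMessage(res)), call. = FALSE)
      message(sprintf("run_cohort: sample '%s' failed (%s); skipped", sid,
                      conditionMessage(res)))
      failures[[sid]] <- conditionMessage(res)
      next
    }
    filter_logs[[sid]] <- attr(res, "filter_log")
    records[[sid]] <- res
  }
  if (!length(records)) stop("no sample could be ingested", call. = FALSE)
  manifest <- manifest[manifest$sample_id %in% names(records), , drop = FALSE]
  all_records <- do.call(rbind, records)

  spectra <- lapply(names(records), function(s)
    build_spectrum(records[[s]], genome, s))
  names(spectra) <- names(records)

  enrichment <- apobec_enrichment(all_records, genome,
                                  q_threshold = q_threshold,
                                  half_width = half_width, motif = motif)

  exposures <- NULL
  if (!is.null(catalog)) {
    exposures <- lapply(spectra, function(sp)
      if (attr(sp, "total") > 0) refit(sp, catalog) else NULL)
    exposures <- Filter(Negate(is.null), exposures)
  }

  indels <- lapply(names(records), function(s)
    summarize_indels(records[[s]], genome, s))
  names(indels) <- names(records)

  # association tables against the enrichment score
  sc <- enrichment$score[match(names(records), enrichment$sample_id)]
  burden <- vapply(records, function(r) sum(is_sbs(r)), 0L)
  enough <- length(records) >= 3L  # correlations need at least 3 pairs
  assoc <- list()
  if (enough) {
  a <- associate(sc, as.numeric(burden), method = "spearman")
  assoc[["sbs_burden"]] <- data.frame(covariate = "sbs_burden",
                                      method = "spearman",
                                      coefficient = a$coefficient,
                                      p_value = a$p_value, n = a$n,
                                      stringsAsFactors = FALSE)
  if (!is.null(exposures) && length(exposures) >= 3L) {
    ids_e <- names(exposures)
    pe <- vapply(exposures, percent_sbs2, 0)
    a <- associate(enrichment$score[match(ids_e, enrichment$sample_id)], pe,
                   method = "pearson")
    assoc[["percent_sbs2"]] <- data.frame(covariate = "percent_sbs2",
                                          method = "pearson",
                                          coefficient = a$coefficient,
                                          p_value = a$p_value, n = a$n,
                                          stringsAsFactors = FALSE)
  }
  if (!is.null(covariates)) {
    for (cv in setdiff(names(covariates), "sample_id")) {
      y <- covariates[[cv]][match(names(records), covariates$sample_id)]
      a <- associate(sc, as.numeric(y), method = "pearson")
      assoc[[cv]] <- data.frame(covariate = cv, method = "pearson",
                                coefficient = a$coefficient,
                                p_value = a$p_value, n = a$n,
                                stringsAsFactors = FALSE)
    }
  }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else NULL
  if (!is.null(associations)) rownames(associations) <- NULL

  indel_assoc <- if (enough)
    indel_enrichment_association(indels, enrichment) else NULL

  # group comparisons (Mann-Whitney)
  es <- enrichment$es_class[match(names(records), enrichment$sample_id)]
  grp <- manifest$group[match(names(records), manifest$sample_id)]
  totals <- vapply(indels, attr, 0L, "total_under_200")
  tests <- list()
  add_test <- function(name, values, by, a_lab, b_lab) {
    va <- values[by == a_lab & !is.na(by)]
    vb <- values[by == b_lab & !is.na(by)]
    if (!length(va) || !length(vb)) return()
    mw <- compare_groups(va, vb)
    tests[[name]] <<- data.frame(
      quantity = name, contrast = paste(a_lab, "vs", b_lab),
      n_a = length(va), n_b = length(vb), u_statistic = mw$u_statistic,
      p_value = mw$p_value, stringsAsFactors = FALSE)
  }
  add_test("total_indels_by_es", as.numeric(totals), es, "high", "low")
  if (length(unique(stats::na.omit(grp))) == 2L) {
    gl <- sort(unique(stats::na.omit(grp)))
    add_test("total_indels_by_group", as.numeric(totals), grp, gl[2L], gl[1L])
    add_test("sbs_burden_by_group", as.numeric(burden), grp, gl[2L], gl[1L])
  }
  if (!is.null(sv_counts)) {
    svv <- sv_counts$count[match(names(records), sv_counts$sample_id)]
    add_test("sv_by_es", as.numeric(svv), es, "high", "low")
  }
  group_tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(group_tests)) rownames(group_tests) <- NULL

  # replication-timing profiles, pooled per group
  timing_profiles <- NULL
  if (!is.null(track)) {
    timing_profiles <- lapply(unique(grp), function(g) {
      pooled <- do.call(rbind, records[grp == g])
      pooled <- pooled[is_sbs(pooled), , drop = FALSE]
      quintile_profile(assign_quintiles(pooled, track), genome, g)
    })
    names(timing_profiles) <- unique(grp)
  }

  provenance <- list(
    package = "sigscan",
    version = as.character(utils::packageVersion("sigscan")),
    parameters = list(q_threshold = q_threshold, half_width = half_width,
                      motif = motif,
                      policy = unclass(policy)),
    n_samples = length(records),
    failures = failures,
    filter_logs = filter_logs)

  report <- structure(list(manifest = manifest, enrichment = enrichment,
                           spectra = spectra, exposures = exposures,
                           indels = indels, associations = associations,
                           indel_associations = indel_assoc,
                           group_tests = group_tests,
                           timing_profiles = timing_profiles,
                           records = records, provenance = provenance),
                      class = "cohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d sample(s)\n", nrow(x$manifest)))
  print(x$enrichment)
  if (!is.null(x$group_tests)) {
    cat("\nGroup comparisons (Mann-Whitney):\n")
    print.data.frame(x$group_tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a cohort report's tables and JSON summary
#'
#' Deterministic output (no timestamps): identical inputs yield
#' byte-identical files.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(as.data.frame(report$enrichment), "enrichment.tsv")
  write_spectra(report$spectra, file.path(out_dir, "spectra.tsv"))
  wt(data.frame(sample = rownames(indel_matrix(report$indels)),
                indel_matrix(report$indels), check.names = FALSE),
     "indels.tsv")
  if (!is.null(report$exposures)) {
    em <- t(vapply(report$exposures, coef,
                   numeric(length(coef(report$exposures[[1L]])))))
    wt(data.frame(sample = names(report$exposures), em,
                  unexplained = vapply(report$exposures, `[[`, 0,
                                       "unexplained"),
                  check.names = FALSE), "exposures.tsv")
  }
  if (!is.null(report$associations)) wt(report$associations,
                                        "associations.tsv")
  if (!is.null(report$indel_associations))
    wt(report$indel_associations, "indel_associations.tsv")
  if (!is.null(report$group_tests)) wt(report$group_tests, "group_tests.tsv")
  if (!is.null(report$timing_profiles)) {
    tp <- do.call(rbind, lapply(report$timing_profiles, function(p)
      data.frame(group = p$group_id, quintile = 1:5, count = p$counts,
                 normalized = p$normalized, tc_tt_percent = p$tc_tt_percent,
                 stringsAsFactors = FALSE)))
    wt(tp, "timing_profiles.tsv")
  }
  summary <- list(
    provenance = report$provenance,
    n_samples = nrow(report$manifest),
    es_high = sum(report$enrichment$es_class == "high", na.rm = TRUE),
    es_low = sum(report$enrichment$es_class == "low", na.rm = TRUE),
    mean_score = mean(report$enrichment$score, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
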