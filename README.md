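# sigscan

Quantifying APOBEC3-driven mutagenesis in somatic mutation cohorts.

APOBEC3 cytidine deaminases (A3A/A3B) attack single-stranded DNA and
deaminate cytosine preferentially at TCA/TCT trinucleotides (the **TCW**
motif), seeding C>T (SBS2) and C>G (SBS13) mutations in tumors. `sigscan`
is an R package for the genomicist asking, sample by sample, *is this
process active in my cohort?* It takes somatic variant calls (VCF or TSV)
plus a reference FASTA and provides:

* **Read-support filtering** — >=3 variant reads, >=10 total reads,
  VAF strictly > 0.05, mitochondrial exclusion (`apply_filters()`).
* **96-context SBS spectra** on the pyrimidine strand
  (`build_spectrum()`, `plot()`).
* **The TCW fold-enrichment score** over 41-base mutation contexts,

  `E = (Mut_TCW / Con_TCW) / (Mut_C / Con_C)`,

  where `Mut_TCW`/`Mut_C` count mutated cytosines (in TCW / in total,
  after filtering to C:G substitutions without C>A) and
  `Con_TCW`/`Con_C` count motifs and cytosines aggregated over each
  mutation's ±20-base window — with one-sided Fisher exact p-values,
  cohort-wide Benjamini–Hochberg correction, and the ES-high (q < 0.1) /
  ES-low dichotomy (`apobec_enrichment()`).
* **Signature refitting** by forward selection with non-negative least
  squares, reporting per-signature contributions such as the SBS2
  percentage (`refit()`, `percent_sbs2()`).
* **Indel class spectra** — 1 bp T/A vs C/G, 2/3/4 bp, 5plus (5–200 bp),
  with junction microhomology on deletions (`summarize_indels()`).
* **Replication-timing quintile profiles** — largest-quintile-normalized
  mutation densities and per-quintile TC>TT percentages
  (`quintilize()`, `quintile_profile()`).
* **A planted-signal simulator** (`cohort_config()`, `generate_cohort()`)
  that emits complete synthetic studies (FASTA + VCFs + BED + truth
  table) so every stage is verifiable by parameter recovery.

`run_cohort()` orchestrates all stages over a manifest and writes TSV
tables plus a JSON summary. A thin command-line front end ships at
`inst/cli/sigscan.R` (`ingest`, `spectrum`, `enrich`, `refit`, `indels`,
`timing`, `simulate`, `run`).

## Worked example

Simulate a six-sample cohort (three controls, three with 60% of mutations
planted at TCW sites) and run the full pipeline:

```r
library(sigscan)

cfg <- cohort_config(seed = 42, n_samples = 6,
                     apobec_fraction = c(0, 0, 0, 0.6, 0.6, 0.6),
                     sbs_per_sample = 1500, indels_per_sample = 150)
cohort <- generate_cohort(cfg, "demo_cohort")
report <- run_cohort("demo_cohort/manifest.tsv", "demo_cohort/genome.fa",
                     track = "demo_cohort/timing.bed")
print(report)
```

```
APOBEC TCW enrichment: 6 sample(s), motif TCW, window 41 bases, ES-high at q < 0.1
 sample_id mut_tcw mut_c con_tcw con_c score p_value q_value es_class
       S01      77   497     649  5410 1.291 0.01579 0.02368     high
       S02      65   524     677  5622 1.030 0.42552 0.42552      low
       S03      70   524     682  5796 1.135 0.15682 0.18819      low
       S04     928  1084    2212 11285 4.368 0.00000 0.00000     high
       S05     925  1091    2186 11518 4.467 0.00000 0.00000     high
       S06     919  1079    2207 11447 4.418 0.00000 0.00000     high

Group comparisons (Mann-Whitney):
              quantity    contrast n_a n_b u_statistic p_value
    total_indels_by_es high vs low   4   2         7.0 0.18763
 total_indels_by_group   WT vs A3B   3   3         0.0 0.04685
   sbs_burden_by_group   WT vs A3B   3   3         4.5 1.00000
```

Reading the table: the three planted samples score ~4.4 — their mutated
cytosines use TCW about 4.4-fold more than the local context offers — with
vanishing q-values, while controls sit near 1. Control S01 illustrates a
caveat discussed in the methods vignette: the statistic's null expectation
is slightly above 1 (~1.1 on an i.i.d. genome), so near-threshold calls in
small cohorts deserve scrutiny — here S01 lands at q = 0.024 by chance.
The planted indel coupling shows up in the WT-vs-A3B comparison
(p = 0.047 at n = 3 + 3); the SBS burden does not differ (p = 1), as
designed.

The replication-timing profile of the planted group recovers the simulated
early-replication bias (geometric weights 1, 0.5, 0.25, 0.125, 0.0625):

```r
print(report$timing_profiles[["A3B"]])
#> quintile_profile 'A3B' (early -> late):
#>   counts:      2325  1161  582  283  149
#>   normalized:  1.000  0.499  0.250  0.122  0.064
#>   % TC->TT:    60.9  61.4  64.9  63.6  62.4

sapply(report$exposures, percent_sbs2)
#>  S01  S02  S03  S04  S05  S06
#>  0.0  0.0  0.0 69.8 70.2 69.6
```

Refitting against the bundled toy catalog attributes ~70% of the planted
samples' spectra to the APOBEC C>T signature and none of the controls'.

## Scope

Upstream read processing (alignment, duplicate marking, somatic calling)
and structural-variant calling are out of scope: the pipeline starts from
variant calls, and SV counts can only be supplied as an external
per-sample table for group comparisons. De novo signature extraction,
kataegis/omikli detection and copy-number analysis are not implemented.
See `vignettes/apobec-enrichment-methods.Rmd` for the model, parameter
defaults, simulator design and known limitations.
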