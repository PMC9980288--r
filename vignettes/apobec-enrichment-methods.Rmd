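---
title: "Quantifying APOBEC mutagenesis in somatic cohorts: methods and design notes"
author: "sigscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying APOBEC mutagenesis in somatic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscan)
```

## The biological question

APOBEC3 family cytidine deaminases attack single-stranded DNA and convert
cytosine to uracil, preferentially when the cytosine is preceded by a
thymine. In tumors this leaves two recognisable traces: C>T transitions
(signature SBS2) and C>G transversions (SBS13), both concentrated at
TCA/TCT trinucleotides — the *TCW* motif (W = A or T). `sigscan`
implements the downstream analysis by which a cohort of somatic variant
calls is interrogated for this process: read-support filtering, 96-context
substitution spectra, a per-sample TCW fold-enrichment score with exact
significance, signature refitting, indel class spectra, and
replication-timing profiles. A planted-signal simulator generates complete
synthetic cohorts so every stage can be verified by parameter recovery.

## Read-support filters

Variant calls enter the pipeline after conservative support filters,
applied by `apply_filters()` with `filter_policy()` defaults:

* at least 3 reads supporting the variant,
* at least 10 reads total at the site,
* variant allele frequency **strictly** greater than 0.05,
* mitochondrial contigs excluded (aliases `chrM`, `MT`, `M`).

The VAF comparison is deliberately strict ("over 0.05" read literally);
records at exactly 0.05 are removed and logged. Filtering is idempotent and
each rule's removal count is attached to the result (`"filter_log"`), so
the funnel is auditable.

## The TCW enrichment score

For each sample, `enrichment_score()` first reduces the record set with
four rules, in order: keep single-base substitutions; keep C:G reference
pairs; drop mitochondrial contigs; drop pyrimidine-strand C>A events
(i.e. C>A and G>T), which are unrelated to deaminase chemistry. Every
retained site is oriented to present the mutated cytosine: G-reference
events and their windows are reverse-complemented.

Around each site a 41-base window (20 bases each side, truncated at contig
edges) is extracted and the aggregate counts formed:

* `mut_tcw` — retained sites whose oriented trinucleotide is TCA or TCT,
* `mut_c` — all retained sites,
* `con_tcw`, `con_c` — TCW motifs and cytosines summed over all windows
  (overlapping windows counted independently).

The fold enrichment is

$$E = \frac{\mathrm{mut}_{TCW}/\mathrm{con}_{TCW}}
           {\mathrm{mut}_{C}/\mathrm{con}_{C}},$$

i.e. TCW usage among mutated cytosines relative to TCW availability in the
local sequence context. Significance is the one-sided Fisher exact test on
the 2x2 table `[[mut_tcw, mut_c - mut_tcw], [con_tcw, con_c - con_tcw]]`,
computed as the hypergeometric tail (`fisher_one_sided()`). Across a
cohort, `apobec_enrichment()` applies a single Benjamini–Hochberg
correction to the defined per-sample p-values — the family is the cohort in
the manifest, so cohorts should not be mixed — and calls a sample *ES-high*
when `q < 0.1` (strict).

Two documented reading choices matter for comparability:

* `mut_c` counts only C>T and C>G events (rule 4 removed C>A), which
  changes the denominator relative to implementations that keep all
  mutated cytosines;
* motif counting is on the oriented strand only. A strict-TCA variant of
  the statistic is exposed via `motif = "TCA"`.

### Null behaviour of the statistic

The score is *not* centred at 1 under a context-free null, and users
should know why. Condition on a mutated cytosine: its window always
contains that C (inflating `con_c` by one), and the two motif positions
adjacent to the centre can never host a TCW (the centre base is C, but the
neighbours of a TCW's cytosine are T and A/T), deflating `con_tcw`. On an
i.i.d. genome with per-base C probability $c$ the expectation works out to

$$E_0 = \frac{1 + 40c}{1 + 36c} \approx 1.10 \text{ at } c = 0.25,$$

independent of the AT split, and simulation over 200 null samples
reproduces the value (~1.09). On real genomes, positive GC autocorrelation
(windows around a C are themselves C-rich) partially offsets the bias,
which is why the statistic looks approximately calibrated in practice. The
exact expectation for any genome is computable by site enumeration, and
the package's tests assert calibration against that enumeration rather
than against 1.0. Interpretation guidance: the Fisher/BH machinery, not
the raw score's distance from 1, carries the inferential weight, and
scores from planted signals (e.g. 4.4 at a 0.6 planted fraction) dwarf the
~10% null inflation.

## 96-context spectra

`classify_sbs()` reports every substitution on the pyrimidine strand with
flanks taken from the reference genome, never from VCF annotations;
purine-reference events are reverse-complemented together with their
flanks. Class order is the conventional catalog serialization
(substitution-major C>A..T>G, flanks lexicographic), so spectra align
column-by-column with signature catalog matrices. Sites at contig edges or
with N in context are excluded with a logged count rather than imputed;
the spectrum total always equals the number of classified substitutions.
Equal-length multi-base substitutions are neither SBS nor indel and take
part in no analysis.

## Signature refitting

`refit()` decomposes a count-normalised spectrum into non-negative catalog
contributions by forward selection: at each step the signature whose
inclusion most reduces the squared reconstruction error (non-negative
least squares sub-solve, via `pracma::lsqnonneg`) is added, until the
improvement falls below `tolerance` (default 1e-9). Weights below
`weight_floor` (default 0.06, mirroring common refitting practice since no
cutoff is otherwise dictated) are zeroed and the surviving set re-solved;
the weight sum is capped at 1 and the remainder reported as `unexplained`.
Ties in selection break by catalog column order, making the fit
deterministic. This replaces a golden-section weight search with NNLS
sub-solves: the objective is identical and exact mixtures are recovered to
machine precision, which is the property the pipeline relies on.

No trinucleotide-abundance renormalization is applied by default (spectrum
and catalog are assumed to live in the same sequence space); an
`abundance` hook accepts a 32-trinucleotide ratio vector when moving
between exome and genome spaces. `toy_signature_catalog()` provides a
synthetic five-signature catalog (ageing-like, APOBEC C>T, flat,
APOBEC C>G, T>G) for tests and demonstrations; real analyses should load a
published catalog with `read_signature_catalog()`.

## Indel classes and microhomology

Indels are classified by net length with categories 1, 2, 3, 4 and 5plus
(5–200 bp); events longer than 200 bp are flagged out-of-spectrum and
tallied separately. Single-base events are subtyped T/A vs C/G by the
inserted/deleted base (strand-symmetric by construction). A deletion of
2+ bp carries *microhomology* when the deleted sequence and the reference
immediately 3' of the deletion share a common prefix of at least one base
(scanned up to `mh_scan = 10` bases) — an operational
longest-common-prefix definition chosen because none is otherwise
specified; repeat-unit subclassification is deliberately not performed.
Complex indels (both alleles longer than the shared prefix) are classified
by net length. Callers are assumed to left-align; `normalize_indels()`
re-left-aligns defensively, sliding the event window while the anchor base
equals the last inserted/deleted base.

## Replication timing

Timing tracks are BED intervals (0-based, half-open; mutation positions
are 1-based internally and converted at the boundary, tested at both
boundary positions). `quintilize()` cuts continuous timing values into
five length-weighted quintiles — quintile 1 is the earliest-replicating
fifth — assigning each interval by its cumulative-coverage midpoint, so
boundary-spanning intervals resolve toward the earlier quintile.
Group-level profiles pool records across a group's samples *before*
normalising to the largest quintile; per-sample profiles are available by
grouping differently. The TC>TT percentage of a quintile depends only on
that quintile's records.

## The synthetic cohort generator

`generate_cohort()` emits a complete study — genome FASTA, per-sample
VCFs, BED timing track, manifest and a truth table — from a
`cohort_config()`. The defaults are the study conditions the package is
tested under:

* 4 contigs x 250 kb, uniform base composition (~1 Mb total; large enough
  that window statistics are stable, small enough for minutes-scale runs);
* 20 samples: 10 controls (planted fraction 0) and 10 with APOBEC fraction
  0.6, 2000 SBS each;
* `apobec_ct_cg_split = 1`: planted events are pure C>T, emulating the
  SBS2-without-SBS13 pattern seen when uracil lesions resolve by A-rule
  bypass rather than REV1 C-insertion; set 0.5 for classic joint
  SBS2/SBS13 cohorts;
* background mutations uniform over all sites with uniform alternates —
  deliberately not shaped like a clock signature, because the enrichment
  null then has an exact closed-form/site-enumeration expectation;
* an early-replication bias with geometric quintile weights
  (1, r, r², r³, r⁴), r = 0.5;
* indel burdens `round(200 x (1 + 2 x fraction))` in coupled mode, so the
  indel–enrichment association planted in the data is monotone;
* synthesised read support (depth 50, VAF ~ U(0.1, 0.5)) so the filter
  stage is exercised rather than bypassed.

Everything derives deterministically from the master seed (per-sample
sub-seeds), and re-running a config reproduces every output byte for byte.

What the simulator does **not** emulate — and hence what green tests do not
establish about real data: GC/trinucleotide autocorrelation (real genomes
partially offset the null bias discussed above), clustered mutations
(kataegis/omikli; the pipeline deliberately has no cluster detector),
subclonal VAF structure, sequencing error, and realistic trinucleotide
abundances. Parameter recovery here demonstrates internal consistency of
the statistics, not robustness to those real-data features.

## Numerical and degenerate-input choices

* Windows truncated at contig edges are used as-is (affects only
  micro-genomes); their truncation is logged.
* A sample with `mut_c = 0` has an undefined score; it is flagged and
  excluded from the BH family rather than imputed.
* Empty spectra are valid (all zeros) and refuse refitting.
* Fisher p-values come from `phyper` — exact, not simulated; BH from
  `p.adjust`; both are property-tested against definitional oracles
  (tail enumeration; step-up arithmetic).
* Mann–Whitney comparisons return p = 1 for fully tied inputs.
* Multi-allelic VCF rows are split per alternate allele (the calls this
  pipeline ingests rarely contain them, and splitting loses nothing).
* No sex-chromosome special-casing is applied.
* The TC>TT percentage uses classified SBS as its denominator.

## Problem sizes used by the test suite

The shipped tests run the pipeline at: 200 null samples x 500 mutations
(calibration), 50 replicates x 2000 mutations at planted fraction 0.75
(recovery), 10,000 indels (classifier round trip), 100 replicates x 1000
mutations (timing recovery), and a 20-sample end-to-end cohort at 2000 SBS
per sample — sizes chosen so the whole suite completes in minutes on one
core while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The enrichment score's null inflation (~10% at a 41-base window) is a
  property of the statistic itself; comparisons of raw scores across
  cohorts with different genome composition should use the
  site-enumeration expectation as the reference point.
* Overlapping windows double-count shared bases in `con_*` by design
  (each substitution contributes its own window); de-duplicating unions
  would change the statistic.
* The indel scheme is coarser than the 83-class catalog standard on
  purpose, matching the size/microhomology categories it reports.
* De novo signature extraction, structural-variant calling, kataegis
  detection and copy-number analysis are out of scope; SV counts may be
  supplied as an external per-sample table for group comparison only.
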