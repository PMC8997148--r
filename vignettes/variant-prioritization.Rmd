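---
title: "Medal-based germline variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medal-based germline variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmedal)
```

## Overview

`varmedal` turns per-patient germline VCFs and delimited evidence tables
into an auditable table of prioritized variants. The pipeline has six
stages, each exposed as ordinary functions so every intermediate can be
inspected: caller-level quality filtering, panel restriction and evidence
annotation, medal classification, post-classification read filtering,
somatic refinement of Silver calls, and cohort-level curation with triage.
This vignette explains the model behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Quality filters

A call in one patient is summarized by its reference and alternate read
depths $(r, a)$. Two derived quantities drive the filters:

* variant allele fraction $\mathrm{VAF} = a/(r+a)$;
* heterozygous allele balance $\mathrm{ABHet} = r/(r+a)$.

`apply_caller_filters()` excludes a record when any of the following fires:
total depth $r+a < 10$; heterozygous ABHet strictly outside $[0.2, 0.8]$;
population-maximum allele frequency $\ge 0.01$ (only variants strictly
rarer than 1% in every reference sub-population are kept); alternate reads
$a < 10$; heterozygous minor allelic fraction
$\min(\mathrm{VAF}, 1-\mathrm{VAF}) < 0.25$. `apply_post_filters()`, run on
the classified Gold/Silver calls, removes records with total depth $< 20$
or $\mathrm{VAF} < 0.25$.

Boundary semantics are deliberately literal readings of each comparator:
depth exactly 10 passes ("depth below 10" excludes), ABHet exactly 0.2 or
0.8 passes (strict inequalities exclude), popmax exactly 0.01 is excluded
("kept if below 0.01"), VAF exactly 0.25 and total exactly 20 pass. The
allele-balance and minor-fraction rules apply to heterozygous genotypes
only: a homozygous alternate call legitimately has ABHet near 0. The
alternate-read rule ($a \ge 10$) and the later total-read rule
($r+a \ge 20$) are both implemented, as two sequential stages; nothing in
the source method indicates one supersedes the other, and the second is not
implied by the first (e.g. $r+a = 15, a = 12$ passes the first and fails
the second).

Records without a usable depth field are not discarded wholesale: the
depth-dependent rules simply skip them, and the reader reports how many
such records were seen. Both filters are idempotent and monotone in their
thresholds; the test suite asserts this on 1,000 randomized records.

## Annotation and the gene panel

Panels are set unions of curated gene lists (`build_panel()`), with symbols
case-normalized; restricting a superset panel can never yield fewer
annotated calls. Consequences are consumed from an annotation column of the
input — the package deliberately does not recompute variant effects from
transcript models, which keeps the pipeline testable without transcript
databases and keeps it agnostic to the upstream annotation engine.

Protein-change strings are parsed with a tolerant regular expression that
handles missense (`R175H`), frameshift (`S1848fs`), stop-gain (`Q678*`),
splice residue-plus-exon codes (`E1892_E37`), and 5'-UTR codes
(`E1_UTR_5`); anything unparseable yields a missing residue index rather
than an error. For intronic splice variants annotated with a residue-exon
code, the printed residue is used as-is; the exon code is kept as opaque
text.

Absent evidence is always explicit after `annotate()`: an empty assertion
table, somatic category `"none"`, population frequency 0 (a variant absent
from the frequency table is treated as never observed, matching "-" entries
in curated tables), and a missing in-silico flag.

## The medal classifier

`classify_germline()` evaluates four tiers in fixed precedence
(gold > silver > bronze > unknown; first match wins):

* **Gold** requires three things simultaneously: a severe signal (a
  truncating consequence — frameshift, nonsense, splice — or a
  pathogenic/likely-pathogenic assertion), a disease-associated gene
  (loss-of-function disease mechanism or tumor-suppressor role), and strong
  database support (a star-rated pathogenic assertion with at least two
  review stars, or a pathogenic assertion from a specialty locus database
  such as a TP53- or BRCA-specific resource).
* **Silver** requires a moderate consequence shape (in-frame indel,
  truncation in a non-tumor-suppressor gene, or a damaging-predicted
  missense) plus at least one match in a configured Silver source.
* **Bronze** is assigned to variants predicted tolerated in silico when no
  higher tier fires. Bronze deliberately does not exclude variants with
  pathogenic assertions: classification must be monotone in evidence
  (adding a pathogenic two-star assertion can never lower a medal), and a
  tolerance prediction is information about the variant regardless of what
  else is asserted.
* **Unknown** otherwise; it is the only tier with an empty reason list.

The source-tag sets are configuration (`medal_config()`), not hard-coded
database clients; the defaults name the tags conventionally used for
star-rated (ClinVar-type) and specialty/locus-specific resources. The
classifier is a pure function of the evidence bundle — the test suite
checks it against an independently enumerated truth table over the full
grid of consequence x gene flags x star rating x specialty source x
tolerance prediction (1,296 bundles) and confirms order-independence with
respect to assertion rows.

**Silver refinement.** A germline Silver call is retained only when the
identical variant appears as Gold or Silver in a somatic mutation
catalogue: recurrence in tumor biopsies raises confidence in a borderline
germline call. Gold calls are unaffected; Bronze/Unknown are outside the
refinement's scope (recorded as `NA`, not `FALSE`).

## C-terminal caution and pLI triage

A truncation near the protein's end may escape nonsense-mediated decay and
leave near-full-length protein, so its impact is uncertain. With residue
index $p$ and canonical protein length $L$,
`truncation_protein_fraction()` returns $p/L \in (0, 1]$, and
`flag_cterm_caution()` raises the flag when the fraction, rounded half-up
to two decimals, reaches 0.90, or when the annotation marks the variant in
the final coding exon. The threshold of 0.90 separates the
caution-annotated truncations observed in practice (fractions 0.95–1.0,
plus one at 0.899 which motivates the two-decimal rounding rule) from
unflagged mid-protein truncations (0.62–0.66). The final-exon signal exists
because some genuinely cautioned truncations sit early in the protein
(12–19%) yet fall in a terminal exon where NMD escape is expected; a
fraction rule alone cannot express that, so both signals are supported and
either suffices.

pLI tiers follow the convention that scores of 0.9 and above mark strong
loss-of-function intolerance: `"high"` at $\ge 0.9$, `"intermediate"` in
$[0.5, 0.9)$ (scores near 0.77–0.79 are genuinely ambiguous and deserve
their own label), `"low"` below 0.5, `"absent"` when the gene has no score.

## Cohort-level curation

Two artifact signatures are codified from manual-curation practice:

* **Mapping artifacts** (`detect_mapping_artifacts()`): a genomic position
  carried by at least `min_patients` (default 3) patients, with at least
  two distinct alternate alleles across carriers, and alternate reads
  strictly below reference reads in every carrier. Real rare variants
  essentially never recur with inconsistent alternate alleles and a
  systematic alternate-read deficit. The default of 3 is the smallest count
  at which "varied genotypes" is observable; the motivating real-world case
  had six carriers.
* **Cohort-common variants** (`detect_common_variants()`): a position
  carried by the entire cohort (default threshold 1.0) is a population
  polymorphism that slipped past the reference-frequency filter —
  under-catalogued ancestries make this failure mode common. The threshold
  is literal ("present in all patients"); a softer fraction is available as
  configuration.

`curate()` removes calls at flagged positions and logs each removal with
its rationale. Curation is anti-monotone: adding flags can never increase
retained calls.

## Summaries

`summarize_cohort()` deduplicates variants by the full allele key
(chrom, pos, ref, alt): a variant recurring in two patients counts once at
the variant level, twice at the occurrence and carrier level. Carrier
frequency is carriers divided by patients (not alleles over $2n$) — in an
all-female cohort of heterozygous carriers this matches how such
frequencies are conventionally reported. Patient percentages round half-up
to integers, carrier frequencies to one decimal.

```{r summary-example}
summarize_cohort(gold_variant_table(), n_patients = 115)
```

## Statistics

`odds_ratio()` computes the cross-product ratio with a Woolf (log-scale
Wald) confidence interval, applying the Haldane–Anscombe 0.5 correction
when any cell is zero — chosen because it is closed-form, standard, and
exactly testable. `fit_logistic()` is maximum likelihood via iteratively
reweighted least squares (`stats::glm`, up to 100 iterations, convergence
tolerance tightened to 1e-10), returning odds ratios with Wald intervals;
complete separation and rank deficiency raise errors naming the offending
covariate rather than returning silently meaningless estimates.
`km_estimate()`/`km_surv()` wrap the product-limit estimator and
`log_rank()` the two-group log-rank test from the survival package; both
are validated in the test suite against hand-computed examples (exact to
1e-12) and, for the log-rank p-value, against a 10,000-permutation null.
Wald intervals are used throughout for uniformity. Subtype enters models as
a dummy-coded factor. Cox regression and covariate-adjusted survival curves
are intentionally out of scope: the package reports unadjusted
Kaplan–Meier curves and the log-rank test, which is what the statistics
module is specified to provide.

## The synthetic-data generator

Real patient-level data of the motivating studies are not redistributable,
so validation rests on `simulate_cohort()`, which generates cohorts with
the statistical structure the pipeline assumes, plus per-variant truth
labels. Defaults are the study conditions: 115 patients, an 862-gene panel
built as the union of two overlapping lists, 49 Gold-like and 106
Silver-like planted variants, two artifact positions, one cohort-common
position, and carrier covariate odds of 3.21 (family history), 3.74 (age
under 30), 1.19 (per BMI unit), calibrated to a 34% carrier prevalence.

Where the emulated design fixes no value, a single realistic choice was
made and kept: total depths are negative-binomial (mean 40, dispersion 10)
floored at 36 so planted true variants clear the alternate-read and VAF
windows; heterozygous VAFs are a symmetric Beta(20, 20) rescaled to
[0.28, 0.72]; artifact-position VAFs are uniform on [0.27, 0.45], which
guarantees the alternate-read deficit; 30% of Silver-like variants get a
somatic-catalogue match; survival uses a baseline hazard of
$-\ln(0.89)/62$ per month (89% event-free at 62 months in non-carriers), a
carrier hazard ratio of 2.5, and uniform censoring on [36, 84] months. All
randomness flows from one seed; a fixed seed yields byte-identical output
files.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: linkage and haplotype structure,
read-level errors (no FASTQ/BAM), multi-transcript annotation ambiguity,
evidence-database noise (assertions are planted clean, so classifier
recovery is exact by construction rather than a statement about ClinVar
curation quality), relatedness between patients, and ancestry-specific
frequency structure. End-to-end recovery of planted Gold variants with
precision and recall 1.0 validates the plumbing and the rule logic, not
the clinical sensitivity of the medal scheme.

## Problem sizes and runtime choices

The test suite exercises: the full 1,296-bundle classifier grid; 1,000
randomized records for filter properties; 50 seeded replicates for
artifact-detector sensitivity/specificity (on 30-patient cohorts);
20 cohorts of n = 2000 for logistic parameter recovery; a 10,000-permutation
log-rank null at n = 60; and one full-scale 115-patient synthetic cohort
end to end. These sizes keep the default suite under a minute of compute
per heavy file while leaving Monte-Carlo error well inside the asserted
tolerances (the permutation check allows the Monte-Carlo band plus 0.02
absolute for the chi-square approximation at that sample size).

## Known limitations

* The published medal scheme's full decision tree has unpublished branches;
  only the documented rules are implemented, and fidelity beyond them is
  unverifiable by construction.
* Consequences and in-silico damage predictions are inputs, not
  computations; garbage annotation in, garbage medals out.
* Caller FILTER vocabularies differ between pipelines; `caller_flags` are
  carried as opaque labels and never interpreted.
* One canonical transcript per gene; no liftover (coordinates are assumed
  hg19 throughout, matching the bundled table).
* X-chromosome genotypes are treated as diploid heterozygous, appropriate
  for an all-female cohort but wrong for males.
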