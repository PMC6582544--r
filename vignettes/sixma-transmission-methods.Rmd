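---
title: "Methods: 6mA density, variant transmission, and the synthetic world"
author: "sixmaTrans developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 6mA density, variant transmission, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The model

The analysis connects three observations made on the same biological sample:

1. **6mA site calls** — single methylated adenines from SMRT kinetics
   analysis, each with a strand and a read-coverage value. Only calls with
   coverage strictly greater than 25x are retained (the threshold is read
   literally as "more than 25-fold"; it is a `min_coverage` parameter).
2. **DNA SNPs** — biallelic single-nucleotide variants with an unphased
   genotype in {0/1, 1/1} after filtering (indels, multiallelic records,
   missing and homozygous-reference genotypes are dropped; phased separators
   are normalized so `1|0` becomes `0/1`).
3. **RNA SNPs** — the same, called from RNA-seq of the same sample.

Three derived statistics carry the analysis:

* **6mA density (6mA/A)** of a region: retained sites in the region divided
  by the region's adenine count.
* **Variant density** of a region: distinct SNP positions divided by region
  length in bp. The two denominators are deliberately different: methylation
  is a per-adenine phenomenon, mutation frequency is a per-bp one.
* **Transmission-type counts**: each DNA-variant site is paired with the RNA
  genotype at the same position, producing one of the six transition types
  `0/1-0/0 ... 1/1-1/1`. "Transmitted" means the RNA genotype is variant
  (not 0/0).

The statistical layer compares per-gene variant densities between
6mA-modified and unmodified genes (two-sample t test), and regresses
per-gene 6mA density on the six per-gene type counts by ordinary least
squares:

$$ y_i = \beta_0 + \sum_{n=1}^{6} a_n x_{in} + \varepsilon_i $$

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 25 | retention threshold, strict `>` |
| `strand_mode` | `"both"` | adenine denominator counts A and T on the forward reference |
| `n_bins` | 100 | metagene profile bins |
| `t_test_flavor` | `"welch"` | `"pooled"` available for literal "Student t" fidelity |
| `include_intercept` | `TRUE` | intercept in the density regression |
| `k` (flanks) | 20 bp | half-width of site flanks for motif work |
| `anchored` | `TRUE` | motif placement anchored at the methylated A |

Why these defaults:

* **Both-strand adenine denominator.** The density statistic never states a
  strand, and the published intergenic density is consistent with counting
  adenines on either strand (A or T in the forward reference). The mode is a
  flag because the alternative reading is defensible.
* **Welch rather than pooled t.** The modified/unmodified split produces
  groups of very different sizes and variances; Welch is the robust default,
  and `"pooled"` reproduces the textbook Student test exactly when wanted.
* **Intercept on.** The published model formula shows no intercept, but the
  accompanying regression table has the shape of standard `lm` output, which
  fits with one. With an intercept the coefficients are interpretable as
  density shifts per additional site of a type; a flag disables it.
* **Anchored motif matching.** Motif coverage of a site is defined as the
  motif's obligate adenine aligned to the methylated adenine. Discovered
  motifs need not be centered, so an unanchored anywhere-in-flank mode is
  provided; both are exposed because the published coverage count does not
  say which was used.
* **Single-exon genes** are labelled `start` in the exon-group analysis (the
  grouping rule is silent about them); they can be excluded from summaries
  via `exon_groups(..., drop_single_exon = TRUE)`.
* **Significance stars** follow the published footnote exactly: `*` below
  0.05 and `***` below 1e-4 — no intermediate tiers, because none are
  defined there.

## The callable-region contract

Counting transitions into RNA genotype 0/0 requires distinguishing "RNA says
reference" from "RNA was never observed". The package makes this explicit:
an absent RNA call is imputed 0/0 **only** inside user-declared RNA-callable
regions (a BED file; typically exons or coverage-derived intervals).
Without a callable file, DNA-variant sites with no RNA record are excluded
as unobservable; an optional fallback (`gene_fallback = TRUE`) treats
positions inside genes that carry at least one RNA variant as callable. The
fallback is off by default because it conflates transcription with
callability.

DNA and RNA records pair only when their alternate alleles agree; mismatched
alleles are excluded and counted in the QC report rather than
force-classified.

## Rounding

`percent()` rounds half-up (`round_half_up`), not half-to-even, because
published percentages are typeset that way. One published value cannot be
reproduced under any consistent rule: 30055/35654 is 84.2963...%, printed as
84.29 — truncation — while the same table's 94.72, 0.85, 0.04, 20 and 15 all
require rounding. The package computes 84.30; the acceptance test records
the discrepancy as a known red rather than special-casing one number.

## The synthetic world

`synth_config()` describes a genome the analysis assumes, and
`generate_bundle()` emits it as FASTA + GFF3 + 6mA GFF + two VCFs + callable
BED + truth tables, byte-identical under a fixed seed. The defaults encode
the stated conditions of the real data where known, scaled to desk size:

* ~35% of genes carry 6mA (the real genome has 7049 of 20,040);
* per-adenine 6mA rates (0.0012 modified / 0.0002 unmodified genes) whose
  p=0.35 mixture reproduces the observed gene-level density of ~0.049%,
  with the intergenic rate at the observed 0.025%;
* modified genes mutate at **half** the unmodified per-bp SNP rate, the
  direction and magnitude the group comparison is meant to detect;
* a methylated upstream intergenic region additionally halves the
  downstream gene's SNP rate (`upstream_effect_multiplier = 0.5`);
* DNA heterozygous sites in modified genes transition to RNA 1/1 more often
  (P = 0.20 vs 0.10), the signal behind the positive `0/1-1/1` regression
  coefficient;
* 6mA coverage is Poisson with mean 74 (the real depth), with a 15% share
  drawn in 5–25x to exercise the strict filter;
* the AGGYANY motif is written into the sequence around 15% of retained
  sites (its published share), anchored at the methylated A;
* 60% of DNA SNPs are heterozygous — not stated in the source; chosen once
  as typical for a single outbred plant individual.

Where a default is not stated by the source, it was chosen once on that kind
of reasoning and not revisited.

What the generator deliberately does **not** emulate: codon structure or any
sequence composition beyond the AT fraction (every in-scope statistic
depends only on adenine placement and interval structure); overlapping
genes and isoforms (one transcript per gene); read-level artifacts (the
pipeline starts at calls, so the generator does too); RNA-callable regions
other than exons. A green round-trip test therefore establishes that the
pipeline's counting, classification and regression are correct on data with
the assumed structure — not that the upstream callers are.

For the statistical acceptance checks (power, parameter recovery, type-I
error) the package uses in-memory simulators
(`simulate_variant_density_experiment`, `simulate_regression_experiment`)
that reproduce the generator's statistical core without the file
round-trip; the round-trip itself is covered by the exact-equality bundle
tests. This keeps 50–200-replicate simulations inside a desk-scale budget.
The regression recovery criterion is evaluated as in its defining example —
mean estimate over 50 replicates within 2 SE of the planted value, positive
sign in at least 95% — because per-replicate 2-SE coverage is ~95.4% for
any consistent OLS and cannot serve as a stable 95% bar at n = 50.

## Numerical and degenerate-input choices

* Ties and edges: intervals are 1-based inclusive everywhere internally;
  BED input is converted at the parser boundary. A site exactly 1 bp past a
  gene end is intergenic; a region abutting a gene directly has no upstream
  intergenic region.
* Zero-adenine regions get density 0 with an explicit flag, never NaN.
* Zero-variance group comparisons: equal means give t = 0, p = 1; unequal
  means give p at the smallest positive double, since the contract requires
  p in (0, 1].
* A genome `N` matches only a pattern `N` in motif work, so ambiguous bases
  cannot inflate coverage.
* Overlapping gene spans are merged for intergenic derivation (with a
  warning) and per-position classification resolves by priority
  exon > intron > pseudogene > intergenic, so the feature partition is
  always exhaustive and disjoint.
* Rank-deficient regression designs error, naming the collinear columns,
  rather than silently dropping terms.

## Known limitations

* Multiallelic variants are dropped, not decomposed; the source's handling
  is unstated and decomposition would complicate the genotype alphabet.
* No multiple-testing correction is applied by default (the source applies
  none); the regression reports six marginal tests.
* The upstream-effect analysis ignores genes whose upstream region cannot be
  resolved (scaffold edge or abutting gene) and reports how many were
  excluded; with few genes the partition can be degenerate, which is an
  error by design rather than a silent small-sample comparison.
* RNA-only variants are exported and counted but not further analyzed (no
  RNA-editing claims).
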