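# sixmaTrans

Integrative analysis of DNA N6-methyladenine (6mA) methylation and genetic
variation: 6mA/A density profiling over scaffolds, genes, exon groups and
metagene bins; IUPAC motif coverage of site flanks; DNA and RNA SNP
annotation and per-gene variant densities; classification of DNA-to-RNA
genotype transmission into the six transition types; and the statistical
layer tying them together (modified-vs-unmodified group comparisons, the
6mA-density regression on transmission-type counts, and the
upstream-intergenic effect).

The package is aimed at epigenomics analysts who have, for one organism and
sample: a genome FASTA, a GFF3 annotation, kinetics-derived 6mA site calls
(ipdSummary-style GFF or BED with coverage), and DNA/RNA variant VCFs from
the same sample. A deterministic synthetic-data generator emits a complete,
internally consistent input bundle with exact truth tables, so the whole
pipeline is testable offline.

## The statistics at the core

* **6mA density** of a region is `6mA/A`: the number of methylated adenines
  divided by the region's adenine count. By default adenines are counted on
  both strands (A and T on the forward reference); a forward-only mode is
  available. Sites are retained when their coverage is strictly greater than
  25x.
* **Transmission types.** At each DNA-variant site the DNA genotype
  (0/1 or 1/1) is paired with the RNA genotype at the same position
  (0/0, 0/1 or 1/1), giving six types: `0/1-0/0, 0/1-0/1, 0/1-1/1, 1/1-0/0,
  1/1-0/1, 1/1-1/1`. An absent RNA call is read as 0/0 only inside declared
  RNA-callable regions; otherwise the site is excluded as unobservable.
  A site is *transmitted* when the RNA genotype is not 0/0.
* **Density regression.** Per gene *i* with 6mA density *y_i* and
  transmission-type counts *x_in* (n = 1..6), ordinary least squares fits
  `y_i = sum_n a_n x_in + eps` (intercept on by default), reporting
  estimates, standard errors, t values, two-sided p values and significance
  stars (`*` p < 0.05, `***` p < 1e-4).
* **Group comparisons** (modified vs unmodified genes, methylated vs normal
  upstream intergenic regions) use a two-sample t test — Welch by default,
  pooled-variance optionally.

## Worked example

```r
library(sixmaTrans)

b     <- generate_bundle(synth_config(seed = 1), "demo")
idx   <- load_annotation(b$paths$gff3, b$paths$fasta)
sites <- load_sixma(b$paths$sixma_gff, min_coverage = 25, genome = idx$genome)
dna   <- load_snps(b$paths$dna_vcf, "DNA")
rna   <- load_snps(b$paths$rna_vcf, "RNA")

## do 6mA-modified genes mutate less?
part <- modified_vs_unmodified_partition(idx, sites)
vd   <- variant_densities(dna, idx, "genes")
d    <- setNames(vd$density, vd$region_id)
compare_groups(d[part$modified], d[part$unmodified],
               label_a = "6mA", label_b = "non6mA")
#> 6mA (n=55, mean=0.001555) vs non6mA (n=92, mean=0.002399): t=-3.905, p=0.000153 [welch]

## 6mA density vs transmission-type counts
jt  <- build_joint_table(dna, rna, read_callable_bed(b$paths$callable_bed),
                         index = idx)
m   <- per_gene_type_counts(jt$joint, idx)
gd  <- sixma_densities(sites, idx, "genes")
fit_density_regression(setNames(gd$density, gd$region_id), m)
#> 6mA-density regression on 147 genes (residual variance 6.3e-07)
#>          term   estimate std_error t_value   p_value stars
#> 1 (intercept)  0.0007460 1.071e-04  6.9619 1.194e-10   ***
#> 2     0/1-0/0 -0.0002246 7.273e-05 -3.0887 2.425e-03     *
#> ...
```

The comparison says modified genes carry significantly lower per-bp variant
density than unmodified genes (the generator plants a 2x rate difference);
the regression table is the Table-1-style output for the synthetic world.

The full pipeline with all table analogs (per-gene densities, metagene
profiles, motif coverage, variant tallies, joint sites, transmission matrix,
comparisons, regression, run summary) is one call — or one CLI invocation:

```r
run_full_analysis(run_config(
  fasta = b$paths$fasta, gff3 = b$paths$gff3, sixma = b$paths$sixma_gff,
  dna_vcf = b$paths$dna_vcf, rna_vcf = b$paths$rna_vcf,
  callable_bed = b$paths$callable_bed, out_dir = "demo_out"))
```

```sh
Rscript inst/cli/sixma-tools.R generate --seed 1 --out-dir demo
Rscript inst/cli/sixma-tools.R all --fasta demo/genome.fasta \
    --gff3 demo/annotation.gff3 --sixma demo/sixma.gff \
    --dna-vcf demo/dna.vcf --rna-vcf demo/rna.vcf \
    --callable-bed demo/callable.bed --out-dir demo_out
```

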