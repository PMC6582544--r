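## Shared synthetic world for the suite: a small, fast bundle with elevated
## rates so every stage has events, cached per session.

small_cfg <- function(seed = 42, ...) {
  defaults <- list(seed = seed,
                   n_scaffolds = 2L, scaffold_length = 20000L,
                   n_genes = 20L, gene_length_range = c(500L, 1200L),
                   gap_range = c(100L, 500L),
                   sixma_rate_modified = 0.012,
                   sixma_rate_unmodified = 0.002,
                   sixma_rate_intergenic = 0.0025,
                   dna_snp_rate_modified = 0.005,
                   dna_snp_rate_unmodified = 0.01,
                   dna_snp_rate_intergenic = 0.012,
                   rna_only_rate = 5e-4,
                   coincident_rate = 0.05,
                   plant_motif_fraction = 0.3)
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  do.call(synth_config, defaults)
}

.cache <- new.env(parent = emptyenv())

test_bundle <- function(seed = 42) {
  key <- paste0("bundle", seed)
  if (!exists(key, .cache)) {
    dir <- file.path(tempdir(), paste0("sixma_bundle_", seed))
    assign(key, generate_bundle(small_cfg(seed), dir), .cache)
  }
  get(key, .cache)
}

## bundle loaded back through the pipeline entry points
test_loaded <- function(seed = 42) {
  key <- paste0("loaded", seed)
  if (!exists(key, .cache)) {
    b <- test_bundle(seed)
    index <- load_annotation(b$paths$gff3, b$paths$fasta)
    sites <- load_sixma(b$paths$sixma_gff, min_coverage = 25,
                        genome = index$genome)
    dna <- load_snps(b$paths$dna_vcf, "DNA")
    rna <- load_snps(b$paths$rna_vcf, "RNA")
    callable <- read_callable_bed(b$paths$callable_bed)
    assign(key, list(bundle = b, index = index, sites = sites, dna = dna,
                     rna = rna, callable = callable), .cache)
  }
  get(key, .cache)
}

## tiny hand-built genome helpers
write_mini_fasta <- function(seqs, path = withr::local_tempfile(
                               fileext = ".fasta", .local_envir = parent.frame())) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

write_lines_tmp <- function(lines, fileext,
                            .env = parent.frame()) {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = .env)
  writeLines(lines, path)
  path
}

mini_vcf_lines <- function(records, contigs = c(s1 = 1000L)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), unname(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    records)
}
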