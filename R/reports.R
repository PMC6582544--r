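## End-to-end pipeline runner, table-analog report emission and the CLI.

#' Build a run configuration
#'
#' @param fasta,gff3,sixma,dna_vcf,rna_vcf,callable_bed input paths
#'   (callable_bed optional).
#' @param out_dir output directory for the report TSVs.
#' @param min_coverage 6mA coverage retention threshold (strictly >).
#' @param strand_mode adenine denominator mode ("both" or "forward").
#' @param n_bins metagene profile bins.
#' @param t_test_flavor "welch" or "pooled".
#' @param include_intercept intercept in the density regression.
#' @param motifs data.frame pattern/anchor_offset for motif coverage; NULL
#'   for the package default (AGGYANY anchored at its central A).
#' @param gene_fallback callable-region fallback mode of
#'   \code{\link{build_joint_table}}.
#' @param seed seed for any resampling (recorded; the analysis itself is
#'   deterministic).
#' @return list of class \code{RunConfig}.
#' @export
run_config <- function(fasta, gff3, sixma, dna_vcf, rna_vcf,
                       callable_bed = NULL, out_dir = ".",
                       min_coverage = 25, strand_mode = "both",
                       n_bins = 100, t_test_flavor = "welch",
                       include_intercept = TRUE, motifs = NULL,
                       gene_fallback = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$motifs))
    cfg$motifs <- data.frame(pattern = "AGGYANY", anchor_offset = 5L,
                             stringsAsFactors = FALSE)
  structure(cfg, class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Loads all inputs, then emits table analogs with stable filenames:
#' per-scaffold / per-gene / per-intergenic 6mA densities, metagene profiles,
#' motif coverage, per-gene variant densities and feature tallies for DNA and
#' RNA, joint 6mA-variant sites, the per-gene transmission-type matrix, the
#' modified-vs-unmodified group comparisons, the density regression, the
#' upstream-intergenic effect, and a run summary with the headline
#' percentages. Deterministic for fixed inputs and config.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return (invisibly) list of all result objects plus \code{files}.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  for (f in c("fasta", "gff3", "sixma", "dna_vcf", "rna_vcf")) {
    if (is.null(cfg[[f]])) stopf("missing required input: --%s", f)
    if (!file.exists(cfg[[f]]))
      stopf("input for --%s does not exist: %s", f, cfg[[f]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## cheap deterministic fingerprint of the analysis *parameters* for the
  ## provenance line; paths excluded so identical inputs in different
  ## directories yield byte-identical reports
  par_fields <- c("min_coverage", "strand_mode", "n_bins", "t_test_flavor",
                  "include_intercept", "gene_fallback", "seed", "motifs")
  cfg_json <- jsonlite::toJSON(cfg[par_fields], auto_unbox = TRUE,
                               force = TRUE)
  sha <- sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                               seq_len(nchar(cfg_json))) %% 0xFFFFFFF)
  out <- function(name) file.path(cfg$out_dir, name)
  emit <- function(df, name) write_tsv_prov(df, out(name), config_sha = sha)

  index <- load_annotation(cfg$gff3, cfg$fasta)
  sites <- load_sixma(cfg$sixma, min_coverage = cfg$min_coverage,
                      genome = index$genome)
  dna <- load_snps(cfg$dna_vcf, "DNA")
  rna <- load_snps(cfg$rna_vcf, "RNA")
  callable <- if (!is.null(cfg$callable_bed)) read_callable_bed(cfg$callable_bed)

  ## 6mA densities (Tables S1/S2 analogs) and metagene profiles (Fig 1b)
  dens_scaffold <- sixma_densities(sites, index, "scaffolds", cfg$strand_mode)
  dens_gene <- sixma_densities(sites, index, "genes", cfg$strand_mode)
  dens_inter <- sixma_densities(sites, index, "intergenic", cfg$strand_mode)
  emit(dens_scaffold, "sixma_density_scaffolds.tsv")
  emit(dens_gene, "sixma_density_genes.tsv")
  emit(dens_inter, "sixma_density_intergenic.tsv")
  coding <- index$genes[index$genes$biotype == "gene", ]
  prof_gene <- metagene_profile(sites, coding, index$genome, cfg$n_bins,
                                cfg$strand_mode)
  inter_regions <- cbind(index$intergenic, strand = "+")
  prof_inter <- metagene_profile(sites, inter_regions, index$genome,
                                 cfg$n_bins, cfg$strand_mode)
  emit(cbind(region_class = "gene", prof_gene), "metagene_gene.tsv")
  emit(cbind(region_class = "intergenic", prof_inter), "metagene_intergenic.tsv")

  ## exon-group densities (Fig 1a analog)
  eg <- exon_groups(index)
  eg_dens <- do.call(rbind, lapply(c("start", "middle", "end"), function(grp) {
    rows <- eg[eg$exon_group == grp, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    n_sites <- sum(count_in_regions(sites$scaffold, sites$pos,
                                    rows[, c("scaffold", "start", "end")]))
    n_aden <- sum(count_adenines(index$genome, rows$scaffold, rows$start,
                                 rows$end, cfg$strand_mode))
    data.frame(exon_group = grp, n_exons = nrow(rows), n_sites = n_sites,
               n_adenines = n_aden,
               density = if (n_aden) n_sites / n_aden else 0)
  }))
  emit(eg_dens, "exon_group_density.tsv")

  ## motif coverage (Fig 2 analog)
  mc <- motif_coverage(sites, cfg$motifs, index$genome)
  emit(cbind(mc$per_pattern,
             pct_of_sites = percent(mc$per_pattern$n_covered,
                                    max(nrow(sites), 1L))),
       "motif_coverage.tsv")

  ## variant distribution (Tables S4-S7, Fig 3 analogs)
  dna_ann <- annotate_feature(dna, index)
  rna_ann <- annotate_feature(rna, index)
  emit(variant_densities(dna, index, "scaffolds"), "dna_variants_scaffolds.tsv")
  emit(variant_densities(rna, index, "scaffolds"), "rna_variants_scaffolds.tsv")
  vd_dna <- variant_densities(dna, index, "genes")
  vd_rna <- variant_densities(rna, index, "genes")
  emit(vd_dna, "dna_variants_genes.tsv")
  emit(vd_rna, "rna_variants_genes.tsv")
  emit(cbind(source = "DNA", feature_tally(dna_ann)), "dna_feature_tally.tsv")
  emit(cbind(source = "RNA", feature_tally(rna_ann)), "rna_feature_tally.tsv")

  ## joint 6mA-variant sites (Tables S8/S9 analogs)
  jd <- overlap_with_sixma(dna, sites, index)
  jr <- overlap_with_sixma(rna, sites, index)
  emit(jd, "joint_sixma_dna.tsv")
  emit(jr, "joint_sixma_rna.tsv")

  ## transmission (Fig 5, Table S10 analogs)
  jt <- build_joint_table(dna, rna, callable_regions = callable,
                          gene_fallback = cfg$gene_fallback, index = index)
  emit(jt$joint, "joint_table.tsv")
  tm <- per_gene_type_counts(jt$joint, index)
  emit(data.frame(gene_id = rownames(tm), as.data.frame(tm),
                  check.names = FALSE), "transmission_type_counts.tsv")
  emit(data.frame(reason = names(jt$qc), n = unlist(jt$qc)), "transmission_qc.tsv")

  ## group comparisons (Fig 4 analog)
  part <- modified_vs_unmodified_partition(index, sites)
  cmp_of <- function(vd, label) {
    d <- setNames(vd$density, vd$region_id)
    compare_groups(d[part$modified], d[part$unmodified],
                   flavor = cfg$t_test_flavor,
                   label_a = paste0(label, "_6mA"),
                   label_b = paste0(label, "_non6mA"))
  }
  cmp_dna <- cmp_of(vd_dna, "DNA")
  cmp_rna <- cmp_of(vd_rna, "RNA")
  cmp_df <- function(x) data.frame(
    group_a = x$group_a_label, group_b = x$group_b_label, n_a = x$n_a,
    n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
    t_statistic = x$t_statistic, p_value = x$p_value,
    test_flavor = x$test_flavor, stringsAsFactors = FALSE)
  emit(rbind(cmp_df(cmp_dna), cmp_df(cmp_rna)), "group_comparisons.tsv")

  ## density regression (Table 1 analog)
  dens_vec <- setNames(dens_gene$density, dens_gene$region_id)
  fit <- fit_density_regression(dens_vec, tm,
                                include_intercept = cfg$include_intercept)
  emit(fit$table, "regression.tsv")

  ## upstream-intergenic effect (Fig 6c/d analog)
  up <- tryCatch(upstream_effect(index, sites, dna, rna,
                                 flavor = cfg$t_test_flavor),
                 error = function(e) e)
  if (inherits(up, "error")) {
    up_df <- data.frame(note = conditionMessage(up))
  } else {
    up_df <- rbind(cmp_df(up$DNA), cmp_df(up$RNA))
    up_df$source <- c("DNA", "RNA")
  }
  emit(up_df, "upstream_effect.tsv")

  ## headline summary
  n_sites <- nrow(sites); n_dna <- nrow(dna); n_rna <- nrow(rna)
  trans <- transmitted_set(jt$joint)
  summary_df <- data.frame(
    statistic = c("n_sixma_retained", "n_dna_variants", "n_rna_variants",
                  "n_joint_sixma_dna", "n_joint_sixma_rna", "n_transmitted",
                  "pct_motif_union", "pct_transmitted_of_dna",
                  "pct_transmitted_of_rna", "pct_joint_of_sixma",
                  "pct_joint_of_dna", "pct_dna_variants_in_genes"),
    value = c(n_sites, n_dna, n_rna, nrow(jd), nrow(jr), nrow(trans),
              if (n_sites) percent(mc$union, n_sites) else 0,
              if (n_dna) percent(nrow(trans), n_dna) else 0,
              if (n_rna) percent(nrow(trans), n_rna) else 0,
              if (n_sites) percent(nrow(jd), n_sites) else 0,
              if (n_dna) percent(nrow(jd), n_dna) else 0,
              if (n_dna) percent(sum(dna_ann$feature_class %in%
                                       c("exon", "intron")), n_dna) else 0),
    stringsAsFactors = FALSE)
  emit(summary_df, "run_summary.tsv")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       out("resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)

  invisible(list(index = index, sites = sites, dna = dna, rna = rna,
                 densities = list(scaffold = dens_scaffold, gene = dens_gene,
                                  intergenic = dens_inter),
                 exon_groups = eg_dens, motif = mc, joint = jt,
                 type_counts = tm, comparisons = list(DNA = cmp_dna,
                                                      RNA = cmp_rna),
                 regression = fit, upstream = up, summary = summary_df,
                 files = list.files(cfg$out_dir, full.names = TRUE)))
}

#' Command-line entry point
#'
#' Subcommands: \code{generate} (synthetic bundle), \code{density},
#' \code{variants}, \code{transmit}, \code{associate} (single stages) and
#' \code{all} (the full pipeline). Logs to stderr, data to files only.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return exit status (0 on success), invisibly.
#' @export
sixma_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: sixma-tools <generate|density|variants|transmit|associate|all> [options]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  opts <- list(
    optparse::make_option("--fasta", type = "character", default = NULL),
    optparse::make_option("--gff3", type = "character", default = NULL),
    optparse::make_option("--sixma", type = "character", default = NULL),
    optparse::make_option("--dna-vcf", dest = "dna_vcf", type = "character",
                          default = NULL),
    optparse::make_option("--rna-vcf", dest = "rna_vcf", type = "character",
                          default = NULL),
    optparse::make_option("--callable-bed", dest = "callable_bed",
                          type = "character", default = NULL),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "."),
    optparse::make_option("--min-coverage", dest = "min_coverage",
                          type = "double", default = 25),
    optparse::make_option("--strand-mode", dest = "strand_mode",
                          type = "character", default = "both"),
    optparse::make_option("--n-bins", dest = "n_bins", type = "integer",
                          default = 100),
    optparse::make_option("--t-test", dest = "t_test_flavor",
                          type = "character", default = "welch"),
    optparse::make_option("--no-intercept", dest = "no_intercept",
                          action = "store_true", default = FALSE),
    optparse::make_option("--gene-fallback", dest = "gene_fallback",
                          action = "store_true", default = FALSE),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-genes", dest = "n_genes", type = "integer",
                          default = 150L))
  p <- optparse::OptionParser(option_list = opts, usage = usage)
  o <- tryCatch(optparse::parse_args(p, args = rest),
                error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(o)) return(invisible(2L))
  status <- tryCatch({
    if (cmd == "generate") {
      cfg <- synth_config(seed = o$seed, n_genes = o$n_genes)
      b <- generate_bundle(cfg, o$out_dir)
      message(sprintf("bundle written to %s (%d retained 6mA sites, %d DNA SNPs)",
                      o$out_dir, b$truth$global$n_sites_retained,
                      b$truth$global$n_dna_snps))
      0L
    } else if (cmd %in% c("all", "density", "variants", "transmit",
                          "associate")) {
      need <- switch(cmd,
                     density = c("fasta", "gff3", "sixma"),
                     variants = c("fasta", "gff3", "dna_vcf", "rna_vcf"),
                     c("fasta", "gff3", "sixma", "dna_vcf", "rna_vcf"))
      for (f in need)
        if (is.null(o[[f]])) stopf("missing required flag --%s",
                                   gsub("_", "-", f))
      cfg <- run_config(fasta = o$fasta, gff3 = o$gff3, sixma = o$sixma,
                        dna_vcf = o$dna_vcf, rna_vcf = o$rna_vcf,
                        callable_bed = o$callable_bed, out_dir = o$out_dir,
                        min_coverage = o$min_coverage,
                        strand_mode = o$strand_mode, n_bins = o$n_bins,
                        t_test_flavor = o$t_test_flavor,
                        include_intercept = !o$no_intercept,
                        gene_fallback = o$gene_fallback, seed = o$seed)
      run_stage(cmd, cfg)
      0L
    } else {
      message(usage)
      2L
    }
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

## stage runners share run_full_analysis for "all"; single stages load only
## what they need and emit their own TSV subset
run_stage <- function(cmd, cfg) {
  if (cmd == "all") return(run_full_analysis(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- load_annotation(cfg$gff3, cfg$fasta)
  emit <- function(df, name) write_tsv_prov(df, file.path(cfg$out_dir, name))
  if (cmd == "density") {
    sites <- load_sixma(cfg$sixma, cfg$min_coverage, genome = index$genome)
    emit(sixma_densities(sites, index, "scaffolds", cfg$strand_mode),
         "sixma_density_scaffolds.tsv")
    emit(sixma_densities(sites, index, "genes", cfg$strand_mode),
         "sixma_density_genes.tsv")
    emit(sixma_densities(sites, index, "intergenic", cfg$strand_mode),
         "sixma_density_intergenic.tsv")
  } else if (cmd == "variants") {
    dna <- annotate_feature(load_snps(cfg$dna_vcf, "DNA"), index)
    rna <- annotate_feature(load_snps(cfg$rna_vcf, "RNA"), index)
    emit(variant_densities(dna, index, "genes"), "dna_variants_genes.tsv")
    emit(variant_densities(rna, index, "genes"), "rna_variants_genes.tsv")
    emit(cbind(source = "DNA", feature_tally(dna)), "dna_feature_tally.tsv")
    emit(cbind(source = "RNA", feature_tally(rna)), "rna_feature_tally.tsv")
  } else if (cmd == "transmit") {
    dna <- load_snps(cfg$dna_vcf, "DNA")
    rna <- load_snps(cfg$rna_vcf, "RNA")
    callable <- if (!is.null(cfg$callable_bed)) read_callable_bed(cfg$callable_bed)
    jt <- build_joint_table(dna, rna, callable, cfg$gene_fallback, index)
    emit(jt$joint, "joint_table.tsv")
    emit(data.frame(gene_id = rownames(per_gene_type_counts(jt$joint, index)),
                    as.data.frame(per_gene_type_counts(jt$joint, index)),
                    check.names = FALSE), "transmission_type_counts.tsv")
  } else if (cmd == "associate") {
    run_full_analysis(cfg)  # association needs every upstream stage anyway
  }
  invisible(NULL)
}
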