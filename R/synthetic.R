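## Deterministic synthetic-data generator: a complete input bundle (FASTA,
## GFF3, 6mA GFF, DNA/RNA VCF, callable BED) with planted statistical
## structure plus exact truth tables, so every pipeline stage is testable
## offline.

#' Synthetic bundle configuration
#'
#' Defaults encode the stated world the analysis assumes: ~35% of genes carry
#' 6mA (7049/20040 in the real genome); per-adenine 6mA rates whose mixture
#' reproduces the observed gene-level density (~0.049%) with the intergenic
#' rate at the observed 0.025%; modified genes mutate at half the rate of
#' unmodified ones; 6mA-methylated upstream intergenic regions halve the
#' downstream gene's SNP rate; mean 6mA coverage 74x with a 15% low-coverage
#' share to exercise the >25x filter; the AGGYANY motif planted at 15% of
#' retained sites.
#'
#' @param seed integer RNG seed; the bundle is byte-identical given the seed.
#' @param n_scaffolds,scaffold_length genome shape.
#' @param at_fraction A+T fraction of the i.i.d. sequence.
#' @param n_genes number of gene models to place (error if infeasible).
#' @param gene_length_range,exon_count_range,gap_range structural ranges (bp).
#' @param p_pseudogene share of gene models emitted as pseudogenes.
#' @param p_gene_modified probability a protein-coding gene is 6mA-modified.
#' @param sixma_rate_modified,sixma_rate_unmodified,sixma_rate_intergenic
#'   marks per adenine (A or T on the forward reference).
#' @param dna_snp_rate_modified,dna_snp_rate_unmodified,dna_snp_rate_intergenic
#'   SNPs per bp.
#' @param het_fraction share of DNA SNPs that are heterozygous (0/1).
#' @param transmission_matrix list with elements \code{modified} and
#'   \code{unmodified}, each a 2x3 row-stochastic matrix
#'   P(rna_gt | dna_gt) over rows {0/1, 1/1} and columns {0/0, 0/1, 1/1}.
#' @param rna_only_rate RNA-only variant rate per callable bp.
#' @param upstream_effect_multiplier factor on a gene's SNP rate when its
#'   upstream intergenic region carries a retained 6mA site.
#' @param cov_mean,cov_low_share 6mA coverage model: Poisson mean for
#'   retained records, and the share of records drawn below the threshold.
#' @param min_coverage the retention threshold (strictly greater-than).
#' @param plant_motif,plant_motif_anchor,plant_motif_fraction IUPAC motif
#'   written into the sequence around a fraction of retained sites, anchored
#'   at the methylated A; set \code{plant_motif = NULL} to disable.
#' @param coincident_rate probability a retained 6mA site also carries a DNA
#'   SNP at the same position.
#' @return list of class \code{SynthConfig}.
#' @export
synth_config <- function(seed = 1L,
                         n_scaffolds = 4L,
                         scaffold_length = 150000L,
                         at_fraction = 0.65,
                         n_genes = 150L,
                         gene_length_range = c(800L, 2500L),
                         exon_count_range = c(1L, 6L),
                         gap_range = c(150L, 1500L),
                         p_pseudogene = 0.05,
                         p_gene_modified = 0.35,
                         sixma_rate_modified = 0.0012,
                         sixma_rate_unmodified = 0.0002,
                         sixma_rate_intergenic = 0.00025,
                         dna_snp_rate_modified = 0.00135,
                         dna_snp_rate_unmodified = 0.0027,
                         dna_snp_rate_intergenic = 0.0043,
                         het_fraction = 0.6,
                         transmission_matrix = default_transmission_matrix(),
                         rna_only_rate = 1e-4,
                         upstream_effect_multiplier = 0.5,
                         cov_mean = 74,
                         cov_low_share = 0.15,
                         min_coverage = 25,
                         plant_motif = "AGGYANY",
                         plant_motif_anchor = 5L,
                         plant_motif_fraction = 0.15,
                         coincident_rate = 0.0085) {
  cfg <- as.list(environment())
  for (m in c("modified", "unmodified")) {
    tm <- cfg$transmission_matrix[[m]]
    if (is.null(tm) || !all(dim(tm) == c(2L, 3L)) ||
        any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
      stopf("transmission_matrix$%s must be a 2x3 row-stochastic matrix", m)
  }
  rates <- unlist(cfg[grep("_rate", names(cfg))])
  if (any(rates < 0)) stopf("rates must be >= 0")
  if (cfg$at_fraction <= 0 || cfg$at_fraction >= 1)
    stopf("at_fraction must be in (0,1)")
  structure(cfg, class = "SynthConfig")
}

#' Default DNA-to-RNA transmission matrix of the synthetic world
#'
#' Modified genes shift heterozygous DNA sites toward RNA homozygosity
#' (higher P(1/1 | 0/1)), the direction the density regression is meant to
#' recover.
#' @return list of two 2x3 row-stochastic matrices.
#' @export
default_transmission_matrix <- function() {
  dn <- list(c("0/1", "1/1"), c("0/0", "0/1", "1/1"))
  list(modified = matrix(c(0.45, 0.35, 0.20,
                           0.05, 0.10, 0.85), 2, 3, byrow = TRUE,
                         dimnames = dn),
       unmodified = matrix(c(0.55, 0.35, 0.10,
                             0.05, 0.10, 0.85), 2, 3, byrow = TRUE,
                           dimnames = dn))
}

#' Generate a synthetic input bundle
#'
#' Writes FASTA, GFF3 annotation, 6mA GFF, DNA and RNA VCFs, an RNA-callable
#' BED, truth tables (TSV) and a config echo (JSON) into \code{out_dir}.
#' Deterministic: rerunning with the same config yields byte-identical files.
#'
#' @param config a \code{\link{synth_config}}.
#' @param out_dir output directory (created if needed).
#' @return list with \code{paths} (named file paths), \code{truth}
#'   (sites, dna_snps, rna_records, genes, global) and \code{config}.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  world <- withr::with_seed(config$seed, build_world(config))
  write_bundle(world, config, out_dir)
}

#' Truth tables of a generated bundle
#'
#' Reads back the exact per-record truth written alongside a bundle, after
#' checking the bundle's config echo matches.
#'
#' @param config the \code{\link{synth_config}} the bundle was built with.
#' @param out_dir the bundle directory.
#' @return list with sites, dna_snps, rna_records, genes and global tables.
#' @export
planted_truth <- function(config, out_dir) {
  echo_path <- file.path(out_dir, "config.json")
  if (!file.exists(echo_path)) stopf("no config echo in %s", out_dir)
  echo <- jsonlite::read_json(echo_path, simplifyVector = TRUE)
  if (!identical(as.integer(echo$seed), as.integer(config$seed)) ||
      !identical(as.integer(echo$n_genes), as.integer(config$n_genes)))
    stopf("bundle in %s was not generated from this config", out_dir)
  list(sites = read_tsv_prov(file.path(out_dir, "truth_sites.tsv")),
       dna_snps = read_tsv_prov(file.path(out_dir, "truth_dna_snps.tsv")),
       rna_records = read_tsv_prov(file.path(out_dir, "truth_rna_records.tsv")),
       genes = read_tsv_prov(file.path(out_dir, "truth_genes.tsv")),
       global = jsonlite::read_json(file.path(out_dir, "truth_global.json"),
                                    simplifyVector = TRUE))
}

## ---- internal world construction (all sampling under the caller's seed) ----

build_world <- function(cfg) {
  bases <- c("A", "T", "C", "G")
  probs <- c(cfg$at_fraction / 2, cfg$at_fraction / 2,
             (1 - cfg$at_fraction) / 2, (1 - cfg$at_fraction) / 2)
  sc_names <- sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds))
  seqs <- lapply(sc_names, function(s)
    sample(bases, cfg$scaffold_length, replace = TRUE, prob = probs))
  names(seqs) <- sc_names
  sl <- setNames(rep(cfg$scaffold_length, cfg$n_scaffolds), sc_names)

  ## ---- gene placement ----
  genes <- list(); exons <- list(); placed <- 0L
  rint <- function(lo, hi) lo + floor(runif(1) * (hi - lo + 1))
  for (sc in sc_names) {
    cursor <- 1L
    while (placed < cfg$n_genes) {
      gap <- rint(cfg$gap_range[1], cfg$gap_range[2])
      len <- rint(cfg$gene_length_range[1], cfg$gene_length_range[2])
      start <- cursor + gap
      end <- start + len - 1L
      if (end > cfg$scaffold_length - 50L) break
      placed <- placed + 1L
      gid <- sprintf("gene%04d", placed)
      strand <- sample(c("+", "-"), 1)
      biotype <- if (runif(1) < cfg$p_pseudogene) "pseudogene" else "gene"
      genes[[placed]] <- data.frame(gene_id = gid, scaffold = sc,
                                    start = start, end = end, strand = strand,
                                    biotype = biotype, stringsAsFactors = FALSE)
      if (biotype == "gene")
        exons[[gid]] <- make_exons(gid, start, end, cfg)
      cursor <- end + 1L
    }
  }
  if (placed < cfg$n_genes)
    stopf("infeasible config: only %d of %d genes fit on %d x %d bp scaffolds",
          placed, cfg$n_genes, cfg$n_scaffolds, cfg$scaffold_length)
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, c(exons, list(make.row.names = FALSE)))
  exons$scaffold <- genes$scaffold[match(exons$gene_id, genes$gene_id)]
  coding <- genes$biotype == "gene"
  genes$modified <- coding & runif(nrow(genes)) < cfg$p_gene_modified

  intergenic <- derive_intergenic(genes, sl)

  ## ---- 6mA marks (genes then intergenic) ----
  pick_marks <- function(sc, start, end, rate) {
    if (rate <= 0) return(integer(0))
    chars <- seqs[[sc]][start:end]
    at <- which(chars %in% c("A", "T")) + start - 1L
    at[runif(length(at)) < rate]
  }
  marks <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$biotype[i] != "gene") next
    rate <- if (genes$modified[i]) cfg$sixma_rate_modified else
      cfg$sixma_rate_unmodified
    p <- pick_marks(genes$scaffold[i], genes$start[i], genes$end[i], rate)
    if (length(p))
      marks[[length(marks) + 1L]] <- data.frame(scaffold = genes$scaffold[i],
                                                pos = p,
                                                stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(intergenic))) {
    p <- pick_marks(intergenic$scaffold[i], intergenic$start[i],
                    intergenic$end[i], cfg$sixma_rate_intergenic)
    if (length(p))
      marks[[length(marks) + 1L]] <- data.frame(
        scaffold = intergenic$scaffold[i], pos = p, stringsAsFactors = FALSE)
  }
  sites <- if (length(marks)) do.call(rbind, marks) else
    data.frame(scaffold = character(), pos = integer(),
               stringsAsFactors = FALSE)
  if (nrow(sites)) {
    sites <- sites[order(sites$scaffold, sites$pos), , drop = FALSE]
    sites$strand <- ifelse(mapply(function(s, p) seqs[[s]][p],
                                  sites$scaffold, sites$pos) == "A", "+", "-")
    low <- runif(nrow(sites)) < cfg$cov_low_share
    cov_hi <- pmax(cfg$min_coverage + 1L, rpois(nrow(sites), cfg$cov_mean))
    cov_lo <- 5L + floor(runif(nrow(sites)) * (cfg$min_coverage - 4L))
    sites$coverage <- as.integer(ifelse(low, cov_lo, cov_hi))
    sites$retained <- sites$coverage > cfg$min_coverage
  } else {
    sites$strand <- character(0); sites$coverage <- integer(0)
    sites$retained <- logical(0)
  }

  ## ---- motif planting on retained sites ----
  sites$planted_motif <- rep(FALSE, nrow(sites))
  if (!is.null(cfg$plant_motif) && nrow(sites)) {
    idx <- which(sites$retained)
    n_plant <- floor(length(idx) * cfg$plant_motif_fraction)
    chosen <- if (n_plant > 0) sample(idx, n_plant) else integer(0)
    pat <- strsplit(cfg$plant_motif, "")[[1]]
    a <- cfg$plant_motif_anchor
    for (i in chosen) {
      real <- vapply(seq_along(pat), function(j)
        if (j == a) "A" else sample(IUPAC_SETS[[pat[j]]], 1), character(1))
      sc <- sites$scaffold[i]; pos <- sites$pos[i]
      if (sites$strand[i] == "+") {
        s <- pos - (a - 1L); e <- pos + (length(pat) - a)
        if (s >= 1L && e <= sl[[sc]]) {
          seqs[[sc]][s:e] <- real
          sites$planted_motif[i] <- TRUE
        }
      } else {
        s <- pos - (length(pat) - a); e <- pos + (a - 1L)
        if (s >= 1L && e <= sl[[sc]]) {
          seqs[[sc]][s:e] <- rev(chartr("ACGT", "TGCA", real))
          sites$planted_motif[i] <- TRUE
        }
      }
    }
    ## planting may have overwritten the base under a neighbouring mark
    if (nrow(sites)) {
      base <- mapply(function(s, p) seqs[[s]][p], sites$scaffold, sites$pos)
      ok <- (sites$strand == "+" & base == "A") |
        (sites$strand == "-" & base == "T")
      sites <- sites[ok, , drop = FALSE]
    }
  }
  rownames(sites) <- NULL

  ## ---- upstream methylation flags, then DNA SNPs ----
  retained <- sites[sites$retained, , drop = FALSE]
  inter_meth <- vapply(seq_len(nrow(intergenic)), function(i)
    any(retained$scaffold == intergenic$scaffold[i] &
          retained$pos >= intergenic$start[i] &
          retained$pos <= intergenic$end[i]), logical(1))
  up_of <- function(i) {
    g <- genes[i, ]
    hit <- if (g$strand == "+")
      which(intergenic$scaffold == g$scaffold & intergenic$end == g$start - 1L)
    else
      which(intergenic$scaffold == g$scaffold & intergenic$start == g$end + 1L)
    if (length(hit)) hit[1] else NA_integer_
  }
  up_idx <- vapply(seq_len(nrow(genes)), up_of, integer(1))
  genes$upstream_methylated <- !is.na(up_idx) & coding &
    ifelse(is.na(up_idx), FALSE, inter_meth[pmax(up_idx, 1L)])

  draw_snps <- function(sc, start, end, rate) {
    len <- end - start + 1L
    n <- rbinom(1, len, min(rate, 1))
    if (n == 0L) return(integer(0))
    sort(sample(start:end, n))
  }
  snp_rows <- list()
  for (i in seq_len(nrow(genes))) {
    rate <- if (genes$biotype[i] != "gene") cfg$dna_snp_rate_unmodified
    else if (genes$modified[i]) cfg$dna_snp_rate_modified
    else cfg$dna_snp_rate_unmodified
    if (genes$upstream_methylated[i]) rate <- rate * cfg$upstream_effect_multiplier
    p <- draw_snps(genes$scaffold[i], genes$start[i], genes$end[i], rate)
    if (length(p))
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        scaffold = genes$scaffold[i], pos = p, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(intergenic))) {
    p <- draw_snps(intergenic$scaffold[i], intergenic$start[i],
                   intergenic$end[i], cfg$dna_snp_rate_intergenic)
    if (length(p))
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        scaffold = intergenic$scaffold[i], pos = p, stringsAsFactors = FALSE)
  }
  dna <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(scaffold = character(), pos = integer(), stringsAsFactors = FALSE)
  ## coincident 6mA + SNP positions
  if (nrow(retained) && cfg$coincident_rate > 0) {
    co <- retained[runif(nrow(retained)) < cfg$coincident_rate,
                   c("scaffold", "pos"), drop = FALSE]
    co <- co[!paste(co$scaffold, co$pos) %in% paste(dna$scaffold, dna$pos), ,
             drop = FALSE]
    dna <- rbind(dna, co)
  }
  dna <- unique(dna)
  dna <- dna[order(dna$scaffold, dna$pos), , drop = FALSE]
  rownames(dna) <- NULL
  if (nrow(dna)) {
    dna$ref <- mapply(function(s, p) seqs[[s]][p], dna$scaffold, dna$pos)
    dna$alt <- vapply(dna$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    dna$gt <- ifelse(runif(nrow(dna)) < cfg$het_fraction, "0/1", "1/1")
  } else {
    dna$ref <- character(0); dna$alt <- character(0); dna$gt <- character(0)
  }

  ## ---- RNA genotypes at callable (exonic) DNA-SNP sites ----
  callable <- exons[, c("scaffold", "start", "end"), drop = FALSE]
  gene_of_pos <- function(sc, p) {
    hit <- which(genes$scaffold == sc & genes$start <= p & genes$end >= p &
                   genes$biotype == "gene")
    if (length(hit)) hit[1] else NA_integer_
  }
  dna$in_callable <- if (nrow(dna))
    in_regions(dna$scaffold, dna$pos, callable) else logical(0)
  dna$rna_gt <- rep(NA_character_, nrow(dna))
  rna_rows <- list()
  for (i in which(dna$in_callable)) {
    gi <- gene_of_pos(dna$scaffold[i], dna$pos[i])
    mkey <- if (!is.na(gi) && genes$modified[gi]) "modified" else "unmodified"
    pr <- cfg$transmission_matrix[[mkey]][dna$gt[i], ]
    dna$rna_gt[i] <- sample(colnames(cfg$transmission_matrix[[mkey]]), 1,
                            prob = pr)
    if (dna$rna_gt[i] != "0/0")
      rna_rows[[length(rna_rows) + 1L]] <- data.frame(
        scaffold = dna$scaffold[i], pos = dna$pos[i], ref = dna$ref[i],
        alt = dna$alt[i], gt = dna$rna_gt[i], rna_only = FALSE,
        stringsAsFactors = FALSE)
  }
  ## RNA-only variants in callable regions
  for (i in seq_len(nrow(callable))) {
    p <- draw_snps(callable$scaffold[i], callable$start[i], callable$end[i],
                   cfg$rna_only_rate)
    if (length(p))
      p <- p[!paste(callable$scaffold[i], p) %in%
               paste(dna$scaffold, dna$pos)]
    for (pp in p) {
      r <- seqs[[callable$scaffold[i]]][pp]
      rna_rows[[length(rna_rows) + 1L]] <- data.frame(
        scaffold = callable$scaffold[i], pos = pp, ref = r,
        alt = sample(setdiff(c("A", "C", "G", "T"), r), 1),
        gt = sample(c("0/1", "1/1"), 1), rna_only = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  rna <- if (length(rna_rows)) do.call(rbind, rna_rows) else
    data.frame(scaffold = character(), pos = integer(), ref = character(),
               alt = character(), gt = character(), rna_only = logical(),
               stringsAsFactors = FALSE)
  rna <- unique(rna)
  rna <- rna[order(rna$scaffold, rna$pos), , drop = FALSE]
  rownames(rna) <- NULL

  ## ---- per-gene truth ----
  genes$n_sixma_total <- count_in_regions(sites$scaffold, sites$pos,
                                          genes[, c("scaffold", "start", "end")])
  genes$n_sixma_retained <- count_in_regions(retained$scaffold, retained$pos,
                                             genes[, c("scaffold", "start", "end")])
  genes$n_dna_snps <- count_in_regions(dna$scaffold, dna$pos,
                                       genes[, c("scaffold", "start", "end")])
  genes$n_rna_records <- count_in_regions(rna$scaffold, rna$pos,
                                          genes[, c("scaffold", "start", "end")])
  joint <- dna[dna$in_callable, , drop = FALSE]
  if (nrow(joint)) {
    joint$type <- paste(joint$gt, joint$rna_gt, sep = "-")
    gi <- vapply(seq_len(nrow(joint)), function(i)
      gene_of_pos(joint$scaffold[i], joint$pos[i]), integer(1))
    joint$gene_id <- genes$gene_id[gi]
  } else joint$type <- character(0)
  for (ty in TRANSMISSION_TYPES) {
    col <- paste0("n_", gsub("[/-]", "_", ty))
    cnt <- integer(nrow(genes))
    if (nrow(joint)) {
      tb <- table(joint$gene_id[joint$type == ty])
      cnt[match(names(tb), genes$gene_id)] <- as.integer(tb)
    }
    genes[[col]] <- cnt
  }

  key <- function(df) paste(df$scaffold, df$pos)
  global <- list(
    n_sites_emitted = nrow(sites),
    n_sites_retained = nrow(retained),
    n_dna_snps = nrow(dna),
    n_rna_records = nrow(rna),
    n_rna_only = sum(rna$rna_only),
    n_joint = nrow(joint),
    n_transmitted = if (nrow(joint)) sum(joint$rna_gt != "0/0") else 0L,
    type_counts = as.list(setNames(
      vapply(TRANSMISSION_TYPES,
             function(t) if (nrow(joint)) sum(joint$type == t) else 0L,
             integer(1)), TRANSMISSION_TYPES)),
    n_coincident_dna = sum(key(retained) %in% key(dna)),
    n_coincident_rna = sum(key(retained) %in% key(rna)),
    n_planted_motif = sum(sites$planted_motif[sites$retained]),
    n_modified_genes = sum(genes$modified),
    n_genes = sum(genes$biotype == "gene"),
    n_pseudogenes = sum(genes$biotype == "pseudogene"))

  list(seqs = seqs, scaffold_lengths = sl, genes = genes, exons = exons,
       intergenic = intergenic, sites = sites, dna = dna, rna = rna,
       callable = callable, joint = joint, global = global)
}

make_exons <- function(gid, start, end, cfg, exon_min = 60L, intron_min = 60L) {
  len <- end - start + 1L
  n_max <- max(1L, (len + intron_min) %/% (exon_min + intron_min))
  n_ex <- min(sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1), n_max)
  n_seg <- 2L * n_ex - 1L
  mins <- rep(c(exon_min, intron_min), length.out = n_seg)
  slack <- len - sum(mins)
  alloc <- if (slack > 0) as.vector(rmultinom(1, slack, rep(1, n_seg))) else
    rep(0L, n_seg)
  seg <- mins + alloc
  ends <- cumsum(seg) + start - 1L
  starts <- c(start, ends[-n_seg] + 1L)
  i <- seq(1, n_seg, by = 2)
  data.frame(gene_id = gid, scaffold = NA_character_, start = starts[i],
             end = ends[i], stringsAsFactors = FALSE)
}

## ---- file emission ----

write_bundle <- function(world, cfg, out_dir) {
  paths <- list(
    fasta = file.path(out_dir, "genome.fasta"),
    gff3 = file.path(out_dir, "annotation.gff3"),
    sixma_gff = file.path(out_dir, "sixma.gff"),
    dna_vcf = file.path(out_dir, "dna.vcf"),
    rna_vcf = file.path(out_dir, "rna.vcf"),
    callable_bed = file.path(out_dir, "callable.bed"),
    config = file.path(out_dir, "config.json"))

  dss <- Biostrings::DNAStringSet(vapply(world$seqs, paste, "", collapse = ""))
  Biostrings::writeXStringSet(dss, paths$fasta, width = 70L)

  ## GFF3 annotation: gene / pseudogene + exon
  g <- world$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    typ <- if (g$biotype[i] == "pseudogene") "pseudogene" else "gene"
    lines <- c(lines, sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                              g$scaffold[i], typ, g$start[i], g$end[i],
                              g$strand[i], g$gene_id[i], g$biotype[i]))
    ex <- world$exons[world$exons$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ex))
      lines <- c(lines, sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                ex$scaffold, ex$start, ex$end, g$strand[i],
                                ex$gene_id))
  }
  writeLines(lines, paths$gff3)

  ## 6mA GFF (ipdSummary-style modification records)
  s <- world$sites
  writeLines(c("##gff-version 3",
               if (nrow(s)) sprintf(
                 "%s\tkinModCall\tm6A\t%d\t%d\t%d\t%s\t.\tcoverage=%d;IPDRatio=4.00",
                 s$scaffold, s$pos, s$pos, s$coverage, s$strand, s$coverage)),
             paths$sixma_gff)

  write_min_vcf(world$dna[, c("scaffold", "pos", "ref", "alt", "gt")],
                world$scaffold_lengths, paths$dna_vcf)
  write_min_vcf(world$rna[, c("scaffold", "pos", "ref", "alt", "gt")],
                world$scaffold_lengths, paths$rna_vcf)

  cb <- world$callable[order(world$callable$scaffold, world$callable$start), ,
                       drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\tcallable\t0\t.", cb$scaffold,
                     cb$start - 1L, cb$end), paths$callable_bed)

  cfg_json <- unclass(cfg)
  cfg_json$transmission_matrix <- lapply(cfg$transmission_matrix, function(m)
    as.data.frame(m))
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  truth <- list(sites = world$sites, dna_snps = world$dna,
                rna_records = world$rna, genes = world$genes,
                global = world$global)
  write_tsv_prov(world$sites, file.path(out_dir, "truth_sites.tsv"))
  write_tsv_prov(world$dna, file.path(out_dir, "truth_dna_snps.tsv"))
  write_tsv_prov(world$rna, file.path(out_dir, "truth_rna_records.tsv"))
  write_tsv_prov(world$genes, file.path(out_dir, "truth_genes.tsv"))
  jsonlite::write_json(world$global, file.path(out_dir, "truth_global.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(paths = paths, truth = truth, config = cfg)
}

write_min_vcf <- function(df, scaffold_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(scaffold_lengths),
                   unname(as.integer(scaffold_lengths))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSYNTH")
  body <- if (nrow(df)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                                df$scaffold, df$pos, df$ref, df$alt, df$gt)
  else character(0)
  writeLines(c(hdr, body), path)
}

## ---- lightweight in-memory simulators for power / type-I checks ----

#' Simulate per-gene variant densities under a modified/unmodified split
#'
#' The statistical core of the file generator without the file round-trip:
#' gene lengths uniform over \code{gene_length_range}, per-gene SNP counts
#' Binomial(length, rate) with the rate set by modification status, densities
#' = count / length.
#'
#' @param n_genes total genes.
#' @param rate_modified,rate_unmodified SNP rates per bp.
#' @param p_modified share of modified genes.
#' @param gene_length_range length range in bp.
#' @return list with numeric vectors \code{modified} and \code{unmodified}.
#' @export
simulate_variant_density_experiment <- function(n_genes = 2000,
                                                rate_modified = 0.00135,
                                                rate_unmodified = 0.0027,
                                                p_modified = 0.35,
                                                gene_length_range = c(800, 2500)) {
  len <- floor(runif(n_genes, gene_length_range[1], gene_length_range[2] + 1))
  mod <- runif(n_genes) < p_modified
  rate <- ifelse(mod, rate_modified, rate_unmodified)
  dens <- rbinom(n_genes, len, rate) / len
  list(modified = dens[mod], unmodified = dens[!mod])
}

#' Simulate the 6mA-density regression world
#'
#' Per-gene transmission-type counts are Poisson with realistic means (the
#' two 1/1-to-x types rare, as in the real data), and density
#' y = baseline + beta * x[type] + Gaussian noise.
#'
#' @param n_genes number of genes.
#' @param beta planted coefficient.
#' @param type the transmission type carrying the effect.
#' @param baseline intercept of the density.
#' @param noise_sd Gaussian noise standard deviation.
#' @param lambda named Poisson means for the six type counts.
#' @return list with \code{density} (named vector) and \code{type_counts}
#'   (matrix), ready for \code{\link{fit_density_regression}}.
#' @export
simulate_regression_experiment <- function(n_genes = 3000, beta = 5e-5,
                                           type = "0/1-1/1",
                                           baseline = 1e-3, noise_sd = 5e-4,
                                           lambda = c("0/1-0/0" = 1.5,
                                                      "0/1-0/1" = 3,
                                                      "0/1-1/1" = 1,
                                                      "1/1-0/0" = 0.05,
                                                      "1/1-0/1" = 0.1,
                                                      "1/1-1/1" = 0.5)) {
  stopifnot(type %in% TRANSMISSION_TYPES)
  X <- vapply(TRANSMISSION_TYPES, function(t)
    rpois(n_genes, lambda[[t]]), numeric(n_genes))
  gid <- sprintf("gene%05d", seq_len(n_genes))
  rownames(X) <- gid
  y <- baseline + beta * X[, type] + rnorm(n_genes, 0, noise_sd)
  list(density = setNames(y, gid), type_counts = X)
}
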