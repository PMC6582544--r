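## DNA-to-RNA genotype transmission: pairing DNA and RNA genotypes at shared
## loci and the 6-type transition classification.

#' The six DNA-to-RNA transmission type labels
#' @export
TRANSMISSION_TYPES <- c("0/1-0/0", "0/1-0/1", "0/1-1/1",
                        "1/1-0/0", "1/1-0/1", "1/1-1/1")

#' Classify a DNA-to-RNA genotype transition
#'
#' Total function on the 2 x 3 domain of DNA genotype (must be variant:
#' 0/1 or 1/1) by RNA genotype (0/0, 0/1 or 1/1). Vectorized.
#'
#' @param dna_gt,rna_gt genotype strings.
#' @return transmission type labels (see \code{TRANSMISSION_TYPES}).
#' @export
classify_transition <- function(dna_gt, rna_gt) {
  if (any(!dna_gt %in% c("0/1", "1/1")))
    stopf("RNA-only variants are not transmission events (dna_gt must be 0/1 or 1/1)")
  if (any(!rna_gt %in% c("0/0", "0/1", "1/1")))
    stopf("invalid RNA genotype")
  paste(dna_gt, rna_gt, sep = "-")
}

#' Pair DNA and RNA genotypes at DNA-variant sites
#'
#' For each DNA SNP: an RNA record at the same position with the same alt
#' allele supplies the RNA genotype; with no RNA record, positions inside a
#' declared callable region are imputed 0/0, others are excluded as RNA
#' unobservable. Same position with a different alt is excluded and counted.
#' RNA-variant positions without a DNA record are returned separately.
#'
#' @param dna_snps,rna_snps SNP tables from \code{\link{load_snps}}.
#' @param callable_regions optional data.frame scaffold, start, end (1-based
#'   inclusive; use \code{\link{read_callable_bed}} for BED input) where an
#'   absent RNA call means genotype 0/0.
#' @param gene_fallback when no callable regions are given, treat any
#'   position inside a gene carrying at least one RNA variant as callable
#'   (needs \code{index}); off by default.
#' @param index optional FeatureIndex; when given, joint sites are annotated
#'   with feature_class and gene_id.
#' @return list with elements \code{joint} (scaffold, pos, ref, alt, dna_gt,
#'   rna_gt, type, transmitted [+ feature_class, gene_id]), \code{rna_only},
#'   and \code{qc} exclusion counts.
#' @export
build_joint_table <- function(dna_snps, rna_snps, callable_regions = NULL,
                              gene_fallback = FALSE, index = NULL) {
  key <- function(df) paste(df$scaffold, df$pos)
  rk <- key(rna_snps)
  hit <- match(key(dna_snps), rk)
  has_rna <- !is.na(hit)
  alt_ok <- has_rna & rna_snps$alt[hit] == dna_snps$alt
  alt_mismatch <- has_rna & !alt_ok

  callable <- rep(FALSE, nrow(dna_snps))
  if (!is.null(callable_regions) && nrow(dna_snps)) {
    callable <- in_regions(dna_snps$scaffold, dna_snps$pos, callable_regions)
  } else if (gene_fallback) {
    if (is.null(index)) stopf("gene_fallback requires a FeatureIndex")
    rna_cl <- classify_positions(index, rna_snps$scaffold, rna_snps$pos)
    rna_genes <- unique(rna_cl$region_id[rna_cl$feature_class %in%
                                           c("exon", "intron")])
    dna_cl <- classify_positions(index, dna_snps$scaffold, dna_snps$pos)
    callable <- dna_cl$feature_class %in% c("exon", "intron") &
      dna_cl$region_id %in% rna_genes
  }

  keep_obs <- alt_ok
  keep_imp <- !has_rna & callable
  excluded_unobs <- !has_rna & !callable

  joint <- data.frame(
    scaffold = dna_snps$scaffold, pos = dna_snps$pos,
    ref = dna_snps$ref, alt = dna_snps$alt, dna_gt = dna_snps$gt,
    rna_gt = NA_character_, stringsAsFactors = FALSE)
  joint$rna_gt[keep_obs] <- rna_snps$gt[hit[keep_obs]]
  joint$rna_gt[keep_imp] <- "0/0"
  joint <- joint[keep_obs | keep_imp, , drop = FALSE]
  rownames(joint) <- NULL
  if (nrow(joint)) {
    joint$type <- classify_transition(joint$dna_gt, joint$rna_gt)
    joint$transmitted <- joint$rna_gt != "0/0"
  } else {
    joint$type <- character(0)
    joint$transmitted <- logical(0)
  }
  if (!is.null(index) && nrow(joint)) {
    cl <- classify_positions(index, joint$scaffold, joint$pos)
    joint$feature_class <- cl$feature_class
    joint$gene_id <- ifelse(cl$feature_class %in% c("exon", "intron"),
                            cl$region_id, NA_character_)
  }
  rna_only <- rna_snps[!key(rna_snps) %in% key(dna_snps), , drop = FALSE]
  rownames(rna_only) <- NULL
  list(joint = joint, rna_only = rna_only,
       qc = list(n_dna = nrow(dna_snps), n_rna = nrow(rna_snps),
                 n_paired = sum(alt_ok), n_imputed_homref = sum(keep_imp),
                 n_alt_mismatch = sum(alt_mismatch),
                 n_rna_unobservable = sum(excluded_unobs),
                 n_rna_only = nrow(rna_only)))
}

in_regions <- function(scaffold, pos, regions) {
  if (!length(pos)) return(logical(0))
  if (!nrow(regions)) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(regions$scaffold,
                              IRanges::IRanges(regions$start, regions$end))
  GenomicRanges::countOverlaps(q, s) > 0L
}

#' Read an RNA-callable region BED (0-based half-open) into 1-based intervals
#' @param path BED file.
#' @return data.frame scaffold, start, end (1-based inclusive).
#' @export
read_callable_bed <- function(path) {
  if (!file.exists(path)) stopf("no such BED: %s", path)
  lines <- grep("^[^#]", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(scaffold = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Transmitted subset of a joint table
#'
#' Sites whose RNA genotype is variant (not 0/0): the DNA-and-RNA overlap of
#' the Venn view.
#'
#' @param joint joint table from \code{\link{build_joint_table}}.
#' @return subset of rows with \code{transmitted == TRUE}.
#' @export
transmitted_set <- function(joint) {
  joint[joint$transmitted, , drop = FALSE]
}

#' Per-gene transmission-type count matrix
#'
#' Rows are all protein-coding genes of the index (genes with no joint sites
#' get zero rows); columns the six transmission types; intergenic and
#' pseudogene joint sites are excluded.
#'
#' @param joint joint table annotated with gene_id (build with an index).
#' @param index FeatureIndex.
#' @return integer matrix genes x 6 with dimnames.
#' @export
per_gene_type_counts <- function(joint, index) {
  genes <- index$genes$gene_id[index$genes$biotype == "gene"]
  m <- matrix(0L, nrow = length(genes), ncol = length(TRANSMISSION_TYPES),
              dimnames = list(genes, TRANSMISSION_TYPES))
  if (is.null(joint$gene_id)) stopf("joint table lacks gene_id annotation")
  j <- joint[!is.na(joint$gene_id) & joint$gene_id %in% genes, , drop = FALSE]
  if (nrow(j)) {
    tab <- table(factor(j$gene_id, levels = genes),
                 factor(j$type, levels = TRANSMISSION_TYPES))
    m[] <- as.integer(tab)
  }
  m
}
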