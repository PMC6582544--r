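## DNA / RNA variant loading, SNP filtering, genotype normalization,
## feature-class annotation, per-region variant densities and 6mA overlap.

#' Load SNPs from a single-sample VCF
#'
#' Keeps biallelic SNPs with a variant genotype: indels, multiallelic sites,
#' missing genotypes (\code{./.} or half calls) and \code{0/0} records are
#' dropped; phased separators are normalized (\code{1|0} becomes \code{0/1}).
#'
#' @param vcf_path VCF v4.x file (optionally bgzipped).
#' @param source "DNA" or "RNA" label carried on every record.
#' @return data.frame scaffold, pos, ref, alt, gt, source, stably sorted by
#'   (scaffold, pos); drop counts by reason in \code{attr(, "qc")}.
#' @export
load_snps <- function(vcf_path, source = c("DNA", "RNA")) {
  source <- match.arg(source)
  if (!file.exists(vcf_path)) stopf("no such VCF: %s", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  gt_field <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(gt_field))
    stopf("VCF %s has no GT FORMAT field", vcf_path)
  gt <- as.character(gt_field$GT[, 1])
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))

  ## drop reasons are counted exclusively, in priority order
  multi <- n_alt != 1L
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  gt_norm <- normalize_gt(gt)
  missing_gt <- !multi & !indel & is.na(gt_norm)
  homref <- !multi & !indel & !missing_gt & gt_norm == "0/0"
  nonacgt <- !multi & !indel & !missing_gt & !homref &
    (!ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T"))
  keep <- !multi & !indel & !missing_gt & !homref & !nonacgt
  if (any(nonacgt))
    warnf("%d record(s) with non-ACGT allele dropped from %s",
          sum(nonacgt), vcf_path)
  df <- data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = ref[keep], alt = alt[keep], gt = gt_norm[keep],
    source = rep(source, sum(keep)), stringsAsFactors = FALSE)
  df <- df[order(df$scaffold, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "qc") <- list(n_input = length(ref), n_multiallelic = sum(multi),
                         n_indel = sum(indel), n_missing_gt = sum(missing_gt),
                         n_homref = sum(homref), n_nonacgt = sum(nonacgt),
                         n_retained = nrow(df))
  df
}

## "1|0" -> "0/1"; half-missing or missing -> NA
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".") || anyNA(p)) return(NA_character_)
    if (!all(p %in% c("0", "1"))) return(NA_character_)
    paste(sort(p), collapse = "/")
  }, character(1))
}

#' Annotate SNPs with feature class and owning region
#'
#' Each SNP gets exactly one class (priority exon > intron > pseudogene >
#' intergenic) and the owning region id, via the FeatureIndex class map.
#'
#' @param snps SNP table from \code{\link{load_snps}}.
#' @param index FeatureIndex.
#' @return input with feature_class and region_id columns added.
#' @export
annotate_feature <- function(snps, index) {
  cl <- classify_positions(index, snps$scaffold, snps$pos)
  snps$feature_class <- cl$feature_class
  snps$region_id <- cl$region_id
  snps
}

#' Feature-class tally of annotated SNPs
#'
#' @param snps output of \code{\link{annotate_feature}}.
#' @return data.frame feature_class, n; classes always in canonical order,
#'   tallies summing to \code{nrow(snps)}.
#' @export
feature_tally <- function(snps) {
  n <- vapply(FEATURE_CLASSES, function(cl) sum(snps$feature_class == cl),
              integer(1))
  data.frame(feature_class = FEATURE_CLASSES, n = unname(n),
             stringsAsFactors = FALSE)
}

#' Variant density of a region
#'
#' Distinct SNP positions in the region divided by region length in bp
#' (mutation frequency, not a per-adenine rate).
#'
#' @param snps SNP table.
#' @param scaffold,start,end region (1-based inclusive).
#' @param region_id output label.
#' @return one-row data.frame region_id, n_variants, region_length, density.
#' @export
variant_density <- function(snps, scaffold, start, end,
                            region_id = NA_character_) {
  len <- end - start + 1L
  if (len <= 0L) stopf("region length must be positive")
  n <- length(unique(snps$pos[snps$scaffold == scaffold &
                                snps$pos >= start & snps$pos <= end]))
  data.frame(region_id = region_id, n_variants = n, region_length = len,
             density = n / len, stringsAsFactors = FALSE)
}

#' Per-gene (or per-scaffold) variant densities
#'
#' @param snps SNP table.
#' @param index FeatureIndex.
#' @param what "genes" or "scaffolds".
#' @return data.frame region_id, n_variants, region_length, density.
#' @export
variant_densities <- function(snps, index, what = c("genes", "scaffolds")) {
  what <- match.arg(what)
  regions <- if (what == "genes")
    data.frame(region_id = index$genes$gene_id, scaffold = index$genes$scaffold,
               start = index$genes$start, end = index$genes$end,
               stringsAsFactors = FALSE)
  else
    data.frame(region_id = names(index$scaffold_lengths),
               scaffold = names(index$scaffold_lengths), start = 1L,
               end = unname(as.integer(index$scaffold_lengths)),
               stringsAsFactors = FALSE)
  u <- unique(snps[, c("scaffold", "pos")])
  n <- count_in_regions(u$scaffold, u$pos, regions)
  len <- regions$end - regions$start + 1L
  data.frame(region_id = regions$region_id, n_variants = n,
             region_length = len, density = n / len, stringsAsFactors = FALSE)
}

#' Positions carrying both a 6mA site and a SNP
#'
#' Exact coincidence of (scaffold, pos); 6mA strand is ignored because SNP
#' records are strandless.
#'
#' @param snps SNP table.
#' @param sites 6mA site table.
#' @param index optional FeatureIndex for feature-class annotation.
#' @return data.frame scaffold, pos (one row per coincident position), plus
#'   feature_class/region_id when an index is supplied.
#' @export
overlap_with_sixma <- function(snps, sites, index = NULL) {
  a <- unique(paste(snps$scaffold, snps$pos))
  b <- unique(paste(sites$scaffold, sites$pos))
  common <- intersect(a, b)
  if (!length(common)) {
    out <- data.frame(scaffold = character(), pos = integer(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(common, " ", fixed = TRUE)
    out <- data.frame(scaffold = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)),
                      stringsAsFactors = FALSE)
    out <- out[order(out$scaffold, out$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(index) && nrow(out)) {
    cl <- classify_positions(index, out$scaffold, out$pos)
    out$feature_class <- cl$feature_class
    out$region_id <- cl$region_id
  }
  out
}
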