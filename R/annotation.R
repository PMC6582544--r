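## Annotation model: genome + gene models, intergenic derivation, exon groups,
## per-position feature classification and adenine denominators.

FEATURE_CLASSES <- c("exon", "intron", "pseudogene", "intergenic")

#' Construct a FeatureIndex from gene/exon tables
#'
#' The FeatureIndex is the package's central annotation container: gene models,
#' derived intergenic regions, and a disjoint per-position feature-class map
#' (priority exon > intron > pseudogene > intergenic).
#'
#' @param genes data.frame with columns gene_id, scaffold, start, end, strand,
#'   biotype ("gene" or "pseudogene"). Coordinates are 1-based inclusive.
#' @param exons data.frame with columns gene_id, scaffold, start, end
#'   (1-based inclusive); one row per exon of a protein-coding gene.
#' @param scaffold_lengths named integer vector of scaffold lengths in bp.
#' @param genome optional \code{Biostrings::DNAStringSet} of the scaffolds;
#'   required for adenine counting and flank extraction.
#' @return object of class \code{FeatureIndex}.
#' @export
feature_index <- function(genes, exons, scaffold_lengths, genome = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stopf("duplicated gene_id in annotation")
    bad <- genes$start > genes$end
    if (any(bad)) stopf("gene %s has start > end", genes$gene_id[which(bad)[1]])
    missing_sc <- setdiff(genes$scaffold, names(scaffold_lengths))
    if (length(missing_sc))
      stopf("gene scaffold(s) absent from genome: %s",
            paste(missing_sc, collapse = ", "))
  }
  if (nrow(exons)) {
    g <- genes[match(exons$gene_id, genes$gene_id), ]
    out <- exons$start < g$start | exons$end > g$end | is.na(g$start)
    if (any(out))
      stopf("exon outside gene span for gene_id %s", exons$gene_id[which(out)[1]])
    exons <- exons[order(exons$gene_id, exons$start), ]
    ## ordinal in coordinate order; transcription order is strand-resolved later
    exons$ordinal <- stats::ave(exons$start, exons$gene_id,
                                FUN = seq_along)
    exons$scaffold <- g$scaffold[match(exons$gene_id, exons$gene_id)] %||% exons$scaffold
    exons$strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  } else {
    exons <- data.frame(gene_id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        ordinal = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  genes$n_exons <- rep(0L, nrow(genes))
  if (nrow(exons)) {
    tab <- table(exons$gene_id)
    genes$n_exons <- as.integer(tab[genes$gene_id])
    genes$n_exons[is.na(genes$n_exons)] <- 0L
  }
  coding <- genes$biotype == "gene"
  if (any(coding & genes$n_exons == 0L))
    stopf("gene %s has no exons", genes$gene_id[which(coding & genes$n_exons == 0L)[1]])

  intergenic <- derive_intergenic(genes, scaffold_lengths)
  idx <- structure(list(genes = genes, exons = exons, intergenic = intergenic,
                        scaffold_lengths = scaffold_lengths, genome = genome),
                   class = "FeatureIndex")
  idx$class_map <- build_class_map(idx)
  idx
}

#' @export
print.FeatureIndex <- function(x, ...) {
  cat(sprintf("FeatureIndex: %d scaffolds (%s bp), %d genes (%d pseudogenes), %d intergenic regions\n",
              length(x$scaffold_lengths),
              format(sum(as.numeric(x$scaffold_lengths)), big.mark = ",",
                     scientific = FALSE),
              sum(x$genes$biotype == "gene"),
              sum(x$genes$biotype == "pseudogene"),
              nrow(x$intergenic)))
  invisible(x)
}

seqinfo_of <- function(scaffold_lengths) {
  GenomeInfoDb::Seqinfo(names(scaffold_lengths),
                        unname(as.integer(scaffold_lengths)))
}

df_granges <- function(df, scaffold_lengths) {
  GenomicRanges::GRanges(df$scaffold,
                         IRanges::IRanges(df$start, df$end),
                         seqinfo = seqinfo_of(scaffold_lengths))
}

## Disjoint class map with priority exon > intron > pseudogene > intergenic.
build_class_map <- function(idx) {
  sl <- idx$scaffold_lengths
  si <- seqinfo_of(sl)
  empty <- GenomicRanges::GRanges(seqinfo = si)
  coding <- idx$genes[idx$genes$biotype == "gene", , drop = FALSE]
  pseudo <- idx$genes[idx$genes$biotype == "pseudogene", , drop = FALSE]
  gr_ex <- if (nrow(idx$exons))
    GenomicRanges::reduce(df_granges(idx$exons, sl)) else empty
  gr_gene <- if (nrow(coding))
    GenomicRanges::reduce(df_granges(coding, sl)) else empty
  gr_intron <- GenomicRanges::setdiff(gr_gene, gr_ex)
  gr_pseudo <- if (nrow(pseudo))
    GenomicRanges::setdiff(GenomicRanges::reduce(df_granges(pseudo, sl)),
                           GenomicRanges::union(gr_gene, gr_ex))
    else empty
  covered <- GenomicRanges::reduce(c(gr_ex, gr_intron, gr_pseudo))
  gr_inter <- GenomicRanges::gaps(covered)
  gr_inter <- gr_inter[BiocGenerics::strand(gr_inter) == "*"]
  cls <- c(rep("exon", length(gr_ex)), rep("intron", length(gr_intron)),
           rep("pseudogene", length(gr_pseudo)),
           rep("intergenic", length(gr_inter)))
  gr <- c(gr_ex, gr_intron, gr_pseudo, gr_inter)
  S4Vectors::mcols(gr)$class <- cls
  gr
}

#' Classify genomic positions by feature class
#'
#' Maps each (scaffold, pos) to exactly one of exon, intron, pseudogene or
#' intergenic (priority exon > intron > pseudogene > intergenic) plus the
#' owning region id (gene_id, pseudogene id, or intergenic region id).
#'
#' @param index a FeatureIndex.
#' @param scaffold,pos character / integer vectors of equal length.
#' @return data.frame with columns scaffold, pos, feature_class, region_id.
#' @export
classify_positions <- function(index, scaffold, pos) {
  stopifnot(inherits(index, "FeatureIndex"), length(scaffold) == length(pos))
  if (!length(pos))
    return(data.frame(scaffold = character(), pos = integer(),
                      feature_class = character(), region_id = character(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(scaffold), names(index$scaffold_lengths))
  if (length(unknown))
    stopf("position(s) on unknown scaffold: %s", paste(unknown, collapse = ", "))
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, pos),
                              seqinfo = seqinfo_of(index$scaffold_lengths))
  hit <- GenomicRanges::findOverlaps(q, index$class_map, select = "first")
  cls <- S4Vectors::mcols(index$class_map)$class[hit]
  rid <- rep(NA_character_, length(pos))

  assign_owner <- function(sel, regions) {
    if (!any(sel) || !nrow(regions)) return()
    rg <- df_granges(regions, index$scaffold_lengths)
    ## deterministic owner for overlapping regions: lowest start, then id
    ord <- order(regions$start, regions[[1]])
    h <- GenomicRanges::findOverlaps(q[sel], rg[ord], select = "first")
    rid[sel] <<- regions[[1]][ord][h]
  }
  assign_owner(cls %in% c("exon", "intron"),
               index$genes[index$genes$biotype == "gene",
                           c("gene_id", "scaffold", "start", "end")])
  assign_owner(cls == "pseudogene",
               index$genes[index$genes$biotype == "pseudogene",
                           c("gene_id", "scaffold", "start", "end")])
  assign_owner(cls == "intergenic",
               index$intergenic[, c("region_id", "scaffold", "start", "end")])
  data.frame(scaffold = scaffold, pos = as.integer(pos), feature_class = cls,
             region_id = rid, stringsAsFactors = FALSE)
}

#' Derive intergenic regions as the complement of gene spans
#'
#' Overlapping gene spans are merged before taking the complement. Each region
#' records the adjacent downstream gene per strand: a region is upstream of a
#' plus-strand gene starting at \code{end + 1} and of a minus-strand gene
#' ending at \code{start - 1} (a region between two divergently transcribed
#' genes is upstream of both).
#'
#' @param genes gene table (as in \code{\link{feature_index}}).
#' @param scaffold_lengths named integer vector.
#' @return data.frame with columns region_id, scaffold, start, end,
#'   downstream_gene_plus, downstream_gene_minus.
#' @export
derive_intergenic <- function(genes, scaffold_lengths) {
  rows <- list()
  coding <- genes[genes$biotype == "gene", , drop = FALSE]
  for (sc in names(scaffold_lengths)) {
    L <- as.integer(scaffold_lengths[[sc]])
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (!nrow(g)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, start = 1L, end = L, stringsAsFactors = FALSE)
      next
    }
    raw <- IRanges::IRanges(g$start, g$end)
    ir <- IRanges::reduce(raw)
    ## reduce() also fuses abutting spans; warn only on true overlap
    if (sum(IRanges::width(ir)) < sum(IRanges::width(raw)))
      warnf("overlapping gene spans on %s merged for intergenic derivation", sc)
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (length(gaps))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, start = IRanges::start(gaps), end = IRanges::end(gaps),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    inter <- data.frame(scaffold = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  } else inter <- do.call(rbind, rows)
  inter <- inter[order(inter$scaffold, inter$start), , drop = FALSE]
  n <- nrow(inter)
  inter$region_id <- if (n) sprintf("intergenic_%04d", seq_len(n)) else character()
  ## strand-aware downstream gene: 5' side of the abutting gene
  key_plus <- paste(coding$scaffold[coding$strand == "+"],
                    coding$start[coding$strand == "+"])
  id_plus <- coding$gene_id[coding$strand == "+"]
  key_minus <- paste(coding$scaffold[coding$strand == "-"],
                     coding$end[coding$strand == "-"])
  id_minus <- coding$gene_id[coding$strand == "-"]
  inter$downstream_gene_plus <-
    id_plus[match(paste(inter$scaffold, inter$end + 1L), key_plus)]
  inter$downstream_gene_minus <-
    id_minus[match(paste(inter$scaffold, inter$start - 1L), key_minus)]
  inter[, c("region_id", "scaffold", "start", "end",
            "downstream_gene_plus", "downstream_gene_minus")]
}

#' Load genome and annotation into a FeatureIndex
#'
#' Reads a FASTA genome and a GFF3 with gene / pseudogene / exon features.
#' Exon \code{Parent} attributes may point at the gene directly or at an mRNA
#' whose Parent is the gene.
#'
#' @param gff3_path path to GFF3 annotation.
#' @param fasta_path path to genome FASTA (optionally gzipped).
#' @return a \code{\link{feature_index}}.
#' @export
load_annotation <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stopf("no such GFF3 file: %s", gff3_path)
  if (!file.exists(fasta_path)) stopf("no such FASTA file: %s", fasta_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  sl <- setNames(Biostrings::width(genome), names(genome))

  validate_gff3_lines(gff3_path)
  gr <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                 error = function(e) stopf("GFF3 parse error in %s: %s",
                                           gff3_path, conditionMessage(e)))
  typ <- as.character(gr$type)
  is_gene <- typ %in% c("gene")
  is_pseudo <- typ %in% c("pseudogene")
  biotype <- if (!is.null(gr$biotype)) as.character(gr$biotype) else
    if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype) else
      rep(NA_character_, length(gr))
  is_pseudo <- is_pseudo | (is_gene & !is.na(biotype) & biotype == "pseudogene")
  is_gene <- is_gene & !is_pseudo
  gsel <- is_gene | is_pseudo
  ids <- as.character(gr$ID)
  genes <- data.frame(
    gene_id = ids[gsel],
    scaffold = as.character(GenomeInfoDb::seqnames(gr))[gsel],
    start = BiocGenerics::start(gr)[gsel],
    end = BiocGenerics::end(gr)[gsel],
    strand = as.character(BiocGenerics::strand(gr))[gsel],
    biotype = ifelse(is_pseudo[gsel], "pseudogene", "gene"),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  ## resolve exon -> gene through an optional transcript layer
  parent_of <- setNames(
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    ids)
  ex <- typ == "exon"
  exon_parent <- vapply(gr$Parent[ex],
                        function(p) if (length(p)) p[[1]] else NA_character_,
                        character(1))
  to_gene <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% genes$gene_id) return(p)
    pp <- parent_of[p]
    if (!is.na(pp) && pp %in% genes$gene_id) return(unname(pp))
    NA_character_
  }
  exon_gene <- vapply(exon_parent, to_gene, character(1))
  if (any(ex) && anyNA(exon_gene))
    stopf("exon with unresolvable Parent in %s", gff3_path)
  exons <- data.frame(
    gene_id = exon_gene,
    scaffold = as.character(GenomeInfoDb::seqnames(gr))[ex],
    start = BiocGenerics::start(gr)[ex],
    end = BiocGenerics::end(gr)[ex],
    stringsAsFactors = FALSE)
  feature_index(genes, exons, sl, genome = genome)
}

## cheap structural validation so parse errors can name the offending line
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_fasta <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##FASTA")) in_fasta <- TRUE
    if (in_fasta || ln == "" || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L)
      stopf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
            i, path)
  }
  invisible(TRUE)
}

#' Exon group (start / middle / end) in transcription order
#'
#' The first exon of a gene (5'-most in transcription order) is \code{start},
#' the last is \code{end}, all others \code{middle}. Single-exon genes are
#' labelled \code{start}; two-exon genes yield \code{start}, \code{end}.
#'
#' @param n_exons number of exons of the gene.
#' @param exon_ordinal ordinal in transcription order (1-based, strand-aware).
#' @return one of \code{"start"}, \code{"middle"}, \code{"end"} (vectorized).
#' @export
assign_exon_group <- function(n_exons, exon_ordinal) {
  if (any(exon_ordinal < 1L | exon_ordinal > n_exons))
    stopf("exon ordinal out of range")
  ifelse(exon_ordinal == 1L, "start",
         ifelse(exon_ordinal == n_exons, "end", "middle"))
}

#' Per-exon table with transcription-order ordinals and groups
#'
#' @param index a FeatureIndex.
#' @param drop_single_exon drop single-exon genes from the table (for
#'   Fig-1a-style summaries); default FALSE.
#' @return exon data.frame with columns ordinal_tx and exon_group added.
#' @export
exon_groups <- function(index, drop_single_exon = FALSE) {
  ex <- index$exons
  if (!nrow(ex)) return(cbind(ex, ordinal_tx = integer(), exon_group = character()))
  n <- index$genes$n_exons[match(ex$gene_id, index$genes$gene_id)]
  ex$ordinal_tx <- ifelse(ex$strand == "-", n - ex$ordinal + 1L, ex$ordinal)
  ex$exon_group <- assign_exon_group(n, ex$ordinal_tx)
  if (drop_single_exon) ex <- ex[n > 1L, , drop = FALSE]
  ex
}

#' Count adenines in a region
#'
#' Denominator of the 6mA/A density. \code{strand_mode = "both"} counts A and
#' T on the forward reference (adenines on either strand); \code{"forward"}
#' counts A only. N is never counted.
#'
#' @param genome DNAStringSet.
#' @param scaffold,start,end region (1-based inclusive); vectorized.
#' @param strand_mode "both" or "forward".
#' @return integer vector of adenine counts.
#' @export
count_adenines <- function(genome, scaffold, start, end,
                           strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  n <- length(scaffold)
  stopifnot(length(start) == n, length(end) == n)
  out <- integer(n)
  for (sc in unique(scaffold)) {
    i <- which(scaffold == sc)
    if (!sc %in% names(genome)) stopf("unknown scaffold: %s", sc)
    L <- length(genome[[sc]])
    if (any(start[i] < 1L | end[i] > L | start[i] > end[i]))
      stopf("region outside scaffold bounds on %s", sc)
    v <- Biostrings::Views(genome[[sc]], start = start[i], end = end[i])
    letters <- if (strand_mode == "both") c("A", "T") else "A"
    f <- Biostrings::letterFrequency(v, letters)
    out[i] <- as.integer(rowSums(f))
  }
  out
}

#' Upstream intergenic region of a gene
#'
#' Strand-aware: for a plus-strand gene the intergenic region ending at
#' \code{start - 1}; for a minus-strand gene the region starting at
#' \code{end + 1}. Returns NULL when the gene directly abuts another gene or
#' the scaffold edge.
#'
#' @param index a FeatureIndex.
#' @param gene_id gene identifier.
#' @return one-row intergenic data.frame, or NULL.
#' @export
upstream_intergenic_of <- function(index, gene_id) {
  g <- index$genes[index$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stopf("unknown gene_id: %s", gene_id)
  it <- index$intergenic
  hit <- if (g$strand == "+")
    which(it$scaffold == g$scaffold & it$end == g$start - 1L)
  else
    which(it$scaffold == g$scaffold & it$start == g$end + 1L)
  if (!length(hit)) return(NULL)
  it[hit[1], , drop = FALSE]
}

#' Relative-position (metagene) density profile of one region
#'
#' Positions are mapped to bin \code{floor(n_bins * (pos - start) / len)};
#' for minus-strand regions bins are flipped so bin 1 is the 5' end. Each
#' bin's value is marked-adenine count divided by its adenine count.
#'
#' @param positions integer vector of marked positions within the region.
#' @param scaffold,start,end,strand the region; strand "." treated as "+".
#' @param genome DNAStringSet.
#' @param n_bins number of bins (default 100).
#' @param strand_mode adenine denominator mode, see \code{\link{count_adenines}}.
#' @return data.frame bin, n_sites, n_adenines, density, empty_bin.
#' @export
relative_position_profile <- function(positions, scaffold, start, end,
                                      strand = "+", genome, n_bins = 100,
                                      strand_mode = "both") {
  len <- end - start + 1L
  if (n_bins < 1L) stopf("n_bins must be >= 1")
  if (len < n_bins)
    stopf("region length %d < n_bins %d; use fewer bins", len, n_bins)
  if (length(positions) && any(positions < start | positions > end))
    stopf("positions outside region")
  bin_of <- function(p) floor(n_bins * (p - start) / len)
  counts <- tabulate(bin_of(positions) + 1L, nbins = n_bins)
  ## adenines per bin
  offs <- 0:(len - 1L)
  b <- floor(n_bins * offs / len)
  chars <- strsplit(as.character(Biostrings::subseq(genome[[scaffold]],
                                                    start, end)), "")[[1]]
  isA <- if (strand_mode == "both") chars %in% c("A", "T") else chars == "A"
  aden <- vapply(0:(n_bins - 1L), function(k) sum(isA[b == k]), integer(1))
  if (identical(strand, "-")) {
    counts <- rev(counts)
    aden <- rev(aden)
  }
  data.frame(bin = seq_len(n_bins), n_sites = counts, n_adenines = aden,
             density = ifelse(aden > 0, counts / aden, 0),
             empty_bin = aden == 0L)
}

#' Aggregate metagene profile over many regions
#'
#' Sums per-bin marked-adenine and adenine counts across all regions of a
#' class, then forms per-bin densities.
#'
#' @param sites 6mA site table (see \code{\link{load_sixma}}).
#' @param regions data.frame with scaffold, start, end, strand.
#' @param genome DNAStringSet.
#' @param n_bins number of bins.
#' @param strand_mode adenine denominator mode.
#' @return data.frame bin, n_sites, n_adenines, density.
#' @export
metagene_profile <- function(sites, regions, genome, n_bins = 100,
                             strand_mode = "both") {
  tot_sites <- integer(n_bins)
  tot_aden <- integer(n_bins)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$end - r$start + 1L < n_bins) next
    pos <- sites$pos[sites$scaffold == r$scaffold &
                       sites$pos >= r$start & sites$pos <= r$end]
    p <- relative_position_profile(pos, r$scaffold, r$start, r$end,
                                   strand = r$strand %||% "+",
                                   genome = genome, n_bins = n_bins,
                                   strand_mode = strand_mode)
    tot_sites <- tot_sites + p$n_sites
    tot_aden <- tot_aden + p$n_adenines
  }
  data.frame(bin = seq_len(n_bins), n_sites = tot_sites, n_adenines = tot_aden,
             density = ifelse(tot_aden > 0, tot_sites / tot_aden, 0))
}
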