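## 6mA site ingestion, the coverage filter, 6mA/A densities, flank extraction
## and IUPAC motif coverage.

## IUPAC degeneracy sets. A window 'N' (ambiguous reference base) matches
## only a pattern 'N' so ambiguity never inflates motif coverage.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Load 6mA site calls and apply the coverage filter
#'
#' Accepts ipdSummary-style modification GFF (one record per methylated base,
#' single-bp features with a \code{coverage=} attribute) or BED6 with the
#' coverage in the score column. Sites with coverage strictly greater than
#' \code{min_coverage} are retained, reading the "more than 25-fold" rule
#' literally.
#'
#' @param path GFF or BED file of 6mA calls.
#' @param min_coverage coverage threshold; retained iff coverage > threshold.
#' @param genome optional DNAStringSet; when given, records whose reference
#'   base is not A (+ strand) / T (- strand) are dropped with a warning and
#'   counted in the QC attribute.
#' @param format "auto" (by extension), "gff" or "bed".
#' @return data.frame id, scaffold, pos, strand, coverage, sorted by
#'   (scaffold, pos, strand); QC counts in \code{attr(, "qc")}.
#' @export
load_sixma <- function(path, min_coverage = 25, genome = NULL,
                       format = c("auto", "gff", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such 6mA file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff"
  n_lines <- length(grep("^[^#]", readLines(path, warn = FALSE), value = TRUE))
  if (n_lines == 0L) {
    out <- data.frame(id = character(), scaffold = character(),
                      pos = integer(), strand = character(),
                      coverage = integer(), stringsAsFactors = FALSE)
    attr(out, "qc") <- list(n_input = 0L, n_low_coverage = 0L, n_bad_base = 0L)
    return(out)
  }
  if (format == "gff") {
    gr <- rtracklayer::import(path, format = "gff")
    cov <- S4Vectors::mcols(gr)$coverage
    if (is.null(cov)) stopf("6mA GFF %s has no coverage attribute", path)
    cov <- as.integer(as.character(cov))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    cov <- as.integer(S4Vectors::mcols(gr)$score)
    if (is.null(cov)) stopf("6mA BED %s has no score/coverage column", path)
  }
  df <- data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(gr)),
    pos = BiocGenerics::start(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    coverage = cov, stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  n_input <- nrow(df)
  keep <- df$coverage > min_coverage
  n_low <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n_bad <- 0L
  if (!is.null(genome) && nrow(df)) {
    base <- ref_base_at(genome, df$scaffold, df$pos)
    ok <- (df$strand == "+" & base == "A") | (df$strand == "-" & base == "T")
    n_bad <- sum(!ok)
    if (n_bad)
      warnf("%d 6mA record(s) with non-adenine reference base dropped", n_bad)
    df <- df[ok, , drop = FALSE]
  }
  df <- df[order(df$scaffold, df$pos, df$strand), , drop = FALSE]
  df <- data.frame(id = sprintf("%s:%d:%s", df$scaffold, df$pos, df$strand),
                   df, stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "qc") <- list(n_input = n_input, n_low_coverage = n_low,
                         n_bad_base = n_bad)
  df
}

ref_base_at <- function(genome, scaffold, pos) {
  out <- character(length(pos))
  for (sc in unique(scaffold)) {
    i <- which(scaffold == sc)
    out[i] <- as.character(Biostrings::extractAt(
      genome[[sc]], IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

#' 6mA/A density of a region
#'
#' Number of retained 6mA sites in the region divided by the region's adenine
#' count (\code{\link{count_adenines}}).
#'
#' @param sites 6mA site table.
#' @param scaffold,start,end the region (1-based inclusive).
#' @param genome DNAStringSet.
#' @param strand_mode adenine denominator mode.
#' @param region_id label for the output row.
#' @return one-row data.frame region_id, n_sites, n_adenines, density,
#'   zero_adenines.
#' @export
region_density <- function(sites, scaffold, start, end, genome,
                           strand_mode = "both", region_id = NA_character_) {
  n_sites <- sum(sites$scaffold == scaffold & sites$pos >= start &
                   sites$pos <= end)
  n_aden <- count_adenines(genome, scaffold, start, end, strand_mode)
  data.frame(region_id = region_id, n_sites = n_sites, n_adenines = n_aden,
             density = if (n_aden > 0) n_sites / n_aden else 0,
             zero_adenines = n_aden == 0L, stringsAsFactors = FALSE)
}

## vectorized site counting over a region table (scaffold,start,end)
count_in_regions <- function(scaffold, pos, regions) {
  if (!length(pos)) return(integer(nrow(regions)))
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(regions$scaffold,
                              IRanges::IRanges(regions$start, regions$end))
  GenomicRanges::countOverlaps(s, q)
}

#' Per-gene (or per-region) 6mA densities
#'
#' @param sites 6mA site table.
#' @param index FeatureIndex (must carry a genome).
#' @param what "genes", "intergenic" or "scaffolds".
#' @param strand_mode adenine denominator mode.
#' @return data.frame region_id, n_sites, n_adenines, density.
#' @export
sixma_densities <- function(sites, index, what = c("genes", "intergenic",
                                                   "scaffolds"),
                            strand_mode = "both") {
  what <- match.arg(what)
  if (is.null(index$genome)) stopf("FeatureIndex carries no genome sequence")
  regions <- switch(what,
    genes = data.frame(region_id = index$genes$gene_id,
                       scaffold = index$genes$scaffold,
                       start = index$genes$start, end = index$genes$end,
                       stringsAsFactors = FALSE),
    intergenic = data.frame(region_id = index$intergenic$region_id,
                            scaffold = index$intergenic$scaffold,
                            start = index$intergenic$start,
                            end = index$intergenic$end,
                            stringsAsFactors = FALSE),
    scaffolds = data.frame(region_id = names(index$scaffold_lengths),
                           scaffold = names(index$scaffold_lengths),
                           start = 1L,
                           end = unname(as.integer(index$scaffold_lengths)),
                           stringsAsFactors = FALSE))
  n_sites <- count_in_regions(sites$scaffold, sites$pos, regions)
  n_aden <- count_adenines(index$genome, regions$scaffold, regions$start,
                           regions$end, strand_mode)
  data.frame(region_id = regions$region_id, n_sites = n_sites,
             n_adenines = n_aden,
             density = ifelse(n_aden > 0, n_sites / n_aden, 0),
             stringsAsFactors = FALSE)
}

#' Extract flanking sequence around 6mA sites
#'
#' Returns the window \code{[pos - k, pos + k]}; minus-strand sites are
#' reverse-complemented so the center character is always A. Windows are
#' truncated at scaffold edges with the true center index reported.
#'
#' @param sites 6mA site table.
#' @param genome DNAStringSet.
#' @param k flank width on each side (default 20).
#' @return data.frame id, flank, center (1-based index of the methylated A in
#'   \code{flank}), left_trunc, right_trunc.
#' @export
extract_flanks <- function(sites, genome, k = 20) {
  stopifnot(k >= 0)
  n <- nrow(sites)
  flank <- character(n); center <- integer(n)
  ltr <- integer(n); rtr <- integer(n)
  for (sc in unique(sites$scaffold)) {
    i <- which(sites$scaffold == sc)
    L <- length(genome[[sc]])
    pos <- sites$pos[i]
    if (any(pos < 1L | pos > L)) stopf("6mA position off scaffold %s", sc)
    s <- pmax(1L, pos - k); e <- pmin(L, pos + k)
    seqs <- as.character(Biostrings::extractAt(
      genome[[sc]], IRanges::IRanges(s, e)))
    ctr <- pos - s + 1L
    minus <- sites$strand[i] == "-"
    if (any(minus)) {
      seqs[minus] <- revcomp_chr(seqs[minus])
      ctr[minus] <- (e - s + 1L)[minus] - ctr[minus] + 1L
    }
    flank[i] <- seqs; center[i] <- ctr
    ## upstream/downstream lengths in the *returned* (strand-oriented) string
    ltr[i] <- ctr - 1L
    rtr[i] <- (e - s + 1L) - ctr
  }
  data.frame(id = sites$id, flank = flank, center = center,
             left_len = ltr, right_len = rtr,
             left_trunc = ltr < k, right_trunc = rtr < k,
             stringsAsFactors = FALSE)
}

#' Match a window against an IUPAC degenerate pattern
#'
#' True iff every window character lies in the degeneracy set of the
#' corresponding pattern character. A window 'N' matches only a pattern 'N'.
#' Vectorized elementwise over pattern/window pairs of equal lengths.
#'
#' @param pattern,window uppercase strings of equal length.
#' @return logical vector.
#' @export
iupac_match <- function(pattern, window) {
  stopifnot(length(pattern) == length(window))
  vapply(seq_along(pattern), function(i) {
    p <- strsplit(pattern[i], "")[[1]]
    w <- strsplit(window[i], "")[[1]]
    if (length(p) != length(w))
      stopf("pattern and window lengths differ (%d vs %d)",
            length(p), length(w))
    unknown <- setdiff(unique(c(p, w)), c(names(IUPAC_SETS)))
    if (length(unknown))
      stopf("unknown IUPAC code(s): %s", paste(unknown, collapse = ", "))
    all(ifelse(w == "N", p == "N",
               mapply(function(pc, wc) wc %in% IUPAC_SETS[[pc]], p, w)))
  }, logical(1))
}

#' IUPAC motif coverage of 6mA sites
#'
#' A site is covered by a pattern when a placement of the pattern inside the
#' site's flank matches. In \code{anchored} mode (default) the single
#' placement aligning the pattern's obligate A (\code{anchor_offset}) to the
#' methylated center is tested; in unanchored mode any placement counts.
#'
#' @param sites 6mA site table.
#' @param patterns data.frame with columns pattern and anchor_offset
#'   (1-based index of the obligate A within the pattern).
#' @param genome DNAStringSet.
#' @param k flank width (must be >= max pattern length for anchored matching
#'   away from edges).
#' @param anchored anchored-at-center (TRUE) or anywhere-in-flank matching.
#' @return list with \code{per_pattern} (data.frame pattern, n_covered),
#'   \code{union} (count of sites covered by at least one pattern) and
#'   \code{covered} (logical site x pattern matrix).
#' @export
motif_coverage <- function(sites, patterns, genome, k = 20, anchored = TRUE) {
  patterns <- as.data.frame(patterns, stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (!nrow(patterns))
    return(list(per_pattern = data.frame(pattern = character(),
                                         n_covered = integer()),
                union = 0L,
                covered = matrix(FALSE, n, 0)))
  for (j in seq_len(nrow(patterns))) {
    pc <- strsplit(patterns$pattern[j], "")[[1]]
    a <- patterns$anchor_offset[j]
    if (a < 1L || a > length(pc) || !("A" %in% IUPAC_SETS[[pc[a]]]))
      stopf("pattern %s: anchor_offset %d is not an A-compatible position",
            patterns$pattern[j], a)
  }
  fl <- if (n) extract_flanks(sites, genome, k) else
    data.frame(flank = character(), center = integer())
  covered <- matrix(FALSE, n, nrow(patterns),
                    dimnames = list(NULL, patterns$pattern))
  for (j in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[j]
    L <- nchar(pat)
    a <- patterns$anchor_offset[j]
    for (i in seq_len(n)) {
      f <- fl$flank[i]; c0 <- fl$center[i]; lf <- nchar(f)
      if (anchored) {
        s <- c0 - a + 1L
        if (s >= 1L && s + L - 1L <= lf)
          covered[i, j] <- iupac_match(pat, substr(f, s, s + L - 1L))
      } else {
        for (s in seq_len(lf - L + 1L)) {
          if (iupac_match(pat, substr(f, s, s + L - 1L))) {
            covered[i, j] <- TRUE
            break
          }
        }
      }
    }
  }
  list(per_pattern = data.frame(pattern = patterns$pattern,
                                n_covered = colSums(covered),
                                row.names = NULL,
                                stringsAsFactors = FALSE),
       union = sum(rowSums(covered) > 0L),
       covered = covered)
}
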