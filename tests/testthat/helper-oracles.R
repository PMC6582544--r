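## Independent brute-force oracles. These deliberately share no code with the
## package internals: per-position scans, quadratic joins, and a separate
## IUPAC degeneracy representation.

## O(1) per-position classifier by direct interval membership
oracle_classify_pos <- function(genes, exons, scaffold, pos) {
  coding <- genes[genes$biotype == "gene", , drop = FALSE]
  pseudo <- genes[genes$biotype == "pseudogene", , drop = FALSE]
  in_any <- function(df) {
    nrow(df) > 0 && any(df$scaffold == scaffold & df$start <= pos &
                          df$end >= pos)
  }
  ex <- exons
  ex$scaffold <- genes$scaffold[match(ex$gene_id, genes$gene_id)]
  ex <- ex[genes$biotype[match(ex$gene_id, genes$gene_id)] == "gene", ,
           drop = FALSE]
  if (in_any(ex)) return("exon")
  if (in_any(coding)) return("intron")
  if (in_any(pseudo)) return("pseudogene")
  "intergenic"
}

## complement of (merged) spans over [1, L] by a literal boolean scan
oracle_complement <- function(starts, ends, L) {
  covered <- rep(FALSE, L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  stop_at <- cumsum(r$lengths)
  start_at <- c(1L, head(stop_at, -1) + 1L)
  data.frame(start = start_at[!r$values], end = stop_at[!r$values])
}

## quadratic all-pairs position intersection
oracle_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a$scaffold[i] == b$scaffold[j] && a$pos[i] == b$pos[j])
        out[[length(out) + 1L]] <- data.frame(scaffold = a$scaffold[i],
                                              pos = a$pos[i])
  if (!length(out)) return(data.frame(scaffold = character(), pos = integer()))
  unique(do.call(rbind, out))
}

## independent IUPAC representation: degeneracy sets as strings
ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_iupac_match <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  if (length(p) != length(w)) stop("length mismatch")
  all(vapply(seq_along(p), function(i) {
    if (w[i] == "N") return(p[i] == "N")
    grepl(w[i], ORACLE_IUPAC[[p[i]]], fixed = TRUE)
  }, logical(1)))
}

oracle_count_adenines <- function(seq_chr, start, end, mode = "both") {
  chars <- strsplit(substr(seq_chr, start, end), "")[[1]]
  if (mode == "both") sum(chars == "A") + sum(chars == "T") else
    sum(chars == "A")
}

## literal nested-loop DNA/RNA genotype pairing (callable = list of intervals)
oracle_joint <- function(dna, rna, callable) {
  rows <- list()
  for (i in seq_len(nrow(dna))) {
    rna_gt <- NA_character_
    found <- FALSE
    for (j in seq_len(nrow(rna))) {
      if (dna$scaffold[i] == rna$scaffold[j] && dna$pos[i] == rna$pos[j]) {
        found <- TRUE
        if (dna$alt[i] == rna$alt[j]) rna_gt <- rna$gt[j]
        break
      }
    }
    if (!found) {
      callable_here <- FALSE
      for (k in seq_len(nrow(callable)))
        if (callable$scaffold[k] == dna$scaffold[i] &&
            callable$start[k] <= dna$pos[i] && callable$end[k] >= dna$pos[i]) {
          callable_here <- TRUE
          break
        }
      if (callable_here) rna_gt <- "0/0"
    }
    if (!is.na(rna_gt))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = dna$scaffold[i], pos = dna$pos[i], dna_gt = dna$gt[i],
        rna_gt = rna_gt, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(scaffold = character(), pos = integer(),
                      dna_gt = character(), rna_gt = character()))
  do.call(rbind, rows)
}

## random gene/exon layout on one scaffold for classification oracles
random_layout <- function(L = 10000L, n_genes = 5L, p_pseudo = 0.2) {
  cursor <- 1L
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    gap <- sample(50:300, 1)
    len <- sample(300:1200, 1)
    start <- cursor + gap
    end <- start + len - 1L
    if (end > L - 50L) break
    gid <- sprintf("g%02d", i)
    biotype <- if (runif(1) < p_pseudo) "pseudogene" else "gene"
    genes[[i]] <- data.frame(gene_id = gid, scaffold = "s1", start = start,
                             end = end, strand = sample(c("+", "-"), 1),
                             biotype = biotype, stringsAsFactors = FALSE)
    if (biotype == "gene") {
      n_ex <- sample(1:3, 1)
      bounds <- sort(sample(start:end, 2 * n_ex))
      exons[[gid]] <- data.frame(
        gene_id = gid,
        start = bounds[seq(1, 2 * n_ex, 2)],
        end = bounds[seq(2, 2 * n_ex, 2)], stringsAsFactors = FALSE)
      ## exon 1 must reach gene bounds? not required; but ensure non-overlap
    }
    cursor <- end + 1L
  }
  list(genes = do.call(rbind, genes),
       exons = do.call(rbind, c(exons, list(make.row.names = FALSE))))
}
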