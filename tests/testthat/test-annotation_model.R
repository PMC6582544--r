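test_that("load_annotation builds the index from GFF3 + FASTA", {
  fa <- write_mini_fasta(c(s1 = paste(rep("ACGT", 250), collapse = "")))
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "s1\tx\tgene\t101\t400\t.\t+\t.\tID=geneA;biotype=gene",
    "s1\tx\texon\t101\t200\t.\t+\t.\tParent=geneA",
    "s1\tx\texon\t301\t400\t.\t+\t.\tParent=geneA"), ".gff3")
  idx <- load_annotation(gff, fa)
  expect_equal(nrow(idx$genes), 1L)
  expect_equal(idx$genes$n_exons, 2L)
  expect_equal(nrow(idx$intergenic), 2L)  # the two flanks
  expect_equal(idx$intergenic$start, c(1L, 401L))
  expect_equal(idx$intergenic$end, c(100L, 1000L))
  ## intron between the exons
  cl <- classify_positions(idx, rep("s1", 4), c(150L, 250L, 500L, 350L))
  expect_equal(cl$feature_class, c("exon", "intron", "intergenic", "exon"))
  expect_equal(cl$region_id[1:2], c("geneA", "geneA"))
})

test_that("empty GFF3 yields one intergenic region per scaffold", {
  fa <- write_mini_fasta(c(s1 = strrep("ACGT", 50)))
  gff <- write_lines_tmp("##gff-version 3", ".gff3")
  idx <- load_annotation(gff, fa)
  expect_equal(nrow(idx$genes), 0L)
  expect_equal(nrow(idx$intergenic), 1L)
  expect_equal(idx$intergenic$start, 1L)
  expect_equal(idx$intergenic$end, 200L)
})

test_that("annotation validation errors are informative", {
  fa <- write_mini_fasta(c(s1 = strrep("ACGT", 250)))
  bad_line <- write_lines_tmp(c("##gff-version 3",
                                "s1\tx\tgene\t10\t20"), ".gff3")
  expect_error(load_annotation(bad_line, fa), "line 2")
  bad_exon <- write_lines_tmp(c(
    "##gff-version 3",
    "s1\tx\tgene\t101\t200\t.\t+\t.\tID=geneB;biotype=gene",
    "s1\tx\texon\t101\t300\t.\t+\t.\tParent=geneB"), ".gff3")
  expect_error(load_annotation(bad_exon, fa), "geneB")
  bad_scaffold <- write_lines_tmp(c(
    "##gff-version 3",
    "s9\tx\tgene\t10\t50\t.\t+\t.\tID=geneC;biotype=gene",
    "s9\tx\texon\t10\t50\t.\t+\t.\tParent=geneC"), ".gff3")
  expect_error(load_annotation(bad_scaffold, fa), "s9")
})

test_that("derive_intergenic handles flanks, gaps and conservation", {
  gene <- function(id, s, e, strand = "+")
    data.frame(gene_id = id, scaffold = "s1", start = s, end = e,
               strand = strand, biotype = "gene", stringsAsFactors = FALSE)
  ## one gene in the middle -> two flanks
  it <- derive_intergenic(gene("g1", 101, 200), c(s1 = 300L))
  expect_equal(it$start, c(1L, 201L))
  expect_equal(it$end, c(100L, 300L))
  expect_equal(it$downstream_gene_plus, c("g1", NA))
  ## two genes -> a single middle gap
  it2 <- derive_intergenic(rbind(gene("g1", 1, 100), gene("g2", 201, 300, "-")),
                           c(s1 = 300L))
  expect_equal(nrow(it2), 1L)
  expect_equal(c(it2$start, it2$end), c(101L, 200L))
  ## neither neighbour has its 5' end on this gap (g1 is +, g2 is -)
  expect_true(is.na(it2$downstream_gene_plus))
  expect_true(is.na(it2$downstream_gene_minus))
  ## divergent promoters: region upstream of both neighbours
  it3 <- derive_intergenic(rbind(gene("gL", 1, 100, "-"),
                                 gene("gR", 201, 300, "+")), c(s1 = 300L))
  expect_equal(it3$downstream_gene_plus, "gR")
  expect_equal(it3$downstream_gene_minus, "gL")

  ## conservation over random non-overlapping genes
  withr::with_seed(11, {
    for (rep in 1:5) {
      lay <- random_layout(L = 10000L, n_genes = 50L, p_pseudo = 0)
      g <- lay$genes
      it <- derive_intergenic(g, c(s1 = 10000L))
      expect_equal(sum(it$end - it$start + 1L),
                   10000L - sum(g$end - g$start + 1L))
      ## agreement with the boolean-scan complement oracle
      orc <- oracle_complement(g$start, g$end, 10000L)
      expect_equal(it$start, orc$start)
      expect_equal(it$end, orc$end)
    }
  })
})

test_that("exon groups follow transcription order", {
  expect_equal(assign_exon_group(5, c(1, 3, 5)), c("start", "middle", "end"))
  expect_equal(assign_exon_group(1, 1), "start")
  expect_equal(assign_exon_group(2, c(1, 2)), c("start", "end"))
  expect_error(assign_exon_group(3, 4), "out of range")

  ## minus-strand gene: highest-coordinate exon is the transcriptional start
  genes <- data.frame(gene_id = "gm", scaffold = "s1", start = 1L, end = 900L,
                      strand = "-", biotype = "gene", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "gm", scaffold = "s1",
                      start = c(1L, 301L, 601L), end = c(100L, 400L, 900L))
  idx <- feature_index(genes, exons, c(s1 = 1000L))
  eg <- exon_groups(idx)
  expect_equal(eg$exon_group[order(eg$start)], c("end", "middle", "start"))
})

test_that("count_adenines matches its contract and the naive oracle", {
  g <- Biostrings::DNAStringSet(c(s1 = "AATG"))
  expect_equal(count_adenines(g, "s1", 1, 4, "both"), 3L)
  expect_equal(count_adenines(g, "s1", 1, 4, "forward"), 2L)
  expect_error(count_adenines(g, "s1", 1, 5), "bounds")
  ## whole synthetic scaffold vs character tally
  l <- test_loaded()
  sc <- names(l$index$scaffold_lengths)[1]
  seq_chr <- as.character(l$index$genome[[sc]])
  L <- nchar(seq_chr)
  expect_equal(count_adenines(l$index$genome, sc, 1, L, "both"),
               oracle_count_adenines(seq_chr, 1, L, "both"))
  expect_equal(count_adenines(l$index$genome, sc, 1, L, "forward"),
               oracle_count_adenines(seq_chr, 1, L, "forward"))
})

test_that("strand symmetry: revcomp leaves both-strand counts and groups invariant", {
  withr::with_seed(5, {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    g <- Biostrings::DNAStringSet(c(s1 = s))
    rc <- Biostrings::reverseComplement(g[[1]])
    g2 <- Biostrings::DNAStringSet(setNames(as.character(rc), "s1"))
    L <- 2000L
    for (i in 1:20) {
      a <- sample(L - 100, 1); b <- a + sample(20:100, 1)
      expect_equal(count_adenines(g, "s1", a, b, "both"),
                   count_adenines(g2, "s1", L - b + 1L, L - a + 1L, "both"))
    }
  })
  ## flipping a gene's strand and coordinates preserves exon groups
  genes <- data.frame(gene_id = "g", scaffold = "s1", start = 101L, end = 700L,
                      strand = "+", biotype = "gene", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g", scaffold = "s1",
                      start = c(101L, 301L, 601L), end = c(200L, 400L, 700L))
  idx <- feature_index(genes, exons, c(s1 = 1000L))
  L <- 1000L
  genes2 <- transform(genes, start = L - end + 1L, end = L - start + 1L,
                      strand = "-")
  exons2 <- data.frame(gene_id = "g", scaffold = "s1",
                       start = L - exons$end + 1L, end = L - exons$start + 1L)
  idx2 <- feature_index(genes2, exons2, c(s1 = L))
  g1 <- exon_groups(idx);  g1 <- g1$exon_group[order(g1$start)]
  g2 <- exon_groups(idx2); g2 <- rev(g2$exon_group[order(g2$start)])
  expect_equal(g1, g2)
})

test_that("upstream_intergenic_of is strand-aware", {
  genes <- data.frame(
    gene_id = c("gp", "gm", "gchain"),
    scaffold = "s1", start = c(101L, 1L, 201L), end = c(200L, 100L, 300L),
    strand = c("+", "-", "+"), biotype = "gene", stringsAsFactors = FALSE)
  ## gp abuts gm on the left and gchain on the right -> layout: gm[1,100],
  ## gp[101,200], gchain[201,300], intergenic [301, 500]
  exons <- data.frame(gene_id = genes$gene_id, scaffold = "s1",
                      start = genes$start, end = genes$end)
  idx <- feature_index(genes, exons, c(s1 = 500L))
  expect_null(upstream_intergenic_of(idx, "gp"))      # abuts gm directly
  up_gm <- upstream_intergenic_of(idx, "gm")
  expect_null(up_gm)                                  # gchain abuts at 201? no:
  ## gm is minus strand at scaffold start; its 5' end is at 100, upstream is
  ## [101, ...] which is gp, a gene -> NULL is correct
  expect_null(upstream_intergenic_of(idx, "gchain"))  # abuts gp
  ## now an isolated plus gene with a free left flank
  genes2 <- data.frame(gene_id = "solo", scaffold = "s1", start = 101L,
                       end = 200L, strand = "+", biotype = "gene",
                       stringsAsFactors = FALSE)
  exons2 <- data.frame(gene_id = "solo", scaffold = "s1", start = 101L,
                       end = 200L)
  idx2 <- feature_index(genes2, exons2, c(s1 = 300L))
  expect_equal(upstream_intergenic_of(idx2, "solo")$start, 1L)
  ## minus-strand gene at scaffold start: upstream is the right-hand region
  genes3 <- transform(genes2, gene_id = "solo_m", start = 1L, end = 100L,
                      strand = "-")
  exons3 <- data.frame(gene_id = "solo_m", scaffold = "s1", start = 1L,
                       end = 100L)
  idx3 <- feature_index(genes3, exons3, c(s1 = 300L))
  expect_equal(upstream_intergenic_of(idx3, "solo_m")$start, 101L)
})

test_that("relative_position_profile bins and denominators behave", {
  g <- Biostrings::DNAStringSet(c(s1 = strrep("A", 100)))
  p <- relative_position_profile(1L, "s1", 1L, 100L, "+", g, n_bins = 10)
  expect_equal(p$density, c(0.1, rep(0, 9)))
  p0 <- relative_position_profile(integer(0), "s1", 1L, 100L, "+", g, 10)
  expect_equal(p0$density, rep(0, 10))
  expect_error(relative_position_profile(integer(0), "s1", 1L, 5L, "+", g, 10),
               "fewer bins")
  ## minus strand: bin 1 is the 3' end of the forward axis
  pm <- relative_position_profile(1L, "s1", 1L, 100L, "-", g, 10)
  expect_equal(pm$density[10], 0.1)
})

test_that("aggregate metagene densities recover a uniform planted rate", {
  withr::with_seed(33, {
    L <- 120000L
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    g <- Biostrings::DNAStringSet(c(s1 = s))
    chars <- strsplit(s, "")[[1]]
    regions <- data.frame(scaffold = "s1",
                          start = seq(1L, by = 600L, length.out = 200L))
    regions$end <- regions$start + 499L
    regions$strand <- "+"
    rate <- 0.02
    pos <- which(chars %in% c("A", "T"))
    marked <- pos[runif(length(pos)) < rate]
    sites <- data.frame(scaffold = "s1", pos = marked)
    prof <- metagene_profile(sites, regions, g, n_bins = 10)
    ## every bin density within 3 binomial SE of the planted rate
    se <- sqrt(rate * (1 - rate) / prof$n_adenines)
    expect_true(all(abs(prof$density - rate) <= 3 * se))
  })
})

test_that("feature classification agrees with the per-position oracle", {
  withr::with_seed(77, {
    lay <- random_layout(L = 10000L, n_genes = 8L, p_pseudo = 0.25)
    idx <- feature_index(lay$genes, lay$exons, c(s1 = 10000L))
    pos <- sample(10000L, 400L)
    got <- classify_positions(idx, rep("s1", length(pos)), pos)
    want <- vapply(pos, function(p)
      oracle_classify_pos(lay$genes, lay$exons, "s1", p), character(1))
    expect_equal(got$feature_class, want)
  })
})

test_that("tiling invariant holds on generated bundles", {
  l <- test_loaded()
  idx <- l$index
  for (sc in names(idx$scaffold_lengths)) {
    spans <- idx$genes[idx$genes$scaffold == sc, ]
    merged <- IRanges::reduce(IRanges::IRanges(spans$start, spans$end))
    inter <- idx$intergenic[idx$intergenic$scaffold == sc, ]
    expect_equal(sum(IRanges::width(merged)) +
                   sum(inter$end - inter$start + 1L),
                 unname(idx$scaffold_lengths[[sc]]))
  }
})
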