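sixma_gff_lines <- function(rows) {
  c("##gff-version 3",
    vapply(rows, function(r)
      sprintf("%s\tkinModCall\tm6A\t%d\t%d\t%d\t%s\t.\tcoverage=%d;IPDRatio=4.00",
              r$sc, r$pos, r$pos, r$cov, r$strand, r$cov), character(1)))
}

test_that("coverage filter is strictly greater-than", {
  rows <- list(list(sc = "s1", pos = 10L, cov = 10L, strand = "+"),
               list(sc = "s1", pos = 20L, cov = 25L, strand = "+"),
               list(sc = "s1", pos = 30L, cov = 26L, strand = "-"))
  path <- write_lines_tmp(sixma_gff_lines(rows), ".gff")
  sites <- load_sixma(path, min_coverage = 25)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 30L)
  expect_equal(attr(sites, "qc")$n_low_coverage, 2L)
  ## idempotence: re-filtering retained sites changes nothing
  again <- sites[sites$coverage > 25, ]
  expect_equal(again$id, sites$id)
})

test_that("empty 6mA files load as empty site tables", {
  path <- write_lines_tmp("##gff-version 3", ".gff")
  sites <- load_sixma(path)
  expect_equal(nrow(sites), 0L)
})

test_that("BED input and genome validation work", {
  g <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTAT"))
  ## pos 5 is A (+ ok), pos 2 is C (invalid for +)
  bed <- write_lines_tmp(c("s1\t4\t5\tm6a1\t40\t+",
                           "s1\t1\t2\tm6a2\t40\t+"), ".bed")
  expect_warning(sites <- load_sixma(bed, genome = g), "non-adenine")
  expect_equal(sites$pos, 5L)
  expect_equal(attr(sites, "qc")$n_bad_base, 1L)
})

test_that("generator-planted sites survive the load exactly", {
  l <- test_loaded()
  truth <- l$bundle$truth$sites
  kept <- truth[truth$retained, ]
  expect_equal(nrow(l$sites), nrow(kept))
  expect_equal(l$sites$pos, kept$pos[order(kept$scaffold, kept$pos)])
  expect_equal(attr(l$sites, "qc")$n_low_coverage, sum(!truth$retained))
  ## every retained site sits on an adenine of the right strand
  b <- as.character(Biostrings::extractAt(
    l$index$genome[[l$sites$scaffold[1]]],
    IRanges::IRanges(1, 1)))  # smoke only; full property below
  base <- mapply(function(sc, p) as.character(
    Biostrings::extractAt(l$index$genome[[sc]], IRanges::IRanges(p, p))),
    l$sites$scaffold, l$sites$pos)
  expect_true(all((l$sites$strand == "+" & base == "A") |
                    (l$sites$strand == "-" & base == "T")))
})

test_that("region_density implements 6mA/A and is monotone", {
  g <- Biostrings::DNAStringSet(c(s1 = "AAAA"))
  s1 <- data.frame(id = "a", scaffold = "s1", pos = 2L, strand = "+",
                   coverage = 30L)
  expect_equal(region_density(s1, "s1", 1, 4, g)$density, 0.25)
  empty <- s1[0, ]
  expect_equal(region_density(empty, "s1", 1, 4, g)$density, 0)
  ## adding a site never decreases density
  s2 <- rbind(s1, data.frame(id = "b", scaffold = "s1", pos = 3L,
                             strand = "+", coverage = 30L))
  expect_gte(region_density(s2, "s1", 1, 4, g)$density,
             region_density(s1, "s1", 1, 4, g)$density)
})

test_that("per-gene densities equal brute-force recomputation", {
  l <- test_loaded()
  d <- sixma_densities(l$sites, l$index, "genes")
  g <- l$index$genes
  for (i in seq_len(nrow(g))) {
    seq_chr <- as.character(l$index$genome[[g$scaffold[i]]])
    n_a <- oracle_count_adenines(seq_chr, g$start[i], g$end[i], "both")
    n_s <- sum(l$sites$scaffold == g$scaffold[i] &
                 l$sites$pos >= g$start[i] & l$sites$pos <= g$end[i])
    expect_equal(d$n_adenines[d$region_id == g$gene_id[i]], n_a)
    expect_equal(d$density[d$region_id == g$gene_id[i]],
                 if (n_a) n_s / n_a else 0)
  }
})

test_that("extract_flanks truncates at edges and recenters minus strands", {
  g <- Biostrings::DNAStringSet(c(s1 = strrep("ACGTTTAGGA", 10)))
  edge <- data.frame(id = "e", scaffold = "s1", pos = 1L, strand = "+",
                     coverage = 30L)
  f <- extract_flanks(edge, g, k = 20)
  expect_equal(nchar(f$flank), 21L)
  expect_true(f$left_trunc)
  expect_equal(substr(f$flank, f$center, f$center), "A")
  ## minus-strand site over a T: returned string centered on A
  stopifnot(substr(as.character(g[[1]]), 5, 5) == "T")
  minus <- data.frame(id = "m", scaffold = "s1", pos = 5L, strand = "-",
                      coverage = 30L)
  fm <- extract_flanks(minus, g, k = 3)
  expect_equal(substr(fm$flank, fm$center, fm$center), "A")
  expect_error(extract_flanks(transform(minus, pos = 500L), g, 3), "off")
  ## property: every flank of a real site set is centered on A
  l <- test_loaded()
  fl <- extract_flanks(l$sites, l$index$genome, k = 20)
  expect_true(all(substr(fl$flank, fl$center, fl$center) == "A"))
})

test_that("iupac_match follows the degeneracy table", {
  expect_true(iupac_match("AGGYANY", "AGGCATT"))
  expect_false(iupac_match("AYCGA", "AACGA"))
  expect_false(iupac_match("A", "N"))  # genome N matches only pattern N
  expect_true(iupac_match("N", "N"))
  expect_error(iupac_match("AXG", "AAA"), "unknown IUPAC")
  expect_error(iupac_match("AA", "AAA"), "lengths differ")
  withr::with_seed(13, {
    codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
    for (i in 1:1000) {
      L <- sample(3:8, 1)
      pat <- paste(sample(codes, L, TRUE), collapse = "")
      win <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                          prob = c(.24, .24, .24, .24, .04)), collapse = "")
      expect_identical(iupac_match(pat, win), oracle_iupac_match(pat, win))
    }
  })
})

test_that("motif coverage counts anchored hits and the union", {
  ## flank centered AGGCACT around the site: pattern AGGYANY anchored at 5
  g <- Biostrings::DNAStringSet(c(s1 = paste0(strrep("C", 20), "AGGCACT",
                                              strrep("C", 20))))
  site <- data.frame(id = "x", scaffold = "s1", pos = 25L, strand = "+",
                     coverage = 30L)
  stopifnot(substr(as.character(g[[1]]), 25, 25) == "A")
  pats <- data.frame(pattern = "AGGYANY", anchor_offset = 5L)
  mc <- motif_coverage(site, pats, g, k = 20)
  expect_equal(mc$per_pattern$n_covered, 1L)
  expect_equal(mc$union, 1L)
  ## no patterns -> union 0
  expect_equal(motif_coverage(site, pats[0, ], g)$union, 0L)
  ## anchored mode must fail when the anchor does not line up
  pats2 <- data.frame(pattern = "AGGYANY", anchor_offset = 1L)
  expect_equal(motif_coverage(site, pats2, g, k = 20)$union, 0L)
  ## unanchored mode finds it anywhere in the flank
  expect_equal(motif_coverage(site, pats2, g, k = 20,
                              anchored = FALSE)$union, 1L)
})

test_that("planted motif coverage matches an independent per-site scan", {
  l <- test_loaded()
  cfgm <- l$bundle$config
  pats <- data.frame(pattern = cfgm$plant_motif,
                     anchor_offset = cfgm$plant_motif_anchor)
  mc <- motif_coverage(l$sites, pats, l$index$genome, k = 20)
  ## oracle: direct substring extraction + independent IUPAC table
  a <- cfgm$plant_motif_anchor
  Lp <- nchar(cfgm$plant_motif)
  hit <- vapply(seq_len(nrow(l$sites)), function(i) {
    sc <- l$sites$scaffold[i]; pos <- l$sites$pos[i]
    seq_chr <- as.character(l$index$genome[[sc]])
    if (l$sites$strand[i] == "+") {
      s <- pos - a + 1L; e <- s + Lp - 1L
      if (s < 1 || e > nchar(seq_chr)) return(FALSE)
      win <- substr(seq_chr, s, e)
    } else {
      s <- pos - (Lp - a); e <- pos + a - 1L
      if (s < 1 || e > nchar(seq_chr)) return(FALSE)
      win <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                       substr(seq_chr, s, e)), "")[[1]]),
                   collapse = "")
    }
    oracle_iupac_match(cfgm$plant_motif, win)
  }, logical(1))
  expect_equal(mc$union, sum(hit))
  ## all explicitly planted sites are covered
  planted <- l$bundle$truth$sites
  planted <- planted[planted$retained & planted$planted_motif, ]
  expect_gte(mc$union, nrow(planted))
  expect_equal(l$bundle$truth$global$n_planted_motif, nrow(planted))
  ## union bound invariant
  expect_lte(mc$union, sum(mc$per_pattern$n_covered))
  expect_lte(mc$union, nrow(l$sites))
})
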