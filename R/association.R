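## Statistical layer: group comparisons, the 6mA-density regression on
## transmission-type counts, upstream-intergenic effect, percentage helper.

#' Two-sample comparison of density vectors
#'
#' Two-sided two-sample t test; Welch by default, with a pooled-variance
#' option for literal "student t-test" fidelity.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param flavor "welch" or "pooled".
#' @param label_a,label_b group labels carried on the result.
#' @return list of class \code{GroupComparisonResult}: labels, n, means,
#'   t_statistic, df, p_value, test_flavor.
#' @export
compare_groups <- function(values_a, values_b, flavor = c("welch", "pooled"),
                           label_a = "a", label_b = "b") {
  flavor <- match.arg(flavor)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("each group needs >= 2 finite values (got %d and %d)",
          length(values_a), length(values_b))
  res <- if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      list(statistic = 0, parameter = length(values_a) + length(values_b) - 2,
           p.value = 1)
    else
      list(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
           parameter = length(values_a) + length(values_b) - 2,
           p.value = .Machine$double.xmin)
  } else {
    t <- t.test(values_a, values_b, var.equal = (flavor == "pooled"))
    list(statistic = unname(t$statistic), parameter = unname(t$parameter),
         p.value = t$p.value)
  }
  structure(list(group_a_label = label_a, group_b_label = label_b,
                 n_a = length(values_a), n_b = length(values_b),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 t_statistic = res$statistic, df = res$parameter,
                 p_value = res$p.value, test_flavor = flavor),
            class = "GroupComparisonResult")
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g): t=%.3f, p=%.3g [%s]\n",
              x$group_a_label, x$n_a, x$mean_a, x$group_b_label, x$n_b,
              x$mean_b, x$t_statistic, x$p_value, x$test_flavor))
  invisible(x)
}

#' Significance stars at the Table-1 thresholds
#'
#' Two levels only: \code{***} below 1e-4 and \code{*} below 0.05.
#' @param p p-values.
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 0.05, "*", ""))
}

#' Fit the 6mA-density linear model on transmission-type counts
#'
#' Ordinary least squares of per-gene 6mA density on the six per-gene
#' transmission-type counts: y_i = sum_n a_n x_in (+ intercept) + eps.
#'
#' @param density named numeric vector of per-gene 6mA densities
#'   (names = gene ids).
#' @param type_counts matrix from \code{\link{per_gene_type_counts}} (rows
#'   named by gene id).
#' @param include_intercept fit an intercept (default TRUE).
#' @return list of class \code{RegressionFit}: data.frame \code{table}
#'   (term, estimate, std_error, t_value, p_value, stars), plus
#'   residual_variance, n_genes, n_dropped.
#' @export
fit_density_regression <- function(density, type_counts,
                                   include_intercept = TRUE) {
  common <- intersect(names(density), rownames(type_counts))
  n_dropped <- length(density) - length(common)
  y <- unname(density[common])
  X <- type_counts[common, , drop = FALSE]
  keep <- is.finite(y)
  n_dropped <- n_dropped + sum(!keep)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  k <- ncol(X) + as.integer(include_intercept)
  if (length(y) <= k)
    stopf("need more genes (%d) than model terms (%d)", length(y), k)
  df <- as.data.frame(X)
  safe <- paste0("x", seq_len(ncol(X)))
  names(df) <- safe
  df$y <- y
  fml <- if (include_intercept) y ~ . else y ~ . + 0
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    bad <- colnames(X)[match(bad, safe)]
    stopf("rank-deficient design; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  ## summary.lm warns on numerically perfect fits (noise-free recovery is a
  ## supported use); the coefficient table itself is still exact
  sm <- suppressWarnings(summary(fit))
  s <- sm$coefficients
  term <- rownames(s)
  term[term %in% safe] <- colnames(X)[match(term[term %in% safe], safe)]
  term[term == "(Intercept)"] <- "(intercept)"
  tab <- data.frame(term = term, estimate = s[, 1], std_error = s[, 2],
                    t_value = s[, 3], p_value = s[, 4],
                    stars = significance_stars(s[, 4]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 residual_variance = sm$sigma^2,
                 n_genes = length(y), n_dropped = n_dropped,
                 include_intercept = include_intercept),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("6mA-density regression on %d genes (residual variance %.3g)\n",
              x$n_genes, x$residual_variance))
  print(x$table, digits = 4)
  invisible(x)
}

#' Percentage with half-up rounding
#'
#' \code{100 * numerator / denominator}, rounded half-up to \code{ndigits}.
#'
#' @param numerator,denominator numbers; denominator must be positive.
#' @param ndigits decimal digits (default 2).
#' @return numeric percentage.
#' @export
percent <- function(numerator, denominator, ndigits = 2) {
  if (any(denominator <= 0)) stopf("denominator must be > 0")
  round_half_up(100 * numerator / denominator, ndigits)
}

#' Partition genes into 6mA-modified and unmodified
#'
#' A gene is modified iff at least one retained 6mA site lies within its span
#' (1-based inclusive). Exhaustive and disjoint over protein-coding genes.
#'
#' @param index FeatureIndex.
#' @param sites retained 6mA site table.
#' @return list with character vectors \code{modified} and \code{unmodified}.
#' @export
modified_vs_unmodified_partition <- function(index, sites) {
  genes <- index$genes[index$genes$biotype == "gene", , drop = FALSE]
  n <- count_in_regions(sites$scaffold, sites$pos,
                        data.frame(scaffold = genes$scaffold,
                                   start = genes$start, end = genes$end))
  list(modified = genes$gene_id[n > 0L], unmodified = genes$gene_id[n == 0L])
}

#' Upstream-intergenic 6mA effect on gene variant density
#'
#' Partitions genes by whether the intergenic region abutting their 5' end
#' contains at least one retained 6mA site, then compares per-gene variant
#' densities between the partitions (one comparison per variant source).
#' Genes without a resolvable upstream region are excluded and counted.
#'
#' @param index FeatureIndex.
#' @param sites retained 6mA site table.
#' @param dna_snps DNA SNP table.
#' @param rna_snps optional RNA SNP table.
#' @param flavor t-test flavor.
#' @return list: \code{DNA} and (optionally) \code{RNA}
#'   GroupComparisonResults, \code{n_methylated_upstream},
#'   \code{n_unmethylated_upstream}, \code{n_no_upstream}.
#' @export
upstream_effect <- function(index, sites, dna_snps, rna_snps = NULL,
                            flavor = "welch") {
  genes <- index$genes[index$genes$biotype == "gene", , drop = FALSE]
  ## upstream region per gene, strand-aware, vectorized over the index
  it <- index$intergenic
  up_plus <- it$region_id[match(paste(genes$scaffold, genes$start - 1L),
                                paste(it$scaffold, it$end))]
  up_minus <- it$region_id[match(paste(genes$scaffold, genes$end + 1L),
                                 paste(it$scaffold, it$start))]
  up <- ifelse(genes$strand == "+", up_plus, up_minus)
  has_up <- !is.na(up)
  n_marks <- count_in_regions(sites$scaffold, sites$pos,
                              it[, c("scaffold", "start", "end")])
  methylated_regions <- it$region_id[n_marks > 0L]
  meth_up <- has_up & up %in% methylated_regions
  grp_meth <- genes$gene_id[meth_up]
  grp_norm <- genes$gene_id[has_up & !meth_up]
  if (length(grp_meth) < 2L || length(grp_norm) < 2L)
    stopf("upstream partition too small (%d methylated / %d unmethylated); larger input needed",
          length(grp_meth), length(grp_norm))
  one <- function(snps) {
    vd <- variant_densities(snps, index, "genes")
    d <- setNames(vd$density, vd$region_id)
    compare_groups(d[grp_meth], d[grp_norm], flavor = flavor,
                   label_a = "upstream_6mA", label_b = "upstream_normal")
  }
  out <- list(DNA = one(dna_snps),
              RNA = if (!is.null(rna_snps)) one(rna_snps) else NULL,
              n_methylated_upstream = length(grp_meth),
              n_unmethylated_upstream = length(grp_norm),
              n_no_upstream = sum(!has_up))
  out
}
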