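#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm pt rbinom rmultinom rnorm rpois runif sd setNames t.test coef ave
#' @importFrom utils write.table read.table packageVersion
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Half-up decimal rounding (round() in R rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Write a TSV with a one-line provenance comment followed by a header row.
write_tsv_prov <- function(df, path, config_sha = "none") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# sixmaTrans %s config_sha=%s",
                     as.character(packageVersion("sixmaTrans")), config_sha),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

## Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
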