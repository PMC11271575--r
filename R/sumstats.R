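#' GWAS summary statistics container
#'
#' A `maprs_sumstats` object is a data frame with one row per SNP and columns
#' `snp_id`, `chrom`, `pos`, `a1` (effect allele), `a2`, `r` (standardized
#' marginal effect, i.e. approximately the SNP-trait correlation), `n` (GWAS
#' sample size) and `freq` (a1 frequency), plus a `population` attribute.
#'
#' @param df data frame with the columns above.
#' @param population population label, e.g. `"EUR"`.
#' @return A validated `maprs_sumstats` data frame.
#' @export
sumstats <- function(df, population) {
  required <- c("snp_id", "chrom", "pos", "a1", "a2", "r", "n", "freq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sumstats: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  if (anyDuplicated(df$snp_id))
    stop("sumstats: duplicated snp_id in population ", population)
  if (any(!is.finite(df$r)) || any(abs(df$r) > 1))
    stop("sumstats: |r| must be finite and <= 1")
  if (any(df$n <= 0)) stop("sumstats: n must be positive")
  if (any(df$a1 == df$a2)) stop("sumstats: a1 must differ from a2")
  attr(df, "population") <- population
  class(df) <- c("maprs_sumstats", "data.frame")
  df
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  unname(COMPLEMENT[a1] == a2 & !is.na(COMPLEMENT[a1]))
}

#' Read and harmonize GWAS summary statistics against a reference SNP set
#'
#' Reads a tab/space-delimited summary-statistics file, maps its columns via
#' `col_map`, and harmonizes alleles to the orientation of a reference panel:
#' records whose alleles are reversed relative to the reference have `r`
#' negated and alleles swapped; SNPs absent from the reference, with
#' mismatching alleles, or strand-ambiguous (A/T, C/G; unless
#' `keep_ambiguous = TRUE`) are dropped. A kept/flipped/dropped report is
#' attached as attribute `"report"`.
#'
#' If the file carries a z-score column instead of `r`, map it as `z` in
#' `col_map` and it is converted with [zscore_to_r()].
#'
#' @param path file path.
#' @param population population label.
#' @param ref_snps data frame of reference SNP metadata with columns
#'   `snp_id`, `a1`, `a2` (canonical orientation), optionally `chrom`, `pos`.
#' @param col_map named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `r` or `z`, `n`, `freq`) to the
#'   file's column names. Defaults to identity.
#' @param keep_ambiguous keep strand-ambiguous SNPs? Default `FALSE`.
#' @return `maprs_sumstats` with attribute `report` (named counts
#'   `kept`, `flipped`, `dropped_missing`, `dropped_ambiguous`,
#'   `dropped_mismatch`).
#' @export
read_sumstats <- function(path, population, ref_snps, col_map = NULL,
                          keep_ambiguous = FALSE) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  canonical <- c("snp_id", "chrom", "pos", "a1", "a2", "r", "z", "n", "freq")
  if (is.null(col_map)) col_map <- setNames(canonical, canonical)
  for (nm in names(col_map)) {
    if (col_map[[nm]] %in% names(raw)) names(raw)[names(raw) == col_map[[nm]]] <- nm
  }
  required <- c("snp_id", "chrom", "pos", "a1", "a2", "n", "freq")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("read_sumstats: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!("r" %in% names(raw))) {
    if (!("z" %in% names(raw)))
      stop("read_sumstats: need an effect column mapped to 'r' or 'z'")
    raw$r <- zscore_to_r(raw$z, raw$n)
  }
  if (anyDuplicated(raw$snp_id))
    stop("read_sumstats: duplicated snp_id")
  harmonize_sumstats(raw, population, ref_snps, keep_ambiguous = keep_ambiguous)
}

#' Harmonize a summary-statistics data frame to reference allele orientation
#'
#' @inheritParams read_sumstats
#' @param df data frame with canonical sumstats columns.
#' @return `maprs_sumstats` with a `report` attribute; see [read_sumstats()].
#' @export
harmonize_sumstats <- function(df, population, ref_snps, keep_ambiguous = FALSE) {
  df$a1 <- toupper(df$a1); df$a2 <- toupper(df$a2)
  n_in <- nrow(df)
  m <- match(df$snp_id, ref_snps$snp_id)
  dropped_missing <- sum(is.na(m))
  df <- df[!is.na(m), , drop = FALSE]
  ref <- ref_snps[m[!is.na(m)], , drop = FALSE]

  ambiguous <- is_strand_ambiguous(df$a1, df$a2)
  dropped_ambiguous <- 0L
  if (!keep_ambiguous && any(ambiguous)) {
    dropped_ambiguous <- sum(ambiguous)
    df <- df[!ambiguous, , drop = FALSE]
    ref <- ref[!ambiguous, , drop = FALSE]
  }

  same <- df$a1 == toupper(ref$a1) & df$a2 == toupper(ref$a2)
  rev  <- df$a1 == toupper(ref$a2) & df$a2 == toupper(ref$a1)
  # non-ambiguous SNPs may be on the other strand: compare complements
  comp_same <- !same & !rev & COMPLEMENT[df$a1] == toupper(ref$a1) &
    COMPLEMENT[df$a2] == toupper(ref$a2)
  comp_rev <- !same & !rev & !comp_same & COMPLEMENT[df$a1] == toupper(ref$a2) &
    COMPLEMENT[df$a2] == toupper(ref$a1)
  comp_same[is.na(comp_same)] <- FALSE
  comp_rev[is.na(comp_rev)] <- FALSE

  keep <- same | rev | comp_same | comp_rev
  dropped_mismatch <- sum(!keep)
  flip <- (rev | comp_rev)[keep]
  df <- df[keep, , drop = FALSE]
  ref <- ref[keep, , drop = FALSE]
  if (any(flip)) {
    df$r[flip] <- -df$r[flip]
    df$freq[flip] <- 1 - df$freq[flip]
  }
  # adopt the canonical orientation (and strand) of the reference
  df$a1 <- toupper(ref$a1)
  df$a2 <- toupper(ref$a2)
  if (any(abs(df$r) > 1)) stop("harmonize_sumstats: |r| > 1 after conversion")

  out <- sumstats(df, population)
  attr(out, "report") <- c(kept = nrow(df), flipped = sum(flip),
                           dropped_missing = dropped_missing,
                           dropped_ambiguous = dropped_ambiguous,
                           dropped_mismatch = dropped_mismatch)
  stopifnot(nrow(df) + dropped_missing + dropped_ambiguous + dropped_mismatch == n_in)
  out
}

#' Write a SNP-weight table
#'
#' Writes a tab-delimited weight table (`snp_id`, `chrom`, `pos`, `a1`, `a2`
#' then one or more weight columns) that round-trips through [read_weights()]
#' at full precision.
#'
#' @param weights data frame with the columns above; weight columns must be
#'   finite.
#' @param path output path.
#' @param sparse drop rows whose weights are all exactly zero? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, sparse = FALSE) {
  if (!nrow(weights)) stop("write_weights: empty weight table")
  meta <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(meta %in% names(weights)))
    stop("write_weights: need columns ", paste(meta, collapse = ", "))
  wcols <- setdiff(names(weights), meta)
  if (!length(wcols)) stop("write_weights: no weight column")
  wmat <- as.matrix(weights[wcols])
  if (any(!is.finite(wmat))) stop("write_weights: non-finite weight")
  if (sparse) weights <- weights[rowSums(wmat != 0) > 0, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(weights), collapse = "\t"), con)
  # full-precision serialization so read/write is an exact round trip
  body <- vapply(seq_len(nrow(weights)), function(i) {
    paste(vapply(weights[i, ], function(x)
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x), ""),
      collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA)
}
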