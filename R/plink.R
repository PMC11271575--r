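#' Genotype panel container
#'
#' A `maprs_panel` holds a samples-by-SNPs dosage matrix together with SNP
#' metadata (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `freq`) and sample ids.
#' Dosages count copies of `a1`. When `standardized = TRUE` the columns have
#' been centered and scaled (population standard deviation, i.e. divide by n);
#' monomorphic SNPs are flagged and left as zero columns.
#'
#' @param dosage numeric matrix, samples x SNPs.
#' @param snps SNP metadata data frame.
#' @param sample_ids character vector of sample ids.
#' @param standardized logical.
#' @param scaling optional list with `mean` and `sd` per SNP (recorded by
#'   [standardize_panel()]).
#' @return A `maprs_panel` object.
#' @export
genotype_panel <- function(dosage, snps, sample_ids,
                           standardized = FALSE, scaling = NULL) {
  stopifnot(ncol(dosage) == nrow(snps), nrow(dosage) == length(sample_ids))
  if (anyDuplicated(sample_ids)) stop("genotype_panel: duplicate sample ids")
  if (anyDuplicated(snps$snp_id)) stop("genotype_panel: duplicate snp ids")
  colnames(dosage) <- snps$snp_id
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, snps = as.data.frame(snps),
                 sample_ids = sample_ids, standardized = standardized,
                 scaling = scaling),
            class = "maprs_panel")
}

#' @method print maprs_panel
#' @export
print.maprs_panel <- function(x, ...) {
  cat("maprs_panel:", nrow(x$dosage), "samples x", ncol(x$dosage), "SNPs",
      if (x$standardized) "(standardized)" else "(dosage scale)", "\n")
  invisible(x)
}

#' Read genotypes from a PLINK 1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet (SNP-major bed). Missing genotypes are
#' mean-imputed per SNP; with `standardize = TRUE` columns are then centered
#' and scaled by the population (divide-by-n) standard deviation, monomorphic
#' columns becoming zeros.
#'
#' @param prefix fileset prefix (without extension).
#' @param snp_subset optional character vector of SNP ids to load.
#' @param standardize center/scale columns? Default `FALSE`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(prefix, snp_subset = NULL, standardize = FALSE) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(fam_df[[2]])
  n <- length(sample_ids); p <- nrow(bim_df)

  keep <- seq_len(p)
  if (!is.null(snp_subset)) {
    keep <- which(bim_df$snp_id %in% snp_subset)
    if (!length(keep)) stop("read_genotypes: no requested SNPs in .bim")
  }

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("read_genotypes: not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("read_genotypes: only SNP-major .bed supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * p)
    stop("read_genotypes: .bed size inconsistent with .bim/.fam")

  # 2-bit codes per sample: 00 = 2 copies of a1, 10 = het, 11 = 0 copies,
  # 01 = missing (PLINK stores a1 as the first/minor allele)
  lookup <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  dosage <- matrix(NA_real_, n, length(keep))
  for (j in seq_along(keep)) {
    off <- (keep[j] - 1) * bytes_per_snp
    b <- as.integer(body[(off + 1):(off + bytes_per_snp)])
    codes <- c(rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L))
    dosage[, j] <- lookup[codes[seq_len(n)] + 1L]
  }

  snps <- bim_df[keep, c("snp_id", "chrom", "pos", "a1", "a2")]
  # mean imputation before any scaling
  if (anyNA(dosage)) {
    for (j in seq_len(ncol(dosage))) {
      miss <- is.na(dosage[, j])
      if (any(miss)) dosage[miss, j] <- mean(dosage[!miss, j])
    }
  }
  snps$freq <- colMeans(dosage) / 2
  panel <- genotype_panel(dosage, snps, sample_ids)
  if (standardize) panel <- standardize_panel(panel) else panel
}

#' Standardize a genotype panel
#'
#' Centers each SNP column and divides by its population standard deviation
#' (`sqrt(mean((x - mean(x))^2)`). Monomorphic columns are set to zero and
#' flagged in `panel$snps$monomorphic`.
#'
#' @param panel a [genotype_panel()].
#' @return The standardized panel with `scaling` recorded.
#' @export
standardize_panel <- function(panel) {
  if (panel$standardized) return(panel)
  X <- panel$dosage
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  mono <- sds < 1e-12
  Xs <- sweep(X, 2, mu)
  Xs[, !mono] <- sweep(Xs[, !mono, drop = FALSE], 2, sds[!mono], "/")
  Xs[, mono] <- 0
  panel$snps$monomorphic <- mono
  genotype_panel(Xs, panel$snps, panel$sample_ids, standardized = TRUE,
                 scaling = list(mean = mu, sd = sds))
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' Rounds dosages to 0/1/2 (the panel must be on the dosage scale) and writes
#' SNP-major `.bed` plus `.bim`/`.fam`.
#'
#' @param panel a [genotype_panel()] on the dosage scale.
#' @param prefix output fileset prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  if (panel$standardized)
    stop("write_plink: panel must be on the dosage (0..2) scale")
  X <- round(panel$dosage)
  X[X < 0] <- 0; X[X > 2] <- 2
  n <- nrow(X); p <- ncol(X)
  code <- matrix(3L, n, p)         # 11 = 0 copies of a1
  code[X == 1] <- 2L               # 10 = het
  code[X == 2] <- 0L               # 00 = 2 copies
  code[is.na(X)] <- 1L             # 01 = missing
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  out <- raw(3 + bytes_per_snp * p)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(p)) {
    codes <- c(code[, j], integer(pad))
    q <- matrix(codes, nrow = 4)
    packed <- q[1, ] + 4L * q[2, ] + 16L * q[3, ] + 64L * q[4, ]
    out[3 + (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)] <- as.raw(packed)
  }
  writeBin(out, paste0(prefix, ".bed"))
  s <- panel$snps
  bim <- data.frame(s$chrom, s$snp_id, 0, s$pos, s$a1, s$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
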