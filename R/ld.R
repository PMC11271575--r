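#' Per-block LD correlation matrices for one population
#'
#' A `maprs_ld` object is a list with the population label and an ordered list
#' of blocks, each `list(block_id, snp_ids, R)` with `R` a correlation matrix
#' (unit diagonal). Blocks are treated as mutually independent, so the implied
#' genome-wide LD matrix is block-diagonal.
#'
#' @param population population label.
#' @param blocks list of `list(block_id, snp_ids, R)`.
#' @return A `maprs_ld` object.
#' @export
ld_blockset <- function(population, blocks) {
  ids <- unlist(lapply(blocks, `[[`, "snp_ids"))
  if (anyDuplicated(ids)) stop("ld_blockset: SNP ids must be disjoint across blocks")
  for (b in blocks) {
    R <- b$R
    if (nrow(R) != length(b$snp_ids)) stop("ld_blockset: R dim mismatch")
    if (nrow(R) && max(abs(R - t(R))) > 1e-10) stop("ld_blockset: R not symmetric")
    if (nrow(R) && max(abs(diag(R) - 1)) > 1e-8) stop("ld_blockset: R diagonal must be 1")
  }
  structure(list(population = population, blocks = blocks), class = "maprs_ld")
}

#' @method print maprs_ld
#' @export
print.maprs_ld <- function(x, ...) {
  p <- sum(vapply(x$blocks, function(b) length(b$snp_ids), 0L))
  cat("maprs_ld:", x$population, "-", length(x$blocks), "blocks,", p, "SNPs\n")
  invisible(x)
}

#' All SNP ids of an LD block set, in block order
#' @param ld a [ld_blockset()].
#' @return Character vector of SNP ids.
#' @export
ld_snp_ids <- function(ld) unlist(lapply(ld$blocks, `[[`, "snp_ids"), use.names = FALSE)

#' Compute per-block LD matrices from a reference genotype panel
#'
#' SNPs with reference minor allele frequency `<= maf_min` are excluded.
#' Within each block (BED-style half-open 0-based intervals) the LD matrix is
#' the Pearson sample correlation of (mean-imputed) dosages, matching
#' `plink --r` semantics. SNPs falling outside every block are assigned to the
#' nearest block on the same chromosome, with a message reporting the count.
#'
#' @param panel a [genotype_panel()] on the dosage scale.
#' @param block_intervals data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param maf_min minimum minor allele frequency; default 0.01.
#' @param population population label stored on the result.
#' @return A [ld_blockset()] for the panel's population of SNPs.
#' @export
compute_block_ld <- function(panel, block_intervals, maf_min = 0.01,
                             population = "pop") {
  if (nrow(panel$dosage) < 2) stop("compute_block_ld: need at least 2 samples")
  if (panel$standardized)
    stop("compute_block_ld: panel must be on the dosage scale")
  freq <- colMeans(panel$dosage) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- maf > maf_min
  snps <- panel$snps[keep, , drop = FALSE]
  X <- panel$dosage[, keep, drop = FALSE]

  bi <- as.data.frame(block_intervals)
  assign_block <- integer(nrow(snps))
  for (j in seq_len(nrow(snps))) {
    same_chr <- which(as.character(bi$chrom) == as.character(snps$chrom[j]))
    if (!length(same_chr)) { assign_block[j] <- NA_integer_; next }
    pos0 <- snps$pos[j] - 1  # convert 1-based position to 0-based coordinate
    inside <- same_chr[bi$start[same_chr] <= pos0 & pos0 < bi$end[same_chr]]
    if (length(inside)) {
      assign_block[j] <- inside[1]
    } else {
      mid <- (bi$start[same_chr] + bi$end[same_chr]) / 2
      assign_block[j] <- same_chr[which.min(abs(mid - pos0))]
      attr(assign_block, "outside") <- c(attr(assign_block, "outside"), j)
    }
  }
  n_outside <- length(attr(assign_block, "outside"))
  if (n_outside)
    message("compute_block_ld: ", n_outside,
            " SNP(s) outside every block assigned to nearest block")
  if (anyNA(assign_block))
    stop("compute_block_ld: SNP(s) on a chromosome with no blocks")

  blocks <- vector("list", nrow(bi))
  for (b in seq_len(nrow(bi))) {
    j <- which(assign_block == b)
    j <- j[order(snps$pos[j])]
    if (!length(j)) {
      warning("compute_block_ld: block ", b, " is empty")
      blocks[[b]] <- list(block_id = b, snp_ids = character(0),
                          R = matrix(0, 0, 0))
      next
    }
    R <- cor(X[, j, drop = FALSE])
    diag(R) <- 1
    blocks[[b]] <- list(block_id = b, snp_ids = snps$snp_id[j], R = R)
  }
  ld_blockset(population, blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-population shared-SNP index
#'
#' Records, for every SNP, which populations model it. SNPs modelled by a
#' single population are population-specific: in the joint model they see only
#' the lasso penalty (empty partner set).
#'
#' @param sumstats_by_pop list of [sumstats()] objects (or any data frames
#'   with `snp_id`), one per population.
#' @return A `maprs_shared` object with `populations`, logical `membership`
#'   matrix (union SNPs x populations), and `pairs`, a list keyed
#'   `"<i>|<j>"` (i < j) of shared SNP id vectors.
#' @export
build_shared_index <- function(sumstats_by_pop) {
  if (!length(sumstats_by_pop)) stop("build_shared_index: no populations")
  pops <- vapply(seq_along(sumstats_by_pop), function(i)
    attr(sumstats_by_pop[[i]], "population") %||% paste0("pop", i), "")
  ids <- lapply(sumstats_by_pop, function(s) s$snp_id)
  union_ids <- unique(unlist(ids))
  membership <- vapply(ids, function(x) union_ids %in% x,
                       logical(length(union_ids)))
  membership <- matrix(membership, nrow = length(union_ids),
                       dimnames = list(union_ids, pops))
  pairs <- list()
  M <- length(pops)
  if (M > 1) {
    for (i in 1:(M - 1)) for (j in (i + 1):M) {
      pairs[[paste0(pops[i], "|", pops[j])]] <-
        union_ids[membership[, i] & membership[, j]]
    }
  }
  structure(list(populations = pops, membership = membership, pairs = pairs),
            class = "maprs_shared")
}

#' Partner populations sharing each SNP of one population
#' @param shared a [build_shared_index()] result.
#' @param population population label.
#' @return Named list: for each SNP of `population`, the other populations
#'   modelling it (possibly empty = population-specific).
#' @export
snp_partners <- function(shared, population) {
  memb <- shared$membership
  mine <- rownames(memb)[memb[, population]]
  lapply(setNames(mine, mine), function(id) {
    setdiff(colnames(memb)[memb[id, ]], population)
  })
}
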