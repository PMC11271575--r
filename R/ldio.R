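#' Serialize / load per-block LD matrices
#'
#' Stores the dense per-block matrices of a [ld_blockset()] as consecutive
#' little-endian doubles in `<prefix>.ldbin`, with a JSON index
#' `<prefix>.ldidx.json` carrying the population label, per-block SNP ids,
#' offsets and an md5 checksum of the binary payload.
#'
#' @param ld a [ld_blockset()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ld <- function(ld, prefix) {
  bin <- paste0(prefix, ".ldbin")
  con <- file(bin, "wb")
  offsets <- integer(length(ld$blocks))
  off <- 0
  for (i in seq_along(ld$blocks)) {
    offsets[i] <- off
    R <- ld$blocks[[i]]$R
    if (length(R)) writeBin(as.numeric(R), con, size = 8, endian = "little")
    off <- off + length(R)
  }
  close(con)
  idx <- list(population = ld$population,
              blocks = lapply(seq_along(ld$blocks), function(i)
                list(block_id = ld$blocks[[i]]$block_id,
                     snp_ids = as.list(ld$blocks[[i]]$snp_ids),
                     offset = offsets[i])),
              checksum = tools::md5sum(bin)[[1]])
  jsonlite::write_json(idx, paste0(prefix, ".ldidx.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_ld
#' @export
read_ld <- function(prefix) {
  idx <- jsonlite::read_json(paste0(prefix, ".ldidx.json"))
  bin <- paste0(prefix, ".ldbin")
  if (tools::md5sum(bin)[[1]] != idx$checksum)
    stop("read_ld: checksum mismatch for ", bin)
  vals <- readBin(bin, "double", n = file.size(bin) / 8, size = 8,
                  endian = "little")
  blocks <- lapply(idx$blocks, function(b) {
    ids <- unlist(b$snp_ids)
    pb <- length(ids)
    R <- if (pb) matrix(vals[b$offset + seq_len(pb^2)], pb, pb)
         else matrix(0, 0, 0)
    list(block_id = b$block_id, snp_ids = ids, R = R)
  })
  ld_blockset(idx$population, blocks)
}
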