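# File interchange: TSV count matrices and clinical tables, plain-text
# key = value config files, and a minimal uncompressed little-endian 16-bit
# grayscale multi-page TIFF reader/writer (no TIFF library is available in
# the target environment; only this baseline subset of the format is
# supported).

#' Write / read a genes x samples count matrix as TSV
#'
#' Layout: header row of sample ids, first column `gene_id`, tab-separated.
#'
#' @param counts genes x samples numeric matrix with dimnames.
#' @param path output file.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") abort("first column must be gene_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "numeric"
  check_count_matrix(m)
  m
}

#' Write / read a clinical table as TSV
#'
#' Columns: `sample_id`, `days`, `event`, `stage`, `dsg2_cnv_amplified`.
#'
#' @param clinical data.frame.
#' @param path output file.
#' @export
write_clinical_tsv <- function(clinical, path) {
  need <- c("sample_id", "days", "event")
  if (!all(need %in% names(clinical))) {
    abort("clinical table needs columns: %s", paste(need, collapse = ", "))
  }
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "days", "event")
  if (!all(need %in% names(df))) {
    abort("clinical table needs columns: %s", paste(need, collapse = ", "))
  }
  df
}

# ---- minimal TIFF subset -------------------------------------------------

tiff_ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value packed into 4 bytes
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L) {
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    } else {
      writeBin(as.integer(value), raw(), size = 4, endian = "little")
    })
}

#' Write / read matrices as minimal 16-bit grayscale multi-page TIFF
#'
#' Uncompressed, little-endian, one strip per page.  Values are clipped to
#' `[0, 65535]` and rounded on write.  The reader accepts only files this
#' subset produces (uncompressed 16-bit grayscale).
#'
#' @param pages a numeric matrix or list of equally-sized matrices.
#' @param path file path.
#' @return `write_tiff16` returns `path` invisibly; `read_tiff16` returns a
#'   list of numeric matrices.
#' @export
write_tiff16 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con) # "II" little-endian
  writeBin(as.integer(42), con, size = 2, endian = "little")
  offset <- 8L
  header_ifd_ptr <- offset
  writeBin(as.integer(header_ifd_ptr), con, size = 4, endian = "little")
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    nbytes <- 2L * h * w
    data_offset <- offset + ifd_size
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    ent <- c(
      tiff_ifd_entry(256, 4L, 1L, w),             # ImageWidth
      tiff_ifd_entry(257, 4L, 1L, h),             # ImageLength
      tiff_ifd_entry(258, 3L, 1L, 16L),           # BitsPerSample
      tiff_ifd_entry(259, 3L, 1L, 1L),            # Compression: none
      tiff_ifd_entry(262, 3L, 1L, 1L),            # Photometric: BlackIsZero
      tiff_ifd_entry(273, 4L, 1L, data_offset),   # StripOffsets
      tiff_ifd_entry(278, 4L, 1L, h),             # RowsPerStrip
      tiff_ifd_entry(279, 4L, 1L, nbytes)         # StripByteCounts
    )
    writeBin(ent, con)
    next_ifd <- if (i < length(pages)) data_offset + nbytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    vals <- as.integer(round(pmin(pmax(t(m), 0), 65535)))
    writeBin(vals, con, size = 2, endian = "little")
    offset <- data_offset + nbytes
  }
  invisible(path)
}

#' @rdname write_tiff16
#' @export
read_tiff16 <- function(path) {
  raw_all <- readBin(path, raw(), file.info(path)$size)
  u16 <- function(off) {
    sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42) {
    abort("not a little-endian TIFF")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd + 2 + (i - 1) * 12
      tag <- u16(base)
      type <- u16(base + 2)
      val <- if (type == 3L) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- val
    }
    if (tags[["259"]] != 1) abort("unsupported TIFF: compressed")
    if (tags[["258"]] != 16) abort("unsupported TIFF: not 16-bit")
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]
    npix <- w * h
    vals <- readBin(raw_all[(off + 1):(off + 2 * npix)], integer(),
                    n = npix, size = 2, endian = "little", signed = FALSE)
    pages[[length(pages) + 1L]] <- t(matrix(vals, w, h))
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}

#' Read / write a flat plain-text config file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numeric when possible, comma-separated values become vectors.
#'
#' @param path file path.
#' @return named list of values.
#' @export
read_vmq_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) abort("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(strsplit(trimws(kv[2L]), ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (all(!is.na(num))) num else val
  }
  out
}
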