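# Minimal MetaImage (.mhd/.mha) support for axis-aligned integer volumes.
# Uncompressed data only; little-endian; identity (scaled) orientation.

mhd_types <- list(
  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4, signed = TRUE),
  MET_INT = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE)
)

parse_mhd_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}

read_metaimage <- function(path) {
  mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (mha) {
    bytes <- readBin(path, "raw", file.size(path))
    hit <- grepRaw("ElementDataFile[^\n]*\n", bytes, value = TRUE)
    off <- grepRaw("ElementDataFile[^\n]*\n", bytes)
    if (length(off) == 0) stop_ms("ms_format_error", "missing ElementDataFile")
    hdr_end <- off[1] + length(hit) - 1L
    hdr_lines <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\n")[[1]]
    payload <- bytes[seq.int(hdr_end + 1L, length(bytes))]
  } else {
    hdr_lines <- readLines(path, warn = FALSE)
    payload <- NULL
  }
  kv <- parse_mhd_header(hdr_lines)
  if (!identical(kv$NDims, "3"))
    stop_ms("ms_format_error", "MetaImage must have NDims = 3")
  if (identical(toupper(kv$CompressedData %||% "FALSE"), "TRUE"))
    stop_ms("ms_format_error", "compressed MetaImage is not supported")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(kv$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  org <- as.numeric(strsplit(kv$Offset %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(kv$TransformMatrix %||% "1 0 0 0 1 0 0 0 1",
                            "\\s+")[[1]])
  if (max(abs(matrix(tm, 3, 3) - diag(3))) > 1e-6)
    stop_ms("ms_orientation_error",
            "non-axis-aligned orientation matrix is not supported")
  tp <- mhd_types[[kv$ElementType]]
  if (is.null(tp)) stop_ms("ms_format_error", "unsupported ElementType %s", kv$ElementType)
  n <- prod(dims)
  if (identical(kv$ElementDataFile, "LOCAL")) {
    if (is.null(payload)) stop_ms("ms_format_error", "LOCAL data in .mhd header")
    vals <- readBin(payload, tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), kv$ElementDataFile)
    vals <- readBin(rawpath, tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = "little")
  }
  if (length(vals) < n) stop_ms("ms_format_error", "truncated MetaImage data")
  if (is.double(vals) && max(abs(vals - round(vals))) > 1e-6)
    stop_ms("ms_format_error", "volume has non-integer voxel values")
  label_volume(array(as.integer(round(vals)), dims), spacing = sp, origin = org)
}

write_metaimage <- function(vol, path) {
  g <- vol$grid
  storage.mode(g) <- "integer"
  mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (mha) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                               ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(dim(g), collapse = " ")),
    "ElementType = MET_INT",
    paste("ElementDataFile =", datafile)
  )
  if (mha) {
    con <- file(path, "wb")
    writeLines(hdr, con)
    writeBin(as.vector(g), con, size = 4, endian = "little")
    close(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.vector(g), con, size = 4, endian = "little")
    close(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
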