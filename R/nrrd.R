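# Minimal NRRD0004 reader/writer for 3-D volumes.
#
# Supports the subset of the format the package emits and the source CT
# datasets use: raw / gzip / ascii encodings, little or big endian,
# integer and float scalar types, per-axis "spacings" or diagonal
# "space directions". Axis order on disk is NRRD's fastest-first
# (col, row, slice); volumes are permuted to the internal
# (slice, row, col) layout on read.

.nrrd_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE)
)

.nrrd_type_aliases <- c(
  "unsigned char" = "uint8", "uchar" = "uint8",
  "short" = "int16", "signed short" = "int16", "short int" = "int16",
  "unsigned short" = "uint16", "ushort" = "uint16",
  "int" = "int32", "signed int" = "int32"
)

.nrrd_norm_type <- function(type) {
  type <- trimws(type)
  if (type %in% names(.nrrd_type_aliases)) type <- .nrrd_type_aliases[[type]]
  if (!type %in% names(.nrrd_types))
    stop("unsupported NRRD type: ", type, call. = FALSE)
  type
}

.nrrd_parse_header <- function(raw_bytes) {
  # header ends at the first empty line (\n\n or \r\n\r\n)
  n <- length(raw_bytes)
  end <- NA_integer_
  i <- 1L
  nl <- as.raw(0x0a); cr <- as.raw(0x0d)
  while (i < n) {
    if (raw_bytes[i] == nl) {
      j <- i + 1L
      if (j <= n && raw_bytes[j] == cr) j <- j + 1L
      if (j <= n && raw_bytes[j] == nl) { end <- i; break }
    }
    i <- i + 1L
  }
  if (is.na(end)) stop("unparseable header: no blank line terminator", call. = FALSE)
  hdr_txt <- rawToChar(raw_bytes[seq_len(end - 1L)])
  data_start <- i + if (i + 1L <= n && raw_bytes[i + 1L] == cr) 3L else 2L
  lines <- strsplit(hdr_txt, "\r?\n")[[1]]
  if (!grepl("^NRRD000[0-9]$", lines[1]))
    stop("unparseable header: missing NRRD magic", call. = FALSE)
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    m <- regexpr(":=?", ln)
    if (m < 0) next
    key <- tolower(trimws(substr(ln, 1, m - 1)))
    val <- trimws(substr(ln, m + attr(m, "match.length"), nchar(ln)))
    fields[[key]] <- val
  }
  list(fields = fields, data_start = data_start)
}

.nrrd_spacings <- function(fields, dimension) {
  if (!is.null(fields[["spacings"]]))
    return(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]))
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(vecs, function(v) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1))
    return(unname(sp))
  }
  rep(1, dimension)
}

read_nrrd <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  h <- .nrrd_parse_header(raw_bytes)
  f <- h$fields
  dimension <- as.integer(f[["dimension"]])
  if (is.na(dimension)) stop("unparseable header: no dimension", call. = FALSE)
  if (dimension != 3L)
    stop("non-3D payload: dimension is ", dimension, call. = FALSE)
  sizes <- as.integer(strsplit(f[["sizes"]], "\\s+")[[1]])
  type <- .nrrd_norm_type(f[["type"]])
  ti <- .nrrd_types[[type]]
  encoding <- tolower(if (is.null(f[["encoding"]])) "raw" else f[["encoding"]])
  endian <- tolower(if (is.null(f[["endian"]])) "little" else f[["endian"]])
  n_vals <- prod(sizes)
  payload <- raw_bytes[h$data_start:length(raw_bytes)]
  vals <- switch(encoding,
    raw = readBin(payload, ti$what, n = n_vals, size = ti$size,
                  signed = ti$signed, endian = endian),
    gzip = , gz = readBin(memDecompress(payload, type = "gzip"), ti$what,
                          n = n_vals, size = ti$size, signed = ti$signed,
                          endian = endian),
    txt = , text = , ascii = as.numeric(strsplit(trimws(rawToChar(payload)),
                                                 "\\s+")[[1]]),
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE))
  if (length(vals) < n_vals)
    stop("unparseable payload: expected ", n_vals, " values, got ",
         length(vals), call. = FALSE)
  arr <- array(vals[seq_len(n_vals)], dim = sizes)  # (col, row, slice)
  sp <- .nrrd_spacings(f, dimension)
  list(data = aperm(arr, c(3, 2, 1)),               # (slice, row, col)
       spacings = sp)                               # (col, row, slice) mm
}

write_nrrd <- function(data, path, spacings = c(1, 1, 1), type = "double",
                       encoding = "raw") {
  stopifnot(length(dim(data)) == 3L, length(spacings) == 3L)
  type <- .nrrd_norm_type(type)
  ti <- .nrrd_types[[type]]
  arr <- aperm(data, c(3, 2, 1))  # (col, row, slice), col fastest on disk
  header <- paste0(
    "NRRD0004\n",
    "type: ", type, "\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(arr), collapse = " "), "\n",
    "spacings: ", paste(format(spacings, digits = 17, trim = TRUE,
                               scientific = FALSE), collapse = " "), "\n",
    "endian: little\n",
    "encoding: ", encoding, "\n",
    "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  vec <- as.vector(arr)
  if (ti$what == "integer") vec <- as.integer(round(vec)) else vec <- as.double(vec)
  if (encoding == "raw") {
    writeBin(vec, con, size = ti$size, endian = "little")
  } else if (encoding %in% c("gzip", "gz")) {
    tmp <- memCompress(writeBin(vec, raw(), size = ti$size, endian = "little"),
                       type = "gzip")
    writeBin(tmp, con)
  } else if (encoding %in% c("ascii", "text", "txt")) {
    writeBin(charToRaw(paste(format(vec, digits = 17, trim = TRUE),
                             collapse = " ")), con)
  } else stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  invisible(path)
}
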