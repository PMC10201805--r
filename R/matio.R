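# Minimal MAT v5 (Level 5 MAT-file) codec: enough to exchange named numeric
# arrays with MATLAB/scipy. Little-endian only; uncompressed elements are
# written, compressed (zlib) elements are decompressed on read when the
# platform zlib supports it.

.mat_mi <- c(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
             UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L, UINT64 = 13L,
             MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L)

.mat_numeric_classes <- 6:13 # mxDOUBLE..mxUINT32 (see MAT v5 spec)

.pad8 <- function(nbytes) (8L - nbytes %% 8L) %% 8L

.mat_write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

.mat_write_element <- function(con, type, raw_data) {
  .mat_write_tag(con, type, length(raw_data))
  writeBin(raw_data, con)
  pad <- .pad8(length(raw_data))
  if (pad > 0L) writeBin(raw(pad), con)
}

# vars: named list of numeric vectors/matrices
write_mat5 <- function(path, vars) {
  stopifnot(is.list(vars), length(vars) >= 1L, !is.null(names(vars)),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, created by eegseize")
  hraw <- c(charToRaw(header), rep(charToRaw(" "), 116L - nchar(header)))
  writeBin(hraw, con)
  writeBin(raw(8L), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                     # version 0x0100
  writeBin(charToRaw("IM"), con)                           # little-endian
  for (nm in names(vars)) {
    v <- vars[[nm]]
    stopifnot(is.numeric(v))
    dims <- if (is.matrix(v)) dim(v) else c(1L, length(v))
    body <- local({
      bcon <- rawConnection(raw(0), "wb")
      on.exit(close(bcon))
      # array flags: class mxDOUBLE_CLASS = 6
      .mat_write_tag(bcon, .mat_mi[["UINT32"]], 8L)
      writeBin(as.integer(c(6L, 0L)), bcon, size = 4L, endian = "little")
      .mat_write_element(bcon, .mat_mi[["INT32"]], writeBin(as.integer(dims), raw(), size = 4L, endian = "little"))
      .mat_write_element(bcon, .mat_mi[["INT8"]], charToRaw(nm))
      .mat_write_element(bcon, .mat_mi[["DOUBLE"]], writeBin(as.numeric(v), raw(), size = 8L, endian = "little"))
      rawConnectionValue(bcon)
    })
    .mat_write_tag(con, .mat_mi[["MATRIX"]], length(body))
    writeBin(body, con)
  }
  invisible(path)
}

.mat_read_tag <- function(raw_vec, pos) {
  word <- readBin(raw_vec[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  small_nbytes <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_nbytes != 0L) { # small data element: type and data share 8 bytes
    list(type = bitwAnd(word, 0xFFFFL), nbytes = small_nbytes,
         data_pos = pos + 4L, next_pos = pos + 8L, small = TRUE)
  } else {
    nbytes <- readBin(raw_vec[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                      endian = "little")
    list(type = word, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + nbytes + .pad8(nbytes), small = FALSE)
  }
}

.mat_read_numeric <- function(raw_vec, type, nbytes) {
  rd <- function(what, size, signed = TRUE) {
    readBin(raw_vec, what, n = nbytes %/% size, size = size,
            signed = signed, endian = "little")
  }
  switch(as.character(type),
    "1" = rd("integer", 1L), "2" = rd("integer", 1L, signed = FALSE),
    "3" = rd("integer", 2L), "4" = rd("integer", 2L, signed = FALSE),
    "5" = rd("integer", 4L), "6" = as.numeric(rd("integer", 4L)),
    "7" = rd("double", 4L), "9" = rd("double", 8L),
    stop("unsupported MAT data type ", type, call. = FALSE))
}

.mat_parse_matrix <- function(body) {
  pos <- 1L
  tg <- .mat_read_tag(body, pos) # array flags
  flags <- readBin(body[tg$data_pos:(tg$data_pos + 3L)], "integer", size = 4L,
                   endian = "little")
  klass <- bitwAnd(flags, 0xFFL)
  pos <- tg$next_pos
  tg <- .mat_read_tag(body, pos) # dimensions
  dims <- readBin(body[tg$data_pos:(tg$data_pos + tg$nbytes - 1L)], "integer",
                  size = 4L, endian = "little")
  pos <- tg$next_pos
  tg <- .mat_read_tag(body, pos) # name
  nm <- if (tg$nbytes > 0L) {
    rawToChar(body[tg$data_pos:(tg$data_pos + tg$nbytes - 1L)])
  } else ""
  pos <- tg$next_pos
  if (!(klass %in% .mat_numeric_classes)) {
    return(list(name = nm, numeric = FALSE))
  }
  tg <- .mat_read_tag(body, pos) # real part
  vals <- .mat_read_numeric(body[tg$data_pos:(tg$data_pos + tg$nbytes - 1L)],
                            tg$type, tg$nbytes)
  list(name = nm, numeric = TRUE, dims = dims, values = vals)
}

read_mat5 <- function(path) {
  raw_vec <- readBin(path, "raw", n = file.size(path))
  if (length(raw_vec) < 128L) stop("not a MAT v5 file: ", path, call. = FALSE)
  endian <- rawToChar(raw_vec[127:128])
  if (endian == "MI") {
    stop("big-endian MAT files are not supported: ", path, call. = FALSE)
  }
  if (endian != "IM") stop("not a MAT v5 file: ", path, call. = FALSE)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw_vec)) {
    tg <- .mat_read_tag(raw_vec, pos)
    body <- if (tg$nbytes > 0L) {
      raw_vec[tg$data_pos:(tg$data_pos + tg$nbytes - 1L)]
    } else raw(0)
    if (tg$type == .mat_mi[["COMPRESSED"]]) {
      body <- tryCatch(memDecompress(body, type = "gzip"),
                       error = function(e) {
                         stop("cannot decompress MAT element in ", path,
                              " (", conditionMessage(e), ")", call. = FALSE)
                       })
      tg2 <- .mat_read_tag(body, 1L)
      if (tg2$type == .mat_mi[["MATRIX"]]) {
        out[[length(out) + 1L]] <- .mat_parse_matrix(
          body[tg2$data_pos:(tg2$data_pos + tg2$nbytes - 1L)])
      }
    } else if (tg$type == .mat_mi[["MATRIX"]]) {
      out[[length(out) + 1L]] <- .mat_parse_matrix(body)
    }
    pos <- tg$next_pos
  }
  out
}
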