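# Minimal MATLAB Level-5 MAT-file codec: a single uncompressed 2-D numeric
# matrix per file, which is how the classic expression benchmark matrices
# (diagnosis column + genes) are distributed. Compressed elements, cells,
# structs and sparse arrays are out of scope and rejected with a message.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mx_numeric_classes <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)  # double..uint64

#' Read a numeric matrix from a MATLAB MAT-file
#'
#' Reads the first 2-D numeric array of an uncompressed Level-5 MAT-file.
#' Intended for expression matrices whose first column is the diagnosis
#' code. Files written by `scipy.io.savemat(..., do_compression=False)` or
#' by [write_mat_matrix()] are supported.
#'
#' @param path file to read.
#' @return A numeric matrix.
#' @export
read_mat_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 128L)
  if (length(header) < 128L) stop("not a MAT-file: truncated header", call. = FALSE)
  magic <- rawToChar(header[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop("not a Level-5 MAT-file (bad endian indicator)", call. = FALSE)
  repeat {
    tag <- readBin(con, "raw", 8L)
    if (length(tag) < 8L) stop("no numeric matrix found in MAT-file", call. = FALSE)
    dtype <- readBin(tag[1:4], "integer", 1L, 4L, endian = endian)
    nbytes <- readBin(tag[5:8], "integer", 1L, 4L, endian = endian)
    if (dtype == MI_COMPRESSED) {
      stop("compressed MAT elements are not supported; ",
           "re-save without compression", call. = FALSE)
    }
    body <- readBin(con, "raw", nbytes)
    pad <- (8L - nbytes %% 8L) %% 8L
    if (pad > 0L) readBin(con, "raw", pad)
    if (dtype != MI_MATRIX) next
    m <- parse_mi_matrix(body, endian)
    if (!is.null(m)) return(m)
  }
}

# Parse one miMATRIX element body; NULL when not a plain 2-D numeric array.
parse_mi_matrix <- function(body, endian) {
  pos <- 1L
  read_sub <- function() {
    t1 <- readBin(body[pos:(pos + 3L)], "integer", 1L, 4L, endian = endian)
    small_size <- bitwAnd(bitwShiftR(t1, 16L), 0xFFFFL)
    if (small_size > 0L) {  # small data element: type+size packed in 4 bytes
      dtype <- bitwAnd(t1, 0xFFFFL)
      dat <- body[(pos + 4L):(pos + 3L + small_size)]
      pos <<- pos + 8L
    } else {
      dtype <- t1
      nb <- readBin(body[(pos + 4L):(pos + 7L)], "integer", 1L, 4L, endian = endian)
      dat <- if (nb > 0L) body[(pos + 8L):(pos + 7L + nb)] else raw(0)
      pos <<- pos + 8L + nb + (8L - nb %% 8L) %% 8L
    }
    list(dtype = dtype, data = dat)
  }
  flags <- read_sub()
  klass <- as.integer(flags$data[if (endian == "little") 1L else 4L])
  if (!klass %in% mx_numeric_classes) return(NULL)
  dims_el <- read_sub()
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) %/% 4L, 4L,
                  endian = endian)
  if (length(dims) != 2L) return(NULL)
  read_sub()  # array name, unused
  re <- read_sub()
  vals <- decode_mi_numeric(re$data, re$dtype, endian)
  if (length(vals) != prod(dims)) {
    stop("corrupt MAT-file: data length does not match dimensions", call. = FALSE)
  }
  matrix(vals, nrow = dims[1], ncol = dims[2])  # column-major, as stored
}

decode_mi_numeric <- function(data, dtype, endian) {
  spec <- switch(as.character(dtype),
    "1" = list(what = "integer", size = 1L, signed = TRUE),
    "2" = list(what = "integer", size = 1L, signed = FALSE),
    "3" = list(what = "integer", size = 2L, signed = TRUE),
    "4" = list(what = "integer", size = 2L, signed = FALSE),
    "5" = list(what = "integer", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 4L, signed = TRUE),
    "7" = list(what = "double", size = 4L, signed = TRUE),
    "9" = list(what = "double", size = 8L, signed = TRUE),
    stop("unsupported MAT numeric storage type ", dtype, call. = FALSE))
  as.numeric(readBin(data, spec$what, length(data) %/% spec$size, spec$size,
                     signed = spec$signed, endian = endian))
}

#' Write a numeric matrix as a MATLAB MAT-file
#'
#' Writes a Level-5 MAT-file containing one uncompressed double-precision
#' 2-D array, readable by MATLAB, Octave, `scipy.io.loadmat` and
#' [read_mat_matrix()].
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param name variable name stored in the file. Default `"data"`.
#' @return `path`, invisibly.
#' @export
write_mat_matrix <- function(m, path, name = "data") {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by apiselect"))
  header <- raw(128L)
  header[seq_along(desc)] <- desc
  header[(length(desc) + 1L):116L] <- as.raw(32L)  # space padding
  header[125:126] <- writeBin(0x0100L, raw(), size = 2L, endian = "little")
  header[127:128] <- charToRaw("IM")
  writeBin(header, con)

  sub_element <- function(dtype, data) {
    nb <- length(data)
    pad <- (8L - nb %% 8L) %% 8L
    c(writeBin(as.integer(dtype), raw(), size = 4L, endian = "little"),
      writeBin(as.integer(nb), raw(), size = 4L, endian = "little"),
      data, raw(pad))
  }
  flags <- raw(8L)
  flags[1] <- as.raw(6L)  # mxDOUBLE_CLASS
  body <- c(
    sub_element(MI_UINT32, flags),
    sub_element(MI_INT32, writeBin(as.integer(dim(m)), raw(), size = 4L,
                                   endian = "little")),
    sub_element(MI_INT8, charToRaw(name)),
    sub_element(MI_DOUBLE, writeBin(as.vector(m), raw(), size = 8L,
                                    endian = "little"))
  )
  writeBin(as.integer(MI_MATRIX), con, size = 4L, endian = "little")
  writeBin(length(body), con, size = 4L, endian = "little")
  writeBin(body, con)
  invisible(path)
}
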