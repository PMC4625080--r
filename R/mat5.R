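# Minimal read-only MAT v5 parser used by the BioPatRec bridge.
# Supports little-endian, uncompressed files containing numeric arrays,
# char arrays, cell arrays and (1x1) structs -- the elements a BioPatRec
# recording-session file uses. Compressed (miCOMPRESSED) elements and
# sparse/complex arrays are rejected with a clear error.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_SPARSE <- 5L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

mat5_read_numeric <- function(raw, type, nbytes) {
  switch(as.character(type),
    "1" = readBin(raw, "integer", n = nbytes, size = 1L, signed = TRUE),
    "2" = readBin(raw, "integer", n = nbytes, size = 1L, signed = FALSE),
    "3" = readBin(raw, "integer", n = nbytes / 2L, size = 2L, signed = TRUE,
                  endian = "little"),
    "4" = readBin(raw, "integer", n = nbytes / 2L, size = 2L, signed = FALSE,
                  endian = "little"),
    "5" = readBin(raw, "integer", n = nbytes / 4L, size = 4L,
                  endian = "little"),
    "6" = {
      v <- readBin(raw, "integer", n = nbytes / 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = readBin(raw, "double", n = nbytes / 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(raw, "double", n = nbytes / 8L, size = 8L,
                  endian = "little"),
    "16" = readBin(raw, "integer", n = nbytes, size = 1L, signed = FALSE),
    stop_param("unsupported MAT data type %d", type)
  )
}

# read one data element starting at offset pos (1-based); returns
# list(type, data = raw payload, next_pos)
mat5_element <- function(raw, pos) {
  type_word <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L,
                       endian = "little")
  small_nbytes <- bitwAnd(bitwShiftR(type_word, 16L), 0xFFFFL)
  if (small_nbytes > 0L) {
    type <- bitwAnd(type_word, 0xFFFFL)
    data <- raw[(pos + 4L):(pos + 3L + small_nbytes)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- type_word
  nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                    endian = "little")
  data <- if (nbytes > 0L) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
  padded <- 8L * ceiling(nbytes / 8)
  list(type = type, data = data, next_pos = pos + 8L + padded)
}

mat5_parse_matrix <- function(raw) {
  pos <- 1L
  flags_el <- mat5_element(raw, pos); pos <- flags_el$next_pos
  flags <- readBin(flags_el$data[1:4], "integer", size = 4L, endian = "little")
  class_id <- bitwAnd(flags, 0xFFL)
  if (class_id == MX_SPARSE) stop_param("sparse MAT arrays are not supported")
  if (bitwAnd(bitwShiftR(flags, 8L), 0x08L) != 0L)
    stop_param("complex MAT arrays are not supported")
  dims_el <- mat5_element(raw, pos); pos <- dims_el$next_pos
  dims <- mat5_read_numeric(dims_el$data, dims_el$type, length(dims_el$data))
  name_el <- mat5_element(raw, pos); pos <- name_el$next_pos
  name <- rawToChar(as.raw(name_el$data[name_el$data != as.raw(0)]))

  if (class_id %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                      MX_UINT16, MX_INT32, MX_UINT32)) {
    re_el <- mat5_element(raw, pos)
    v <- mat5_read_numeric(re_el$data, re_el$type, length(re_el$data))
    value <- array(as.numeric(v), dim = dims)
    if (length(dims) == 2L) value <- matrix(value, dims[1], dims[2])
  } else if (class_id == MX_CHAR) {
    ch_el <- mat5_element(raw, pos)
    codes <- mat5_read_numeric(ch_el$data, ch_el$type, length(ch_el$data))
    # char arrays come column-major; flatten row-wise strings
    m <- matrix(codes, nrow = dims[1], ncol = dims[2])
    value <- apply(m, 1L, function(row) intToUtf8(row[row != 0]))
    if (length(value) == 1L) value <- value[[1]]
  } else if (class_id == MX_CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      el <- mat5_element(raw, pos); pos <- el$next_pos
      if (el$type != MI_MATRIX) stop_param("malformed cell array element")
      sub <- mat5_parse_matrix(el$data)
      value[[i]] <- sub$value
    }
  } else if (class_id == MX_STRUCT) {
    len_el <- mat5_element(raw, pos); pos <- len_el$next_pos
    fname_len <- mat5_read_numeric(len_el$data, len_el$type, 4L)[1]
    names_el <- mat5_element(raw, pos); pos <- names_el$next_pos
    nf <- length(names_el$data) / fname_len
    fields <- vapply(seq_len(nf), function(i) {
      chunk <- names_el$data[((i - 1L) * fname_len + 1L):(i * fname_len)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, character(1))
    n_elem <- prod(dims)
    if (n_elem != 1L)
      stop_param("struct arrays with %d elements are not supported", n_elem)
    value <- stats::setNames(vector("list", nf), fields)
    for (i in seq_len(nf)) {
      el <- mat5_element(raw, pos); pos <- el$next_pos
      if (el$type != MI_MATRIX) stop_param("malformed struct field")
      sub <- mat5_parse_matrix(el$data)
      value[[i]] <- sub$value
    }
  } else {
    stop_param("unsupported MAT array class %d", class_id)
  }
  list(name = name, value = value)
}

#' Read variables from a MAT v5 file
#'
#' Minimal reader for little-endian, uncompressed MAT v5 files containing
#' numeric arrays, char arrays, cell arrays and scalar structs. Intended
#' for the BioPatRec session bridge ([read_biopatrec_session()]); files
#' saved with compression (MATLAB's default `save` since R2008) must be
#' re-saved with `-v6` or `-nocompression`.
#'
#' @param path MAT file path.
#' @return named list of variables.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) stop_param("%s is not a MAT v5 file (too short)", path)
  endian <- rawToChar(raw[127:128])
  if (endian == "MI")
    stop_param("big-endian MAT files are not supported")
  if (endian != "IM")
    stop_param("%s is not a MAT v5 file (bad endian indicator)", path)
  pos <- 129L
  vars <- list()
  while (pos + 7L <= length(raw)) {
    el <- mat5_element(raw, pos)
    pos <- el$next_pos
    if (el$type == MI_COMPRESSED)
      stop_param(paste0("compressed MAT element found; re-save the file ",
                        "uncompressed (MATLAB: save -v6)"))
    if (el$type != MI_MATRIX)
      stop_param("unexpected top-level MAT element type %d", el$type)
    parsed <- mat5_parse_matrix(el$data)
    vars[[parsed$name]] <- parsed$value
  }
  vars
}
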