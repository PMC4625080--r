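# test-only writer of uncompressed little-endian MAT v5 files, used to
# build BioPatRec-layout fixtures for the bridge round-trip tests

m5_int32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")
m5_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                  endian = "little")
m5_double <- function(x) writeBin(as.numeric(x), raw(), size = 8L,
                                  endian = "little")
m5_pad8 <- function(r) c(r, raw((8L - length(r) %% 8L) %% 8L))
m5_elem <- function(type, data) c(m5_int32(c(type, length(data))),
                                  m5_pad8(data))

m5_flags <- function(class_id) m5_elem(6L, m5_int32(c(class_id, 0L)))
m5_dims <- function(d) m5_elem(5L, m5_int32(d))
m5_name <- function(nm) m5_elem(1L, charToRaw(nm))

m5_numeric <- function(nm, m) {
  d <- if (is.matrix(m)) dim(m) else c(1L, length(m))
  m5_elem(14L, c(m5_flags(6L), m5_dims(d), m5_name(nm),
                 m5_elem(9L, m5_double(as.vector(m)))))
}

m5_char <- function(nm, s) {
  m5_elem(14L, c(m5_flags(4L), m5_dims(c(1L, nchar(s))), m5_name(nm),
                 m5_elem(4L, m5_uint16(utf8ToInt(s)))))
}

m5_cell_of_strings <- function(nm, strings) {
  items <- do.call(c, lapply(strings, function(s) m5_char("", s)))
  m5_elem(14L, c(m5_flags(1L), m5_dims(c(length(strings), 1L)),
                 m5_name(nm), items))
}

# fields: named list of raw miMATRIX elements built with empty names
m5_struct <- function(nm, fields) {
  fn <- names(fields)
  fname_raw <- do.call(c, lapply(fn, function(f) {
    r <- charToRaw(f)
    c(r, raw(32L - length(r)))
  }))
  m5_elem(14L, c(m5_flags(2L), m5_dims(c(1L, 1L)), m5_name(nm),
                 m5_elem(5L, m5_int32(32L)),
                 m5_elem(1L, fname_raw),
                 do.call(c, unname(fields))))
}

write_mat5 <- function(path, elements) {
  txt <- sprintf("%-116s", "MATLAB 5.0 MAT-file, synthetic test fixture")
  header <- c(charToRaw(txt), raw(8L), as.raw(c(0x00, 0x01)),
              charToRaw("IM"))
  writeBin(c(header, do.call(c, elements)), path)
}

# BioPatRec-layout recording-session fixture
write_biopatrec_fixture <- function(path, data, sF = 500, mov = c("a", "b"),
                                    nR = 2, cT = 1, rT = 0.5,
                                    extra_fields = list(),
                                    drop_fields = character()) {
  fields <- list(
    data = m5_numeric("", data),
    sF = m5_numeric("", sF),
    mov = m5_cell_of_strings("", mov),
    nR = m5_numeric("", nR),
    cT = m5_numeric("", cT),
    rT = m5_numeric("", rT))
  for (f in names(extra_fields))
    fields[[f]] <- m5_numeric("", extra_fields[[f]])
  fields <- fields[setdiff(names(fields), drop_fields)]
  write_mat5(path, list(m5_struct("recSession", fields)))
  invisible(path)
}
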