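# Build a minimal single-strip 32-bit float grayscale TIFF (little-endian),
# so tests can exercise floating-point weight-map files with values the
# high-level writers refuse to store (e.g. > 1).
make_float_tiff <- function(values, path) {
  h <- nrow(values)
  w <- ncol(values)
  data <- writeBin(as.numeric(t(values)), raw(), size = 4,
                   endian = "little")
  n_tags <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  tag <- function(id, type, count, value) {
    c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
      writeBin(as.integer(type), raw(), size = 2, endian = "little"),
      writeBin(as.integer(count), raw(), size = 4, endian = "little"),
      writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  }
  out <- c(charToRaw("II"),
           writeBin(42L, raw(), size = 2, endian = "little"),
           writeBin(ifd_offset, raw(), size = 4, endian = "little"),
           writeBin(n_tags, raw(), size = 2, endian = "little"),
           tag(256, 3, 1, w), tag(257, 3, 1, h), tag(258, 3, 1, 32),
           tag(259, 3, 1, 1), tag(262, 3, 1, 1),
           tag(273, 4, 1, data_offset), tag(277, 3, 1, 1),
           tag(278, 3, 1, h), tag(279, 4, 1, length(data)),
           tag(339, 3, 1, 3),
           writeBin(0L, raw(), size = 4, endian = "little"),
           data)
  writeBin(out, path)
  invisible(path)
}
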