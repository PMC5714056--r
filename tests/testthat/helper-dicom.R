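# Build a minimal synthetic DICOM CT slice (explicit VR little endian) for
# reader tests. Pixel data are 16-bit; geometry tags as supplied.

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(.le16(group), .le16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .le32(length(value_raw)), value_raw)
  } else {
    c(head, .le16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr,
                                                    charToRaw(s))

write_synthetic_dicom <- function(path, pixels, slope = 1,
                                  intercept = -1024,
                                  spacing = c(1, 1), ipp = c(0, 0, 0),
                                  iop = c(1, 0, 0, 0, 1, 0),
                                  thickness = 2.5) {
  rows <- ncol(pixels)   # pixels is [x, y]; DICOM rows are y
  cols <- nrow(pixels)
  ts <- "1.2.840.10008.1.2.1"
  meta_body <- c(
    dcm_str(0x0002, 0x0010, "UI", ts),
    dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", .le32(length(meta_body))),
            meta_body)
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = "\\")
  # pixel order: row-major, x (column index) fastest
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  ds <- c(
    dcm_str(0x0018, 0x0050, "DS", fmt(thickness)),
    dcm_str(0x0020, 0x0032, "DS", fmt(ipp)),
    dcm_str(0x0020, 0x0037, "DS", fmt(iop)),
    dcm_element(0x0028, 0x0010, "US", .le16(rows)),
    dcm_element(0x0028, 0x0011, "US", .le16(cols)),
    dcm_str(0x0028, 0x0030, "DS", fmt(spacing)),
    dcm_element(0x0028, 0x0100, "US", .le16(16)),
    dcm_element(0x0028, 0x0103, "US", .le16(1)),
    dcm_str(0x0028, 0x1052, "DS", fmt(intercept)),
    dcm_str(0x0028, 0x1053, "DS", fmt(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}
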