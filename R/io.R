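#' Volume I/O
#'
#' Minimal, bit-exact NRRD and MetaImage (.mha) readers/writers and a
#' read-only DICOM CT series reader (explicit VR little endian,
#' uncompressed). NRRD/MetaImage round-trips are bit-identical for double
#' payloads; DICOM rescale slope/intercept are applied to produce HU.
#'
#' @name io
NULL

#' Write a volume as NRRD
#'
#' Raw little-endian payload, first (x) axis fastest; spacing/origin in mm
#' and the volume's metadata stored as `ctmar:<key>` key-value fields.
#'
#' @param vol a `ct_volume`.
#' @param path output path (`.nrrd`).
#' @return invisible `path`.
#' @export
write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(dim(vol$data), collapse = " ")),
           paste0("spacings: ", paste(format(vol$spacing, digits = 17),
                                      collapse = " ")),
           "encoding: raw",
           "endian: little",
           paste0("ctmar:origin:=", paste(format(vol$origin, digits = 17),
                                          collapse = " ")),
           paste0("ctmar:kind:=", vol$kind))
  for (k in names(vol$meta)) {
    v <- vol$meta[[k]]
    if (is.character(v) || is.numeric(v))
      if (length(v) == 1)
        hdr <- c(hdr, paste0("ctmar:", k, ":=", as.character(v)))
  }
  writeLines(c(hdr, ""), con, sep = "\n")
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the subset written by [write_nrrd()] plus int16/int32/float
#' types and ascii encoding.
#'
#' @param path `.nrrd` file.
#' @return a `ct_volume`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list(); kv <- list()
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0 || !nzchar(ln)) break
    if (startsWith(ln, "#")) next
    if (grepl(":=", ln, fixed = TRUE)) {
      p <- strsplit(ln, ":=", fixed = TRUE)[[1]]
      kv[[trimws(p[1])]] <- trimws(p[2])
    } else {
      p <- strsplit(ln, ":", fixed = TRUE)[[1]]
      fields[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = ":"))
    }
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  if (!is.null(fields$dimension) && as.integer(fields$dimension) != length(sizes))
    stop("inconsistent NRRD dimension field")
  if (enc %in% c("raw")) {
    endian <- if (is.null(fields$endian)) "little" else fields$endian
    data <- switch(type,
      double = readBin(con, numeric(), n, size = 8, endian = endian),
      float = readBin(con, numeric(), n, size = 4, endian = endian),
      int = ,
      int32 = readBin(con, integer(), n, size = 4, endian = endian),
      short = ,
      int16 = readBin(con, integer(), n, size = 2, signed = TRUE,
                      endian = endian),
      uchar = ,
      uint8 = readBin(con, integer(), n, size = 1, signed = FALSE),
      stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("ascii", "text", "txt")) {
    data <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(data) != n) stop("truncated NRRD payload in ", path)
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv[["ctmar:origin"]]))
    as.numeric(strsplit(kv[["ctmar:origin"]], "\\s+")[[1]]) else NULL
  kind <- if (!is.null(kv[["ctmar:kind"]])) kv[["ctmar:kind"]] else "raw"
  meta <- kv[setdiff(names(kv), c("ctmar:origin", "ctmar:kind"))]
  names(meta) <- sub("^ctmar:", "", names(meta))
  ct_volume(array(data, sizes), spacing, origin, kind = kind, meta = meta)
}

#' Write a volume as MetaImage (single-file .mha)
#'
#' @param vol a `ct_volume`.
#' @param path output path (`.mha`).
#' @return invisible `path`.
#' @export
write_mha <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                           collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 17),
                                   collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume (.mha with LOCAL payload or .mhd + raw)
#'
#' @param path `.mha` or `.mhd` file.
#' @return a `ct_volume`.
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) stop("no ElementDataFile field in ", path)
    p <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = "="))
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  sizes <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$ElementType
  read_payload <- function(conn) switch(type,
    MET_DOUBLE = readBin(conn, numeric(), n, size = 8, endian = "little"),
    MET_FLOAT = readBin(conn, numeric(), n, size = 4, endian = "little"),
    MET_INT = readBin(conn, integer(), n, size = 4, endian = "little"),
    MET_SHORT = readBin(conn, integer(), n, size = 2, signed = TRUE,
                        endian = "little"),
    stop("unsupported MetaImage ElementType: ", type))
  if (identical(fields$ElementDataFile, "LOCAL")) {
    data <- read_payload(con)
  } else {
    raw_path <- file.path(dirname(path), fields$ElementDataFile)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    data <- read_payload(rcon)
  }
  if (length(data) != n) stop("truncated MetaImage payload in ", path)
  spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(fields$Offset))
    as.numeric(strsplit(fields$Offset, "\\s+")[[1]]) else NULL
  ct_volume(array(data, sizes), spacing, origin)
}

# ---- minimal DICOM (explicit VR little endian, uncompressed) ----

.dcm_u16 <- function(raw, off) as.integer(raw[off + 1]) +
  256L * as.integer(raw[off + 2])
.dcm_u32 <- function(raw, off) .dcm_u16(raw, off) + 65536 * .dcm_u16(raw, off + 2)

# parse one explicit-VR-LE dataset; returns named list tag -> raw value
parse_dicom_elements <- function(raw, off, stop_at_pixeldata = TRUE) {
  out <- list()
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    group <- .dcm_u16(raw, off); elem <- .dcm_u16(raw, off + 2)
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (vr %in% long_vrs) {
      len <- .dcm_u32(raw, off + 8)
      voff <- off + 12
    } else {
      len <- .dcm_u16(raw, off + 6)
      voff <- off + 8
    }
    if (len == 4294967295) stop("undefined-length DICOM element unsupported")
    tag <- sprintf("%04X%04X", group, elem)
    out[[tag]] <- list(vr = vr, value = raw[(voff + 1):(voff + len)])
    off <- voff + len
    if (stop_at_pixeldata && tag == "7FE00010") break
  }
  out
}

dcm_string <- function(el) if (is.null(el)) NULL else
  trimws(rawToChar(el$value))
dcm_numbers <- function(el) if (is.null(el)) NULL else
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # file meta group (always explicit LE)
  off <- 132
  meta <- parse_dicom_elements(raw, off, stop_at_pixeldata = FALSE)
  # meta ends where group != 0002; re-parse conservatively: find meta length
  ts <- dcm_string(meta[["00020010"]])
  if (!is.null(meta[["00020000"]])) {
    meta_len <- readBin(meta[["00020000"]]$value, integer(), 1, size = 4,
                        endian = "little")
    # meta group length counts bytes after its own element
    hdr_end <- 132 + 12 + meta_len
  } else stop("missing DICOM meta group length in ", path)
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported DICOM transfer syntax (only explicit VR little endian): ", ts)
  els <- parse_dicom_elements(raw, hdr_end)
  rows <- readBin(els[["00280010"]]$value, integer(), 1, size = 2,
                  signed = FALSE, endian = "little")
  cols <- readBin(els[["00280011"]]$value, integer(), 1, size = 2,
                  signed = FALSE, endian = "little")
  signed <- !is.null(els[["00280103"]]) &&
    readBin(els[["00280103"]]$value, integer(), 1, size = 2,
            endian = "little") == 1L
  slope <- dcm_numbers(els[["00281053"]]); if (is.null(slope)) slope <- 1
  intercept <- dcm_numbers(els[["00281052"]]); if (is.null(intercept)) intercept <- 0
  px_spacing <- dcm_numbers(els[["00280030"]]); if (is.null(px_spacing)) px_spacing <- c(1, 1)
  ipp <- dcm_numbers(els[["00200032"]]); if (is.null(ipp)) ipp <- c(0, 0, 0)
  iop <- dcm_numbers(els[["00200037"]]); if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
  thick <- dcm_numbers(els[["00180050"]]); if (is.null(thick)) thick <- 1
  px <- readBin(els[["7FE00010"]]$value, integer(), rows * cols, size = 2,
                signed = signed, endian = "little")
  hu <- px * slope + intercept
  # DICOM pixel order is row-major, i.e. x (column index) fastest
  img <- matrix(hu, nrow = cols, ncol = rows)
  list(img = img, rows = rows, cols = cols, spacing = px_spacing,
       ipp = ipp, iop = iop, thick = thick)
}

#' Read a DICOM CT series
#'
#' Reads every file in a directory as explicit-VR little-endian CT slices,
#' applies rescale slope/intercept to HU, verifies a single orientation and
#' consistent in-plane/axial spacing, and stacks slices by position along
#' the slice normal. Mixed orientations or non-uniform spacing raise
#' errors; slices are never silently reordered onto an inconsistent grid.
#'
#' @param dir directory containing the series.
#' @return an HU `ct_volume`.
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files)) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, read_dicom_slice)
  iop0 <- slices[[1]]$iop
  for (s in slices) {
    if (max(abs(s$iop - iop0)) > 1e-6)
      stop("mixed-orientation DICOM series in ", dir)
    if (max(abs(s$spacing - slices[[1]]$spacing)) > 1e-6)
      stop("inconsistent DICOM pixel spacing in ", dir)
    if (s$rows != slices[[1]]$rows || s$cols != slices[[1]]$cols)
      stop("inconsistent DICOM matrix size in ", dir)
  }
  normal <- c(iop0[2] * iop0[6] - iop0[3] * iop0[5],
              iop0[3] * iop0[4] - iop0[1] * iop0[6],
              iop0[1] * iop0[5] - iop0[2] * iop0[4])
  pos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  dz <- if (length(pos) > 1) diff(pos) else slices[[1]]$thick
  if (length(pos) > 2 && max(abs(diff(dz))) > 1e-3)
    stop("inconsistent DICOM slice spacing in ", dir)
  dz1 <- if (length(pos) > 1) dz[1] else slices[[1]]$thick
  arr <- array(0, c(slices[[1]]$cols, slices[[1]]$rows, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$img
  ct_volume(arr, c(slices[[1]]$spacing[2], slices[[1]]$spacing[1], dz1),
            origin = c(slices[[1]]$ipp[1], slices[[1]]$ipp[2], pos[1]),
            kind = "HU")
}

#' Read a volume from NRRD, MetaImage or a DICOM series directory
#'
#' @param path `.nrrd`, `.mha`/`.mhd` file or a directory of DICOM slices.
#' @return a `ct_volume`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = read_nrrd(path),
         mha = ,
         mhd = read_mha(path),
         stop("unknown volume format '.", ext,
              "' (supported: .nrrd, .mha, .mhd, DICOM directory)"))
}
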