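# Minimal DICOM slice writer/reader.
#
# Writes single-frame CT image objects in explicit VR little endian with the
# small set of attributes a viewer needs (geometry, photometric, rescale).
# The companion reader parses exactly this profile and is used for round-trip
# verification; it is not a general DICOM parser.

uid_root <- "1.2.826.0.1.3680043.10.9431"

dcm_elem <- function(group, element, vr, value_raw) {
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"))
  n <- length(value_raw)
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(n), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(n), raw(), size = 2, endian = "little"), value_raw)
  }
}

dcm_str <- function(s, pad = c("space", "null")) {
  pad <- match.arg(pad)
  r <- charToRaw(s)
  if (length(r) %% 2 == 1)
    r <- c(r, if (pad == "space") charToRaw(" ") else as.raw(0L))
  r
}

dcm_us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")

write_dicom_slice <- function(slice, path, instance, pixel_mm, slice_mm,
                              z_mm) {
  nr <- nrow(slice); nc <- ncol(slice)
  stored <- matrix(as.integer(round(pmin(pmax(slice, -32768), 32767))),
                   nr, nc)
  # signed int16, row-major (columns fastest) as DICOM expects
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  sop_class <- "1.2.840.10008.5.1.4.1.1.2"  # CT Image Storage
  sop_inst <- sprintf("%s.%d.%d", uid_root, as.integer(Sys.getpid()) %% 10000L,
                      instance)
  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_str(sop_class, "null")),
    dcm_elem(0x0008, 0x0018, "UI", dcm_str(sop_inst, "null")),
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem(0x0018, 0x0050, "DS", dcm_str(format(slice_mm))),
    dcm_elem(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_elem(0x0020, 0x0032, "DS", dcm_str(sprintf("0\\0\\%s", format(z_mm)))),
    dcm_elem(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
    dcm_elem(0x0028, 0x0002, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(nr)),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(nc)),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(sprintf("%s\\%s", format(pixel_mm[1]), format(pixel_mm[2])))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0101, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0102, "US", dcm_us(15)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_str("0")),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str("1")),
    dcm_elem(0x7FE0, 0x0010, "OW", px)
  )
  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", dcm_str(sop_class, "null")),
    dcm_elem(0x0002, 0x0003, "UI", dcm_str(sop_inst, "null")),
    dcm_elem(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1", "null")),
    dcm_elem(0x0002, 0x0012, "UI", dcm_str(uid_root, "null"))
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL",
                     writeBin(length(meta_body), raw(), size = 4,
                              endian = "little")),
            meta_body)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

#' Read back a DICOM slice written by this package
#'
#' Parses the explicit-VR little-endian profile produced by
#' [export_volume()] and returns pixel values with the rescale convention
#' applied (slope * stored + intercept).
#'
#' @param path a `.dcm` file written by this package.
#' @return Numeric matrix `[rows, columns]` of rescaled values.
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(bytes[129:132]) != "DICM") stopf("not a DICOM file: %s", path)
  pos <- 133L
  u16 <- function(at) as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
  u32 <- function(at) sum(as.double(bytes[at + 0:3]) * 256^(0:3))
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- bytes[data_at + seq_len(len) - 1L]
    pos <- data_at + len
  }
  getstr <- function(key) trimws(rawToChar(tags[[key]]))
  nr <- u16o(tags[["0028,0010"]]); nc <- u16o(tags[["0028,0011"]])
  slope <- as.numeric(getstr("0028,1053"))
  inter <- as.numeric(getstr("0028,1052"))
  px <- readBin(tags[["7fe0,0010"]], "integer", n = nr * nc, size = 2L,
                signed = TRUE, endian = "little")
  t(matrix(px, nrow = nc, ncol = nr)) * slope + inter
}

u16o <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])
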