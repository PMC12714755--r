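#' Raw detector frame format specification
#'
#' Describes the headerless raw frame format used by the detector: 16-bit
#' unsigned little-endian words in row-major order (row by row, channels
#' varying fastest).  The instrument's full frame is 2063 channels wide by
#' 505 effective rows (513 physical rows minus four cropped from each edge).
#'
#' @param width number of detector channels (horizontal), default 2063.
#' @param height number of detector rows (vertical), default 505.
#' @return An object of class `raw_frame_spec`.
#' @export
raw_frame_spec <- function(width = 2063L, height = 505L) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stopf("frame dimensions must be >= 1")
  structure(list(width = width, height = height, bytes = 2L,
                 byte_order = "little"),
            class = "raw_frame_spec")
}

#' Construct a projection image
#'
#' A projection image is a numeric matrix of detector readings laid out as
#' `[row, channel]` with metadata: the energy bin it was acquired in (or
#' derived for), its view angle, and whether values are photon counts or
#' air-corrected log projections.
#'
#' @param values numeric matrix, rows = detector rows, cols = channels.
#' @param bin one of `"total"`, `"high"`, `"low"`.
#' @param kind `"counts"` (integers) or `"log"` (line integrals, unitless).
#' @param angle_deg view angle in degrees, `NA` for flats.
#' @return A `proj_image` (matrix with metadata attributes).
#' @export
proj_image <- function(values, bin = c("total", "high", "low"),
                       kind = c("counts", "log"), angle_deg = NA_real_) {
  bin <- match.arg(bin); kind <- match.arg(kind)
  if (!is.matrix(values)) stopf("projection values must be a matrix")
  structure(values, bin = bin, kind = kind, angle_deg = angle_deg,
            class = c("proj_image", class(values)))
}

proj_bin  <- function(img) attr(img, "bin")
proj_kind <- function(img) attr(img, "kind")

#' Bundle per-view frames into a projection stack
#'
#' @param data 3-D array `[rows, channels, n_views]`, or a list of
#'   `proj_image` frames sharing bin/kind.
#' @param angles_deg strictly increasing view angles (degrees).
#' @param bin,kind metadata shared by all frames.
#' @return A `proj_stack` object.
#' @export
proj_stack <- function(data, angles_deg, bin = "total", kind = "counts") {
  if (is.list(data)) {
    bin <- proj_bin(data[[1]]); kind <- proj_kind(data[[1]])
    same <- vapply(data, function(f)
      identical(dim(f), dim(data[[1]])) && identical(proj_bin(f), bin) &&
        identical(proj_kind(f), kind), logical(1))
    if (!all(same)) stopf("all frames in a stack must share shape, bin and kind")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)))
  }
  if (length(dim(data)) != 3L) stopf("stack data must be [rows, channels, views]")
  if (dim(data)[3] != length(angles_deg))
    stopf("number of frames (%d) != number of angles (%d)",
          dim(data)[3], length(angles_deg))
  if (length(angles_deg) > 1 && any(diff(angles_deg) <= 0))
    stopf("stack angles must be strictly increasing")
  structure(list(data = data, angles_deg = as.numeric(angles_deg),
                 bin = bin, kind = kind),
            class = "proj_stack")
}

#' @export
print.proj_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<proj_stack> %s/%s: %d rows x %d channels x %d views (%.2f..%.2f deg)\n",
              x$bin, x$kind, d[1], d[2], d[3],
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

n_views <- function(stack) dim(stack$data)[3]

stack_frame <- function(stack, k) {
  proj_image(stack$data[, , k], bin = stack$bin, kind = stack$kind,
             angle_deg = stack$angles_deg[k])
}

#' Read a raw detector frame
#'
#' Decodes a headerless 16-bit unsigned little-endian frame file written in
#' row-major order (channels varying fastest) into a counts-kind
#' [proj_image].
#'
#' @param path file to read.
#' @param spec a [raw_frame_spec]; defaults to the full-detector format.
#' @param bin energy-bin tag to attach.
#' @param angle_deg view angle to attach.
#' @return A `proj_image` of kind `"counts"`.
#' @export
read_raw_frame <- function(path, spec = raw_frame_spec(), bin = "total",
                           angle_deg = NA_real_) {
  if (!file.exists(path)) stopf("raw frame not found: %s", path)
  expected <- 2 * as.double(spec$width) * spec$height
  actual <- file.size(path)
  if (actual != expected)
    stopf("raw frame size mismatch for %s: expected %.0f bytes, got %.0f",
          path, expected, actual)
  con <- file(path, "rb"); on.exit(close(con))
  words <- readBin(con, what = "integer", n = spec$width * spec$height,
                   size = 2L, signed = FALSE, endian = "little")
  # row-major file order -> [row, channel] matrix
  values <- matrix(words, nrow = spec$height, ncol = spec$width, byrow = TRUE)
  proj_image(values, bin = bin, kind = "counts", angle_deg = angle_deg)
}

#' Write a raw detector frame
#'
#' Byte-exact inverse of [read_raw_frame]: 16-bit unsigned little-endian,
#' row-major.
#'
#' @param img counts-kind `proj_image` (or plain integer matrix) with all
#'   values in `[0, 65535]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raw_frame <- function(img, path) {
  if (inherits(img, "proj_image") && proj_kind(img) != "counts")
    stopf("only counts-kind frames can be written as raw")
  v <- round(unclass(img))
  if (any(v < 0 | v > 65535))
    stopf("raw frame values out of 16-bit range [0, 65535]")
  words <- as.integer(t(v))  # row-major
  # encode unsigned 16-bit through raw bytes (writeBin has no unsigned size=2)
  lo <- as.raw(words %% 256L)
  hi <- as.raw(words %/% 256L)
  bytes <- as.raw(rbind(lo, hi))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

#' Scan a dataset directory tree into a file manifest
#'
#' Understands the three on-disk layouts the instrument writes:
#' * `walnut_couch`: `<root>/{High,Total}/proj_<j>.raw`, `j` 1-based and
#'   zero-padded to five digits;
#' * `slab_series`: `<root>/PMMA_<m>_AL_<n>/proj_{high,total}.raw` with slab
#'   thicknesses `m`, `n` in mm encoded in the folder name;
#' * `flat`: `<root>/air_table_<bin>.raw` averaged flat fields.
#'
#' @param root directory to scan.
#' @param layout one of `"walnut_couch"`, `"slab_series"`, `"flat"`.
#' @return A data.frame manifest with columns `bin`, `index` (0-based view
#'   index, `NA` where not applicable), `pmma_mm`, `al_mm`, `path`.
#' @export
scan_directory <- function(root,
                           layout = c("walnut_couch", "slab_series", "flat")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stopf("directory not found: %s", root)
  if (layout == "walnut_couch") {
    rows <- list()
    for (bf in c("Total", "High")) {
      sub <- file.path(root, bf)
      if (!dir.exists(sub))
        stopf("missing energy-bin folder '%s' under %s", bf, root)
      files <- sort(list.files(sub, pattern = "^proj_\\d+\\.raw$"))
      if (length(files) == 0L)
        stopf("no projection files in %s", sub)
      j <- as.integer(sub("^proj_(\\d+)\\.raw$", "\\1", files))
      o <- order(j); files <- files[o]; j <- j[o]
      if (!identical(j, seq_len(max(j))[seq_along(j)]) ||
          any(diff(j) != 1L) || j[1] != 1L) {
        miss <- setdiff(seq(j[1], j[length(j)]), j)
        if (length(miss))
          warnf("non-contiguous view indices in %s: missing %s", sub,
                paste(head(miss, 10), collapse = ", "))
      }
      rows[[bf]] <- data.frame(bin = tolower(bf), index = j - 1L,
                               pmma_mm = NA_real_, al_mm = NA_real_,
                               path = file.path(sub, files),
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  if (layout == "slab_series") {
    dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
    dirs <- grep("^PMMA_[0-9.]+_AL_[0-9.]+$", dirs, value = TRUE)
    if (length(dirs) == 0L) stopf("no PMMA_<m>_AL_<n> folders under %s", root)
    rows <- lapply(dirs, function(d) {
      m <- as.numeric(sub("^PMMA_([0-9.]+)_AL_([0-9.]+)$", "\\1", d))
      n <- as.numeric(sub("^PMMA_([0-9.]+)_AL_([0-9.]+)$", "\\2", d))
      out <- NULL
      for (b in c("total", "high")) {
        f <- file.path(root, d, sprintf("proj_%s.raw", b))
        if (!file.exists(f)) stopf("missing %s in %s", basename(f), d)
        out <- rbind(out, data.frame(bin = b, index = NA_integer_,
                                     pmma_mm = m, al_mm = n, path = f,
                                     stringsAsFactors = FALSE))
      }
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  # flat layout
  files <- list.files(root, pattern = "^air_table_(total|high|low)\\.raw$")
  if (length(files) == 0L) stopf("no air_table_<bin>.raw files under %s", root)
  data.frame(bin = sub("^air_table_(.*)\\.raw$", "\\1", files),
             index = NA_integer_, pmma_mm = NA_real_, al_mm = NA_real_,
             path = file.path(root, files), stringsAsFactors = FALSE)
}

#' Acquisition protocol constants and design arithmetic
#'
#' Returns the acquisition protocol of the instrument as a named list, and
#' companions compute the bookkeeping quantities that follow from it (frame
#' counts, effective rows, slab-series size, exported slice counts).
#'
#' @return A named list of protocol parameters.
#' @export
acquisition_protocol <- function() {
  list(
    kvp = 80, tube_current_uA = 200, filter_mm_al = 0.5,
    thresholds_keV = c(15, 30),
    n_channels = 2063L, n_rows_physical = 513L, rows_cropped_per_edge = 4L,
    pixel_mm = 0.1, exposure_ms = 70, counter_max = 4096L,
    fov_mm = 80, n_views = 1440L, angle_increment_deg = 0.25,
    sid_mm = 140, sdd_mm = 325,
    n_samples = 15L, n_couch = 4L, couch_spacing_mm = 15,
    slices_per_orbit = 300L,
    pmma_mm = c(0, 5, 10, 15, 20, 30, 40),
    al_mm = c(0, 0.5, 1, 1.5, 2, 3, 4, 5)
  )
}

#' @rdname acquisition_protocol
#' @param protocol a protocol list from [acquisition_protocol()].
#' @export
effective_detector_rows <- function(protocol = acquisition_protocol()) {
  protocol$n_rows_physical - 2L * protocol$rows_cropped_per_edge
}

#' @rdname acquisition_protocol
#' @param n_acquired_bins number of simultaneously acquired threshold bins.
#' @export
total_raw_frames <- function(protocol = acquisition_protocol(),
                             n_acquired_bins = 2L) {
  protocol$n_samples * protocol$n_couch * protocol$n_views * n_acquired_bins
}

#' @rdname acquisition_protocol
#' @export
slab_series_size <- function(protocol = acquisition_protocol()) {
  length(protocol$pmma_mm) * length(protocol$al_mm)
}

#' @rdname acquisition_protocol
#' @export
dicom_slices_per_sample <- function(protocol = acquisition_protocol()) {
  protocol$n_couch * protocol$slices_per_orbit
}
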