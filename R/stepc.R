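# Per-pixel polynomial non-uniformity calibration.
#
# Calibration: slab scans of known flat attenuators are air-corrected to log
# frames; for each scan and bin the deviation of each pixel from the fitted
# ideal 2-D quadratic surface is the uniformity error.  A per-pixel
# polynomial in the pixel's own multi-energy signals,
#   e(i,j) = c0 + c1 S_T + c2 S_H + c3 S_T^2 + c4 S_H^2,
# is least-squares fitted across the slab scans (S_T, S_H are the pixel's
# air-corrected Total/High log signals).  Correction: the model predicts and
# subtracts the error for every projection of a real scan.  The 5-term basis
# matches the released coefficient-table shape; it is a documented
# compatible stand-in for the instrument's exact basis.

stepc_basis <- function(st, sh) cbind(1, st, sh, st^2, sh^2)

#' Calibrate the per-pixel non-uniformity polynomial tables
#'
#' @param slab_logframes list of slab scans; each element is a named list of
#'   log-kind [proj_image]s containing at least `total` and `high` (any
#'   further bins present, e.g. `low`, are calibrated too).
#' @return A `stepc_table`: per-bin coefficient arrays
#'   `[rows, channels, 5]`, the basis description, and per-bin residual RMS
#'   before/after correction on the calibration scans.
#' @export
stepc_calibrate <- function(slab_logframes) {
  ns <- length(slab_logframes)
  if (ns < 6L) stopf("need at least 6 slab scans, got %d", ns)
  bins <- names(slab_logframes[[1]])
  if (!all(c("total", "high") %in% bins))
    stopf("every slab scan must include total and high log frames")
  d <- dim(slab_logframes[[1]]$total)
  nr <- d[1]; nc <- d[2]; npix <- nr * nc

  ST <- vapply(slab_logframes, function(s) as.numeric(s$total),
               numeric(npix))
  SH <- vapply(slab_logframes, function(s) as.numeric(s$high),
               numeric(npix))
  # per-scan, per-bin residuals from the ideal surface
  resid <- lapply(bins, function(b)
    vapply(slab_logframes, function(s)
      as.numeric(fit_uniformity_surface(s[[b]])$residual), numeric(npix)))
  names(resid) <- bins

  # distinctness of the design: attenuation levels must differ
  if (ns < 6L || qr(stepc_basis(colMeans(ST), colMeans(SH)))$rank < 5L)
    stopf("rank-deficient calibration design: too few distinct slab thicknesses (all %d pixels affected)",
          npix)

  coeffs <- list(); rms <- list()
  for (b in bins) {
    R <- resid[[b]]
    cf <- matrix(0, npix, 5L)
    for (p in seq_len(npix)) {
      X <- stepc_basis(ST[p, ], SH[p, ])
      xtx <- crossprod(X)
      cf[p, ] <- tryCatch(solve(xtx, crossprod(X, R[p, ])),
                          error = function(e) {
                            # fall back to pseudoinverse for degenerate pixels
                            as.numeric(qr.coef(qr(X), R[p, ]))
                          })
    }
    cf[is.na(cf)] <- 0
    pred <- vapply(seq_len(ns), function(s)
      rowSums(stepc_basis(ST[, s], SH[, s]) * cf), numeric(npix))
    rms[[b]] <- c(before = sqrt(mean(R^2)), after = sqrt(mean((R - pred)^2)))
    coeffs[[b]] <- array(cf, dim = c(nr, nc, 5L))
  }
  structure(list(coeffs = coeffs,
                 basis = c("1", "S_T", "S_H", "S_T^2", "S_H^2"),
                 fit_rms = rms, n_scans = ns),
            class = "stepc_table")
}

#' @export
print.stepc_table <- function(x, ...) {
  d <- dim(x$coeffs[[1]])
  cat(sprintf("<stepc_table> bins: %s; %d x %d x %d coefficients; %d calibration scans\n",
              paste(names(x$coeffs), collapse = ", "), d[1], d[2], d[3],
              x$n_scans))
  invisible(x)
}

stepc_predict <- function(table, bin, st_frame, sh_frame) {
  cf <- table$coeffs[[bin]]
  if (is.null(cf)) stopf("no coefficients for bin '%s' in table", bin)
  d <- dim(cf)
  st <- as.numeric(st_frame); sh <- as.numeric(sh_frame)
  pred <- cf[, , 1] + cf[, , 2] * st + cf[, , 3] * sh +
    cf[, , 4] * st^2 + cf[, , 5] * sh^2
  matrix(pred, d[1], d[2])
}

#' Apply the non-uniformity correction to a projection stack
#'
#' Subtracts the predicted per-pixel uniformity error from every frame.
#' The model's predictors are each frame's paired Total and High
#' air-corrected log signals, so those stacks must accompany any stack
#' being corrected.
#'
#' @param stack log-kind [proj_stack] to correct.
#' @param table a `stepc_table` from [stepc_calibrate()].
#' @param total,high log-kind [proj_stack]s giving the paired signals; may
#'   be omitted when `stack` itself is that bin.
#' @return Corrected [proj_stack].
#' @export
stepc_apply <- function(stack, table, total = NULL, high = NULL) {
  if (stack$kind != "log") stopf("non-uniformity correction operates on log stacks")
  if (is.null(total)) total <- if (stack$bin == "total") stack else
    stopf("paired total-bin stack required")
  if (is.null(high)) high <- if (stack$bin == "high") stack else
    stopf("paired high-bin stack required")
  if (n_views(total) != n_views(stack) || n_views(high) != n_views(stack))
    stopf("paired stacks must have the same number of views")
  out <- stack
  for (k in seq_len(n_views(stack)))
    out$data[, , k] <- stack$data[, , k] -
      stepc_predict(table, stack$bin, total$data[, , k], high$data[, , k])
  out
}

#' Write and read non-uniformity coefficient tables
#'
#' On-disk format mirroring the released tables: one 32-bit float
#' little-endian file per bin holding the `[rows, channels, 5]` coefficient
#' array (column-major), plus a YAML sidecar documenting shape, basis and
#' bin order.
#'
#' @param table a `stepc_table`.
#' @param dir output directory.
#' @return `dir` (write) or a `stepc_table` (read), invisibly for write.
#' @export
write_stepc_table <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(table$coeffs)) {
    con <- file(file.path(dir, sprintf("STEPC_table_%s.data", b)), "wb")
    writeBin(as.numeric(table$coeffs[[b]]), con, size = 4L,
             endian = "little")
    close(con)
  }
  yaml::write_yaml(list(shape = dim(table$coeffs[[1]]),
                        bins = names(table$coeffs), basis = table$basis,
                        dtype = "float32le", order = "column-major"),
                   file.path(dir, "stepc_table.yaml"))
  invisible(dir)
}

#' @rdname write_stepc_table
#' @export
read_stepc_table <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stepc_table.yaml"))
  shape <- as.integer(meta$shape)
  coeffs <- lapply(meta$bins, function(b) {
    path <- file.path(dir, sprintf("STEPC_table_%s.data", b))
    con <- file(path, "rb")
    v <- readBin(con, "numeric", n = prod(shape), size = 4L,
                 endian = "little")
    close(con)
    array(v, dim = shape)
  })
  names(coeffs) <- meta$bins
  structure(list(coeffs = coeffs, basis = meta$basis, fit_rms = NULL,
                 n_scans = NA_integer_),
            class = "stepc_table")
}
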