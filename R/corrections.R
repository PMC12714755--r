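#' Derive the low energy bin by subtraction
#'
#' The detector acquires Total (15-80 keV) and High (30-80 keV) bins; the
#' Low bin (15-30 keV) is `Total - High`, clipped below at zero (counts are
#' physical).  The number of clipped pixels is recorded in the
#' `clip_count` attribute.
#'
#' @param total,high counts-kind [proj_image]s or [proj_stack]s of matching
#'   shape and angles.
#' @return Low-bin object of the same class.
#' @export
derive_low <- function(total, high) {
  if (inherits(total, "proj_stack")) {
    stopifnot(inherits(high, "proj_stack"))
    if (!identical(dim(total$data), dim(high$data)) ||
        total$kind != "counts" || high$kind != "counts")
      stopf("total/high stacks must be counts-kind with identical shape")
    low <- total$data - high$data
    nclip <- sum(low < 0)
    low[low < 0] <- 0
    out <- proj_stack(low, total$angles_deg, bin = "low", kind = "counts")
    attr(out, "clip_count") <- nclip
    return(out)
  }
  if (!identical(dim(total), dim(high)) ||
      proj_kind(total) != "counts" || proj_kind(high) != "counts")
    stopf("total/high frames must be counts-kind with identical shape")
  a1 <- attr(total, "angle_deg"); a2 <- attr(high, "angle_deg")
  if (!identical(is.na(a1), is.na(a2)) || (!is.na(a1) && a1 != a2))
    stopf("total/high frames are from different view angles")
  low <- unclass(total) - unclass(high)
  nclip <- sum(low < 0)
  low[low < 0] <- 0
  out <- proj_image(low, bin = "low", kind = "counts", angle_deg = a1)
  attr(out, "clip_count") <- nclip
  out
}

#' Flat-field (air) correction to log projections
#'
#' `P = -ln(I_obj / I_air)` per pixel, with both numerator and denominator
#' clamped below at one count so zero readings stay finite.
#'
#' @param obj counts-kind [proj_image] or [proj_stack].
#' @param air counts-kind averaged flat field of the same bin and shape.
#' @param eps clamp floor in counts.
#' @return Log-kind object of the same class as `obj`.
#' @export
air_correct <- function(obj, air, eps = 1) {
  if (proj_kind(air) != "counts") stopf("air frame must be counts-kind")
  if (all(unclass(air) == 0)) stopf("all-zero air frame: flat field unusable")
  airc <- pmax(unclass(air), eps)
  if (inherits(obj, "proj_stack")) {
    if (obj$kind != "counts") stopf("object stack must be counts-kind")
    if (!identical(dim(obj$data)[1:2], dim(air)) &&
        !identical(as.integer(dim(obj$data)[1:2]), as.integer(dim(air))))
      stopf("air frame shape does not match stack")
    if (obj$bin != proj_bin(air))
      stopf("air frame bin '%s' does not match stack bin '%s'",
            proj_bin(air), obj$bin)
    P <- -log(pmax(obj$data, eps) / as.numeric(airc))
    return(proj_stack(P, obj$angles_deg, bin = obj$bin, kind = "log"))
  }
  if (proj_kind(obj) != "counts") stopf("object frame must be counts-kind")
  if (!identical(dim(obj), dim(air))) stopf("object/air shape mismatch")
  if (proj_bin(obj) != proj_bin(air)) stopf("object/air bin mismatch")
  P <- -log(pmax(unclass(obj), eps) / airc)
  proj_image(P, bin = proj_bin(obj), kind = "log",
             angle_deg = attr(obj, "angle_deg"))
}

#' Fit the ideal-response polynomial surface of a projection
#'
#' Least-squares fit of a full 2-D second-order polynomial
#' `p(i,j) = c0 + c1 i + c2 j + c3 i^2 + c4 ij + c5 j^2` (row/channel
#' coordinates normalized to `[0, 1]` for conditioning) over the good
#' pixels of a log-kind frame.  The residual `measured - surface` is the
#' per-pixel uniformity error the non-uniformity calibration models.
#'
#' @param frame log-kind [proj_image] (or plain matrix).
#' @param good_mask optional logical matrix of pixels to fit over.
#' @return List with `surface`, `residual` (matrices) and `coefficients`.
#' @export
fit_uniformity_surface <- function(frame, good_mask = NULL) {
  if (inherits(frame, "proj_image") && proj_kind(frame) != "log")
    stopf("uniformity surface is fitted on log-kind frames")
  m <- unclass(frame)
  nr <- nrow(m); nc <- ncol(m)
  i <- matrix((seq_len(nr) - 1) / max(nr - 1, 1), nr, nc)
  j <- matrix((seq_len(nc) - 1) / max(nc - 1, 1), nr, nc, byrow = TRUE)
  X <- cbind(1, as.numeric(i), as.numeric(j), as.numeric(i)^2,
             as.numeric(i) * as.numeric(j), as.numeric(j)^2)
  sel <- if (is.null(good_mask)) rep(TRUE, nr * nc) else as.logical(good_mask)
  if (sum(sel) < 6L) stopf("fewer than 6 good pixels: cannot fit surface")
  fit <- qr(X[sel, , drop = FALSE])
  beta <- qr.coef(fit, as.numeric(m)[sel])
  beta[is.na(beta)] <- 0
  surface <- matrix(X %*% beta, nr, nc)
  list(surface = surface, residual = m - surface, coefficients = beta)
}

#' Detect bad pixels from a counts stack
#'
#' Flags any pixel whose count in any frame falls below `lo` or above `hi`
#' (strict inequalities), and unions the result with a prior bad-pixel
#' table (pre-identified abnormal pixels / tile gap pixels).
#'
#' @param stack counts-kind [proj_stack] or [proj_image].
#' @param lo,hi count limits (defaults 5 and 4090).
#' @param prior optional data.frame with columns `row`, `channel`.
#' @return data.frame with columns `row`, `channel`, sorted, unique.
#' @export
detect_bad_pixels <- function(stack, lo = 5, hi = 4090, prior = NULL) {
  data <- if (inherits(stack, "proj_stack")) {
    if (stack$kind != "counts") stopf("bad-pixel detection needs counts")
    stack$data
  } else {
    if (proj_kind(stack) != "counts") stopf("bad-pixel detection needs counts")
    array(unclass(stack), dim = c(dim(stack), 1L))
  }
  flag <- apply(data < lo | data > hi, c(1, 2), any)
  idx <- which(flag, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], channel = idx[, 2])
  if (!is.null(prior) && nrow(prior) > 0)
    out <- rbind(out, data.frame(row = prior$row, channel = prior$channel))
  out <- unique(out)
  out[order(out$row, out$channel), , drop = FALSE]
}

#' Interpolate bad pixels along detector rows
#'
#' Replaces each flagged pixel by 1-D linear interpolation along its row
#' (channel direction) between the nearest good neighbours; runs at a row
#' edge take the nearest good value.
#'
#' @param frame a [proj_image] (counts or log) or plain matrix; also accepts
#'   a [proj_stack] (applied per frame).
#' @param bad data.frame with columns `row`, `channel` from
#'   [detect_bad_pixels()].
#' @return Corrected object of the same class.
#' @export
interp_bad_pixels <- function(frame, bad) {
  if (inherits(frame, "proj_stack")) {
    out <- frame
    for (k in seq_len(n_views(frame)))
      out$data[, , k] <- interp_bad_pixels(frame$data[, , k], bad)
    return(out)
  }
  m <- unclass(frame)
  if (nrow(bad) == 0) return(frame)
  for (r in unique(bad$row)) {
    cols <- bad$channel[bad$row == r]
    good <- setdiff(seq_len(ncol(m)), cols)
    if (length(good) == 0L)
      stopf("detector row %d has no good pixels to interpolate from", r)
    if (length(good) == 1L) {
      m[r, cols] <- m[r, good]
    } else {
      m[r, cols] <- approx(good, m[r, good], xout = cols, rule = 2)$y
    }
  }
  if (inherits(frame, "proj_image"))
    proj_image(m, bin = proj_bin(frame), kind = proj_kind(frame),
               angle_deg = attr(frame, "angle_deg"))
  else m
}
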