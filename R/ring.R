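# Projection-domain ring-artifact correction.
#
# Static per-pixel response errors survive flat-fielding as a fixed additive
# offset in the log projections and backproject into concentric rings.  The
# estimator: split the views into M contiguous-angle subsets; average each
# subset (object structure smears out, the static offset stays); median
# filter the subset mean with a kernel narrow across rows and wide along
# channels to get the smooth background; per-subset error = mean - smooth;
# pixel-wise median across subsets rejects residual object edges; a wide
# Gaussian of that map is the background bias, subtracted so only the
# high-frequency (ring-forming) component is removed from the data.

#' Estimate the static ring-artifact error map
#'
#' @param stack log-kind [proj_stack].
#' @param M number of contiguous-angle subsets (1 <= M <= views).
#' @param median_kernel 2-element integer vector, median window in
#'   (rows, channels).
#' @param gauss_sigma Gaussian sigma (pixels) of the background-bias
#'   smoothing.
#' @param window optional channel range `c(first, last)` the correction is
#'   restricted to; the map is zero outside.
#' @return A `ring_error_map`: list with `error` matrix and `window`.
#' @export
ring_estimate <- function(stack, M = 8L, median_kernel = c(3L, 9L),
                          gauss_sigma = 10, window = NULL) {
  if (stack$kind != "log") stopf("ring estimation operates on log stacks")
  K <- n_views(stack)
  if (M < 1L || M > K) stopf("M must be within [1, %d]", K)
  groups <- split(seq_len(K), ceiling(seq_len(K) * M / K))
  err <- vapply(groups, function(ks) {
    pm <- if (length(ks) == 1L) stack$data[, , ks] else
      rowMeans(stack$data[, , ks, drop = FALSE], dims = 2)
    ps <- .cpp_median2d(pm, as.integer(median_kernel[1]),
                        as.integer(median_kernel[2]))
    as.numeric(pm - ps)
  }, numeric(dim(stack$data)[1] * dim(stack$data)[2]))
  emap <- matrix(apply(err, 1, median),
                 dim(stack$data)[1], dim(stack$data)[2])
  bias <- gauss_blur2d(emap, gauss_sigma, gauss_sigma)
  final <- emap - bias
  if (!is.null(window)) {
    keep <- seq(window[1], window[2])
    mask <- matrix(0, nrow(final), ncol(final))
    mask[, keep] <- 1
    final <- final * mask
  }
  structure(list(error = final, window = window), class = "ring_error_map")
}

#' Subtract the ring-error map from every projection
#'
#' @param stack log-kind [proj_stack].
#' @param map a `ring_error_map` from [ring_estimate()].
#' @return Corrected [proj_stack].
#' @export
ring_apply <- function(stack, map) {
  if (!identical(dim(map$error), dim(stack$data)[1:2]) &&
      !identical(as.integer(dim(map$error)), as.integer(dim(stack$data)[1:2])))
    stopf("ring map shape does not match stack frames")
  out <- stack
  out$data <- stack$data - as.numeric(map$error)
  out
}
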