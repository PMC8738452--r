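# Grayscale morphology with a disc structuring element, used for
# rolling-ball-style background estimation. Erosion/dilation are
# decomposed into horizontal running min/max per disc row followed by a
# vertical combination, with replicate padding at the borders.

.shift_cols <- function(m, dx) {
  j <- pmin(pmax(seq_len(ncol(m)) + dx, 1L), ncol(m))
  m[, j, drop = FALSE]
}

.shift_rows <- function(m, dy) {
  i <- pmin(pmax(seq_len(nrow(m)) + dy, 1L), nrow(m))
  m[i, , drop = FALSE]
}

.running_ext_cols <- function(m, w, op) {
  out <- m
  for (dx in seq_len(w)) {
    out <- op(out, .shift_cols(m, dx))
    out <- op(out, .shift_cols(m, -dx))
  }
  out
}

.disc_extremum <- function(img, radius, op) {
  r <- as.integer(radius)
  dys <- -r:r
  wxs <- as.integer(floor(sqrt(radius^2 - dys^2)))
  hcache <- list()
  out <- NULL
  for (k in seq_along(dys)) {
    w <- wxs[k]
    key <- as.character(w)
    if (is.null(hcache[[key]]))
      hcache[[key]] <- .running_ext_cols(img, w, op)
    band <- .shift_rows(hcache[[key]], dys[k])
    out <- if (is.null(out)) band else op(out, band)
  }
  out
}

.gray_erode <- function(img, radius) .disc_extremum(img, radius, pmin)
.gray_dilate <- function(img, radius) .disc_extremum(img, radius, pmax)

# Binary erosion of a logical mask by a disc (TRUE survives only if the
# whole disc fits inside the foreground). Borders count as background.
.binary_erode <- function(mask, radius) {
  m <- matrix(0, nrow(mask) + 2 * radius, ncol(mask) + 2 * radius)
  m[radius + seq_len(nrow(mask)), radius + seq_len(ncol(mask))] <-
    as.numeric(mask)
  er <- .gray_erode(m, radius)
  er[radius + seq_len(nrow(mask)), radius + seq_len(ncol(mask))] >= 1
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a single-channel image as the
#' grayscale opening (erosion followed by dilation) with a disc of the
#' configured rolling-ball radius, then subtracts it and clips at zero.
#' Structures smaller than the ball (cells) are preserved; anything the
#' ball can roll under (flat or slowly varying background) is removed.
#' A uniform image maps to all zeros; the operation is idempotent on
#' sparse-foreground images.
#'
#' @param image numeric matrix (single channel, row = y + 1,
#'   col = x + 1).
#' @param params a [detection_params()]; only `rolling_ball_radius` is
#'   used.
#' @return numeric matrix of the same size, non-negative everywhere,
#'   with the estimated background in attribute `"background"`.
#' @export
subtract_background <- function(image, params) {
  stopifnot(is.matrix(image))
  r <- params$rolling_ball_radius
  if (r < 1) stop("rolling_ball_radius must be >= 1")
  if (2 * r + 1 > min(dim(image)))
    stop("rolling_ball_radius larger than the image")
  bg <- .gray_dilate(.gray_erode(image, r), r)
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}
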