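#' Object-recognition parameters
#'
#' The parameter set of the detection recipe: background level,
#' threshold above background, rolling-ball radius, and the size and
#' circularity gates. All live in one configuration object so a run can
#' persist the exact parameter set next to its outputs.
#'
#' @param background_level nominal camera background (AU), subtracted
#'   before rolling-ball estimation when supplied to pipelines that use
#'   raw images; 0 if images are already offset-corrected.
#' @param threshold_delta minimal intensity above the estimated
#'   background for a pixel to count as foreground (AU).
#' @param rolling_ball_radius disc radius of the background estimator
#'   (px).
#' @param min_area,max_area object size gates (px^2).
#' @param min_circularity circularity gate in \[0, 1\];
#'   circularity = 4*pi*A/P^2, 1 for a perfect disk.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(background_level = 0,
                             threshold_delta = 1000,
                             rolling_ball_radius = 25,
                             min_area = 50, max_area = 2000,
                             min_circularity = 0.8) {
  if (min_area >= max_area) stop("need min_area < max_area")
  if (rolling_ball_radius <= 0) stop("rolling_ball_radius must be > 0")
  if (min_circularity < 0 || min_circularity > 1)
    stop("min_circularity must be in [0, 1]")
  structure(list(background_level = background_level,
                 threshold_delta = threshold_delta,
                 rolling_ball_radius = rolling_ball_radius,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity),
            class = "detection_params")
}

# 8-connected component labelling of a logical mask via a pixel graph.
.label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0) return(labels)
  idx <- matrix(seq_along(mask), h, w)
  ea <- integer(0); eb <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- d[1]; dc <- d[2]
    r1 <- seq.int(max(1L, 1L - dr), min(h, h - dr))
    c1 <- seq.int(max(1L, 1L - dc), min(w, w - dc))
    a <- idx[r1, c1]
    b <- idx[r1 + dr, c1 + dc]
    keep <- mask[a] & mask[b]
    ea <- c(ea, a[keep]); eb <- c(eb, b[keep])
  }
  vid <- match(c(ea, eb), fg)
  g <- igraph::graph_from_edgelist(
    cbind(vid[seq_along(ea)], vid[-seq_along(ea)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  labels[fg] <- as.integer(igraph::components(g)$membership)
  labels
}

# Outer-contour length of one object (logical matrix), measured as the
# polyline length of the 0.5 iso-contour of its indicator image; this is
# the border chain length on the half-pixel grid.
.contour_perimeter <- function(obj) {
  z <- matrix(0, nrow(obj) + 2, ncol(obj) + 2)
  z[seq_len(nrow(obj)) + 1, seq_len(ncol(obj)) + 1] <- as.numeric(obj)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  sum(vapply(cl, function(p)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2)) +
      sqrt((p$x[1] - p$x[length(p$x)])^2 +
           (p$y[1] - p$y[length(p$y)])^2),
    numeric(1)))
}

#' Detect transfected cells in the red channel
#'
#' Implements the object-recognition recipe on a background-subtracted
#' red (transfection marker) image: pixels more than `threshold_delta`
#' above zero are foreground, 8-connected components become candidate
#' objects, and objects are kept only if their area lies in
#' `[min_area, max_area]` and their circularity (4*pi*A/P^2, perimeter
#' from the border chain length, capped at 1) reaches
#' `min_circularity`. Touching cells that merge into one low-circularity
#' blob are thereby rejected, not split. Records are ordered by centroid
#' (y, then x); rejected objects go to a rejects log, never silently.
#'
#' @param red_image background-subtracted red channel (numeric matrix);
#'   see [subtract_background()].
#' @param params a [detection_params()].
#' @return a `data.frame` of cell records: `cell_id`, `x`, `y` (0-based
#'   centroid, x = column), `area_px`, `perimeter_px`, `circularity`,
#'   `red_mean`, `red_integral`, `green_mean`/`green_integral` (`NA`
#'   until [measure_green()]), `is_transfected`. Attributes: `"labels"`
#'   (full label map re-indexed to the returned records), `"rejects"`
#'   (log with reasons), `"params"`.
#' @export
segment_cells <- function(red_image, params) {
  stopifnot(is.matrix(red_image), inherits(params, "detection_params"))
  mask <- red_image > params$threshold_delta
  lab <- .label_components(mask)
  n_obj <- max(lab)
  empty <- data.frame(
    cell_id = character(0), x = numeric(0), y = numeric(0),
    area_px = numeric(0), perimeter_px = numeric(0),
    circularity = numeric(0), red_mean = numeric(0),
    red_integral = numeric(0), green_mean = numeric(0),
    green_integral = numeric(0), is_transfected = logical(0))
  if (n_obj == 0) {
    attr(empty, "labels") <- lab
    attr(empty, "rejects") <- cbind(empty[0, ], reason = character(0))
    attr(empty, "params") <- params
    return(empty)
  }

  fg <- which(lab > 0)
  l <- lab[fg]
  rows <- (fg - 1L) %% nrow(red_image) + 1L
  cols <- (fg - 1L) %/% nrow(red_image) + 1L
  area <- tabulate(l, n_obj)
  cx <- rowsum(cols - 1, l)[, 1] / area   # 0-based x = column
  cy <- rowsum(rows - 1, l)[, 1] / area
  isum <- rowsum(red_image[fg], l)[, 1]

  perim <- vapply(seq_len(n_obj), function(i) {
    sel <- l == i
    rr <- range(rows[sel]); cc <- range(cols[sel])
    obj <- matrix(FALSE, rr[2] - rr[1] + 1, cc[2] - cc[1] + 1)
    obj[cbind(rows[sel] - rr[1] + 1, cols[sel] - cc[1] + 1)] <- TRUE
    .contour_perimeter(obj)
  }, numeric(1))
  circ <- pmin(1, 4 * pi * area / perim^2)

  rec <- data.frame(
    cell_id = NA_character_,
    x = cx, y = cy, area_px = area, perimeter_px = perim,
    circularity = circ,
    red_mean = isum / area, red_integral = isum,
    green_mean = NA_real_, green_integral = NA_real_,
    is_transfected = TRUE, stringsAsFactors = FALSE)

  keep <- rec$area_px >= params$min_area & rec$area_px <= params$max_area &
    rec$circularity >= params$min_circularity
  rejects <- rec[!keep, , drop = FALSE]
  if (nrow(rejects) > 0) {
    rejects$reason <- ifelse(
      rejects$area_px < params$min_area, "below_min_area",
      ifelse(rejects$area_px > params$max_area, "above_max_area",
             "below_min_circularity"))
  } else rejects$reason <- character(0)

  rec <- rec[keep, , drop = FALSE]
  ord <- order(rec$y, rec$x)
  rec <- rec[ord, , drop = FALSE]
  rec$cell_id <- sprintf("cell%04d", seq_len(nrow(rec)))
  rownames(rec) <- NULL

  # re-index the label map so label i is the i-th returned record
  old <- which(keep)[ord]
  remap <- integer(n_obj)
  remap[old] <- seq_along(old)
  lab[fg] <- remap[l]
  attr(rec, "labels") <- lab
  attr(rec, "rejects") <- rejects
  attr(rec, "params") <- params
  rec
}

#' Measure green reporter intensity within red-derived cell masks
#'
#' Fills `green_mean` and `green_integral` of a segmented cell table
#' using the pixel masks derived from the red channel; the masks
#' themselves are unchanged, so green measurement is strictly
#' mask-determined.
#'
#' @param cells output of [segment_cells()] (carries the label map).
#' @param green_image co-registered green channel, same dimensions as
#'   the red image.
#' @return `cells` with green columns filled.
#' @export
measure_green <- function(cells, green_image) {
  lab <- attr(cells, "labels")
  if (is.null(lab)) stop("cells must carry a label map (from segment_cells)")
  if (!all(dim(lab) == dim(green_image)))
    stop("green channel dimensions differ from the segmented red channel")
  if (nrow(cells) == 0) return(cells)
  fg <- which(lab > 0)
  gsum <- rowsum(green_image[fg], lab[fg])[, 1]
  cells$green_integral <- as.numeric(gsum)
  cells$green_mean <- cells$green_integral / cells$area_px
  cells
}
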