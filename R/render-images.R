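#' Render a two-channel image pair from a simulated cell table
#'
#' Paints each cell as a uniform disk of its `red_mean` / `green_mean`
#' intensity on a constant background, adds Gaussian pixel noise, and
#' clamps to the 16-bit range. A ground-truth label map (integer cell
#' index per pixel, 0 = background) is returned alongside; pixels
#' claimed by more than one cell keep the first cell's label and the
#' overlap is flagged in the metadata rather than treated as an error.
#'
#' @param cells a cell table from [simulate_cell_table()] (needs
#'   `x`, `y`, `radius_px`, `red_mean`, `green_mean`).
#' @param config a [sim_config()] supplying image geometry.
#' @param background background level added to both channels (AU).
#' @param noise_sd Gaussian pixel noise SD (AU); 0 for noise-free
#'   fixtures.
#' @param seed integer seed for the pixel noise.
#' @return a list of class `image_pair`: integer matrices `red`,
#'   `green`, `labels` (height x width; row = y + 1, column = x + 1),
#'   plus `overlap` (logical, any overlapping disks) and
#'   `overlap_cells` (ids involved).
#' @examples
#' cfg <- sim_config(n_cells_per_well = 5, width = 128, height = 128)
#' tab <- simulate_cell_table(cfg, stimulus_model(), dose = 1,
#'                            avoid_overlap = TRUE)
#' img <- render_image_pair(tab, cfg, noise_sd = 0)
#' max(img$labels)
#' @export
render_image_pair <- function(cells, config, background = 200,
                              noise_sd = config$noise_sd,
                              seed = config$rng_seed) {
  w <- config$width; h <- config$height
  if (nrow(cells) > 0) {
    if (any(cells$radius_px <= 0)) stop("radii must be positive")
    if (any(cells$x < 0 | cells$x > w - 1 | cells$y < 0 | cells$y > h - 1))
      stop("cell centroids must lie within image bounds")
  }
  red <- matrix(background, nrow = h, ncol = w)
  green <- matrix(background, nrow = h, ncol = w)
  labels <- matrix(0L, nrow = h, ncol = w)
  overlap_ids <- character(0)

  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]; r <- cells$radius_px[i]
    cols <- max(1, floor(cx - r) + 1):min(w, ceiling(cx + r) + 1)
    rows <- max(1, floor(cy - r) + 1):min(h, ceiling(cy + r) + 1)
    # pixel (row, col) has 0-based coordinates (col - 1, row - 1)
    dx <- outer(rep(1, length(rows)), cols - 1 - cx)
    dy <- outer(rows - 1 - cy, rep(1, length(cols)))
    inside <- dx * dx + dy * dy <= r * r
    sub <- labels[rows, cols, drop = FALSE]
    if (any(sub[inside] != 0)) {
      prev <- unique(sub[inside]); prev <- prev[prev != 0]
      overlap_ids <- union(overlap_ids,
                           c(cells$cell_id[i], cells$cell_id[prev]))
      inside <- inside & sub == 0   # first cell keeps contested pixels
    }
    sub[inside] <- i
    labels[rows, cols] <- sub
    rsub <- red[rows, cols, drop = FALSE]
    gsub <- green[rows, cols, drop = FALSE]
    rsub[inside] <- background + cells$red_mean[i]
    gsub[inside] <- background + cells$green_mean[i]
    red[rows, cols] <- rsub
    green[rows, cols] <- gsub
  }

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    red <- red + matrix(rnorm(h * w, 0, noise_sd), h, w)
    green <- green + matrix(rnorm(h * w, 0, noise_sd), h, w)
  }
  clamp16 <- function(m) matrix(as.integer(pmin(pmax(round(m), 0), 65535L)),
                                nrow(m), ncol(m))
  structure(list(red = clamp16(red), green = clamp16(green),
                 labels = labels,
                 overlap = length(overlap_ids) > 0,
                 overlap_cells = overlap_ids),
            class = "image_pair")
}

#' Write / read an image pair as 16-bit TIFF
#'
#' The two channels go into one multi-page TIFF (page 1 red, page 2
#' green); the label map into a sidecar TIFF next to it.
#'
#' @param pair an `image_pair` from [render_image_pair()].
#' @param path output TIFF path; the label map goes to
#'   `<path>.labels.tif`.
#' @return `write_image_pair`: the main path, invisibly.
#' @export
write_image_pair <- function(pair, path) {
  tiff::writeTIFF(list(pair$red / 65535, pair$green / 65535),
                  path, bits.per.sample = 16L)
  tiff::writeTIFF(pair$labels / 65535, paste0(path, ".labels.tif"),
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_pair
#' @param labels logical; also read the sidecar label map?
#' @return `read_image_pair`: an `image_pair` list (without overlap
#'   metadata; `labels` is `NULL` when no sidecar is requested/found).
#' @export
read_image_pair <- function(path, labels = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF (red, green)")
  toint <- function(m) matrix(as.integer(round(m * 65535)),
                              nrow(m), ncol(m))
  lab <- NULL
  side <- paste0(path, ".labels.tif")
  if (labels && file.exists(side)) lab <- toint(tiff::readTIFF(side))
  structure(list(red = toint(pages[[1]]), green = toint(pages[[2]]),
                 labels = lab, overlap = NA, overlap_cells = character(0)),
            class = "image_pair")
}
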