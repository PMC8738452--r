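#' Subcellular region masks derived from a cell label map
#'
#' Builds the four region masks used for trafficking-style region
#' ratios: whole cell, a membrane band (the outermost
#' `membrane_width`-pixel rim of the cell mask), a nuclear disk around
#' the centroid (`nuclear_frac` of the equivalent radius), and the
#' perinuclear (cytoplasmic) region — the interior minus the nucleus.
#' Regions are subsets of the whole-cell mask and the nucleus never
#' touches the membrane band.
#'
#' @param labels integer label map as returned in the `"labels"`
#'   attribute of [segment_cells()] or by [render_image_pair()].
#' @param membrane_width rim width in pixels (default 2).
#' @param nuclear_frac nuclear radius as a fraction of the cell's
#'   equivalent radius (default 0.5).
#' @return named list of integer label maps `whole`, `membrane`,
#'   `perinuclear`, `nuclear`, each coded with the input cell labels.
#' @export
make_region_masks <- function(labels, membrane_width = 2,
                              nuclear_frac = 0.5) {
  stopifnot(membrane_width >= 1, nuclear_frac > 0, nuclear_frac < 1)
  interior_mask <- .binary_erode(labels > 0, membrane_width)
  membrane <- labels
  membrane[interior_mask] <- 0L
  interior <- labels
  interior[!interior_mask] <- 0L

  nuclear <- matrix(0L, nrow(labels), ncol(labels))
  fg <- which(labels > 0)
  if (length(fg) > 0) {
    l <- labels[fg]
    rows <- (fg - 1L) %% nrow(labels) + 1L
    cols <- (fg - 1L) %/% nrow(labels) + 1L
    area <- tabulate(l, max(l))
    cx <- rowsum(as.numeric(cols), l)[, 1] / area[sort(unique(l))]
    cy <- rowsum(as.numeric(rows), l)[, 1] / area[sort(unique(l))]
    ids <- sort(unique(l))
    r_eq <- sqrt(area[ids] / pi)
    pos <- match(l, ids)
    d2 <- (cols - cx[pos])^2 + (rows - cy[pos])^2
    in_nuc <- d2 <= (nuclear_frac * r_eq[pos])^2
    sel <- fg[in_nuc & interior[fg] > 0]   # keep nucleus off the membrane
    nuclear[sel] <- labels[sel]
  }
  perinuclear <- interior
  perinuclear[nuclear > 0] <- 0L
  list(whole = labels, membrane = membrane,
       perinuclear = perinuclear, nuclear = nuclear)
}

#' Per-cell region intensity ratios
#'
#' Mean intensity of the numerator region divided by the mean intensity
#' of the denominator region, per cell — e.g. membrane/cell to track
#' receptor internalisation, perinuclear/cell for endosomal
#' accumulation, nuclear/cell as a control ratio. Identical regions give
#' exactly 1. A cell whose denominator region is empty gets `NA` and is
#' listed in the `"empty_denominator"` attribute.
#'
#' @param cells a segmented cell table (only its labels/ids are used).
#' @param image single-channel intensity image.
#' @param masks region label maps from [make_region_masks()].
#' @param numerator,denominator region names among
#'   `"whole"`, `"membrane"`, `"perinuclear"`, `"nuclear"`.
#' @return numeric vector of ratios, one per row of `cells`.
#' @export
region_ratio <- function(cells, image, masks,
                         numerator = "perinuclear",
                         denominator = "whole") {
  stopifnot(numerator %in% names(masks), denominator %in% names(masks))
  n <- nrow(cells)
  mean_by_label <- function(m) {
    out <- rep(NA_real_, n)
    fg <- which(m > 0 & m <= n)
    if (length(fg) > 0) {
      s <- rowsum(image[fg], m[fg])
      cnt <- tabulate(m[fg], n)
      ids <- as.integer(rownames(s))
      out[ids] <- s[, 1] / cnt[ids]
    }
    out
  }
  num <- mean_by_label(masks[[numerator]])
  den <- mean_by_label(masks[[denominator]])
  ratio <- num / den
  empty <- which(is.na(den))
  attr(ratio, "empty_denominator") <- cells$cell_id[empty]
  ratio
}
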