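test_that("rolling-ball background subtraction: flat, disk, idempotence", {
  p <- detection_params(rolling_ball_radius = 10)

  flat <- matrix(137.5, 80, 80)
  out <- subtract_background(flat, p)
  expect_true(all(out == 0))

  # single bright disk (r = 4) << ball radius on background b: preserved
  img <- matrix(50, 80, 80)
  yy <- row(img) - 41; xx <- col(img) - 41
  disk <- yy^2 + xx^2 <= 16
  img[disk] <- 50 + 900
  out <- subtract_background(img, p)
  expect_equal(out[disk], rep(900, sum(disk)), tolerance = 1e-12)
  expect_true(all(out[!disk] == 0))

  # idempotence on sparse foreground
  out2 <- subtract_background(out, p)
  expect_equal(as.numeric(out2), as.numeric(out), tolerance = 1e-9)

  expect_error(subtract_background(matrix(0, 10, 10),
                                   detection_params(rolling_ball_radius = 30)),
               "larger than the image")
})

test_that("segmentation recovers all gated objects with sub-pixel centroids", {
  fx <- make_clean_image(n_cells = 12, seed = 42)
  cells <- segment_cells(fx$img$red + 0, default_gates())
  expect_equal(nrow(cells), nrow(fx$tab))      # recall 1, precision 1
  idx <- match_centroids(cells, fx$tab)
  expect_equal(sort(idx), seq_len(nrow(fx$tab)))
  expect_true(all(abs(cells$x - fx$tab$x[idx]) <= 1))
  expect_true(all(abs(cells$y - fx$tab$y[idx]) <= 1))
  # deterministic ordering by centroid (y, x)
  expect_true(all(diff(cells$y) >= 0 |
                    (abs(diff(cells$y)) < 1e-9 & diff(cells$x) > 0)))
})

test_that("size and circularity gates exclude and log objects", {
  p <- detection_params(threshold_delta = 100, rolling_ball_radius = 20,
                        min_area = 40, max_area = 700,
                        min_circularity = 0.8)
  img <- matrix(0, 120, 120)
  paint <- function(cx, cy, r, v) {
    yy <- row(img) - cy; xx <- col(img) - cx
    img[yy^2 + xx^2 <= r^2] <<- v
  }
  paint(25, 25, 8, 5000)            # valid disk
  paint(60, 25, 2, 5000)            # below min_area
  paint(90, 60, 8, 5000)            # two touching disks -> low circularity
  paint(90 + 13, 60, 8, 5000)
  cells <- segment_cells(img, p)
  expect_equal(nrow(cells), 1)
  rej <- attr(cells, "rejects")
  expect_setequal(rej$reason, c("below_min_area", "below_min_circularity"))

  # gating monotonicity: tightening gates never adds objects
  tighter <- detection_params(threshold_delta = 100,
                              rolling_ball_radius = 20,
                              min_area = 100, max_area = 400,
                              min_circularity = 0.9)
  expect_lte(nrow(segment_cells(img, tighter)), nrow(cells))
})

test_that("green measurement is mask-determined", {
  fx <- make_clean_image(n_cells = 6, seed = 31)
  cells <- segment_cells(fx$img$red + 0, default_gates())
  green <- fx$img$green + 0
  m1 <- measure_green(cells, green)
  # green_mean equals the rendered value exactly at zero noise
  idx <- match_centroids(m1, fx$tab)
  expect_equal(m1$green_mean, round(fx$tab$green_mean[idx]),
               tolerance = 1e-12)
  expect_equal(m1$green_integral, m1$green_mean * m1$area_px)

  # permuting pixels outside all masks changes nothing
  lab <- attr(cells, "labels")
  outside <- which(lab == 0)
  green2 <- green
  set.seed(1)
  green2[outside] <- sample(green[outside])
  m2 <- measure_green(cells, green2)
  expect_equal(m1$green_mean, m2$green_mean)

  expect_error(measure_green(cells, green[1:50, ]), "dimensions")
})

test_that("region ratios: identity, uniformity, membrane contrast oracle", {
  fx <- make_clean_image(n_cells = 5, seed = 17)
  cells <- segment_cells(fx$img$red + 0, default_gates())
  lab <- attr(cells, "labels")
  masks <- make_region_masks(lab, membrane_width = 2)

  # regions are nested and nucleus avoids the membrane
  expect_true(all(masks$membrane[masks$membrane > 0] ==
                    masks$whole[masks$membrane > 0]))
  expect_false(any(masks$nuclear > 0 & masks$membrane > 0))

  img <- matrix(100, nrow(lab), ncol(lab))
  expect_equal(region_ratio(cells, img, masks, "whole", "whole"),
               rep(1, nrow(cells)), ignore_attr = TRUE)
  expect_equal(region_ratio(cells, img, masks, "membrane", "whole"),
               rep(1, nrow(cells)), ignore_attr = TRUE)

  # membrane at 2m, interior at m: ratio equals direct pixel averaging
  img2 <- matrix(0, nrow(lab), ncol(lab))
  img2[masks$whole > 0] <- 50
  img2[masks$membrane > 0] <- 100
  r <- region_ratio(cells, img2, masks, "membrane", "whole")
  oracle <- vapply(seq_len(nrow(cells)), function(i)
    mean(img2[masks$membrane == i]) / mean(img2[masks$whole == i]),
    numeric(1))
  expect_equal(as.numeric(r), oracle)
  expect_true(all(r > 1))

  # empty denominator -> NA, logged
  masks$nuclear[] <- 0L
  rn <- region_ratio(cells, img2, masks, "membrane", "nuclear")
  expect_true(all(is.na(rn)))
  expect_setequal(attr(rn, "empty_denominator"), cells$cell_id)
})
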