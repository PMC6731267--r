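test_that("Gaussian smoothing preserves constants and total mass", {
  expect_equal(smooth_dapi(matrix(7, 20, 20), 2), matrix(7, 20, 20))
  imp <- matrix(0, 24, 24); imp[3, 21] <- 5   # near-corner impulse
  expect_equal(sum(smooth_dapi(imp, 1.7)), 5, tolerance = 1e-6)
  expect_error(smooth_dapi(matrix(1, 16, 16), 0),
               class = "ringtrack_parameter_error")
})

test_that("separable smoothing equals direct 2-D convolution", {
  m <- matrix(0, 18, 18); m[4, 5] <- 3; m[12, 14] <- 8
  for (sigma in c(1, 2.3)) {
    expect_equal(smooth_dapi(m, sigma), direct_gaussian_conv(m, sigma),
                 tolerance = 1e-6)
  }
  set.seed(3)
  r <- matrix(runif(16 * 16, 0, 255), 16, 16)
  expect_equal(smooth_dapi(r, 1.5), direct_gaussian_conv(r, 1.5),
               tolerance = 1e-9)
})

test_that("global threshold separates a bimodal image and rejects constants", {
  m <- matrix(c(rep(10, 128), rep(200, 128)), 16, 16)
  fg <- global_binarize(m)
  expect_identical(unclass(fg)[, ], m == 200)
  expect_gt(attr(fg, "threshold"), 10)
  expect_lt(attr(fg, "threshold"), 200)
  expect_error(global_binarize(matrix(4, 16, 16)),
               class = "ringtrack_degenerate_error")
})

test_that("global threshold is invariant to intensity scaling", {
  set.seed(9)
  m <- matrix(c(rnorm(300, 40, 8), rnorm(212, 180, 20)), 32, 16)
  fg1 <- global_binarize(m)
  for (k in c(0.5, 2, 10)) {
    fg2 <- global_binarize(m * k)
    expect_identical(unclass(fg2)[, ], unclass(fg1)[, ])
  }
})

test_that("threshold agrees with independent Otsu implementations", {
  set.seed(4)
  m <- matrix(c(rnorm(400, 50, 10), rnorm(400, 200, 15)), 40, 20)
  thr <- attr(global_binarize(m), "threshold")
  expect_equal(thr, otsu_oracle(m), tolerance = 1e-9)
  # EBImage's Otsu as an external cross-check, to one histogram bin
  eb <- EBImage::otsu(m / 255, range = range(m) / 255, levels = 256L) * 255
  binw <- diff(range(m)) / 256
  expect_lt(abs(thr - eb), 2 * binw)
})

test_that("morphological refinement fills holes and roughly preserves area", {
  disc <- render_disc(40, 20, 20, 10)
  holed <- disc; holed[18:22, 18:22] <- FALSE
  out <- refine_mask(holed, seg_params(n_dilations = 1, n_erosions = 1))
  expect_true(all(out[18:22, 18:22]))
  expect_lt(abs(sum(out) - sum(disc)) / sum(disc), 0.05)

  empty <- matrix(FALSE, 20, 20)
  expect_equal(sum(refine_mask(empty)), 0)
})

test_that("refinement matches brute-force morphology with the same element", {
  brush <- EBImage::makeBrush(7, "disc")
  disc <- render_disc(36, 17, 17, 9)
  holed <- disc; holed[15:18, 15:18] <- FALSE
  expected <- brute_erode(
    EBImage::fillHull(brute_dilate(holed, brush) * 1) > 0, brush)
  got <- refine_mask(holed, seg_params(n_dilations = 1, n_erosions = 1))
  expect_identical(got, expected)
})

test_that("labelling is 8-connected with scan-order labels", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal contact: one object
  expect_equal(attr(label_objects(m), "n_objects"), 1L)
  m2 <- matrix(FALSE, 8, 8)
  m2[2, 2:3] <- TRUE; m2[6:7, 5:6] <- TRUE  # separated: two objects
  lm2 <- label_objects(m2)
  expect_equal(attr(lm2, "n_objects"), 2L)
  expect_equal(lm2[2, 2], 1L)               # top-left component first
  expect_equal(lm2[6, 5], 2L)
})

test_that("labelling agrees with a flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(runif(16 * 16) < 0.4, 16, 16)
    expect_identical(unclass(label_objects(m))[, ], flood_fill_oracle(m))
  }
})

test_that("object measurements match analytic geometry", {
  disc <- render_disc(80, 40, 40, 30)
  rec <- measure_nuclei(label_objects(disc), matrix(1, 80, 80))
  expect_lt(abs(rec$area_px - pi * 30^2) / (pi * 30^2), 0.02)
  expect_lt(rec$eccentricity, 0.1)
  expect_gt(rec$circularity, 0.85)
  expect_lt(rec$circularity, 1.1)
  expect_equal(rec$centroid_row, 40, tolerance = 0.1)
  expect_equal(rec$centroid_col, 40, tolerance = 0.1)

  ell <- render_ellipse(120, 60, 60, 40, 20)
  rec2 <- measure_nuclei(label_objects(ell), matrix(1, 120, 120))
  expect_equal(rec2$eccentricity, sqrt(1 - (20 / 40)^2), tolerance = 0.02)
})

test_that("single-pixel objects degrade gracefully", {
  m <- matrix(FALSE, 16, 16); m[5, 7] <- TRUE
  rec <- measure_nuclei(label_objects(m), matrix(2, 16, 16))
  expect_equal(rec$area_px, 1L)
  b <- attr(rec, "boundary")[[1]]
  expect_equal(unname(b[, 1]), 4)   # 0-based coordinates
  expect_equal(unname(b[, 2]), 6)
})

test_that("mean DAPI intensity is averaged over member pixels", {
  m <- matrix(FALSE, 16, 16); m[4:6, 4:6] <- TRUE
  d <- matrix(10, 16, 16); d[4:6, 4:6] <- c(1:9) * 10
  rec <- measure_nuclei(label_objects(m), d)
  expect_equal(rec$mean_dapi, mean(1:9) * 10)
})

test_that("the four filters use strict inequalities in the stated order", {
  rec <- data.frame(nucleus_id = 1:6,
                    area_px = c(400L, 500L, 500L, 500L, 500L, 500L),
                    perimeter_px = 80, centroid_row = 0, centroid_col = 0,
                    eccentricity = c(0.1, 0.79, 0.81, 0.1, 0.1, 0.1),
                    circularity = c(0.9, 0.9, 0.9, 0.84, 0.86, 0.9),
                    mean_dapi = c(100, 100, 100, 100, 100, 100),
                    touches_border = FALSE, accepted = NA,
                    rejection_reason = NA_character_)
  out <- filter_nuclei(rec, seg_params())
  expect_equal(out$rejection_reason,
               c("area", "none", "eccentricity", "regularity", "none", "none"))
  expect_equal(out$accepted, out$rejection_reason == "none")
})

test_that("the intensity filter uses the median over all candidates", {
  rec <- data.frame(nucleus_id = 1:3, area_px = 500L, perimeter_px = 80,
                    centroid_row = 0, centroid_col = 0, eccentricity = 0.1,
                    circularity = 0.9, mean_dapi = c(100, 100, 250),
                    touches_border = FALSE, accepted = NA,
                    rejection_reason = NA_character_)
  out <- filter_nuclei(rec, seg_params())
  expect_equal(out$rejection_reason, c("none", "none", "intensity"))
  # exactly 2 x median fails the strict rule
  rec$mean_dapi <- c(100, 100, 200)
  out2 <- filter_nuclei(rec, seg_params())
  expect_equal(out2$rejection_reason[3], "intensity")
  # outcome is independent of record order
  out3 <- filter_nuclei(rec[c(3, 1, 2), ], seg_params())
  expect_equal(out3$rejection_reason[order(out3$nucleus_id)],
               out2$rejection_reason)
  expect_error(filter_nuclei(rec[0, ], seg_params()),
               class = "ringtrack_degenerate_error")
})

test_that("phantom nuclei are segmented and accepted in full", {
  g <- small_field()
  seg <- segment_nuclei(g$fov)
  expect_equal(sum(seg$records$accepted), nrow(g$truth))
  expect_equal(attr(seg$mask, "n_objects"), nrow(g$truth))
  # relabelled mask is contiguous 1..k
  expect_setequal(unique(as.vector(unclass(seg$mask))),
                  0:nrow(g$truth))
})

test_that("an undersized object is rejected by the area filter", {
  g <- small_field()
  dapi <- g$fov$channels$dapi$pixels
  # stamp a disc of ~300 px2 at a spot far from every phantom nucleus
  spot <- NULL
  for (r in seq(40, 470, by = 10)) {
    for (cc in seq(40, 470, by = 10)) {
      if (min(sqrt((g$truth$centroid_row - r)^2 +
                   (g$truth$centroid_col - cc)^2)) > 80) {
        spot <- c(r, cc); break
      }
    }
    if (!is.null(spot)) break
  }
  expect_false(is.null(spot))
  small <- render_disc(nrow(dapi), spot[1], spot[2], 9.7)
  dapi[small] <- 500
  fov <- field_of_view(list(
    dapi = channel_image(dapi, "dapi"),
    gh2ax = g$fov$channels$gh2ax
  ), field_id = "stamped", condition = "x")
  seg <- segment_nuclei(fov)
  rej <- seg$records[!seg$records$accepted, ]
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$rejection_reason, "area")
  expect_lte(rej$area_px, 400)
  expect_equal(sum(seg$records$accepted), nrow(g$truth))
})

test_that("a blank field raises a degenerate-input error", {
  fov <- field_of_view(list(
    dapi = channel_image(matrix(0, 64, 64), "dapi"),
    gh2ax = channel_image(matrix(0, 64, 64), "gh2ax")
  ))
  expect_error(segment_nuclei(fov), class = "ringtrack_degenerate_error")
})

test_that("the accepted set is invariant to DAPI intensity scaling", {
  g <- small_field()
  base <- segment_nuclei(g$fov)
  ids <- sort(base$records$nucleus_id[base$records$accepted])
  for (k in c(0.5, 3, 10)) {
    px <- g$fov$channels$dapi$pixels * k
    fov <- field_of_view(list(dapi = channel_image(px, "dapi"),
                              gh2ax = g$fov$channels$gh2ax))
    seg <- segment_nuclei(fov)
    expect_equal(sort(seg$records$nucleus_id[seg$records$accepted]), ids)
  }
})
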