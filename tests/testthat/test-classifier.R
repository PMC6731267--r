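test_that("adaptive threshold finds plateaus and ignores flat signal", {
  mask <- matrix(TRUE, 40, 40)
  flat <- matrix(50, 40, 40)
  expect_equal(sum(adaptive_binarize(flat, mask)), 0)

  spot <- matrix(50, 40, 40); spot[18:22, 18:22] <- 500
  fg <- adaptive_binarize(spot, mask)
  expect_true(all(fg[18:22, 18:22]))
  expect_equal(sum(fg), 25)

  # multiplicative rule is invariant to intensity scaling
  for (k in c(0.5, 3, 10)) {
    expect_identical(adaptive_binarize(spot * k, mask), fg)
  }
  expect_error(adaptive_binarize(spot, matrix(FALSE, 40, 40) |
                                   (row(spot) == 1 & col(spot) <= 4)),
               class = "ringtrack_degenerate_error")
})

test_that("the local window is restricted to nucleus pixels", {
  # nucleus surrounded by very bright background: with the window clipped
  # to the nucleus the flat interior stays empty
  img <- matrix(5000, 60, 60)
  mask <- render_disc(60, 30, 30, 12)
  img[mask] <- 80
  expect_equal(sum(adaptive_binarize(img, mask)), 0)
})

test_that("foci density rule is strict at the printed cutoff", {
  mk <- function(n_foci) {
    m <- matrix(FALSE, 60, 60)
    for (i in seq_len(n_foci)) {
      r <- 5 + 7 * ((i - 1) %% 8); cc <- 5 + 7 * ((i - 1) %/% 8)
      m[r:(r + 1), cc:(cc + 1)] <- TRUE   # 4-px focus
    }
    m
  }
  r8 <- count_foci(mk(8), area_px = 2000)
  expect_equal(r8$foci_count, 8L)
  expect_equal(r8$foci_density, 0.004)
  expect_true(r8$is_foci)
  r7 <- count_foci(mk(7), area_px = 2000)
  expect_equal(r7$foci_density, 0.0035)
  expect_false(r7$is_foci)              # not strictly greater
  r0 <- count_foci(matrix(FALSE, 20, 20), area_px = 2000)
  expect_equal(r0$foci_count, 0L)
  expect_false(r0$is_foci)
})

test_that("components below the minimum focus area are not counted", {
  m <- matrix(FALSE, 30, 30)
  m[5, 5] <- TRUE                        # 1 px: noise
  m[10:11, 10:11] <- TRUE                # 4 px: focus
  res <- count_foci(m, area_px = 1000)
  expect_equal(res$foci_count, 1L)
  expect_equal(nrow(res$focus_centroids), 1L)
  expect_equal(unname(res$focus_centroids[1, ]), c(9.5, 9.5))  # 0-based
})

test_that("radial rays follow an analytic radial field", {
  R <- 25
  disc <- render_disc(64, 31, 31, R)
  g <- expand.grid(r = 0:63, c = 0:63)
  field <- matrix(sqrt((g$r - 31)^2 + (g$c - 31)^2) / R, 64, 64)
  rec <- measure_nuclei(label_objects(disc), field)
  b <- attr(rec, "boundary")[[1]]
  rays <- cast_radial_profiles(field, c(rec$centroid_row, rec$centroid_col),
                               b, disc)
  expect_length(rays, nrow(b))           # one ray per boundary pixel
  # each ray ~ linear from 0 to ~1
  for (ray in rays[seq(1, length(rays), by = 7)]) {
    ideal <- seq(0, ray[length(ray)], length.out = length(ray))
    expect_lt(sqrt(mean((ray - ideal)^2)), 0.05)
  }
  # constant nucleus gives constant rays
  crays <- cast_radial_profiles(matrix(3, 64, 64),
                                c(rec$centroid_row, rec$centroid_col), b, disc)
  expect_true(all(vapply(crays, function(x) max(abs(x - 3)) < 1e-9, logical(1))))
})

test_that("ray resampling matches a dense linear-interpolation oracle", {
  prof <- resample_and_average(list(c(1, 1), c(1, 1, 1, 1)))
  expect_equal(prof$L, 4L)
  expect_equal(prof$profile, rep(1, 4))

  single <- resample_and_average(list(c(2, 4, 8, 1, 0)))
  expect_equal(single$profile, c(2, 4, 8, 1, 0))

  rays <- list(c(0, 1, 2, 3), c(5, 2, 0.5, 7, 7, 1, 2))
  prof2 <- resample_and_average(rays)
  L <- max(lengths(rays))
  expected <- (linear_resample_oracle(rays[[1]], L) +
                 linear_resample_oracle(rays[[2]], L)) / 2
  expect_equal(prof2$profile, expected, tolerance = 1e-9)
  expect_error(resample_and_average(list()), class = "ringtrack_internal_error")
})

test_that("quartile arithmetic implements the 10% peripheral-excess rule", {
  # first three quartiles at 1, last at 2: diff 1 > 0.1 * 1.25
  prof <- resample_and_average(list(c(1, 1, 1, 2)))
  expect_equal(prof$mean_q123, 1)
  expect_equal(prof$mean_q4, 2)
  expect_equal(prof$overall_mean, 1.25)
  expect_equal(prof$ring_score, 0.8)
  expect_true(classify_ring(prof))

  flat <- resample_and_average(list(rep(3, 8)))
  expect_false(classify_ring(flat))

  inverted <- resample_and_average(list(c(2, 2, 2, 1)))
  expect_false(classify_ring(inverted))  # signed: bright centre is not a ring

  zero <- resample_and_average(list(rep(0, 8)))
  res <- classify_ring(zero)
  expect_false(as.logical(res))
  expect_equal(attr(res, "qc"), "zero_signal")
})

test_that("averaged profile of an analytic radial field matches closed form", {
  for (R in c(20, 30)) {
    size <- 2 * R + 14
    ctr <- (size - 1) / 2
    disc <- render_disc(size, ctr, ctr, R)
    g <- expand.grid(r = 0:(size - 1), c = 0:(size - 1))
    field <- matrix(sqrt((g$r - ctr)^2 + (g$c - ctr)^2) / R, size, size)
    rec <- measure_nuclei(label_objects(disc), field)
    rays <- cast_radial_profiles(field, c(rec$centroid_row, rec$centroid_col),
                                 attr(rec, "boundary")[[1]], disc)
    prof <- resample_and_average(rays)
    ideal <- seq(0, 1, length.out = prof$L) * prof$profile[prof$L]
    rms <- sqrt(mean((prof$profile - ideal)^2))
    expect_lt(rms, 0.02)
  }
})

test_that("every phantom nucleus gets its true phenotype call", {
  g <- small_field()
  seg <- segment_nuclei(g$fov)
  cls <- classify_field(g$fov, seg)
  rec <- seg$records[match(cls$nucleus_id, seg$records$nucleus_id), ]
  m <- match_truth(rec, g$truth)
  expect_equal(cls$phenotype, g$truth$true_phenotype[m])
  # exactly one of the three phenotypes per accepted nucleus
  expect_true(all(cls$phenotype %in% c("FOCI", "RING", "UNIFORM")))
  expect_equal(nrow(cls), sum(seg$records$accepted))
  # FOCI calls carry no radial profile; the marked phenotypes are exclusive
  calls <- attr(cls, "calls")
  for (cl in calls) {
    if (cl$phenotype == "FOCI") expect_null(cl$radial)
    else expect_false(cl$foci$is_foci)
  }
})

test_that("phenotype calls are invariant to gamma-H2AX intensity scaling", {
  g <- small_field()
  seg <- segment_nuclei(g$fov)
  base <- classify_field(g$fov, seg)
  for (k in c(0.5, 3, 10)) {
    fov2 <- field_of_view(list(
      dapi = g$fov$channels$dapi,
      gh2ax = channel_image(g$fov$channels$gh2ax$pixels * k, "gh2ax")
    ))
    cls <- classify_field(fov2, seg)
    expect_equal(cls$phenotype, base$phenotype)
    expect_equal(cls$foci_count, base$foci_count)
  }
})
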