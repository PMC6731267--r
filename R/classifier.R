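#' Phenotype classifier parameters
#'
#' Controls the two-step gamma-H2AX phenotype call. Nuclei whose number of
#' detected foci divided by nucleus area exceeds `foci_density_cutoff`
#' (strict `>`) are FOCI. Remaining nuclei are RING when the mean radial
#' intensity in the last quartile of the averaged centroid-to-boundary
#' profile exceeds the mean over the first three quartiles by more than
#' `ring_rel_threshold` times the overall profile mean (strict, signed:
#' the periphery must be brighter); otherwise UNIFORM.
#'
#' @param adaptive_window_px Odd side length (px) of the local-statistics
#'   window of the adaptive threshold.
#' @param adaptive_rel_offset Relative offset: a pixel is focus candidate
#'   when brighter than `(1 + offset)` times its local mean.
#' @param min_focus_area_px Smallest connected component (px) counted as a
#'   focus; suppresses single-pixel noise.
#' @param foci_density_cutoff Foci per px^2 above which a nucleus is FOCI.
#' @param ring_rel_threshold Fraction of the overall profile mean that the
#'   periphery excess must exceed for a RING call.
#' @param n_profile_rays `"all_boundary_pixels"` (one ray per boundary
#'   pixel) or an integer number of evenly chosen boundary pixels.
#' @return A `ClassifierParams` list.
#' @export
classifier_params <- function(adaptive_window_px = 15L,
                              adaptive_rel_offset = 0.15,
                              min_focus_area_px = 4L,
                              foci_density_cutoff = 0.0035,
                              ring_rel_threshold = 0.10,
                              n_profile_rays = "all_boundary_pixels") {
  stopifnot(adaptive_window_px >= 3L, adaptive_window_px %% 2L == 1L,
            min_focus_area_px >= 1L, foci_density_cutoff > 0,
            ring_rel_threshold > 0, ring_rel_threshold < 1)
  structure(list(adaptive_window_px = as.integer(adaptive_window_px),
                 adaptive_rel_offset = adaptive_rel_offset,
                 min_focus_area_px = as.integer(min_focus_area_px),
                 foci_density_cutoff = foci_density_cutoff,
                 ring_rel_threshold = ring_rel_threshold,
                 n_profile_rays = n_profile_rays),
            class = "ClassifierParams")
}

#' Adaptive binarisation of gamma-H2AX signal within one nucleus
#'
#' A pixel is foreground when its intensity strictly exceeds
#' `(1 + adaptive_rel_offset)` times the local mean over the window
#' centred on it, with both the window and the candidate set restricted to
#' nucleus pixels. The multiplicative offset makes the rule invariant to
#' intensity scaling.
#'
#' @param gh2ax A [channel_image()] or numeric matrix.
#' @param nucleus_mask Logical matrix marking the nucleus's pixels.
#' @param params [classifier_params()].
#' @return Logical matrix (same size as the image) of focus-candidate
#'   pixels inside the nucleus.
#' @export
adaptive_binarize <- function(gh2ax, nucleus_mask, params = classifier_params()) {
  img <- if (inherits(gh2ax, "ChannelImage")) gh2ax$pixels else gh2ax
  npix <- sum(nucleus_mask)
  if (npix < 9L)
    rt_error("nucleus smaller than 3x3: adaptive threshold undefined",
             "ringtrack_degenerate_error")
  bb <- mask_bbox(nucleus_mask)
  sub <- img[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  msk <- nucleus_mask[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  half <- (params$adaptive_window_px - 1L) %/% 2L
  local_mean <- box_local_mean(sub, half, mask = msk)
  fg_sub <- msk & !is.na(local_mean) &
    sub > (1 + params$adaptive_rel_offset) * local_mean
  out <- matrix(FALSE, nrow(img), ncol(img))
  out[bb$r1:bb$r2, bb$c1:bb$c2] <- fg_sub
  out
}

#' Count foci in a binarised nucleus
#'
#' Foci are 8-connected components of the focus-candidate mask with area at
#' least `min_focus_area_px`. The foci density is the count divided by the
#' nucleus area; the FOCI call requires density strictly above
#' `foci_density_cutoff`.
#'
#' @param foci_mask Logical matrix from [adaptive_binarize()].
#' @param area_px Nucleus area in pixels.
#' @param params [classifier_params()].
#' @return List (`FociResult`): `foci_count`, `foci_density`, `is_foci`,
#'   `focus_centroids` (0-based, one row per focus).
#' @export
count_foci <- function(foci_mask, area_px, params = classifier_params()) {
  lm <- label_objects(foci_mask)
  n <- attr(lm, "n_objects")
  centroids <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  count <- 0L
  if (n > 0L) {
    h <- nrow(lm)
    idx <- which(lm > 0L)
    lab <- as.integer(lm[idx])
    sizes <- tabulate(lab, nbins = n)
    keep <- which(sizes >= params$min_focus_area_px)
    count <- length(keep)
    if (count) {
      r <- ((idx - 1L) %% h)
      cc <- ((idx - 1L) %/% h)
      cr <- as.numeric(rowsum(r, lab)) / sizes
      ccol <- as.numeric(rowsum(cc, lab)) / sizes
      centroids <- cbind(row = cr[keep], col = ccol[keep])
    }
  }
  density <- count / area_px
  list(foci_count = count, foci_density = density,
       is_foci = density > params$foci_density_cutoff,
       focus_centroids = centroids)
}

#' Cast intensity rays from the centroid to every boundary pixel
#'
#' One ray per boundary pixel, sampled at ~1 px steps (endpoints included)
#' with bilinear interpolation of the gamma-H2AX intensities. If the
#' centroid falls outside the nucleus (strongly concave object), the
#' interior pixel nearest the centroid is used as the ray origin.
#'
#' @param gh2ax A [channel_image()] or numeric matrix.
#' @param centroid Numeric length-2, 0-based (row, col) centre of mass.
#' @param boundary n x 2 matrix of 0-based boundary (row, col) pixels.
#' @param nucleus_mask Logical matrix of nucleus membership.
#' @return List of numeric vectors, one per boundary pixel.
#' @export
cast_radial_profiles <- function(gh2ax, centroid, boundary, nucleus_mask) {
  img <- if (inherits(gh2ax, "ChannelImage")) gh2ax$pixels else gh2ax
  m <- nrow(boundary)
  if (m < 8L)
    rt_error("nucleus has fewer than 8 boundary pixels",
             "ringtrack_degenerate_error")
  if (sum(nucleus_mask) <= m)
    rt_error("nucleus is all boundary: radial profile undefined",
             "ringtrack_degenerate_error")
  r0 <- centroid[1]; c0 <- centroid[2]
  ri <- round(r0) + 1L; ci <- round(c0) + 1L
  inside <- ri >= 1L && ri <= nrow(img) && ci >= 1L && ci <= ncol(img) &&
    nucleus_mask[ri, ci]
  if (!inside) {
    idx <- which(nucleus_mask)
    h <- nrow(nucleus_mask)
    rr <- ((idx - 1L) %% h); cc <- ((idx - 1L) %/% h)
    nearest <- which.min((rr - r0)^2 + (cc - c0)^2)
    r0 <- rr[nearest]; c0 <- cc[nearest]
  }
  dr <- boundary[, 1] - r0
  dc <- boundary[, 2] - c0
  len <- sqrt(dr^2 + dc^2)
  n_i <- pmax(2L, ceiling(len) + 1L)
  step <- sequence(n_i) - 1L
  ray_of <- rep.int(seq_len(m), n_i)
  frac <- step / (rep.int(n_i, n_i) - 1L)
  vals <- bilinear_sample(img, r0 + frac * rep.int(dr, n_i),
                          c0 + frac * rep.int(dc, n_i))
  unname(split(vals, ray_of))
}

#' Resample rays to a common length and average
#'
#' Each ray is linearly interpolated onto `L` equally spaced positions,
#' where `L` is the longest ray's sample count (endpoints preserved), then
#' averaged pointwise. The quartile split is at `floor(0.75 L)`: profile
#' positions `1..floor(0.75L)` form the first three quartiles (nuclear
#' interior) and the remainder the last quartile (periphery). The ring
#' score is `(mean_q4 - mean_q123) / overall_mean`.
#'
#' @param rays List of numeric vectors from [cast_radial_profiles()].
#' @return List (`RadialProfile`): `profile`, `L`, `mean_q4`, `mean_q123`,
#'   `overall_mean`, `ring_score`.
#' @export
resample_and_average <- function(rays) {
  if (length(rays) == 0L)
    rt_error("no rays to average", "ringtrack_internal_error")
  lens <- lengths(rays)
  L <- max(lens)
  xout <- seq(0, 1, length.out = L)
  acc <- numeric(L)
  for (ray in rays) {
    n <- length(ray)
    acc <- acc + if (n == L) ray
    else stats::approx(seq(0, 1, length.out = n), ray, xout = xout)$y
  }
  profile <- acc / length(rays)
  n123 <- floor(0.75 * L)
  mean_q123 <- mean(profile[seq_len(n123)])
  mean_q4 <- mean(profile[(n123 + 1L):L])
  overall <- mean(profile)
  score <- if (overall > 0) (mean_q4 - mean_q123) / overall else NA_real_
  list(profile = profile, L = L, mean_q4 = mean_q4, mean_q123 = mean_q123,
       overall_mean = overall, ring_score = score)
}

#' RING decision on an averaged radial profile
#'
#' `TRUE` when the last-quartile mean exceeds the first-three-quartile mean
#' by strictly more than `ring_rel_threshold` times the overall mean. The
#' difference is signed: a bright centre can never produce a RING call. A
#' zero-signal profile returns `FALSE` with attribute `qc = "zero_signal"`.
#'
#' @param profile `RadialProfile` from [resample_and_average()].
#' @param params [classifier_params()].
#' @return Logical scalar.
#' @export
classify_ring <- function(profile, params = classifier_params()) {
  if (!is.finite(profile$overall_mean) || profile$overall_mean <= 0)
    return(structure(FALSE, qc = "zero_signal"))
  (profile$mean_q4 - profile$mean_q123) >
    params$ring_rel_threshold * profile$overall_mean
}

#' Classify one nucleus's gamma-H2AX distribution
#'
#' Applies the foci-density rule first; only non-foci nuclei proceed to the
#' radial-profile RING/UNIFORM split, so the two marked phenotypes are
#' mutually exclusive by construction.
#'
#' @param gh2ax A [channel_image()] or numeric matrix.
#' @param nucleus_mask Logical matrix of this nucleus's pixels.
#' @param record One-row data frame for this nucleus (from
#'   [measure_nuclei()]): needs `nucleus_id`, `area_px`, `centroid_row`,
#'   `centroid_col`.
#' @param boundary n x 2 matrix of 0-based boundary pixels.
#' @param params [classifier_params()].
#' @return List (`PhenotypeCall`): `nucleus_id`, `phenotype` (one of
#'   `"FOCI"`, `"RING"`, `"UNIFORM"`), `foci` (FociResult), `radial`
#'   (RadialProfile, `NULL` for FOCI nuclei).
#' @export
classify_nucleus <- function(gh2ax, nucleus_mask, record, boundary,
                             params = classifier_params()) {
  fm <- adaptive_binarize(gh2ax, nucleus_mask, params)
  foci <- count_foci(fm, record$area_px, params)
  if (foci$is_foci) {
    return(list(nucleus_id = record$nucleus_id, phenotype = "FOCI",
                foci = foci, radial = NULL))
  }
  if (is.numeric(params$n_profile_rays) && nrow(boundary) > params$n_profile_rays) {
    pick <- unique(round(seq(1, nrow(boundary), length.out = params$n_profile_rays)))
    boundary <- boundary[pick, , drop = FALSE]
  }
  rays <- cast_radial_profiles(gh2ax, c(record$centroid_row, record$centroid_col),
                               boundary, nucleus_mask)
  prof <- resample_and_average(rays)
  ring <- classify_ring(prof, params)
  list(nucleus_id = record$nucleus_id,
       phenotype = if (isTRUE(as.logical(ring))) "RING" else "UNIFORM",
       foci = foci, radial = prof)
}

#' Classify every accepted nucleus in a segmented field
#'
#' @param fov A [field_of_view()].
#' @param seg Result of [segment_nuclei()].
#' @param params [classifier_params()].
#' @return Data frame with one row per accepted nucleus: `nucleus_id`,
#'   `foci_count`, `foci_density`, `ring_score`, `phenotype`. The list of
#'   full `PhenotypeCall`s is attached as attribute `"calls"`.
#' @export
classify_field <- function(fov, seg, params = classifier_params()) {
  gh2ax <- fov$channels$gh2ax
  ids <- attr(seg$mask, "nucleus_id")
  k <- length(ids)
  calls <- vector("list", k)
  rows <- vector("list", k)
  maskm <- unclass(seg$mask)
  for (j in seq_len(k)) {
    id <- ids[j]
    nucleus_mask <- maskm == j
    record <- seg$records[seg$records$nucleus_id == id, , drop = FALSE]
    call <- classify_nucleus(gh2ax, nucleus_mask, record,
                             seg$boundary[[id]], params)
    calls[[j]] <- call
    rows[[j]] <- data.frame(
      nucleus_id = id,
      foci_count = call$foci$foci_count,
      foci_density = call$foci$foci_density,
      ring_score = if (is.null(call$radial)) NA_real_ else call$radial$ring_score,
      phenotype = call$phenotype
    )
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(0), foci_count = integer(0),
               foci_density = numeric(0), ring_score = numeric(0),
               phenotype = character(0))
  attr(out, "calls") <- calls
  out
}
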