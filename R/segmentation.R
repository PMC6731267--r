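#' Nucleus segmentation parameters
#'
#' Parameters of DAPI-channel nucleus detection. The four object filters
#' (area, eccentricity, circularity, intensity) use strict inequalities:
#' an object is kept when area > `min_area_px`, eccentricity <
#' `max_eccentricity`, circularity (4*pi*A/P^2) > `min_circularity`, and
#' mean DAPI intensity < `intensity_median_factor` times the median mean
#' intensity over all candidate objects in the field.
#'
#' @param gaussian_sigma_px Gaussian smoothing sigma (px) applied to DAPI
#'   before thresholding.
#' @param struct_radius_px Radius (px) of the disc structuring element used
#'   by morphological refinement.
#' @param n_dilations,n_erosions Number of dilation / erosion passes.
#' @param min_area_px Minimum object area in pixels (strict `>`).
#' @param max_eccentricity Maximum moment-ellipse eccentricity (strict `<`).
#' @param min_circularity Minimum circularity 4*pi*A/P^2 (strict `>`).
#' @param intensity_median_factor Objects at or above this multiple of the
#'   field's median object intensity are rejected (strict `<` to keep).
#' @param exclude_border If `TRUE`, drop objects touching the image border.
#' @return A `SegmentationParams` list.
#' @export
seg_params <- function(gaussian_sigma_px = 2.0, struct_radius_px = 3L,
                       n_dilations = 2L, n_erosions = 2L,
                       min_area_px = 400, max_eccentricity = 0.8,
                       min_circularity = 0.85, intensity_median_factor = 2.0,
                       exclude_border = FALSE) {
  stopifnot(gaussian_sigma_px > 0, struct_radius_px >= 1,
            n_dilations >= 0, n_erosions >= 0,
            min_area_px > 0, max_eccentricity >= 0, max_eccentricity < 1,
            min_circularity > 0, intensity_median_factor > 1)
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 struct_radius_px = as.integer(struct_radius_px),
                 n_dilations = as.integer(n_dilations),
                 n_erosions = as.integer(n_erosions),
                 min_area_px = min_area_px,
                 max_eccentricity = max_eccentricity,
                 min_circularity = min_circularity,
                 intensity_median_factor = intensity_median_factor,
                 exclude_border = isTRUE(exclude_border)),
            class = "SegmentationParams")
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along matrix rows (dimension 1) with symmetric-reflect padding.
conv_dim1 <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n:(n - min(r, n) + 1L))
  while (length(idx) < n + 2L * r) idx <- c(rev(idx), idx, rev(idx)) # tiny images
  p <- m[idx[seq_len(n + 2L * r)], , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * p[j:(j + n - 1L), , drop = FALSE]
  out
}

#' Gaussian-smooth a DAPI image
#'
#' Separable 2-D Gaussian convolution with a normalised kernel truncated at
#' 3 sigma and symmetric (reflective) boundary padding, so total intensity
#' is conserved.
#'
#' @param dapi A [channel_image()] or numeric matrix.
#' @param sigma Positive smoothing sigma in pixels.
#' @return Numeric matrix of the same dimensions.
#' @export
smooth_dapi <- function(dapi, sigma = 2.0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    rt_error("sigma must be a positive number", "ringtrack_parameter_error")
  m <- if (inherits(dapi, "ChannelImage")) dapi$pixels else dapi
  k <- gaussian_kernel_1d(sigma)
  t(conv_dim1(t(conv_dim1(m, k)), k))
}

# Exhaustive between-class-variance maximisation over a 256-bin histogram
# spanning the image's own intensity range (hence exactly scale-invariant).
# Returns the threshold value; foreground is strictly above it.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2])
    rt_error("constant image: no global threshold exists",
             "ringtrack_degenerate_error")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bin, nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[levels]; mu_total <- mu[levels]
  t_cand <- seq_len(levels - 1L)
  w0 <- w[t_cand]; m0 <- mu[t_cand]
  valid <- w0 > 0 & w0 < n
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- (mu_total * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * (1 - w0[valid] / n))
  best <- which(sb == max(sb))
  t_star <- round(mean(best))           # tie-break: centre of the flat optimum
  breaks[t_star + 1L]                   # upper edge of the background class
}

#' Binarise a smoothed image with an automatic global threshold
#'
#' The threshold is found by exhaustive between-class-variance maximisation
#' (Otsu's criterion) on a 256-bin histogram of the image. Foreground is
#' strictly above the threshold. The chosen threshold is attached as
#' attribute `"threshold"` for provenance logging.
#'
#' @param smoothed Numeric matrix (typically from [smooth_dapi()]).
#' @return Logical matrix (foreground mask) with attribute `threshold`.
#' @export
global_binarize <- function(smoothed) {
  thr <- otsu_threshold(smoothed)
  structure(smoothed > thr, threshold = thr)
}

#' Morphologically refine a binary mask
#'
#' Applies `n_dilations` dilation passes with a disc structuring element,
#' fills all enclosed background holes, then applies `n_erosions` erosion
#' passes with the same element.
#'
#' @param binary Logical/0-1 matrix.
#' @param params [seg_params()].
#' @return Logical matrix.
#' @export
refine_mask <- function(binary, params = seg_params()) {
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  brush <- EBImage::makeBrush(2L * params$struct_radius_px + 1L, shape = "disc")
  for (i in seq_len(params$n_dilations)) m <- EBImage::dilate(m, brush)
  m <- EBImage::fillHull(m)
  for (i in seq_len(params$n_erosions)) m <- EBImage::erode(m, brush)
  matrix(as.logical(m), nrow(binary), ncol(binary))
}

#' Label 8-connected foreground components
#'
#' Components are labelled `1..n` in top-left-first scan order (row-major:
#' the component whose first pixel comes first reading row by row gets the
#' lower label). Diagonal contact joins objects (8-connectivity).
#'
#' @param binary Logical/0-1 matrix.
#' @return A [label_mask()].
#' @export
label_objects <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  fg <- binary != 0
  labels <- matrix(0L, h, w)
  idx <- which(fg)
  if (length(idx)) {
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    idx <- idx[order(rows, cols)]     # row-major scan order
    lab <- 0L
    for (p in idx) {
      if (labels[p] != 0L) next
      lab <- lab + 1L
      labels[p] <- lab
      frontier <- p
      while (length(frontier)) {
        r <- ((frontier - 1L) %% h) + 1L
        cc <- ((frontier - 1L) %/% h) + 1L
        nb <- integer(0)
        for (dr in -1L:1L) {
          rr <- r + dr
          keep_r <- rr >= 1L & rr <= h
          for (dc in -1L:1L) {
            if (dr == 0L && dc == 0L) next
            c2 <- cc + dc
            ok <- keep_r & c2 >= 1L & c2 <= w
            if (any(ok)) nb <- c(nb, (c2[ok] - 1L) * h + rr[ok])
          }
        }
        nb <- unique(nb)
        nb <- nb[fg[nb] & labels[nb] == 0L]
        if (length(nb)) labels[nb] <- lab
        frontier <- nb
      }
    }
  }
  label_mask(labels)
}

# Vossepoel-Smeulders contour-length estimator: border pixels are weighted
# by their local 3x3 border configuration (straight 1, diagonal sqrt(2),
# corner (1+sqrt(2))/2). Returns the per-pixel weight image (non-zero only
# on border pixels of the 4-connectivity-eroded complement).
perimeter_weight_image <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  shift_pad <- function(m, dr, dc, fill = 0) {
    out <- matrix(fill, h, w)
    rs <- max(1L, 1L - dr):min(h, h - dr)
    cs <- max(1L, 1L - dc):min(w, w - dc)
    out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  f <- fg * 1
  eroded <- fg & shift_pad(f, -1L, 0L) & shift_pad(f, 1L, 0L) &
    shift_pad(f, 0L, -1L) & shift_pad(f, 0L, 1L)
  border <- (fg & !eroded) * 1
  code <- border +
    2 * (shift_pad(border, -1L, 0L) + shift_pad(border, 1L, 0L) +
           shift_pad(border, 0L, -1L) + shift_pad(border, 0L, 1L)) +
    10 * (shift_pad(border, -1L, -1L) + shift_pad(border, -1L, 1L) +
            shift_pad(border, 1L, -1L) + shift_pad(border, 1L, 1L))
  wt <- numeric(50)
  wt[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  wt[c(21, 33) + 1L] <- sqrt(2)
  wt[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  matrix(wt[code + 1L], h, w)
}

#' Measure geometry and intensity of labelled objects
#'
#' For every label computes: pixel area; perimeter by the standard weighted
#' contour-length estimator; unweighted centroid; eccentricity of the
#' moment-matched ellipse; circularity 4*pi*A/P^2; mean DAPI intensity;
#' and the boundary pixels (member pixels 8-adjacent to non-members or to
#' the image edge). Coordinates are 0-based (row, col), origin top-left.
#'
#' @param mask A [label_mask()].
#' @param dapi A [channel_image()] or numeric matrix aligned with `mask`.
#' @return Data frame with one row per object (columns `nucleus_id`,
#'   `area_px`, `perimeter_px`, `centroid_row`, `centroid_col`,
#'   `eccentricity`, `circularity`, `mean_dapi`, `touches_border`,
#'   `accepted`, `rejection_reason`) and attribute `boundary`: a list of
#'   n x 2 matrices of 0-based boundary (row, col) per object.
#' @export
measure_nuclei <- function(mask, dapi) {
  d <- if (inherits(dapi, "ChannelImage")) dapi$pixels else dapi
  if (!all(dim(mask) == dim(d)))
    rt_error("mask and DAPI dimensions differ", "ringtrack_format_error")
  h <- nrow(mask); w <- ncol(mask)
  n <- attr(mask, "n_objects")
  if (is.null(n)) n <- max(mask)
  empty <- data.frame(nucleus_id = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), eccentricity = numeric(0),
                      circularity = numeric(0), mean_dapi = numeric(0),
                      touches_border = logical(0), accepted = logical(0),
                      rejection_reason = character(0))
  if (n == 0L) {
    attr(empty, "boundary") <- list()
    return(empty)
  }
  idx <- which(mask > 0L)
  lab <- as.integer(mask[idx])
  r <- as.numeric((idx - 1L) %% h)          # 0-based; double to avoid
  cc <- as.numeric((idx - 1L) %/% h)        # integer overflow in moments
  area <- tabulate(lab, nbins = n)
  sum_by <- function(v) as.numeric(rowsum(v, lab, reorder = TRUE))
  cr <- sum_by(r) / area
  ccol <- sum_by(cc) / area
  mu20 <- sum_by(r^2) / area - cr^2
  mu02 <- sum_by(cc^2) / area - ccol^2
  mu11 <- sum_by(r * cc) / area - cr * ccol
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  mean_dapi <- sum_by(d[idx]) / area

  pw <- perimeter_weight_image(mask > 0L)
  perim <- as.numeric(rowsum(pw[idx], lab, reorder = TRUE))
  perim[perim == 0] <- 1            # isolated pixels: unit perimeter floor
  circ <- 4 * pi * area / perim^2

  # boundary: member pixels with any 8-neighbour of a different label
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  is_boundary <- rep(FALSE, length(idx))
  pr <- r + 2L; pc <- cc + 2L       # 1-based position in padded
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    nbr <- padded[(pc + dc - 1L) * (h + 2L) + (pr + dr)]
    is_boundary <- is_boundary | nbr != lab
  }
  bidx <- which(is_boundary)
  boundary <- split.data.frame(cbind(row = r[bidx], col = cc[bidx]), lab[bidx])
  boundary <- lapply(seq_len(n), function(i) {
    b <- boundary[[as.character(i)]]
    if (is.null(b)) cbind(row = cr[i], col = ccol[i]) else b
  })

  touches <- as.logical(rowsum((r == 0L | r == h - 1L | cc == 0L | cc == w - 1L) * 1,
                               lab, reorder = TRUE) > 0)
  out <- data.frame(nucleus_id = seq_len(n), area_px = area,
                    perimeter_px = perim, centroid_row = cr,
                    centroid_col = ccol, eccentricity = ecc,
                    circularity = circ, mean_dapi = mean_dapi,
                    touches_border = touches,
                    accepted = NA, rejection_reason = NA_character_)
  attr(out, "boundary") <- boundary
  out
}

#' Apply the four nucleus filters
#'
#' Objects are kept only if (in this order) area > `min_area_px`,
#' eccentricity < `max_eccentricity`, circularity > `min_circularity`, and
#' mean DAPI < `intensity_median_factor` x the median of mean DAPI over
#' *all* candidate objects (computed once, before any rejection, so the
#' outcome is independent of record order). All inequalities are strict;
#' the first failed criterion is recorded as the rejection reason.
#'
#' @param records Data frame from [measure_nuclei()].
#' @param params [seg_params()].
#' @return `records` with `accepted` and `rejection_reason` filled in.
#' @export
filter_nuclei <- function(records, params = seg_params()) {
  if (nrow(records) == 0L)
    rt_error("no candidate objects to filter", "ringtrack_degenerate_error")
  med <- stats::median(records$mean_dapi)
  reason <- rep("none", nrow(records))
  reason[!(records$mean_dapi < params$intensity_median_factor * med)] <- "intensity"
  reason[!(records$circularity > params$min_circularity)] <- "regularity"
  reason[!(records$eccentricity < params$max_eccentricity)] <- "eccentricity"
  reason[!(records$area_px > params$min_area_px)] <- "area"
  if (params$exclude_border)
    reason[reason == "none" & records$touches_border] <- "border"
  records$accepted <- reason == "none"
  records$rejection_reason <- reason
  records
}

#' Segment nuclei in a field of view
#'
#' Full DAPI segmentation: Gaussian smoothing, automatic global threshold,
#' morphological refinement, 8-connected labelling, per-object measurement
#' and the four-filter quality gate. The returned mask contains only
#' accepted nuclei, relabelled `1..k` in scan order; the record table keeps
#' every candidate (accepted and rejected) for QC.
#'
#' @param fov A [field_of_view()].
#' @param params [seg_params()].
#' @return List with `mask` (accepted-nuclei [label_mask()], attribute
#'   `nucleus_id` maps mask label -> candidate `nucleus_id`, attribute
#'   `threshold` the global threshold used), `records` (all candidates),
#'   and `boundary` (boundary pixel list indexed by candidate id).
#' @export
segment_nuclei <- function(fov, params = seg_params()) {
  dapi <- fov$channels$dapi
  sm <- smooth_dapi(dapi, params$gaussian_sigma_px)
  bin <- global_binarize(sm)
  thr <- attr(bin, "threshold")
  ref <- refine_mask(bin, params)
  lm <- label_objects(ref)
  if (attr(lm, "n_objects") == 0L) {
    warning("no objects detected after refinement")
    rec <- measure_nuclei(lm, dapi)
    return(list(mask = lm, records = rec, boundary = list(), threshold = thr))
  }
  rec <- measure_nuclei(lm, dapi)
  boundary <- attr(rec, "boundary")
  rec <- filter_nuclei(rec, params)
  keep <- rec$nucleus_id[rec$accepted]
  if (length(keep) == 0L) warning("all candidate objects rejected by filters")
  relab <- integer(attr(lm, "n_objects") + 1L)   # old label+1 -> new label
  relab[keep + 1L] <- seq_along(keep)
  newmask <- label_mask(matrix(relab[unclass(lm) + 1L], nrow(lm), ncol(lm)))
  attr(newmask, "nucleus_id") <- keep
  attr(newmask, "threshold") <- thr
  list(mask = newmask, records = rec, boundary = boundary, threshold = thr)
}
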