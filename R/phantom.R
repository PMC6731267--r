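#' Specification of a synthetic phantom field
#'
#' Parameters of the synthetic-microscopy generator used to validate the
#' pipeline. Nuclei are non-overlapping filled ellipses at 20x widefield
#' scale (areas roughly 600-6400 px^2); the gamma-H2AX channel renders one
#' of three ground-truth patterns per nucleus: UNIFORM (flat base level),
#' FOCI (base plus Gaussian puncta) or RING (base amplified by
#' `ring_amplitude_ratio` in the outer `ring_band_fraction` of the
#' elliptical radial coordinate). Defaults keep every generated nucleus
#' clear of the four segmentation filters and make both classification
#' rules hold analytically before noise.
#'
#' @param field_size_px Integer (height, width); default 1024 x 1024.
#' @param n_nuclei Number of nuclei to place.
#' @param phenotype_mix Named proportions for FOCI/RING/UNIFORM, summing
#'   to 1.
#' @param axis_range_px (min, max) ellipse semi-axis lengths in px.
#' @param axis_ratio_max Maximum major/minor axis ratio. The default 1.4
#'   bounds eccentricity near 0.70 and digital circularity above 0.90, so
#'   phantom nuclei pass the shape filters with margin by construction.
#' @param dapi_level DAPI intensity inside nuclei (arbitrary units).
#' @param gh2ax_base gamma-H2AX base intensity inside nuclei.
#' @param focus_sigma_px Gaussian sigma of rendered foci.
#' @param focus_amplitude Peak intensity a focus adds on top of the base.
#' @param foci_per_nucleus_range `NULL` (default) draws each FOCI
#'   nucleus's count uniformly between 1.5x and 2.5x `cutoff * area` so
#'   the density rule holds with margin at any nucleus size; or an
#'   explicit integer (min, max) range.
#' @param ring_band_fraction Fraction of the radial coordinate occupied by
#'   the peripheral band (default 0.25, i.e. the last radial quartile).
#' @param ring_amplitude_ratio Band-to-interior intensity ratio.
#' @param p53bp1_mode `"absent"`, `"copy_foci"` (53BP1 mirrors the
#'   gamma-H2AX foci pattern, as canonical repair foci do) or
#'   `"independent"` (53BP1 foci drawn independently).
#' @param noise_model See [degrade()]; default `"none"`.
#' @param bit_depth 8 or 16 (default 16).
#' @param seed Integer seed; the whole field is deterministic given it.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(field_size_px = c(1024L, 1024L), n_nuclei = 30L,
                         phenotype_mix = c(FOCI = 1 / 3, RING = 1 / 3, UNIFORM = 1 / 3),
                         axis_range_px = c(18, 45), axis_ratio_max = 1.4,
                         dapi_level = 10000, gh2ax_base = 10000,
                         focus_sigma_px = 1.5, focus_amplitude = 30000,
                         foci_per_nucleus_range = NULL,
                         ring_band_fraction = 0.25, ring_amplitude_ratio = 2.0,
                         p53bp1_mode = c("absent", "copy_foci", "independent"),
                         noise_model = "none", bit_depth = 16L, seed = 1L) {
  p53bp1_mode <- match.arg(p53bp1_mode)
  if (abs(sum(phenotype_mix) - 1) > 1e-9)
    rt_error("phenotype_mix proportions must sum to 1", "ringtrack_config_error")
  stopifnot(length(field_size_px) == 2L, all(field_size_px >= 64),
            axis_range_px[1] > 0, axis_range_px[2] >= axis_range_px[1],
            axis_ratio_max >= 1, ring_band_fraction > 0, ring_band_fraction < 1,
            ring_amplitude_ratio > 1, bit_depth %in% c(8L, 16L))
  structure(list(field_size_px = as.integer(field_size_px),
                 n_nuclei = as.integer(n_nuclei),
                 phenotype_mix = phenotype_mix,
                 axis_range_px = axis_range_px, axis_ratio_max = axis_ratio_max,
                 dapi_level = dapi_level, gh2ax_base = gh2ax_base,
                 focus_sigma_px = focus_sigma_px,
                 focus_amplitude = focus_amplitude,
                 foci_per_nucleus_range = foci_per_nucleus_range,
                 ring_band_fraction = ring_band_fraction,
                 ring_amplitude_ratio = ring_amplitude_ratio,
                 p53bp1_mode = p53bp1_mode, noise_model = noise_model,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Largest-remainder apportionment of n into the given proportions.
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

# Elliptical radial coordinate (0 at centre, 1 on the boundary) of grid
# points relative to an ellipse (0-based centre, semi-axes a >= b, theta).
ellipse_rho <- function(rows, cols, cr, cc, a, b, theta) {
  dr <- rows - cr; dc <- cols - cc
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

place_foci <- function(a, b, theta, cr, cc, count, min_dist) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < count && tries < 2000L * count) {
    tries <- tries + 1L
    # uniform in the ellipse interior, kept away from the rim
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * 0.85
    u <- rad * a * cos(ang); v <- rad * b * sin(ang)
    r <- cr + u * sin(theta) + v * cos(theta)
    cl <- cc + u * cos(theta) - v * sin(theta)
    if (nrow(pts) == 0 ||
        min((pts[, 1] - r)^2 + (pts[, 2] - cl)^2) >= min_dist^2)
      pts <- rbind(pts, c(r, cl))
  }
  if (nrow(pts) < count)
    rt_error("could not place the requested number of foci", "ringtrack_placement_error")
  pts
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Renders the phantom described by `spec` and returns both the field and
#' the per-nucleus ground truth. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param condition Condition label for the field.
#' @param field_id Field identifier.
#' @return List: `fov` ([field_of_view()]) and `truth` (data frame with
#'   `nucleus_id`, `centroid_row`, `centroid_col`, `semi_major`,
#'   `semi_minor`, `orientation`, `true_phenotype`, `true_foci_count`,
#'   `area_px`).
#' @export
generate_field <- function(spec, condition = "phantom", field_id = "phantom1") {
  with_seed(spec$seed, {
    h <- spec$field_size_px[1]; w <- spec$field_size_px[2]
    n <- spec$n_nuclei
    counts <- apportion(n, spec$phenotype_mix[c("FOCI", "RING", "UNIFORM")])
    phenos <- sample(rep(names(counts), counts))

    # rejection-sample non-overlapping ellipse placements
    placed <- data.frame(cr = numeric(0), cc = numeric(0), a = numeric(0),
                         b = numeric(0), theta = numeric(0))
    fails <- 0L
    # gap between nuclei must exceed the morphological closing reach
    # (2 dilation passes x radius-3 disc = 12 px) plus smoothing spread,
    # or neighbouring phantoms would merge during segmentation
    margin <- 16
    while (nrow(placed) < n) {
      if (fails > 10L * n)
        rt_error("cannot place the requested nuclei without overlap",
                 "ringtrack_placement_error")
      a <- stats::runif(1, spec$axis_range_px[1], spec$axis_range_px[2])
      ratio <- stats::runif(1, 1, spec$axis_ratio_max)
      b <- a / ratio
      theta <- stats::runif(1, 0, pi)
      cr <- stats::runif(1, a + margin, h - 1 - a - margin)
      cc <- stats::runif(1, a + margin, w - 1 - a - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$cr - cr)^2 + (placed$cc - cc)^2) >
              placed$a + a + margin)) {
        placed <- rbind(placed, data.frame(cr = cr, cc = cc, a = a, b = b,
                                           theta = theta))
        fails <- 0L
      } else fails <- fails + 1L
    }

    dapi <- matrix(0, h, w)
    gh2ax <- matrix(0, h, w)
    p53 <- if (spec$p53bp1_mode != "absent") matrix(0, h, w) else NULL
    truth <- vector("list", n)

    for (i in seq_len(n)) {
      p <- placed[i, ]
      ext <- ceiling(p$a) + 2L
      r1 <- max(1L, floor(p$cr) - ext); r2 <- min(h, ceiling(p$cr) + ext)
      c1 <- max(1L, floor(p$cc) - ext); c2 <- min(w, ceiling(p$cc) + ext)
      rows <- matrix((r1:r2) - 1, r2 - r1 + 1L, c2 - c1 + 1L)
      cols <- matrix((c1:c2) - 1, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
      rho <- ellipse_rho(rows, cols, p$cr, p$cc, p$a, p$b, p$theta)
      inside <- rho <= 1
      area <- sum(inside)
      dapi[r1:r2, c1:c2][inside] <- spec$dapi_level

      ph <- phenos[i]
      g <- matrix(0, nrow(rows), ncol(cols))
      g[inside] <- spec$gh2ax_base
      nf <- 0L
      if (ph == "RING") {
        band <- inside & rho > (1 - spec$ring_band_fraction)
        g[band] <- spec$gh2ax_base * spec$ring_amplitude_ratio
      } else if (ph == "FOCI") {
        rng <- spec$foci_per_nucleus_range
        if (is.null(rng)) {
          cutoff <- 0.0035
          lo <- ceiling(1.3 * cutoff * area)
          hi <- ceiling(1.7 * cutoff * area)
        } else {
          lo <- rng[1]; hi <- rng[2]
        }
        nf <- if (hi > lo) sample(lo:hi, 1L) else as.integer(lo)
        pts <- place_foci(p$a, p$b, p$theta, p$cr, p$cc, nf,
                          min_dist = max(7.5, 5 * spec$focus_sigma_px))
        for (j in seq_len(nf)) {
          d2 <- (rows - pts[j, 1])^2 + (cols - pts[j, 2])^2
          g <- g + spec$focus_amplitude * exp(-d2 / (2 * spec$focus_sigma_px^2))
        }
        g[!inside] <- 0
        if (!is.null(p53) && spec$p53bp1_mode == "copy_foci") {
          pg <- matrix(0, nrow(rows), ncol(cols))
          pg[inside] <- spec$gh2ax_base / 2
          for (j in seq_len(nf)) {
            d2 <- (rows - pts[j, 1])^2 + (cols - pts[j, 2])^2
            pg <- pg + spec$focus_amplitude * exp(-d2 / (2 * spec$focus_sigma_px^2))
          }
          pg[!inside] <- 0
          p53[r1:r2, c1:c2] <- pmax(p53[r1:r2, c1:c2], pg)
        }
      }
      gh2ax[r1:r2, c1:c2] <- pmax(gh2ax[r1:r2, c1:c2], g)
      if (!is.null(p53) && spec$p53bp1_mode == "copy_foci" && ph != "FOCI") {
        # diffuse nucleoplasmic 53BP1 in nuclei without canonical foci
        pg <- matrix(0, nrow(rows), ncol(cols))
        pg[inside] <- spec$gh2ax_base / 2
        p53[r1:r2, c1:c2] <- pmax(p53[r1:r2, c1:c2], pg)
      }
      if (!is.null(p53) && spec$p53bp1_mode == "independent") {
        pg <- matrix(0, nrow(rows), ncol(cols))
        pg[inside] <- spec$gh2ax_base / 2
        npts <- max(1L, round(area / 800))
        pts <- place_foci(p$a, p$b, p$theta, p$cr, p$cc, npts,
                          min_dist = 4.5 * spec$focus_sigma_px)
        for (j in seq_len(nrow(pts))) {
          d2 <- (rows - pts[j, 1])^2 + (cols - pts[j, 2])^2
          pg <- pg + spec$focus_amplitude * exp(-d2 / (2 * spec$focus_sigma_px^2))
        }
        pg[!inside] <- 0
        p53[r1:r2, c1:c2] <- pmax(p53[r1:r2, c1:c2], pg)
      }
      truth[[i]] <- data.frame(nucleus_id = i, centroid_row = p$cr,
                               centroid_col = p$cc, semi_major = p$a,
                               semi_minor = p$b, orientation = p$theta,
                               true_phenotype = ph, true_foci_count = nf,
                               area_px = area)
    }

    maxval <- 2^spec$bit_depth - 1
    clipr <- function(m) round(pmin(pmax(m, 0), maxval))
    channels <- list(
      dapi = channel_image(clipr(dapi), "dapi", spec$bit_depth),
      gh2ax = channel_image(clipr(gh2ax), "gh2ax", spec$bit_depth)
    )
    if (!is.null(p53))
      channels$p53bp1 <- channel_image(clipr(p53), "p53bp1", spec$bit_depth)
    fov <- field_of_view(channels, field_id = field_id, condition = condition)
    if (!identical(spec$noise_model, "none"))
      fov <- degrade(fov, spec$noise_model, seed = spec$seed + 1L)
    list(fov = fov, truth = do.call(rbind, truth))
  })
}

#' Apply a camera noise model to a field
#'
#' Supported models: `"none"`, `list(type = "gaussian", sd = s)` (additive
#' read noise), `list(type = "poisson")` (shot noise: each pixel replaced
#' by a Poisson draw with its value as mean), and
#' `list(type = "poisson+gaussian", sd = s)`. Output is rounded and
#' clipped to the channel's bit-depth range. Deterministic given `seed`.
#'
#' @param fov A [field_of_view()].
#' @param noise_model Model descriptor as above.
#' @param seed Integer seed.
#' @return A degraded [field_of_view()].
#' @export
degrade <- function(fov, noise_model, seed = 1L) {
  if (identical(noise_model, "none")) return(fov)
  if (is.character(noise_model)) noise_model <- list(type = noise_model)
  type <- noise_model$type
  if (!type %in% c("none", "gaussian", "poisson", "poisson+gaussian"))
    rt_error(sprintf("unknown noise model '%s'", type), "ringtrack_config_error")
  if (type == "none") return(fov)
  with_seed(seed, {
    for (role in names(fov$channels)) {
      ch <- fov$channels[[role]]
      px <- ch$pixels
      if (type %in% c("poisson", "poisson+gaussian"))
        px <- matrix(stats::rpois(length(px), lambda = px), nrow(px), ncol(px))
      if (type %in% c("gaussian", "poisson+gaussian"))
        px <- px + stats::rnorm(length(px), sd = noise_model$sd)
      maxval <- 2^ch$bit_depth - 1
      px <- round(pmin(pmax(px, 0), maxval))
      fov$channels[[role]] <- channel_image(px, ch$channel_role, ch$bit_depth)
    }
    fov
  })
}
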