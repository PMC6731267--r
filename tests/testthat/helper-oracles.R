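# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-derivations (loops, direct definitions) so that
# agreement with the package implementations is informative.

# -- flood-fill connected-component oracle (8-connectivity, scan order) ----
flood_fill_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (r in 1:h) for (cc in 1:w) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nextlab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; c2 <- p[2] + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nextlab
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# -- direct 2-D convolution oracle with symmetric-reflect padding ---------
direct_gaussian_conv <- function(m, sigma) {
  radius <- ceiling(3 * sigma)
  x <- seq(-radius, radius)
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- nrow(m); w <- ncol(m)
  reflect <- function(i, n) {          # symmetric: ...2,1,1,2,...,n,n,n-1...
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  out <- matrix(0, h, w)
  for (r in 1:h) for (cc in 1:w) {
    acc <- 0
    for (dr in -radius:radius) for (dc in -radius:radius) {
      acc <- acc + k2[dr + radius + 1, dc + radius + 1] *
        m[reflect(r + dr, h), reflect(cc + dc, w)]
    }
    out[r, cc] <- acc
  }
  out
}

# -- exhaustive Otsu oracle on an explicit histogram ----------------------
otsu_oracle <- function(x, levels = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bin, nbins = levels)
  best <- -Inf; best_t <- integer(0)
  for (t in 1:(levels - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    sb <- w0 / sum(h) * w1 / sum(h) * (m0 - m1)^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
    else if (abs(sb - best) <= 1e-12) best_t <- c(best_t, t)
  }
  breaks[round(mean(best_t)) + 1]
}

# -- dense linear-interpolation oracle ------------------------------------
linear_resample_oracle <- function(ray, L) {
  n <- length(ray)
  xs <- seq(0, 1, length.out = n)
  vapply(seq(0, 1, length.out = L), function(t) {
    if (t <= 0) return(ray[1])
    if (t >= 1) return(ray[n])
    i <- max(which(xs <= t))
    if (i == n) return(ray[n])
    ray[i] + (ray[i + 1] - ray[i]) * (t - xs[i]) / (xs[i + 1] - xs[i])
  }, numeric(1))
}

# -- two-pass naive-sum Pearson oracle ------------------------------------
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# -- brute-force binary morphology with an explicit structuring element ---
brute_dilate <- function(mask, brush) {
  h <- nrow(mask); w <- ncol(mask)
  br <- (nrow(brush) - 1) / 2
  off <- which(brush > 0, arr.ind = TRUE) - br - 1
  out <- matrix(FALSE, h, w)
  for (r in 1:h) for (cc in 1:w) if (mask[r, cc]) {
    for (k in seq_len(nrow(off))) {
      rr <- r + off[k, 1]; c2 <- cc + off[k, 2]
      if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) out[rr, c2] <- TRUE
    }
  }
  out
}
brute_erode <- function(mask, brush) {
  h <- nrow(mask); w <- ncol(mask)
  br <- (nrow(brush) - 1) / 2
  off <- which(brush > 0, arr.ind = TRUE) - br - 1
  out <- matrix(FALSE, h, w)
  for (r in 1:h) for (cc in 1:w) {
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      rr <- r + off[k, 1]; c2 <- cc + off[k, 2]
      if (rr < 1 || rr > h || c2 < 1 || c2 > w || !mask[rr, c2]) {
        keep <- FALSE; break
      }
    }
    out[r, cc] <- keep
  }
  out
}

# -- fixture builders ------------------------------------------------------
render_disc <- function(size, cr, cc, radius) {
  g <- expand.grid(r = 0:(size - 1), c = 0:(size - 1))
  matrix((g$r - cr)^2 + (g$c - cc)^2 <= radius^2, size, size)
}
render_ellipse <- function(size, cr, cc, a, b) {
  g <- expand.grid(r = 0:(size - 1), c = 0:(size - 1))
  matrix(((g$r - cr) / a)^2 + ((g$c - cc) / b)^2 <= 1, size, size)
}

match_truth <- function(acc, truth) {
  vapply(seq_len(nrow(acc)), function(i) {
    which.min((truth$centroid_row - acc$centroid_row[i])^2 +
                (truth$centroid_col - acc$centroid_col[i])^2)
  }, integer(1))
}

rot90m <- function(m, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
rotate_fov <- function(fov, k) {
  chans <- lapply(fov$channels, function(ch)
    channel_image(rot90m(ch$pixels, k), ch$channel_role, ch$bit_depth))
  field_of_view(chans, field_id = fov$field_id, condition = fov$condition)
}

# Shared phantom fields, built once per test run.
.fixtures <- new.env(parent = emptyenv())
acceptance_field <- function(noisy = FALSE) {
  key <- if (noisy) "noisy" else "clean"
  if (is.null(.fixtures[[key]])) {
    spec <- phantom_spec(
      n_nuclei = 60,
      phenotype_mix = c(FOCI = 1 / 3, RING = 1 / 3, UNIFORM = 1 / 3),
      seed = 11,
      noise_model = if (noisy) list(type = "poisson+gaussian", sd = 500) else "none"
    )
    .fixtures[[key]] <- generate_field(spec, condition = if (noisy) "noisy" else "clean")
  }
  .fixtures[[key]]
}
small_field <- function(seed = 5) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    spec <- phantom_spec(field_size_px = c(512L, 512L), n_nuclei = 15L,
                         phenotype_mix = c(FOCI = 0.4, RING = 0.3, UNIFORM = 0.3),
                         dapi_level = 500, gh2ax_base = 500,
                         focus_amplitude = 1500, seed = seed)
    .fixtures[[key]] <- generate_field(spec)
  }
  .fixtures[[key]]
}
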