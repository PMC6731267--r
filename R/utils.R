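# Internal helpers shared across the pipeline.

rt_error <- function(message, class) {
  stop(structure(
    class = c(class, "ringtrack_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Bilinear interpolation of a matrix at 0-based sub-pixel (row, col)
# coordinates. Coordinates are clamped to the image domain.
bilinear_sample <- function(img, row, col) {
  h <- nrow(img); w <- ncol(img)
  r <- pmin(pmax(row, 0), h - 1)
  cc <- pmin(pmax(col, 0), w - 1)
  r0 <- floor(r); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- r - r0; fc <- cc - c0
  # convert to 1-based linear indices (column-major)
  at <- function(ri, ci) img[ri + 1L + ci * h]
  (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c1) +
    fr * (1 - fc) * at(r1, c0) +
    fr * fc * at(r1, c1)
}

# Summed-area table with a zero first row/column so that the sum over rows
# a..b, cols c..d (1-based, inclusive) is I[b+1,d+1]-I[a,d+1]-I[b+1,c]+I[a,c].
integral_image <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 1L, w + 1L)
  out[-1L, -1L] <- m
  out <- apply(out, 2L, cumsum)
  t(apply(out, 1L, cumsum))
}

# Mean of `m` over a centred (2*half+1)^2 square window clipped at the image
# border, optionally restricted to `mask` (mean over masked pixels only).
box_local_mean <- function(m, half, mask = NULL) {
  h <- nrow(m); w <- ncol(m)
  if (is.null(mask)) {
    num <- m
    den <- matrix(1, h, w)
  } else {
    num <- m * mask
    den <- mask * 1
  }
  In <- integral_image(num)
  Id <- integral_image(den)
  rlo <- pmax(seq_len(h) - half, 1L); rhi <- pmin(seq_len(h) + half, h)
  clo <- pmax(seq_len(w) - half, 1L); chi <- pmin(seq_len(w) + half, w)
  win <- function(I) {
    I[rhi + 1L, chi + 1L, drop = FALSE] - I[rlo, chi + 1L, drop = FALSE] -
      I[rhi + 1L, clo, drop = FALSE] + I[rlo, clo, drop = FALSE]
  }
  s <- win(In); n <- win(Id)
  out <- matrix(NA_real_, h, w)
  ok <- n > 0
  out[ok] <- s[ok] / n[ok]
  out
}

# Bounding box (1-based row/col ranges) of TRUE pixels in a logical matrix.
mask_bbox <- function(mask) {
  idx <- which(mask)
  h <- nrow(mask)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  list(r1 = min(r), r2 = max(r), c1 = min(cc), c2 = max(cc))
}
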