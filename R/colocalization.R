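#' Per-nucleus pixelwise correlation between two channels
#'
#' Pearson product-moment correlation between the two channels' raw
#' intensities over the member pixels of one nucleus (no background
#' subtraction). The coefficient is undefined — reported as `NA` with a
#' flag, not an error — when either channel is constant within the nucleus
#' or the nucleus has fewer than 10 pixels.
#'
#' @param chan_a,chan_b [channel_image()] objects or numeric matrices,
#'   pixel-aligned.
#' @param nucleus_mask Logical matrix marking the nucleus's pixels.
#' @param nucleus_id Identifier copied into the result.
#' @return List (`ColocalizationResult`): `nucleus_id`, `pearson_r`
#'   (`NA` when undefined), `n_pixels`, `flag` (`"ok"`,
#'   `"constant_channel"` or `"too_few_pixels"`).
#' @export
pixel_correlation <- function(chan_a, chan_b, nucleus_mask, nucleus_id = NA_integer_) {
  a <- if (inherits(chan_a, "ChannelImage")) chan_a$pixels else chan_a
  b <- if (inherits(chan_b, "ChannelImage")) chan_b$pixels else chan_b
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(nucleus_mask)))
    rt_error("channels and mask must be pixel-aligned", "ringtrack_format_error")
  idx <- which(nucleus_mask)
  n <- length(idx)
  if (n < 10L)
    return(list(nucleus_id = nucleus_id, pearson_r = NA_real_, n_pixels = n,
                flag = "too_few_pixels"))
  x <- a[idx]; y <- b[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(nucleus_id = nucleus_id, pearson_r = NA_real_, n_pixels = n,
                flag = "constant_channel"))
  list(nucleus_id = nucleus_id, pearson_r = stats::cor(x, y), n_pixels = n,
       flag = "ok")
}
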