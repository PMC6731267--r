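#' Construct a single-channel image
#'
#' Wraps a matrix of raw pixel intensities together with its acquisition
#' role. Intensities are stored in the native integer range of the camera
#' (no rescaling); all downstream arithmetic is floating point.
#'
#' @param pixels Numeric matrix of non-negative intensities, row = image row
#'   (origin top-left). Must be at least 16x16.
#' @param channel_role One of `"dapi"`, `"gh2ax"`, `"p53bp1"`, `"other"`.
#' @param bit_depth 8 or 16.
#' @return A `ChannelImage` (list with `pixels`, `height_px`, `width_px`,
#'   `channel_role`, `bit_depth`).
#' @export
channel_image <- function(pixels, channel_role = c("dapi", "gh2ax", "p53bp1", "other"),
                          bit_depth = 16L) {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels)) rt_error("pixels must be a matrix", "ringtrack_format_error")
  if (!bit_depth %in% c(8L, 16L))
    rt_error("bit_depth must be 8 or 16", "ringtrack_format_error")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    rt_error("image must be at least 16x16", "ringtrack_format_error")
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    rt_error(sprintf("intensities outside [0, %d]", 2^bit_depth - 1),
             "ringtrack_format_error")
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels),
         channel_role = channel_role, bit_depth = as.integer(bit_depth)),
    class = "ChannelImage"
  )
}

#' Construct a multi-channel field of view
#'
#' A field of view is a set of pixel-aligned channels from one microscope
#' position plus its experimental condition label. The DAPI (nuclear
#' counterstain) and gamma-H2AX channels are mandatory; 53BP1 is optional.
#'
#' @param channels Named list of [channel_image()] objects; names are the
#'   channel roles and must include `dapi` and `gh2ax`.
#' @param field_id Character identifier for this field.
#' @param condition Character condition label (e.g. `"toxin_WT"`).
#' @param pixel_size_um Optional physical pixel size in micrometres.
#' @param magnification Objective magnification label; default `"20x"`.
#' @return A `FieldOfView` object.
#' @export
field_of_view <- function(channels, field_id = "field1", condition = "unknown",
                          pixel_size_um = NULL, magnification = "20x") {
  if (!all(c("dapi", "gh2ax") %in% names(channels)))
    rt_error("channels must include 'dapi' and 'gh2ax'", "ringtrack_config_error")
  dims <- vapply(channels, function(ch) c(ch$height_px, ch$width_px), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    rt_error("all channels must share the same dimensions", "ringtrack_format_error")
  structure(
    list(channels = channels, field_id = field_id, condition = condition,
         pixel_size_um = pixel_size_um, magnification = magnification),
    class = "FieldOfView"
  )
}

#' @export
print.FieldOfView <- function(x, ...) {
  ch <- x$channels[[1]]
  cat(sprintf("FieldOfView '%s' (%s): %dx%d px, channels: %s\n",
              x$field_id, x$condition, ch$height_px, ch$width_px,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Construct a label mask
#'
#' @param labels Integer matrix; 0 = background, objects labelled with the
#'   contiguous set `1..n_objects`.
#' @return A `LabelMask` (integer matrix with class and `n_objects` attribute).
#' @export
label_mask <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- if (length(labels) && max(labels) > 0L) max(labels) else 0L
  present <- sort(unique(labels[labels > 0L]))
  if (n > 0L && !identical(present, seq_len(n)))
    rt_error("labels must form the contiguous set 1..n_objects",
             "ringtrack_format_error")
  structure(labels, class = "LabelMask", n_objects = n)
}

read_one_image <- function(path) {
  if (!file.exists(path))
    rt_error(sprintf("file not found: %s", path), "ringtrack_config_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L)
      rt_error("RGB/multi-sample PNG not supported; grayscale only",
               "ringtrack_format_error")
    # readPNG rescales to [0,1]; PNG here is 8-bit grayscale by contract
    list(pages = list(round(px * 255)), bits = 8L)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    if (!bits %in% c(8L, 16L))
      rt_error(sprintf("unsupported TIFF bit depth: %s", bits),
               "ringtrack_format_error")
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      rt_error("multi-sample (RGB) TIFF not supported; grayscale only",
               "ringtrack_format_error")
    list(pages = pages, bits = as.integer(bits))
  } else {
    rt_error(sprintf("unsupported image format: .%s", ext),
             "ringtrack_format_error")
  }
}

#' Read a multi-channel field from image files
#'
#' Accepts either one file per channel or a single multi-page TIFF
#' (including OME-TIFF). Channel assignment is always explicit through
#' `channel_map`, never inferred from file order. Intensities are kept in
#' the file's native integer range.
#'
#' @param paths Character vector: one path per channel, or a single path to
#'   a multi-page file.
#' @param channel_map Named list/vector mapping channel roles (`dapi`,
#'   `gh2ax`, `p53bp1`, `other`) to an index. With one file per channel the
#'   index selects the file in `paths`; with one multi-page file it selects
#'   the page (1-based in both cases).
#' @param condition Condition label attached to the field.
#' @param field_id Field identifier; defaults to the first file's base name.
#' @return A [field_of_view()] object.
#' @export
#' @examples
#' \dontrun{
#' fov <- read_field(c("dapi.tif", "gh2ax.tif"),
#'                   channel_map = list(dapi = 1, gh2ax = 2),
#'                   condition = "toxin_WT")
#' }
read_field <- function(paths, channel_map, condition = "unknown",
                       field_id = NULL) {
  roles <- names(channel_map)
  if (!all(c("dapi", "gh2ax") %in% roles))
    rt_error("channel_map must assign both 'dapi' and 'gh2ax'",
             "ringtrack_config_error")
  bad <- setdiff(roles, c("dapi", "gh2ax", "p53bp1", "other"))
  if (length(bad))
    rt_error(sprintf("unknown channel role(s): %s", paste(bad, collapse = ", ")),
             "ringtrack_config_error")
  if (is.null(field_id))
    field_id <- tools::file_path_sans_ext(basename(paths[[1]]))

  channels <- list()
  if (length(paths) == 1L) {
    img <- read_one_image(paths[[1]])
    for (role in roles) {
      page <- as.integer(channel_map[[role]])
      if (page < 1L || page > length(img$pages))
        rt_error(sprintf("page %d for role '%s' out of range (file has %d)",
                         page, role, length(img$pages)),
                 "ringtrack_config_error")
      channels[[role]] <- channel_image(img$pages[[page]], role, img$bits)
    }
  } else {
    for (role in roles) {
      i <- as.integer(channel_map[[role]])
      if (i < 1L || i > length(paths))
        rt_error(sprintf("file index %d for role '%s' out of range", i, role),
                 "ringtrack_config_error")
      img <- read_one_image(paths[[i]])
      channels[[role]] <- channel_image(img$pages[[1]], role, img$bits)
    }
  }
  field_of_view(channels, field_id = field_id, condition = condition)
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels are stored verbatim as 16-bit gray values, so reading the file
#' back reproduces the mask bit-exactly. Limited to 65535 objects.
#'
#' @param mask A [label_mask()] or integer matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_label_mask <- function(mask, path) {
  n <- if (!is.null(attr(mask, "n_objects"))) attr(mask, "n_objects") else max(mask)
  if (n >= 65536L)
    rt_error("more than 65535 objects cannot be stored in a 16-bit mask",
             "ringtrack_capacity_error")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path Path to a 16-bit label TIFF.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_mask(m)
}

#' Per-nucleus result table column schema
#'
#' Fixed column order of the per-nucleus CSV produced by the pipeline.
#' @return Character vector of column names.
#' @export
nucleus_table_schema <- function() {
  c("field_id", "condition", "nucleus_id", "area_px", "perimeter_px",
    "centroid_row", "centroid_col", "eccentricity", "circularity",
    "mean_dapi", "accepted", "rejection_reason", "foci_count",
    "foci_density", "ring_score", "phenotype", "pearson_gh2ax_53bp1")
}

#' Write a per-nucleus table as deterministic CSV
#'
#' Enforces the fixed column schema, sorts rows by `field_id` then
#' `nucleus_id`, and writes UTF-8 CSV with '.' decimal separator so that
#' identical inputs yield byte-identical files.
#'
#' @param rows Data frame with exactly the [nucleus_table_schema()] columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  schema <- nucleus_table_schema()
  if (!identical(names(rows), schema))
    rt_error(sprintf("table columns must be exactly: %s",
                     paste(schema, collapse = ", ")),
             "ringtrack_schema_error")
  if (nrow(rows) > 0)
    rows <- rows[order(rows$field_id, rows$nucleus_id), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
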