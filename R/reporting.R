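#' Summarise phenotype calls per field and condition
#'
#' Produces the population-level readout: per (condition, field) counts of
#' accepted nuclei by phenotype with their proportions, and per condition
#' the mean and standard deviation of the per-field proportions.
#'
#' @param calls Data frame with at least `field_id`, `condition`,
#'   `phenotype` (one row per accepted nucleus). Fields with zero accepted
#'   nuclei may be passed as rows with `phenotype = NA`.
#' @return List of two data frames: `per_field` (`condition`, `field_id`,
#'   `n_accepted`, `n_foci`, `n_ring`, `n_uniform`, `prop_foci`,
#'   `prop_ring`, `prop_uniform`) and `per_condition` (mean/sd of each
#'   proportion over fields).
#' @export
summarize_phenotypes <- function(calls) {
  if (nrow(calls) == 0L || all(is.na(calls$phenotype))) {
    warning("no accepted nuclei: empty summary")
  }
  key <- interaction(calls$condition, calls$field_id, drop = TRUE, lex.order = TRUE)
  groups <- split(calls, key)
  per_field <- do.call(rbind, lapply(groups, function(g) {
    ph <- g$phenotype[!is.na(g$phenotype)]
    n <- length(ph)
    nf <- sum(ph == "FOCI"); nr <- sum(ph == "RING"); nu <- sum(ph == "UNIFORM")
    data.frame(condition = g$condition[1], field_id = g$field_id[1],
               n_accepted = n, n_foci = nf, n_ring = nr, n_uniform = nu,
               prop_foci = if (n) nf / n else NA_real_,
               prop_ring = if (n) nr / n else NA_real_,
               prop_uniform = if (n) nu / n else NA_real_)
  }))
  rownames(per_field) <- NULL
  per_field <- per_field[order(per_field$condition, per_field$field_id), ,
                         drop = FALSE]
  per_condition <- do.call(rbind, lapply(split(per_field, per_field$condition),
    function(g) {
      data.frame(condition = g$condition[1], n_fields = nrow(g),
                 n_accepted = sum(g$n_accepted),
                 mean_prop_foci = mean(g$prop_foci, na.rm = TRUE),
                 sd_prop_foci = stats::sd(g$prop_foci[!is.na(g$prop_foci)]),
                 mean_prop_ring = mean(g$prop_ring, na.rm = TRUE),
                 sd_prop_ring = stats::sd(g$prop_ring[!is.na(g$prop_ring)]),
                 mean_prop_uniform = mean(g$prop_uniform, na.rm = TRUE),
                 sd_prop_uniform = stats::sd(g$prop_uniform[!is.na(g$prop_uniform)]))
    }))
  rownames(per_condition) <- NULL
  list(per_field = per_field, per_condition = per_condition)
}

#' Analyse one field end-to-end
#'
#' Segmentation, phenotype classification and (when a 53BP1 channel is
#' present) per-nucleus gamma-H2AX/53BP1 correlation, assembled into the
#' fixed per-nucleus table schema. Rejected candidate objects are included
#' with `accepted = FALSE` and empty phenotype columns.
#'
#' @param fov A [field_of_view()].
#' @param seg_par [seg_params()].
#' @param cls_par [classifier_params()].
#' @return List: `table` (per-nucleus data frame in
#'   [nucleus_table_schema()] order), `mask`, `threshold`, `calls`.
#' @export
analyze_field <- function(fov, seg_par = seg_params(), cls_par = classifier_params()) {
  seg <- segment_nuclei(fov, seg_par)
  cls <- classify_field(fov, seg, cls_par)
  rec <- seg$records
  tab <- data.frame(
    field_id = rep(fov$field_id, nrow(rec)),
    condition = rep(fov$condition, nrow(rec)),
    nucleus_id = rec$nucleus_id, area_px = rec$area_px,
    perimeter_px = round(rec$perimeter_px, 6),
    centroid_row = round(rec$centroid_row, 6),
    centroid_col = round(rec$centroid_col, 6),
    eccentricity = round(rec$eccentricity, 6),
    circularity = round(rec$circularity, 6),
    mean_dapi = round(rec$mean_dapi, 6),
    accepted = rec$accepted, rejection_reason = rec$rejection_reason,
    foci_count = NA_integer_, foci_density = NA_real_,
    ring_score = NA_real_, phenotype = NA_character_,
    pearson_gh2ax_53bp1 = NA_real_
  )
  if (nrow(cls)) {
    m <- match(cls$nucleus_id, tab$nucleus_id)
    tab$foci_count[m] <- cls$foci_count
    tab$foci_density[m] <- round(cls$foci_density, 8)
    tab$ring_score[m] <- round(cls$ring_score, 6)
    tab$phenotype[m] <- cls$phenotype
  }
  if ("p53bp1" %in% names(fov$channels)) {
    ids <- attr(seg$mask, "nucleus_id")
    maskm <- unclass(seg$mask)
    for (j in seq_along(ids)) {
      res <- pixel_correlation(fov$channels$gh2ax, fov$channels$p53bp1,
                               maskm == j, ids[j])
      tab$pearson_gh2ax_53bp1[tab$nucleus_id == ids[j]] <-
        round(res$pearson_r, 6)
    }
  }
  list(table = tab, mask = seg$mask, threshold = seg$threshold,
       calls = attr(cls, "calls"))
}

#' Run the full pipeline over a set of fields
#'
#' Accepts either in-memory fields or a configuration referencing image
#' files on disk, analyses every field, and writes the per-nucleus CSV,
#' per-field and per-condition summary CSVs, one label-mask TIFF per field
#' and a provenance log (all parameter values plus each field's computed
#' global threshold). Outputs are deterministic: rerunning the same
#' configuration produces byte-identical CSVs.
#'
#' @param fields List of [field_of_view()] objects, or a config list whose
#'   `fields` element is a list of `list(paths=, channel_map=, condition=,
#'   field_id=)` entries for [read_field()].
#' @param out_dir Output directory (created if needed).
#' @param seg_par [seg_params()].
#' @param cls_par [classifier_params()].
#' @return Invisibly, a list with `table` (combined per-nucleus data
#'   frame), `summary` (from [summarize_phenotypes()]) and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(fields, out_dir, seg_par = seg_params(),
                         cls_par = classifier_params()) {
  if (!is.null(fields$fields)) {
    cfg <- fields$fields
    fields <- lapply(cfg, function(f) {
      read_field(unlist(f$paths), f$channel_map,
                 condition = if (is.null(f$condition)) "unknown" else f$condition,
                 field_id = f$field_id)
    })
  }
  if (!length(fields))
    rt_error("no fields to analyse", "ringtrack_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)

  tabs <- list(); thresholds <- character(0)
  for (fov in fields) {
    res <- analyze_field(fov, seg_par, cls_par)
    tabs[[fov$field_id]] <- res$table
    write_label_mask(res$mask,
                     file.path(out_dir, "masks",
                               paste0(fov$field_id, "_mask.tif")))
    thresholds <- c(thresholds,
                    sprintf("field %s (%s): global_threshold = %.6g",
                            fov$field_id, fov$condition, res$threshold))
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  per_nucleus_path <- file.path(out_dir, "per_nucleus.csv")
  write_table(tab, per_nucleus_path)

  acc <- tab[!is.na(tab$accepted) & tab$accepted, , drop = FALSE]
  summ <- summarize_phenotypes(acc)
  pf_path <- file.path(out_dir, "summary_per_field.csv")
  pc_path <- file.path(out_dir, "summary_per_condition.csv")
  for (p in list(list(summ$per_field, pf_path), list(summ$per_condition, pc_path))) {
    con <- file(p[[2]], open = "wb")
    utils::write.csv(p[[1]], con, row.names = FALSE, quote = FALSE, na = "NA",
                     fileEncoding = "UTF-8", eol = "\n")
    close(con)
  }

  log_path <- file.path(out_dir, "provenance.log")
  par_lines <- c(
    "ringtrack provenance",
    sprintf("segmentation: %s",
            paste(sprintf("%s=%s", names(seg_par), unlist(seg_par)), collapse = " ")),
    sprintf("classifier: %s",
            paste(sprintf("%s=%s", names(cls_par), unlist(cls_par)), collapse = " ")),
    thresholds)
  writeLines(par_lines, log_path)

  invisible(list(table = tab, summary = summ,
                 paths = list(per_nucleus = per_nucleus_path,
                              per_field = pf_path, per_condition = pc_path,
                              log = log_path)))
}
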