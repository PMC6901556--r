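# Summaries of VOR maps over parcellations (anatomical regions or
# resting-state networks).

region_summary <- function(vals) {
  n_valid <- length(vals)
  if (n_valid == 0L)
    return(c(mean = NA_real_, sd = NA_real_, max = NA_real_))
  c(mean = mean(vals),
    sd = if (n_valid > 1L) stats::sd(vals) else 0,
    max = max(vals))
}

#' Per-region summary of a VOR map
#'
#' For every region in the atlas label table (regions with no valid voxels
#' are emitted with undefined statistics, never dropped): the mean, sample
#' (n-1) SD, and maximum of the VOR values over the region's voxels.
#' Statistics are always computed over valid (defined) voxels only; the two
#' `support` modes differ in bookkeeping: `"valid_only"` (default) treats
#' the valid subset as the intended support, `"all_region"` additionally
#' attaches the per-region count discrepancy between region voxels and
#' valid voxels as `attr(, "support_discrepancy")`.
#'
#' @param vor a [vor_map()].
#' @param atlas a [parcellation_atlas()] on the same grid.
#' @param support `"valid_only"` or `"all_region"`.
#' @return a `region_table` data.frame with columns `region_id`,
#'   `region_name`, `mean_vor`, `sd_vor`, `max_vor`, `n_voxels_region`,
#'   `n_voxels_valid`, sorted by `region_id`.
#' @export
region_stats <- function(vor, atlas, support = c("valid_only", "all_region")) {
  support <- match.arg(support)
  stopifnot(inherits(vor, "vor_map"), inherits(atlas, "parcellation_atlas"))
  assert_same_grid(vor$grid, atlas$grid, "VOR map and atlas")
  if (nrow(atlas$label_table) < 1L)
    lnm_abort("atlas has no regions", "lnm_config_error")
  lt <- atlas$label_table
  lab <- as.vector(atlas$labels)
  v <- as.vector(vor$values)
  ok <- as.vector(vor$valid) & !is.na(v)
  rows <- lapply(seq_len(nrow(lt)), function(i) {
    in_region <- lab == lt$id[i]
    vals <- v[in_region & ok]
    s <- region_summary(vals)
    data.frame(region_id = lt$id[i], region_name = lt$name[i],
               mean_vor = s[["mean"]], sd_vor = s[["sd"]], max_vor = s[["max"]],
               n_voxels_region = sum(in_region),
               n_voxels_valid = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_table", "data.frame")
  if (support == "all_region")
    attr(out, "support_discrepancy") <-
      data.frame(region_id = out$region_id,
                 n_invalid = out$n_voxels_region - out$n_voxels_valid)
  out
}

#' Region table carrying both VOR directions
#'
#' One row per atlas region with the P-direction and C-direction summaries
#' side by side, mirroring paired published columns such as
#' "SF Mean VOR ... NSF Mean VOR".
#'
#' @param vor_P [vor_map()] with direction `"P_vs_C"`.
#' @param vor_C [vor_map()] with direction `"C_vs_P"`.
#' @param atlas [parcellation_atlas()] on the same grid.
#' @return a `region_table` data.frame with columns `region_id`,
#'   `region_name`, `mean_P`, `sd_P`, `max_P`, `mean_C`, `sd_C`, `max_C`,
#'   `n_voxels_region`, `n_voxels_valid_P`, `n_voxels_valid_C`.
#' @export
dual_direction_table <- function(vor_P, vor_C, atlas) {
  tp <- region_stats(vor_P, atlas)
  tc <- region_stats(vor_C, atlas)
  out <- data.frame(region_id = tp$region_id, region_name = tp$region_name,
                    mean_P = tp$mean_vor, sd_P = tp$sd_vor, max_P = tp$max_vor,
                    mean_C = tc$mean_vor, sd_C = tc$sd_vor, max_C = tc$max_vor,
                    n_voxels_region = tp$n_voxels_region,
                    n_voxels_valid_P = tp$n_voxels_valid,
                    n_voxels_valid_C = tc$n_voxels_valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Write a region table as tab-delimited text
#'
#' Columns are written in the table's fixed, documented order; undefined
#' statistics are written as `NA`.
#'
#' @param table a `region_table` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_region_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
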