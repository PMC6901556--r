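# Seed-based lesion connectivity: lesion mask -> seed time course ->
# per-subject r-map -> Fisher z -> across-subject t-map -> thresholded
# binary network map.

#' Extract a seed time course for one subject
#'
#' The unweighted mean, at each timepoint, of the subject's signal over the
#' voxels in `mask` intersected with the brain mask.
#'
#' @param subject 4-D numeric array `(x, y, z, t)`.
#' @param mask [lesion_mask()] on the same grid.
#' @param brain_mask optional 3-D 0/1 array; default: whole grid.
#' @return a `seed_timecourse`: list with `values` (length-t numeric) and
#'   `n_voxels` (seed voxel count).
#' @export
extract_seed_timecourse <- function(subject, mask, brain_mask = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  d <- dim(subject)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), mask$grid$shape))
    lnm_abort("subject array does not match the mask grid",
              "lnm_grid_mismatch_error")
  sel <- mask$voxels == 1
  if (!is.null(brain_mask)) sel <- sel & (brain_mask == 1)
  idx <- which(sel)
  if (!length(idx))
    lnm_abort(sprintf("seed '%s' has no voxels inside the brain mask",
                      mask$subject_id), "lnm_empty_seed_error")
  X <- matrix(subject, prod(d[1:3]), d[4L])
  values <- colMeans(X[idx, , drop = FALSE])
  if (stats::var(values) <= 0)
    lnm_abort(sprintf("seed '%s' has zero variance", mask$subject_id),
              "lnm_degenerate_seed_error")
  structure(list(values = values, n_voxels = length(idx)),
            class = "seed_timecourse")
}

#' Correlate a seed time course with every brain voxel
#'
#' Pearson correlation between the seed series and each voxel's series,
#' computed only within the brain mask. Voxels with zero temporal variance
#' (and everything outside the brain mask) are marked invalid.
#'
#' @param subject 4-D numeric array.
#' @param seed a `seed_timecourse`.
#' @param grid the cohort `volume_grid`.
#' @param brain_mask optional 3-D 0/1 array.
#' @return a [stat_map()] of kind `"r"`.
#' @export
subject_r_map <- function(subject, seed, grid, brain_mask = NULL) {
  stopifnot(inherits(seed, "seed_timecourse"), inherits(grid, "volume_grid"))
  d <- dim(subject)
  nvox <- prod(d[1:3])
  X <- matrix(subject, nvox, d[4L])
  sc <- seed$values - mean(seed$values)
  Xc <- X - rowMeans(X)
  num <- as.vector(Xc %*% sc)
  den <- sqrt(rowSums(Xc^2)) * sqrt(sum(sc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)  # guard rounding past the bounds
  if (!is.null(brain_mask)) r[as.vector(brain_mask) != 1] <- NA_real_
  stat_map(array(r, dim = d[1:3]), grid, kind = "r",
           provenance = sprintf("seed r-map (%d seed voxels, %d timepoints)",
                                seed$n_voxels, d[4L]))
}

#' Fisher z-transform of a correlation map
#'
#' Elementwise `atanh(r)`, the variance-stabilizing transform used before
#' across-subject inference. Correlations at the boundary (`|r| = 1`) are
#' clipped to `1 - clip` before the transform so z stays finite while
#' ordering is preserved; validity propagates unchanged.
#'
#' @param r_map [stat_map()] of kind `"r"`.
#' @param clip boundary clip; `|r|` is capped at `1 - clip`.
#' @return a [stat_map()] of kind `"z"`.
#' @export
fisher_z <- function(r_map, clip = 1e-7) {
  stopifnot(inherits(r_map, "stat_map"))
  if (r_map$kind != "r")
    lnm_abort("fisher_z expects a stat_map of kind 'r'", "lnm_kind_error")
  r <- pmin(pmax(r_map$values, -(1 - clip)), 1 - clip)
  stat_map(array(atanh(r), dim = r_map$grid$shape), r_map$grid, kind = "z",
           valid = r_map$valid,
           provenance = paste0(r_map$provenance, " -> fisher z"))
}

#' One-sample t-map across subjects' z-maps
#'
#' At each voxel valid in every subject, the one-sample t statistic of the
#' subjects' z values against zero: `t = mean(z) * sqrt(n) / sd(z)` with the
#' sample (n-1) standard deviation. The degenerate voxels where `sd = 0`:
#' if the mean is also 0 the voxel is a clean null and t = 0; if the mean is
#' nonzero the statistic is unbounded, and the voxel is flagged invalid
#' rather than set to infinity so downstream sums stay finite (the count is
#' recorded in `attr(, "n_degenerate")` and the provenance string).
#'
#' @param z_maps list of [stat_map()]s of kind `"z"`, one per subject
#'   (at least 3).
#' @return a [stat_map()] of kind `"t"`.
#' @export
group_t_map <- function(z_maps) {
  if (length(z_maps) < 3L)
    lnm_abort("group_t_map needs at least 3 subjects",
              "lnm_insufficient_subjects_error")
  grid <- z_maps[[1L]]$grid
  for (m in z_maps) {
    stopifnot(inherits(m, "stat_map"))
    if (m$kind != "z")
      lnm_abort("group_t_map expects stat_maps of kind 'z'", "lnm_kind_error")
    assert_same_grid(grid, m$grid, "z-maps")
  }
  n <- length(z_maps)
  Z <- vapply(z_maps, function(m) as.vector(m$values), numeric(prod(grid$shape)))
  valid <- rowSums(vapply(z_maps, function(m) as.vector(m$valid),
                          logical(prod(grid$shape)))) == n
  m <- rowMeans(Z)
  sdv <- sqrt(rowSums((Z - m)^2) / (n - 1))
  t <- rep(NA_real_, length(m))
  ok <- valid & sdv > 0
  t[ok] <- m[ok] * sqrt(n) / sdv[ok]
  null0 <- valid & sdv == 0 & m == 0
  t[null0] <- 0                                  # 0/0 -> 0 convention
  degen <- valid & sdv == 0 & m != 0             # flagged invalid
  out <- stat_map(array(t, dim = grid$shape), grid, kind = "t",
                  valid = array(valid & !degen, dim = grid$shape),
                  provenance = sprintf(
                    "one-sample t over %d subjects' z-maps (%d sd=0 voxels flagged invalid)",
                    n, sum(degen)))
  attr(out, "n_degenerate") <- sum(degen)
  attr(out, "degenerate") <- array(degen, dim = grid$shape)
  out
}

# Alternative r->t conversion: average the subject z-maps, transform back to
# a pooled r, and apply the single-map conversion t = r*sqrt(df)/sqrt(1-r^2)
# with df = n_timepoints - 2. Provided for completeness; the across-subject
# one-sample test is the default construction.
single_map_t <- function(z_maps, n_timepoints) {
  grid <- z_maps[[1L]]$grid
  Z <- vapply(z_maps, function(m) as.vector(m$values), numeric(prod(grid$shape)))
  valid <- rowSums(vapply(z_maps, function(m) as.vector(m$valid),
                          logical(prod(grid$shape)))) == length(z_maps)
  r <- tanh(rowMeans(Z))
  df <- n_timepoints - 2L
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-14))
  t[!valid] <- NA_real_
  stat_map(array(t, dim = grid$shape), grid, kind = "t",
           valid = array(valid, dim = grid$shape),
           provenance = sprintf(
             "single-map t (pooled r over %d subjects, df = %d)",
             length(z_maps), df))
}

#' Lesion network map: mask + cohort -> thresholded binary connectivity map
#'
#' The full per-lesion chain: seed the mask in every cohort subject, obtain
#' per-subject correlation maps, Fisher z-transform them, combine across
#' subjects into a t-map, then threshold (default t = 5.1, the whole-brain
#' Bonferroni level at p_cor < 0.05 for a 1000-subject normative cohort)
#' and binarize.
#'
#' @param cohort [connectome_cohort()].
#' @param mask [lesion_mask()] on the cohort grid.
#' @param t_threshold threshold applied to the t-map (inclusive).
#' @param tail `"two_sided"` (`|t| >= threshold`) or `"positive"`.
#' @param r_to_t_mode `"group_ttest"` (one-sample t across subjects,
#'   default) or `"single_map"` (pooled-r conversion with
#'   `df = n_timepoints - 2`).
#' @param return_t if `TRUE`, also return the intermediate t-map.
#' @return a [stat_map()] of kind `"binary"` (or, with `return_t`, a list
#'   with `binary` and `t_map`).
#' @export
lesion_network_map <- function(cohort, mask, t_threshold = 5.1,
                               tail = c("two_sided", "positive"),
                               r_to_t_mode = c("group_ttest", "single_map"),
                               return_t = FALSE) {
  tail <- match.arg(tail)
  r_to_t_mode <- match.arg(r_to_t_mode)
  stopifnot(inherits(cohort, "connectome_cohort"),
            inherits(mask, "lesion_mask"))
  assert_same_grid(cohort$grid, mask$grid,
                   sprintf("cohort and mask '%s'", mask$subject_id))
  z_maps <- vector("list", cohort$n_subjects)
  for (s in seq_len(cohort$n_subjects)) {
    seed <- extract_seed_timecourse(cohort$subjects[[s]], mask,
                                    cohort$brain_mask)
    r <- subject_r_map(cohort$subjects[[s]], seed, cohort$grid,
                       cohort$brain_mask)
    z_maps[[s]] <- fisher_z(r)
  }
  t_map <- if (r_to_t_mode == "group_ttest") group_t_map(z_maps)
           else single_map_t(z_maps, cohort$n_timepoints)
  out <- threshold_binarize(t_map, t_threshold, tail)
  out$provenance <- sprintf(
    "lesion '%s' network map: %s, t >= %g (%s), %d subjects",
    mask$subject_id, r_to_t_mode, t_threshold, tail, cohort$n_subjects)
  if (return_t) list(binary = out, t_map = t_map) else out
}
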