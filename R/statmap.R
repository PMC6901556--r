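#' Voxelwise statistical map
#'
#' A `stat_map` is a 3-D real-valued volume tagged with the statistic it
#' carries (`kind`), a validity mask, and a provenance string recording the
#' operation chain that produced it. Invalid voxels hold `NA` and are
#' excluded from every downstream statistic; they are written to disk as
#' IEEE NaN.
#'
#' @param values 3-D numeric array.
#' @param grid `volume_grid` the values live on.
#' @param kind one of `"r"`, `"z"`, `"t"`, `"binary"`, `"sum"`, `"vor"`.
#' @param valid optional 3-D logical/0-1 array; defaults to `is.finite(values)`.
#' @param provenance free-text record of how the map was produced.
#' @return An object of class `stat_map` with fields `grid`, `values`,
#'   `kind`, `valid` (logical array) and `provenance`.
#' @export
stat_map <- function(values, grid, kind, valid = NULL, provenance = "") {
  kind <- match.arg(kind, c("r", "z", "t", "binary", "sum", "vor"))
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (!identical(dim(values), grid$shape))
    lnm_abort("stat_map values do not match the grid shape", "lnm_grid_error")
  storage.mode(values) <- "double"
  if (is.null(valid)) valid <- is.finite(values)
  valid <- array(as.logical(valid), dim = grid$shape)
  values[!valid] <- NA_real_
  if (kind == "binary" && !all(values[valid] %in% c(0, 1)))
    lnm_abort("binary stat_map must contain only 0/1 at valid voxels",
              "lnm_kind_error")
  if (kind == "r" && any(abs(values[valid]) > 1 + 1e-12))
    lnm_abort("r stat_map values must lie in [-1, 1]", "lnm_kind_error")
  structure(list(grid = grid, values = values, kind = kind, valid = valid,
                 provenance = provenance),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map kind=%s> %s voxels, %d valid\n  provenance: %s\n",
              x$kind, paste(x$grid$shape, collapse = "x"),
              sum(x$valid), x$provenance))
  invisible(x)
}

#' Binary lesion (ablation) mask with its outcome label
#'
#' The seed object for lesion network mapping: a nonempty binary volume in
#' template space plus a two-level outcome label. `"P"` is the outcome of
#' interest (e.g. seizure-free after ablation) and `"C"` its complement.
#'
#' @param voxels 3-D array of 0/1 (or logical); at least one voxel set.
#' @param grid `volume_grid`.
#' @param subject_id identifier string.
#' @param outcome `"P"` or `"C"`.
#' @return A `lesion_mask` with fields `grid`, `voxels` (0/1 numeric array),
#'   `subject_id`, `outcome`, `n_voxels`, and `volume_mm3`
#'   (voxel count times voxel volume).
#' @export
lesion_mask <- function(voxels, grid, subject_id, outcome = c("P", "C")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(grid, "volume_grid"))
  voxels <- as.array(voxels)
  if (!identical(dim(voxels), grid$shape))
    lnm_abort("mask does not match the grid shape", "lnm_grid_error")
  storage.mode(voxels) <- "double"
  if (!all(voxels %in% c(0, 1)))
    lnm_abort("lesion mask must be binary (0/1)", "lnm_kind_error")
  n <- sum(voxels)
  if (n < 1)
    lnm_abort(sprintf("lesion mask '%s' is empty", subject_id),
              "lnm_empty_mask_error")
  structure(list(grid = grid, voxels = voxels,
                 subject_id = as.character(subject_id), outcome = outcome,
                 n_voxels = as.integer(n),
                 volume_mm3 = n * prod(grid$voxel_size)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask '%s' outcome=%s> %d voxels (%.0f mm^3)\n",
              x$subject_id, x$outcome, x$n_voxels, x$volume_mm3))
  invisible(x)
}

#' Labelled parcellation atlas
#'
#' An integer label volume (0 = background) plus a label table naming every
#' region. Construction fails if the volume contains a nonzero label absent
#' from the table.
#'
#' @param labels 3-D integer array, 0 for background.
#' @param grid `volume_grid`.
#' @param label_table data.frame with columns `id` (non-negative integer) and
#'   `name` (character).
#' @return A `parcellation_atlas` with fields `grid`, `labels`, `label_table`.
#' @export
parcellation_atlas <- function(labels, grid, label_table) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- as.array(labels)
  if (!identical(dim(labels), grid$shape))
    lnm_abort("atlas labels do not match the grid shape", "lnm_grid_error")
  if (any(labels != round(labels)) || any(labels < 0))
    lnm_abort("atlas labels must be non-negative integers", "lnm_kind_error")
  storage.mode(labels) <- "integer"
  label_table <- data.frame(id = as.integer(label_table$id),
                            name = as.character(label_table$name),
                            stringsAsFactors = FALSE)
  if (any(label_table$id < 0) || anyDuplicated(label_table$id))
    lnm_abort("label table ids must be unique non-negative integers",
              "lnm_kind_error")
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_table$id)
  if (length(missing))
    lnm_abort(sprintf("labels present in volume but missing from table: %s",
                      paste(sort(missing), collapse = ", ")),
              "lnm_missing_label_error", missing_labels = sort(missing))
  label_table <- label_table[label_table$id != 0L, , drop = FALSE]
  label_table <- label_table[order(label_table$id), , drop = FALSE]
  rownames(label_table) <- NULL
  structure(list(grid = grid, labels = labels, label_table = label_table),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %d regions on %s grid\n",
              nrow(x$label_table), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Normative resting-state cohort
#'
#' Per-subject 4-D time-series volumes sharing one grid, plus a brain mask
#' restricting where statistics are computed. This is the fixed normative
#' substrate that every lesion mask is seeded into.
#'
#' @param subjects list of 4-D numeric arrays `(x, y, z, t)`, all the same
#'   shape, with at least 4 timepoints.
#' @param grid `volume_grid` of the spatial dimensions.
#' @param brain_mask 3-D 0/1 array (default: whole grid).
#' @param subject_ids optional character vector of identifiers.
#' @return A `connectome_cohort` with fields `grid`, `subjects`,
#'   `brain_mask`, `n_subjects`, `n_timepoints`, `subject_ids`.
#' @export
connectome_cohort <- function(subjects, grid, brain_mask = NULL,
                              subject_ids = NULL) {
  stopifnot(inherits(grid, "volume_grid"), is.list(subjects),
            length(subjects) >= 1L)
  d1 <- dim(subjects[[1L]])
  if (length(d1) != 4L || !identical(as.integer(d1[1:3]), grid$shape))
    lnm_abort("cohort subjects must be 4-D arrays on the cohort grid",
              "lnm_dimensionality_error")
  if (d1[4L] < 4L)
    lnm_abort("cohort needs n_timepoints >= 4", "lnm_config_error")
  for (s in subjects)
    if (!identical(dim(s), d1))
      lnm_abort("all cohort subjects must share one shape and n_timepoints",
                "lnm_grid_mismatch_error")
  if (is.null(brain_mask)) brain_mask <- array(1, dim = grid$shape)
  brain_mask <- array(as.double(as.logical(brain_mask)), dim = grid$shape)
  if (sum(brain_mask) < 1)
    lnm_abort("brain mask is empty", "lnm_empty_mask_error")
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%03d", seq_along(subjects))
  structure(list(grid = grid, subjects = subjects, brain_mask = brain_mask,
                 n_subjects = length(subjects),
                 n_timepoints = as.integer(d1[4L]),
                 subject_ids = as.character(subject_ids)),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("<connectome_cohort> %d subjects x %d timepoints on %s grid (%d brain voxels)\n",
              x$n_subjects, x$n_timepoints,
              paste(x$grid$shape, collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}
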