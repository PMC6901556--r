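#' Read a volume from a NIfTI-1 file
#'
#' Reads a 3-D (or, with `expect_4d = TRUE`, 4-D) volume and builds the
#' `volume_grid` from the header. No resampling is performed: the volume is
#' taken on the grid it arrives on.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param expect_4d if `TRUE` a 4-D time-series volume is required; by
#'   default a 3-D volume is required and a 4-D file raises a
#'   dimensionality error.
#' @return list with `values` (array) and `grid` (`volume_grid`).
#' @export
read_volume <- function(path, expect_4d = FALSE) {
  nii <- read_nifti_file(path)
  ndim <- length(dim(nii$values))
  if (expect_4d && ndim != 4L)
    lnm_abort(sprintf("expected a 4-D time-series volume: %s", path),
              "lnm_dimensionality_error")
  if (!expect_4d && ndim != 3L)
    lnm_abort(sprintf("expected a 3-D volume, got 4-D: %s", path),
              "lnm_dimensionality_error")
  shape <- dim(nii$values)[1:3]
  list(values = nii$values, grid = volume_grid(shape, nii$affine))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param values 3-D or 4-D numeric array (a `stat_map`'s `values` field,
#'   a mask, an atlas label volume, or a subject time series). `NA` values
#'   are stored as IEEE NaN (float datatypes) or 0 (integer datatypes).
#' @param grid `volume_grid` supplying the affine.
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype on-disk datatype: `"float64"` (default), `"float32"`,
#'   `"uint8"`, `"int16"`, `"int32"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(values, grid, path, datatype = "float64") {
  stopifnot(inherits(grid, "volume_grid"))
  d <- dim(values)
  if (is.null(d) || !identical(as.integer(d[1:3]), grid$shape))
    lnm_abort("values do not match the grid shape", "lnm_grid_error")
  write_nifti_file(values, grid$affine, path, datatype = datatype)
}

#' Binarize a real-valued volume
#'
#' Value 1 where `volume > threshold`, else 0. The default threshold of 0.5
#' tolerates interpolation dust left by upstream nearest-neighbour
#' registration of nominally binary masks. Idempotent on its own output.
#'
#' @param volume numeric array, finite everywhere.
#' @param threshold scalar cut (strictly greater-than).
#' @return array of 0/1 with the same dimensions.
#' @examples
#' binarize_mask(array(c(0, 0.4, 0.6, 1), c(4, 1, 1)))
#' @export
binarize_mask <- function(volume, threshold = 0.5) {
  if (any(!is.finite(volume)))
    lnm_abort("binarize_mask requires finite input", "lnm_kind_error")
  out <- (volume > threshold) + 0
  dim(out) <- dim(volume)
  out
}

# Label tables arrive as two-column delimited text (id, name), tab- or
# comma-separated, header row optional. First dialect that yields two
# columns wins.
read_label_table <- function(path) {
  if (!file.exists(path))
    lnm_abort(sprintf("label table not found: %s", path), "lnm_format_error")
  for (sep in c("\t", ",")) {
    tab <- tryCatch(
      utils::read.table(path, sep = sep, header = FALSE, quote = "\"",
                        stringsAsFactors = FALSE, comment.char = "",
                        strip.white = TRUE),
      error = function(e) NULL)
    if (!is.null(tab) && ncol(tab) >= 2L) {
      # drop a header row if the first field is not numeric
      if (is.na(suppressWarnings(as.integer(tab[1, 1]))))
        tab <- tab[-1, , drop = FALSE]
      if (nrow(tab) == 0L) next
      ids <- suppressWarnings(as.integer(tab[[1]]))
      if (any(is.na(ids))) next
      return(data.frame(id = ids, name = as.character(tab[[2]]),
                        stringsAsFactors = FALSE))
    }
  }
  lnm_abort(sprintf("could not parse label table (need two delimited columns): %s",
                    path), "lnm_format_error")
}

#' Read a parcellation atlas (label volume + label table)
#'
#' @param volume_path NIfTI file with integer labels (0 = background).
#' @param table_path two-column delimited text file (`id`, `name`), tab- or
#'   comma-separated, header optional.
#' @return a [parcellation_atlas()].
#' @export
read_atlas <- function(volume_path, table_path) {
  vol <- read_volume(volume_path)
  if (any(vol$values != round(vol$values)))
    lnm_abort(sprintf("atlas volume is not integer-valued: %s", volume_path),
              "lnm_format_error")
  parcellation_atlas(vol$values, vol$grid, read_label_table(table_path))
}

#' Read a lesion mask file
#'
#' Reads a 3-D volume, binarizes it (tolerance for interpolation dust), and
#' wraps it with its outcome label.
#'
#' @param path NIfTI file.
#' @param subject_id identifier.
#' @param outcome `"P"` or `"C"`.
#' @param threshold binarization threshold, see [binarize_mask()].
#' @return a [lesion_mask()].
#' @export
read_lesion_mask <- function(path, subject_id, outcome, threshold = 0.5) {
  vol <- read_volume(path)
  lesion_mask(binarize_mask(vol$values, threshold), vol$grid,
              subject_id, outcome)
}

# Flat key-value sidecar/manifest files: "key = value" per line, '#' comments.
write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k) sprintf("%s = %s", k, as.character(x[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$", lines,
                                 perl = TRUE))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    lnm_abort(sprintf("malformed key-value line(s) in %s: %s", path,
                      paste(lines[bad], collapse = "; ")), "lnm_config_error")
  stats::setNames(lapply(m, `[`, 3L), vapply(m, `[`, "", 2L))
}
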