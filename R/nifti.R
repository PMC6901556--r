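# Minimal NIfTI-1 reader/writer in base R.
#
# No NIfTI package ships with this toolchain, so the 348-byte single-file
# (.nii / .nii.gz, magic "n+1") format is handled directly. Scope is the
# subset this package produces and consumes: 3-D and 4-D volumes, datatypes
# uint8 / int8 / int16 / uint16 / int32 / float32 / float64, sform or qform
# affines, scl_slope/scl_inter rescaling, both endiannesses on read.
# Writing always emits little-endian, sform_code = 2, vox_offset = 352.

NIFTI_DT <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  int8    = list(code = 256L, size = 1L, what = "integer", signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

nifti_dt_by_code <- function(code) {
  for (nm in names(NIFTI_DT)) if (NIFTI_DT[[nm]]$code == code) {
    out <- NIFTI_DT[[nm]]; out$name <- nm; return(out)
  }
  lnm_abort(sprintf("unsupported NIfTI datatype code %d", code),
            "lnm_format_error")
}

# Decode fixed-width fields out of the raw header at byte offsets.
raw_field <- function(raw, offset, what, n, size, endian, signed = TRUE) {
  readBin(raw[(offset + 1L):(offset + n * size)], what = what, n = n,
          size = size, endian = endian, signed = signed)
}

# Quaternion (method 2) fallback when no sform is present.
qform_affine <- function(b, c, d, qx, qy, qz, pixdim) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - c * c - b * b
  ), 3, 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4] <- c(qx, qy, qz)
  aff
}

# Parse the 348-byte header. Returns everything needed to interpret the data.
parse_nifti_header <- function(hdr, path) {
  if (length(hdr) < 348L)
    lnm_abort(sprintf("truncated NIfTI header in %s", path), "lnm_format_error")
  endian <- "little"
  if (raw_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (raw_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L)
      lnm_abort(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path),
                "lnm_format_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (magic == "ni1")
    lnm_abort(sprintf("two-file (.hdr/.img) NIfTI not supported: %s", path),
              "lnm_format_error")
  if (magic != "n+1")
    lnm_abort(sprintf("not a NIfTI-1 file (bad magic '%s'): %s", magic, path),
              "lnm_format_error")

  dims <- raw_field(hdr, 40L, "integer", 8L, 2L, endian)
  ndim <- dims[1]
  if (ndim < 3L || ndim > 4L)
    lnm_abort(sprintf("expected a 3-D or 4-D volume, got %d-D: %s", ndim, path),
              "lnm_dimensionality_error")
  shape <- dims[2:(1 + ndim)]
  pixdim <- raw_field(hdr, 76L, "double", 8L, 4L, endian)
  qform_code <- raw_field(hdr, 252L, "integer", 1L, 2L, endian)
  sform_code <- raw_field(hdr, 254L, "integer", 1L, 2L, endian)
  quat <- raw_field(hdr, 256L, "double", 6L, 4L, endian)
  srow <- raw_field(hdr, 280L, "double", 12L, 4L, endian)
  affine <- if (sform_code > 0L) {
    rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_affine(quat[1], quat[2], quat[3], quat[4], quat[5], quat[6], pixdim)
  } else {
    diag(c(abs(pixdim[2:4]), 1)) # headerless fallback: scaled identity
  }
  list(endian = endian, ndim = ndim, shape = shape, affine = affine,
       datatype = raw_field(hdr, 70L, "integer", 1L, 2L, endian),
       vox_offset = raw_field(hdr, 108L, "double", 1L, 4L, endian),
       scl_slope = raw_field(hdr, 112L, "double", 1L, 4L, endian),
       scl_inter = raw_field(hdr, 116L, "double", 1L, 4L, endian))
}

# Header-only read: the spatial grid plus dimensionality, without touching
# the voxel data (used by input validation across whole cohorts).
read_nifti_grid <- function(path) {
  if (!file.exists(path))
    lnm_abort(sprintf("file not found: %s", path), "lnm_format_error")
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  h <- parse_nifti_header(readBin(con, "raw", n = 348L), path)
  list(grid = volume_grid(h$shape[1:3], h$affine), ndim = h$ndim,
       shape = h$shape)
}

# Read one .nii/.nii.gz file. Returns list(values = array, affine = 4x4).
read_nifti_file <- function(path) {
  if (!file.exists(path))
    lnm_abort(sprintf("file not found: %s", path), "lnm_format_error")
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  h <- parse_nifti_header(readBin(con, "raw", n = 348L), path)
  dt <- nifti_dt_by_code(h$datatype)
  skip <- round(h$vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(h$shape)
  values <- readBin(con, dt$what, n = n, size = dt$size, endian = h$endian,
                    signed = dt$signed)
  if (length(values) < n)
    lnm_abort(sprintf("truncated NIfTI data in %s", path), "lnm_format_error")
  values <- as.double(values)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      (h$scl_slope != 1 || (is.finite(h$scl_inter) && h$scl_inter != 0)))
    values <- values * h$scl_slope +
      if (is.finite(h$scl_inter)) h$scl_inter else 0
  list(values = array(values, dim = h$shape), affine = h$affine)
}

pad_raw <- function(n) raw(n)

# Write a 3-D or 4-D array as single-file NIfTI-1 (gz if path ends in .gz).
write_nifti_file <- function(values, affine, path, datatype = "float64") {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt))
    lnm_abort(sprintf("unknown datatype '%s'", datatype), "lnm_format_error")
  dims <- dim(values)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    lnm_abort("only 3-D and 4-D arrays can be written", "lnm_dimensionality_error")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  w(348L, 4L)                               # sizeof_hdr
  writeBin(pad_raw(10L + 18L), con)         # data_type, db_name (unused)
  w(0L, 4L); w(0L, 2L)                      # extents, session_error
  writeBin(as.raw(c(114L, 0L)), con)        # regular = 'r', dim_info
  w(as.integer(c(length(dims), dims, rep(1L, 7L - length(dims)))), 2L) # dim[8]
  w(c(0, 0, 0), 4L); w(0L, 2L)              # intent_p1..3, intent_code
  w(dt$code, 2L); w(dt$size * 8L, 2L); w(0L, 2L) # datatype, bitpix, slice_start
  w(c(1, vs, if (length(dims) == 4L) 1 else 0, 0, 0, 0), 4L) # pixdim[8]
  w(352, 4L); w(1, 4L); w(0, 4L)            # vox_offset, scl_slope, scl_inter
  w(0L, 2L); writeBin(as.raw(c(0L, 10L)), con) # slice_end, slice_code, xyzt=mm|s
  w(c(0, 0, 0, 0), 4L)                      # cal_max, cal_min, slice_dur, toffset
  w(c(0L, 0L), 4L)                          # glmax, glmin
  desc <- charToRaw("lnmapr")
  writeBin(c(desc, pad_raw(80L - length(desc))), con)  # descrip[80]
  writeBin(pad_raw(24L), con)               # aux_file[24]
  w(0L, 2L); w(2L, 2L)                      # qform_code = 0, sform_code = 2
  w(c(0, 0, 0), 4L)                         # quatern_b,c,d
  w(as.numeric(affine[1:3, 4]), 4L)         # qoffset_x,y,z
  w(as.numeric(t(affine[1:3, ])), 4L)       # srow_x, srow_y, srow_z
  writeBin(pad_raw(16L), con)               # intent_name[16]
  writeBin(c(charToRaw("n+1"), pad_raw(1L)), con) # magic
  writeBin(pad_raw(4L), con)                # extension indicator

  v <- as.vector(values)
  if (dt$what == "integer") {
    v[is.na(v)] <- 0
    w(as.integer(round(v)), dt$size)
  } else {
    v <- as.double(v)
    v[is.na(v)] <- NaN                      # invalid voxels: IEEE NaN sentinel
    w(v, dt$size)
  }
  invisible(path)
}
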