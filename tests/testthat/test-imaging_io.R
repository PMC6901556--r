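# imaging_io: NIfTI read/write, binarization, grid contract, atlases.

test_that("volume round-trips through NIfTI preserve values and affine", {
  g <- volume_grid(c(7L, 6L, 5L),
                   rbind(c(-2, 0, 0, 90), c(0, 2, 0, -126),
                         c(0, 0, 2, -72), c(0, 0, 0, 1)))
  set.seed(42)
  v <- array(rnorm(prod(g$shape)), dim = g$shape)
  v[c(3, 17)] <- NA # invalid-voxel sentinel
  for (ext in c(".nii", ".nii.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(v, g, f)
    rt <- read_volume(f)
    expect_lt(max(abs(rt$values - v), na.rm = TRUE), 1e-6)
    expect_true(all(is.na(rt$values[c(3, 17)]) | is.nan(rt$values[c(3, 17)])))
    expect_lt(max(abs(rt$grid$affine - g$affine)), 1e-6)
    expect_identical(rt$grid$shape, g$shape)
  }
})

test_that("a template-grid mask file echoes its header", {
  g <- volume_grid(c(91L, 109L, 91L), diag(c(2, 2, 2, 1)))
  v <- array(0, dim = g$shape)
  v[45:47, 50:55, 40:42] <- 1
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, g, f, datatype = "uint8")
  rt <- read_volume(f)
  expect_identical(rt$grid$shape, c(91L, 109L, 91L))
  expect_equal(unname(rt$grid$voxel_size), c(2, 2, 2))
  expect_identical(rt$values, v)
})

test_that("the NIfTI writer is readable by an independent implementation", {
  # nibabel (Python) is the format oracle: our files must parse there with
  # identical shape, affine, and data.
  g <- volume_grid(c(5L, 4L, 3L),
                   rbind(c(-2, 0, 0, 10), c(0, 2, 0, -8),
                         c(0, 0, 2, 4), c(0, 0, 0, 1)))
  set.seed(1)
  v <- array(round(rnorm(prod(g$shape)), 6), dim = g$shape)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  out <- withr::local_tempfile(fileext = ".txt")
  write_volume(v, g, f)
  script <- sprintf(paste0(
    "import nibabel, numpy; img = nibabel.load('%s');",
    "d = img.get_fdata();",
    "print(max(abs(numpy.asarray(img.affine)-numpy.array(%s).reshape(4,4,order='F')).max(),",
    "abs(d - numpy.array(%s).reshape(%s,order='F')).max()))"),
    f, paste0("[", paste(g$affine, collapse = ","), "]"),
    paste0("[", paste(v, collapse = ","), "]"),
    paste0("(", paste(dim(v), collapse = ","), ")"))
  res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  expect_lt(as.numeric(res[length(res)]), 1e-9)
})

test_that("dimensionality and format faults are reported as such", {
  g <- test_grid()
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(array(0, c(g$shape, 3L)), g, f4)
  expect_lnm_error(read_volume(f4), "lnm_dimensionality_error")
  expect_silent(read_volume(f4, expect_4d = TRUE))
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(array(0, g$shape), g, f3)
  expect_lnm_error(read_volume(f3, expect_4d = TRUE), "lnm_dimensionality_error")
  junk <- withr::local_tempfile(fileext = ".nii")
  writeBin(as.raw(1:100), junk)
  expect_lnm_error(read_volume(junk), "lnm_format_error")
  expect_lnm_error(read_volume(tempfile()), "lnm_format_error")
})

test_that("binarize_mask follows its definition and is idempotent", {
  x <- array(c(0, 0.4, 0.6, 1, -1, 2), c(6, 1, 1))
  b <- binarize_mask(x)
  expect_equal(as.vector(b), c(0, 0, 1, 1, 0, 1))
  expect_identical(binarize_mask(b), b)     # idempotence
  expect_equal(as.vector(binarize_mask(x, threshold = 0.9)),
               c(0, 0, 0, 1, 0, 1))
  expect_lnm_error(binarize_mask(array(c(1, NA), c(2, 1, 1))),
                   "lnm_kind_error")
})

test_that("grid compatibility is exact on shape, tolerant to 1e-4 on affine", {
  g <- test_grid(c(91L, 109L, 91L))
  expect_true(check_grid_compatible(g, g))  # reflexive
  shifted <- volume_grid(g$shape, {
    a <- g$affine; a[1, 4] <- a[1, 4] + 1; a
  })
  expect_false(check_grid_compatible(g, shifted)) # 1 mm translation
  expect_false(check_grid_compatible(g, test_grid(c(90L, 109L, 91L))))
  within_tol <- volume_grid(g$shape, g$affine + 5e-5)
  expect_true(check_grid_compatible(g, within_tol))
  # symmetry over randomized perturbations
  set.seed(9)
  for (i in 1:20) {
    h <- volume_grid(g$shape, g$affine + matrix(rnorm(16, sd = 1e-4), 4))
    expect_identical(check_grid_compatible(g, h), check_grid_compatible(h, g))
  }
})

test_that("atlases read with complete label tables, fail loudly otherwise", {
  g <- test_grid()
  labels <- array(0L, g$shape)
  labels[1:5] <- 1L; labels[10:12] <- 2L
  fvol <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(labels, g, fvol, datatype = "int16")
  ftab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tLeft hippocampus", "2\tRight hippocampus"), ftab)
  atlas <- read_atlas(fvol, ftab)
  expect_s3_class(atlas, "parcellation_atlas")
  expect_identical(nrow(atlas$label_table), 2L)
  # comma dialect with header row
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name", "1,Left hippocampus", "2,Right hippocampus"), fcsv)
  expect_identical(read_atlas(fvol, fcsv)$label_table$name,
                   atlas$label_table$name)
  # label 3 in volume but not in table -> error naming 3
  labels[20] <- 3L
  fvol3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(labels, g, fvol3, datatype = "int16")
  err <- tryCatch(read_atlas(fvol3, ftab), error = identity)
  expect_s3_class(err, "lnm_missing_label_error")
  expect_match(conditionMessage(err), "3")
})

test_that("fixture masks reread from disk keep the generator's bookkeeping", {
  fx <- tiny_fixture()
  for (i in seq_along(fx$masks)) {
    m <- fx$masks[[i]]
    reread <- read_lesion_mask(fx$mask_paths[i], m$subject_id, m$outcome)
    expect_identical(reread$n_voxels, m$n_voxels)
    expect_equal(reread$volume_mm3, m$n_voxels * prod(m$grid$voxel_size))
    expect_identical(reread$voxels, m$voxels)
  }
  # synthetic atlas reread from disk: region voxel counts match the
  # generator's planted supports exactly (supports are disjoint here)
  atlas <- read_atlas(fx$atlas_volume, fx$atlas_table)
  for (k in seq_along(fx$networks))
    expect_identical(sum(atlas$labels == k),
                     as.integer(sum(fx$networks[[k]]$support)))
})
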