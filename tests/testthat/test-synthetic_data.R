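# synthetic_data: network supports, cohort simulation, planted lesions,
# fixture writing. Oracles are the generator's own closed forms.

test_that("network supports are deterministic spheres on the lattice", {
  shp <- c(10L, 10L, 10L)
  one <- make_network_supports(shp, k = 1,
                               geometry = list(list(center = c(5, 5, 5),
                                                    radius = 0)))
  expect_equal(sum(one[[1]]$support), 1)    # radius 0 -> one voxel
  expect_equal(one[[1]]$support[5, 5, 5], 1)

  two <- make_network_supports(shp, k = 2,
                               geometry = list(list(center = c(3, 3, 3), radius = 2),
                                               list(center = c(8, 8, 8), radius = 2)))
  expect_equal(sum(two[[1]]$support * two[[2]]$support), 0) # disjoint

  a <- make_network_supports(shp, k = 3, geometry = "random", radius = 2,
                             seed = 99)
  b <- make_network_supports(shp, k = 3, geometry = "random", radius = 2,
                             seed = 99)
  expect_identical(lapply(a, `[[`, "support"), lapply(b, `[[`, "support"))
  expect_lnm_error(
    make_network_supports(c(4L, 4L, 4L), 1, geometry = "random", radius = 3),
    "lnm_geometry_error")
})

test_that("identical config and seed give bit-identical cohorts", {
  nw <- make_network_supports(c(6L, 6L, 6L), 1,
                              geometry = list(list(center = c(3, 3, 3),
                                                   radius = 1)))
  cfg <- cohort_config(c(6L, 6L, 6L), 4, 10, nw, noise_sd = 0.3, seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- simulate_cohort(cohort_config(c(6L, 6L, 6L), 4, 10, nw,
                                      noise_sd = 0.3, seed = 8))
  expect_false(identical(c1$subjects, c3$subjects))
})

test_that("config invariants reject degenerate worlds", {
  nw <- make_network_supports(c(6L, 6L, 6L), 1,
                              geometry = list(list(center = c(3, 3, 3),
                                                   radius = 1)))
  expect_lnm_error(cohort_config(c(6L, 6L, 6L), 2, 10, nw), "lnm_config_error")
  expect_lnm_error(cohort_config(c(6L, 6L, 6L), 4, 3, nw), "lnm_config_error")
  expect_lnm_error(cohort_config(c(6L, 6L, 6L), 4, 10, nw, noise_sd = 0),
                   "lnm_config_error")
})

test_that("within-support correlation matches the closed-form variance ratio", {
  # population r between two voxels sharing one network:
  #   loading^2 / (loading^2 + noise_sd^2); with loading = noise_sd = 1 -> 0.5
  shp <- c(7L, 7L, 7L)
  nw <- make_network_supports(shp, 1,
                              geometry = list(list(center = c(4, 4, 4),
                                                   radius = 2)))
  cfg <- cohort_config(shp, n_subjects = 100L, n_timepoints = 60L,
                       networks = nw, noise_sd = 1, seed = 21)
  cohort <- simulate_cohort(cfg)
  inside <- which(nw[[1]]$support == 1)
  v1 <- inside[1]; v2 <- inside[length(inside)]
  rs <- vapply(cohort$subjects, function(s) {
    X <- matrix(s, prod(shp), cfg$n_timepoints)
    stats::cor(X[v1, ], X[v2, ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)
})

test_that("noise-free limits: r -> 1 inside a network, -> 0 outside", {
  world <- noisefree_world()
  supp <- world$networks[[1]]$support
  inside <- which(supp == 1)
  outside <- which(supp == 0)
  s1 <- world$cohort$subjects[[1]]
  X <- matrix(s1, prod(dim(s1)[1:3]), dim(s1)[4])
  expect_gt(stats::cor(X[inside[1], ], X[inside[5], ]), 0.99)
  expect_lt(abs(stats::cor(X[inside[1], ], X[outside[1], ])), 0.5)
  # seed series of a planted lesion tracks the stored latent course
  seed <- extract_seed_timecourse(s1, world$mask)
  latent <- attr(world$cohort, "latents")[[1]][1, ]
  expect_gt(stats::cor(seed$values, latent), 0.999)
})

test_that("planted lesions live inside their supports and share truth", {
  shp <- c(12L, 12L, 12L)
  nw <- make_network_supports(shp, 2,
                              geometry = list(list(center = c(4, 4, 4), radius = 3),
                                              list(center = c(9, 9, 9), radius = 3)))
  grid <- volume_grid(shp, diag(c(2, 2, 2, 1)))
  pl <- plant_lesion_masks(nw, data.frame(network = c(1L, 1L, 2L),
                                          outcome = c("P", "P", "C")),
                           grid, lesion_radius = 1, seed = 2)
  for (i in 1:3) {
    m <- pl$masks[[i]]
    supp <- nw[[pl$truth$assignments$network[i]]]$support
    expect_true(all(supp[m$voxels == 1] == 1))  # containment
  }
  # lesions sharing a network share the expected-connectivity map
  expect_identical(pl$truth$expected[["lesion-01"]],
                   pl$truth$expected[["lesion-02"]])
  # radius 0 -> 1-voxel mask
  pl0 <- plant_lesion_masks(nw, data.frame(network = 1L, outcome = "P"),
                            grid, lesion_radius = 0, seed = 2)
  expect_identical(pl0$masks[[1]]$n_voxels, 1L)
  # a lesion that cannot fit raises a geometry error
  nw0 <- make_network_supports(shp, 1,
                               geometry = list(list(center = c(6, 6, 6),
                                                    radius = 0)))
  expect_lnm_error(
    plant_lesion_masks(nw0, data.frame(network = 1L, outcome = "P"),
                       grid, lesion_radius = 2, seed = 1),
    "lnm_geometry_error")
})

test_that("the written fixture is self-consistent on disk", {
  fx <- tiny_fixture()
  # all volumes land on one grid
  ref <- read_volume(fx$mask_paths[1])$grid
  expect_true(check_grid_compatible(ref,
                                    read_volume(fx$cohort_paths[1],
                                                expect_4d = TRUE)$grid))
  expect_true(check_grid_compatible(ref, read_volume(fx$atlas_volume)$grid))
  # truth manifest voxel counts equal mask voxel counts on disk
  truth <- lnmapr:::read_keyvalue(file.path(fx$dir, "truth.txt"))
  for (i in seq_along(fx$masks)) {
    id <- fx$masks[[i]]$subject_id
    on_disk <- sum(read_volume(fx$mask_paths[i])$values)
    expect_equal(as.integer(truth[[sprintf("%s.n_voxels", id)]]), on_disk)
  }
  # manifest + config suffice to rerun: config parses and validates clean
  cfg <- read_pipeline_config(fx$config_path)
  rep <- validate_inputs(cfg)
  expect_true(rep$ok)
  expect_identical(rep$problems, character(0))
})
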