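# Shared fixtures, built in code and memoized for the whole test run.

lnm_test_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(lnm_test_cache[[key]])) lnm_test_cache[[key]] <- builder()
  lnm_test_cache[[key]]
}

test_grid <- function(shape = c(6L, 5L, 4L), voxel = 2) {
  volume_grid(shape, diag(c(voxel, voxel, voxel, 1)))
}

# Binary array with 1s at the given linear indices.
mask_array <- function(shape, idx) {
  a <- array(0, dim = shape)
  a[idx] <- 1
  a
}

# Desk-scale stated-world fixture (20^3 grid, 50 subjects, 60 timepoints,
# loading 1, noise_sd 0.5), written to disk once and reused.
default_fixture <- function() {
  memo("default_fixture", function() {
    write_fixture(file.path(tempdir(), "lnmapr-default-fixture"),
                  default_fixture_config(seed = 1L))
  })
}

# Per-lesion thresholded binary maps for the default fixture (t = 5.1,
# two-sided, group t-test), plus the group sum maps.
default_fixture_maps <- function() {
  memo("default_fixture_maps", function() {
    fx <- default_fixture()
    maps <- lapply(fx$masks, function(m)
      lesion_network_map(fx$cohort, m, t_threshold = 5.1,
                         tail = "two_sided"))
    outcomes <- vapply(fx$masks, `[[`, "", "outcome")
    list(maps = maps, outcomes = outcomes,
         sum_P = sum_maps(maps[outcomes == "P"], "P"),
         sum_C = sum_maps(maps[outcomes == "C"], "C"))
  })
}

# Near-noiseless single-network cohort for exact-recovery and latent-course
# oracle tests: 8^3 grid, one radius-2 network, 30 subjects, 30 timepoints.
# noise_sd = 0.05 rather than ~0: at noise levels below the Fisher-z clip
# every subject's within-support r clips to the same value, the
# across-subject sd collapses to 0 and the degenerate-voxel rule blanks the
# map; 0.05 keeps r ~ 0.9975, below the clip, with exact recovery.
noisefree_world <- function() {
  memo("noisefree_world", function() {
    shp <- c(8L, 8L, 8L)
    networks <- make_network_supports(
      shp, k = 1, geometry = list(list(center = c(4, 4, 4), radius = 2)))
    cfg <- cohort_config(shp, n_subjects = 30L, n_timepoints = 30L,
                         networks = networks, noise_sd = 0.05, seed = 11L)
    cohort <- simulate_cohort(cfg)
    planted <- plant_lesion_masks(networks,
                                  data.frame(network = 1L, outcome = "P"),
                                  cohort$grid, lesion_radius = 1, seed = 3L)
    list(networks = networks, cohort = cohort,
         mask = planted$masks[[1]], truth = planted$truth)
  })
}

# Small fast fixture for pipeline/CLI tests: 14^3 grid, 8 subjects,
# 24 timepoints, same 2P/3C/1P1C assignment pattern as the default world.
tiny_fixture <- function() {
  memo("tiny_fixture", function() {
    shp <- c(14L, 14L, 14L)
    networks <- make_network_supports(
      shp, k = 3,
      geometry = list(list(center = c(4, 4, 4), radius = 3),
                      list(center = c(11, 11, 11), radius = 3),
                      list(center = c(4, 11, 11), radius = 3)))
    fixture <- list(
      config = cohort_config(shp, n_subjects = 8L, n_timepoints = 24L,
                             networks = networks, noise_sd = 0.5, seed = 5L),
      networks = networks,
      assignments = data.frame(
        network = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
        outcome = c("P", "P", "C", "C", "C", "P", "C")))
    write_fixture(file.path(tempdir(), "lnmapr-tiny-fixture"), fixture)
  })
}

expect_lnm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
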