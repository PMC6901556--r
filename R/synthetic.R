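# Synthetic normative connectome with planted ground truth.
#
# The generative model: each subject s carries one independent standard
# normal latent time course c_{k,s}(t) per spatial network k; the voxel
# series is Y_s(v,t) = sum_k loading_k * support_k(v) * c_{k,s}(t) + eps,
# eps ~ N(0, noise_sd^2) i.i.d. Networks are axis-aligned spheres on the
# voxel lattice, shared across subjects. Two voxels sharing exactly one
# network with loading a therefore have population correlation
# a^2 / (a^2 + noise_sd^2), which the tests use as a closed-form oracle.

# Evaluate code with a temporary RNG state; restores .Random.seed after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Binary sphere on the voxel lattice, clipped to the grid.
sphere_support <- function(grid_shape, center, radius) {
  ax <- (seq_len(grid_shape[1]) - center[1])^2
  ay <- (seq_len(grid_shape[2]) - center[2])^2
  az <- (seq_len(grid_shape[3]) - center[3])^2
  d2 <- outer(outer(ax, ay, "+"), az, "+")
  (d2 <= radius^2) + 0
}

#' Generate latent network supports (spheres on the voxel lattice)
#'
#' @param grid_shape integer triple.
#' @param k number of networks (ignored when `geometry` is a list).
#' @param geometry `"random"` (centers drawn so each sphere fits inside the
#'   grid) or a list of `list(center =, radius =)` with 1-based voxel
#'   centers.
#' @param radius sphere radius in voxels, used when `geometry = "random"`.
#' @param loading signal amplitude attached to each network (recycled).
#' @param seed RNG seed; identical seeds give identical supports.
#' @return list of `network_spec` objects: `support` (0/1 array), `loading`,
#'   `center`, `radius`.
#' @export
make_network_supports <- function(grid_shape, k, geometry = "random",
                                  radius = 3, loading = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.character(geometry) && identical(geometry, "random")) {
    if (any(2 * radius + 1 > grid_shape))
      lnm_abort("radius does not fit inside the grid", "lnm_geometry_error")
    centers <- with_seed(seed, lapply(seq_len(k), function(i)
      vapply(grid_shape, function(n)
        sample(seq(1L + ceiling(radius), n - ceiling(radius)), 1L), 1L)))
    geometry <- lapply(centers, function(ctr) list(center = ctr, radius = radius))
  }
  loading <- rep_len(loading, length(geometry))
  out <- vector("list", length(geometry))
  for (i in seq_along(geometry)) {
    g <- geometry[[i]]
    supp <- sphere_support(grid_shape, g$center, g$radius)
    if (sum(supp) < 1)
      lnm_abort(sprintf("network %d support is empty after clipping", i),
                "lnm_geometry_error")
    out[[i]] <- structure(
      list(support = supp, loading = loading[i],
           center = as.numeric(g$center), radius = g$radius),
      class = "network_spec")
  }
  out
}

#' Cohort simulation configuration
#'
#' @param grid_shape integer triple.
#' @param n_subjects >= 3 (degrees of freedom for the across-subject t-test).
#' @param n_timepoints >= 4 (degrees of freedom for correlation).
#' @param networks list from [make_network_supports()].
#' @param noise_sd i.i.d. Gaussian noise SD, > 0.
#' @param seed master seed; per-subject streams are derived from it.
#' @param affine voxel-to-world affine; default 2 mm isotropic.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(grid_shape, n_subjects, n_timepoints, networks,
                          noise_sd = 0.5, seed = 1L,
                          affine = diag(c(2, 2, 2, 1))) {
  if (n_timepoints < 4L)
    lnm_abort("n_timepoints must be >= 4", "lnm_config_error")
  if (n_subjects < 3L)
    lnm_abort("n_subjects must be >= 3", "lnm_config_error")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    lnm_abort("noise_sd must be > 0", "lnm_config_error")
  if (!length(networks))
    lnm_abort("at least one network is required", "lnm_config_error")
  structure(list(grid_shape = as.integer(grid_shape),
                 n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 networks = networks, noise_sd = noise_sd,
                 seed = as.integer(seed), affine = affine),
            class = "cohort_config")
}

#' Simulate a normative resting-state cohort
#'
#' Draws, for every subject, one latent time course per network plus i.i.d.
#' Gaussian voxel noise (model described above). Deterministic given
#' `config$seed`: one master seed spawns one derived stream per subject, so
#' the same config always yields bit-identical arrays.
#'
#' @param config a [cohort_config()].
#' @return a [connectome_cohort()]; the per-subject latent courses are
#'   attached as `attr(, "latents")` (list of k x n_timepoints matrices) for
#'   use as a test oracle.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  shp <- config$grid_shape
  nvox <- prod(shp)
  nt <- config$n_timepoints
  k <- length(config$networks)
  S <- vapply(config$networks,
              function(nw) as.vector(nw$support) * nw$loading,
              numeric(nvox))                       # nvox x k loading matrix
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    config$n_subjects))
  subjects <- vector("list", config$n_subjects)
  latents <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    dat <- with_seed(sub_seeds[s], {
      C <- matrix(stats::rnorm(k * nt), k, nt)
      Y <- S %*% C + matrix(stats::rnorm(nvox * nt, sd = config$noise_sd),
                            nvox, nt)
      list(C = C, Y = Y)
    })
    latents[[s]] <- dat$C
    subjects[[s]] <- array(dat$Y, dim = c(shp, nt))
  }
  cohort <- connectome_cohort(subjects, volume_grid(shp, config$affine))
  attr(cohort, "latents") <- latents
  cohort
}

#' Plant lesion masks inside network supports
#'
#' Each lesion is a sphere placed uniformly at random among the voxels where
#' it fits entirely inside its assigned network support, so the planted
#' truth (which network a lesion belongs to, hence its expected thresholded
#' connectivity map) holds by construction.
#'
#' @param networks list from [make_network_supports()].
#' @param assignments data.frame with columns `network` (index into
#'   `networks`) and `outcome` (`"P"`/`"C"`).
#' @param grid `volume_grid` of the cohort.
#' @param lesion_radius sphere radius in voxels.
#' @param seed RNG seed.
#' @return list with `masks` (list of [lesion_mask()]) and `truth`: a list
#'   with `assignments` (data.frame `subject_id`, `outcome`, `network`,
#'   `n_voxels`) and `expected` (per-lesion binary expected-connectivity
#'   array = the assigned network's support).
#' @export
plant_lesion_masks <- function(networks, assignments, grid,
                               lesion_radius = 1, seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  assignments <- as.data.frame(assignments)
  n <- nrow(assignments)
  masks <- vector("list", n)
  expected <- vector("list", n)
  ids <- sprintf("lesion-%02d", seq_len(n))
  centers <- with_seed(seed, lapply(seq_len(n), function(i) {
    supp <- networks[[assignments$network[i]]]$support
    cand <- which(supp == 1, arr.ind = TRUE)
    fits <- vapply(seq_len(nrow(cand)), function(j) {
      sph <- sphere_support(grid$shape, cand[j, ], lesion_radius)
      all(supp[sph == 1] == 1)
    }, logical(1))
    if (!any(fits))
      lnm_abort(sprintf(
        "lesion of radius %g does not fit inside network %d",
        lesion_radius, assignments$network[i]), "lnm_geometry_error")
    cand[sample(which(fits), 1L), ]
  }))
  for (i in seq_len(n)) {
    vox <- sphere_support(grid$shape, centers[[i]], lesion_radius)
    masks[[i]] <- lesion_mask(vox, grid, ids[i], assignments$outcome[i])
    expected[[i]] <- networks[[assignments$network[i]]]$support
  }
  truth <- list(
    assignments = data.frame(subject_id = ids,
                             outcome = assignments$outcome,
                             network = assignments$network,
                             n_voxels = vapply(masks, `[[`, 0L, "n_voxels"),
                             stringsAsFactors = FALSE),
    expected = stats::setNames(expected, ids))
  list(masks = masks, truth = truth)
}

#' Synthetic parcellation from network supports
#'
#' One label per network support (later networks overwrite earlier ones
#' where supports overlap) plus background 0.
#'
#' @param networks list from [make_network_supports()].
#' @param grid `volume_grid`.
#' @return a [parcellation_atlas()] with regions named `Network 1`, ...
#' @export
synthetic_atlas <- function(networks, grid) {
  labels <- array(0L, dim = grid$shape)
  for (i in seq_along(networks)) labels[networks[[i]]$support == 1] <- i
  parcellation_atlas(labels, grid,
                     data.frame(id = seq_along(networks),
                                name = sprintf("Network %d", seq_along(networks))))
}

#' Default desk-scale fixture configuration
#'
#' The stated world of the bundled fixture: a 20^3 grid (2 mm voxels), 50
#' subjects, 60 timepoints, loading 1, noise SD 0.5, three disjoint
#' radius-3 spherical networks, and seven radius-1 lesions: two group-P
#' lesions in network 1, three group-C lesions in network 2 (the C-only
#' discriminative network), and one of each in network 3 (shared), giving
#' N_P = 3, N_C = 4.
#'
#' @param seed master seed for cohort and lesion placement.
#' @return list with `config` ([cohort_config()]), `networks`, and
#'   `assignments`.
#' @export
default_fixture_config <- function(seed = 1L) {
  shp <- c(20L, 20L, 20L)
  networks <- make_network_supports(
    shp, k = 3,
    geometry = list(list(center = c(5, 5, 5), radius = 3),
                    list(center = c(15, 15, 15), radius = 3),
                    list(center = c(5, 15, 15), radius = 3)),
    loading = 1)
  assignments <- data.frame(
    network = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
    outcome = c("P", "P", "C", "C", "C", "P", "C"),
    stringsAsFactors = FALSE)
  list(config = cohort_config(shp, n_subjects = 50L, n_timepoints = 60L,
                              networks = networks, noise_sd = 0.5,
                              seed = seed),
       networks = networks, assignments = assignments)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits everything the pipeline consumes: per-subject 4-D NIfTI volumes and
#' a brain mask under `cohort/`, lesion masks under `masks/` with a
#' tab-delimited mask manifest, a synthetic parcellation (one label per
#' network) with its label table, a flat key-value truth manifest, and a
#' ready-to-run pipeline config. The default fixture runs end-to-end in
#' under a minute.
#'
#' @param dir output directory (created if needed).
#' @param fixture list from [default_fixture_config()] (or a custom one with
#'   the same fields).
#' @param lesion_radius lesion sphere radius in voxels.
#' @param zero_cell_policy policy written into the fixture's pipeline
#'   config. The fixture's discriminative network is occupied by group-C
#'   lesions only, so its support voxels have V_P = 0; the Haldane
#'   correction keeps them defined (the exclude policy would mark the
#'   entire planted contrast invalid by construction).
#' @return list with `dir`, `config_path`, `truth`, `cohort`, `masks`,
#'   `atlas`, and the cohort/mask/atlas paths.
#' @export
write_fixture <- function(dir, fixture = default_fixture_config(),
                          lesion_radius = 1,
                          zero_cell_policy = "haldane") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in file.path(dir, c("cohort", "masks", "atlas")))
    dir.create(d, showWarnings = FALSE)
  cfg <- fixture$config
  cohort <- simulate_cohort(cfg)
  grid <- cohort$grid

  cohort_paths <- character(cohort$n_subjects)
  for (s in seq_len(cohort$n_subjects)) {
    cohort_paths[s] <- file.path(dir, "cohort",
                                 sprintf("%s.nii.gz", cohort$subject_ids[s]))
    write_volume(cohort$subjects[[s]], grid, cohort_paths[s],
                 datatype = "float32")
  }
  write_volume(cohort$brain_mask, grid,
               file.path(dir, "cohort", "brain_mask.nii.gz"),
               datatype = "uint8")

  planted <- plant_lesion_masks(fixture$networks, fixture$assignments, grid,
                                lesion_radius = lesion_radius,
                                seed = cfg$seed + 1L)
  mask_paths <- character(length(planted$masks))
  for (i in seq_along(planted$masks)) {
    m <- planted$masks[[i]]
    mask_paths[i] <- file.path(dir, "masks",
                               sprintf("%s.nii.gz", m$subject_id))
    write_volume(m$voxels, grid, mask_paths[i], datatype = "uint8")
  }
  manifest <- data.frame(subject_id = planted$truth$assignments$subject_id,
                         outcome = planted$truth$assignments$outcome,
                         path = file.path("masks",
                                          basename(mask_paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "mask_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  atlas <- synthetic_atlas(fixture$networks, grid)
  write_volume(atlas$labels, grid, file.path(dir, "atlas", "networks.nii.gz"),
               datatype = "int16")
  utils::write.table(atlas$label_table,
                     file.path(dir, "atlas", "networks_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  truth_kv <- list()
  ta <- planted$truth$assignments
  for (i in seq_len(nrow(ta))) {
    truth_kv[[sprintf("%s.network", ta$subject_id[i])]] <- ta$network[i]
    truth_kv[[sprintf("%s.outcome", ta$subject_id[i])]] <- ta$outcome[i]
    truth_kv[[sprintf("%s.n_voxels", ta$subject_id[i])]] <- ta$n_voxels[i]
  }
  for (k in seq_along(fixture$networks))
    truth_kv[[sprintf("network%d.n_voxels", k)]] <-
      sum(fixture$networks[[k]]$support)
  write_keyvalue(truth_kv, file.path(dir, "truth.txt"))

  config_path <- file.path(dir, "config.txt")
  write_keyvalue(list(
    cohort_dir = "cohort", mask_manifest = "mask_manifest.tsv",
    atlas_volumes = "atlas/networks.nii.gz",
    atlas_tables = "atlas/networks_labels.tsv",
    atlas_names = "networks",
    t_threshold = 5.1, tail = "two_sided",
    zero_cell_policy = zero_cell_policy, vor_cutoff = 2.0,
    r_to_t_mode = "group_ttest", n_perm = 499,
    out_dir = "out", seed = cfg$seed), config_path)

  list(dir = dir, config_path = config_path, truth = planted$truth,
       cohort = cohort, masks = planted$masks, atlas = atlas,
       networks = fixture$networks,
       cohort_paths = cohort_paths, mask_paths = mask_paths,
       atlas_volume = file.path(dir, "atlas", "networks.nii.gz"),
       atlas_table = file.path(dir, "atlas", "networks_labels.tsv"))
}

#' Jaccard overlap of two binary volumes
#'
#' `|A intersect B| / |A union B|`; the planted-recovery tests score
#' thresholded maps against planted supports with it.
#'
#' @param a,b binary arrays (or `stat_map`s of kind binary).
#' @return value in `[0, 1]`; empty union is an error.
#' @export
jaccard_index <- function(a, b) {
  if (inherits(a, "stat_map")) a <- a$values
  if (inherits(b, "stat_map")) b <- b$values
  a <- as.vector(a) > 0 & !is.na(a)
  b <- as.vector(b) > 0 & !is.na(b)
  u <- sum(a | b)
  if (u == 0)
    lnm_abort("Jaccard undefined for two empty volumes", "lnm_undefined_overlap_error")
  sum(a & b) / u
}
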