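# Config-driven end-to-end orchestration: masks + cohort + atlases in;
# per-lesion maps, group sum maps, VOR maps, likelihood maps, Dice report
# and region tables out. Deterministic given config + seed; a rerun over an
# existing output directory reproduces checksum-identical artifacts.

#' Pipeline configuration
#'
#' Every published analysis parameter surfaces here with its canonical
#' default: the whole-brain Bonferroni threshold `t_threshold = 5.1`, the
#' "at least twice as likely" cutoff `vor_cutoff = 2.0`, the zero-cell
#' policy, the t-map tail, and the r-to-t construction.
#'
#' @param cohort_dir directory of per-subject 4-D NIfTI volumes (pattern
#'   `sub-*.nii[.gz]`) plus optional `brain_mask.nii[.gz]`.
#' @param mask_manifest tab-delimited file with columns `subject_id`,
#'   `outcome` (`P`/`C`), `path` (relative paths resolved against
#'   `base_dir`).
#' @param out_dir output directory.
#' @param t_threshold t-map threshold (default 5.1).
#' @param tail `"two_sided"` or `"positive"`.
#' @param zero_cell_policy `"exclude"` or `"haldane"`.
#' @param vor_cutoff likelihood-map cutoff (default 2.0).
#' @param atlases named list of `list(volume =, table =)` paths; may be
#'   empty.
#' @param seed seed for the Dice permutation test.
#' @param r_to_t_mode `"group_ttest"` or `"single_map"`.
#' @param n_perm Dice permutation count.
#' @param mask_threshold binarization threshold applied when reading masks.
#' @param base_dir directory against which relative paths are resolved.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir, mask_manifest, out_dir,
                            t_threshold = 5.1,
                            tail = c("two_sided", "positive"),
                            zero_cell_policy = c("exclude", "haldane"),
                            vor_cutoff = 2.0, atlases = list(), seed = 1L,
                            r_to_t_mode = c("group_ttest", "single_map"),
                            n_perm = 999L, mask_threshold = 0.5,
                            base_dir = ".") {
  resolve <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  structure(list(
    cohort_dir = resolve(cohort_dir),
    mask_manifest = resolve(mask_manifest),
    out_dir = resolve(out_dir),
    t_threshold = as.numeric(t_threshold),
    tail = match.arg(tail),
    zero_cell_policy = match.arg(zero_cell_policy),
    vor_cutoff = as.numeric(vor_cutoff),
    atlases = lapply(atlases, function(a)
      list(volume = resolve(a$volume), table = resolve(a$table))),
    seed = as.integer(seed),
    r_to_t_mode = match.arg(r_to_t_mode),
    n_perm = as.integer(n_perm),
    mask_threshold = as.numeric(mask_threshold)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Format: one `key = value` per line, `#` comments. Keys mirror
#' [pipeline_config()] arguments; atlases are given as parallel
#' comma-separated lists `atlas_volumes`, `atlas_tables` and (optionally)
#' `atlas_names`. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    lnm_abort(sprintf("config file not found: %s", path), "lnm_config_error")
  kv <- read_keyvalue(path)
  need <- c("cohort_dir", "mask_manifest", "out_dir")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    lnm_abort(sprintf("config is missing required key(s): %s",
                      paste(miss, collapse = ", ")), "lnm_config_error")
  atlases <- list()
  if (!is.null(kv$atlas_volumes)) {
    vols <- trimws(strsplit(kv$atlas_volumes, ",")[[1]])
    tabs <- trimws(strsplit(kv$atlas_tables %||% "", ",")[[1]])
    if (length(vols) != length(tabs))
      lnm_abort("atlas_volumes and atlas_tables must have equal length",
                "lnm_config_error")
    nms <- if (!is.null(kv$atlas_names))
      trimws(strsplit(kv$atlas_names, ",")[[1]])
    else sprintf("atlas%d", seq_along(vols))
    atlases <- stats::setNames(
      lapply(seq_along(vols), function(i)
        list(volume = vols[i], table = tabs[i])), nms)
  }
  pipeline_config(
    cohort_dir = kv$cohort_dir, mask_manifest = kv$mask_manifest,
    out_dir = kv$out_dir,
    t_threshold = as.numeric(kv$t_threshold %||% 5.1),
    tail = kv$tail %||% "two_sided",
    zero_cell_policy = kv$zero_cell_policy %||% "exclude",
    vor_cutoff = as.numeric(kv$vor_cutoff %||% 2.0),
    atlases = atlases,
    seed = as.integer(kv$seed %||% 1L),
    r_to_t_mode = kv$r_to_t_mode %||% "group_ttest",
    n_perm = as.integer(kv$n_perm %||% 999L),
    mask_threshold = as.numeric(kv$mask_threshold %||% 0.5),
    base_dir = dirname(path))
}

read_mask_manifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "outcome", "path")
  if (!all(need %in% names(tab)))
    lnm_abort(sprintf("mask manifest must have columns %s",
                      paste(need, collapse = ", ")), "lnm_config_error")
  tab
}

list_cohort_files <- function(cohort_dir) {
  files <- list.files(cohort_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  sort(files[!grepl("brain_mask", basename(files))])
}

#' Validate pipeline inputs before any computation
#'
#' Checks, without throwing (report contract): that every path resolves,
#' that all masks, cohort subjects and atlases share one grid, that no mask
#' is empty, that both outcome groups are present, and that atlas label
#' tables cover their volumes. [run_pipeline()] refuses to start on a
#' failing report.
#'
#' @param config a `pipeline_config`.
#' @return list with `ok` (logical), `problems` (character vector, empty
#'   when clean), `n_P`, `n_C`, `n_subjects`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  n_P <- n_C <- n_subjects <- 0L
  ref_grid <- NULL

  cohort_files <- character(0)
  if (!dir.exists(config$cohort_dir)) {
    note(sprintf("cohort directory not found: %s", config$cohort_dir))
  } else {
    cohort_files <- list_cohort_files(config$cohort_dir)
    n_subjects <- length(cohort_files)
    if (n_subjects < 3L)
      note(sprintf("cohort has %d subject file(s); need >= 3", n_subjects))
    for (f in cohort_files) {
      h <- tryCatch(read_nifti_grid(f), error = function(e) e)
      if (inherits(h, "error")) {
        note(sprintf("unreadable cohort file %s: %s", f, conditionMessage(h)))
      } else if (h$ndim != 4L) {
        note(sprintf("cohort file is not 4-D: %s", f))
      } else if (is.null(ref_grid)) {
        ref_grid <- h$grid
      } else if (!check_grid_compatible(ref_grid, h$grid)) {
        note(sprintf("cohort file on an incompatible grid: %s", f))
      }
    }
  }

  if (!file.exists(config$mask_manifest)) {
    note(sprintf("mask manifest not found: %s", config$mask_manifest))
  } else {
    man <- tryCatch(read_mask_manifest(config$mask_manifest),
                    error = function(e) e)
    if (inherits(man, "error")) {
      note(sprintf("unreadable mask manifest: %s", conditionMessage(man)))
    } else {
      if (any(!man$outcome %in% c("P", "C")))
        note("mask manifest outcomes must be 'P' or 'C'")
      n_P <- sum(man$outcome == "P")
      n_C <- sum(man$outcome == "C")
      if (n_P == 0L) note("outcome group P has no masks")
      if (n_C == 0L) note("outcome group C has no masks")
      base <- dirname(config$mask_manifest)
      for (i in seq_len(nrow(man))) {
        p <- man$path[i]
        if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
        m <- tryCatch(read_lesion_mask(p, man$subject_id[i],
                                       man$outcome[i],
                                       config$mask_threshold),
                      error = function(e) e)
        if (inherits(m, "error")) {
          note(sprintf("mask '%s' (%s): %s", man$subject_id[i], p,
                       conditionMessage(m)))
        } else if (!is.null(ref_grid) &&
                   !check_grid_compatible(ref_grid, m$grid)) {
          note(sprintf("mask '%s' on an incompatible grid: %s",
                       man$subject_id[i], p))
        }
      }
    }
  }

  for (nm in names(config$atlases)) {
    a <- config$atlases[[nm]]
    at <- tryCatch(read_atlas(a$volume, a$table), error = function(e) e)
    if (inherits(at, "error")) {
      note(sprintf("atlas '%s': %s", nm, conditionMessage(at)))
    } else if (!is.null(ref_grid) &&
               !check_grid_compatible(ref_grid, at$grid)) {
      note(sprintf("atlas '%s' on an incompatible grid: %s", nm, a$volume))
    }
  }

  list(ok = length(problems) == 0L, problems = problems,
       n_P = n_P, n_C = n_C, n_subjects = n_subjects)
}

#' Load a cohort directory into memory
#'
#' @param cohort_dir directory of `sub-*.nii[.gz]` 4-D volumes plus optional
#'   `brain_mask.nii[.gz]`.
#' @return a [connectome_cohort()].
#' @export
load_cohort <- function(cohort_dir) {
  files <- list_cohort_files(cohort_dir)
  if (length(files) < 3L)
    lnm_abort(sprintf("cohort directory %s has fewer than 3 subject files",
                      cohort_dir), "lnm_config_error")
  subjects <- lapply(files, function(f) read_volume(f, expect_4d = TRUE)$values)
  grid <- read_volume(files[[1]], expect_4d = TRUE)$grid
  bm_file <- list.files(cohort_dir, pattern = "^brain_mask\\.nii(\\.gz)?$",
                        full.names = TRUE)
  brain_mask <- if (length(bm_file)) {
    bm <- read_volume(bm_file[[1]])
    assert_same_grid(grid, bm$grid, "cohort and brain mask")
    binarize_mask(bm$values)
  } else NULL
  connectome_cohort(subjects, grid, brain_mask,
                    subject_ids = sub("\\.nii(\\.gz)?$", "", basename(files)))
}

write_sidecar <- function(path, fields) write_keyvalue(fields, path)

#' Run the full lesion network mapping pipeline
#'
#' Stages, each logged with voxel-count summaries (silent empty maps are
#' the dominant failure mode): validate inputs; load the cohort and masks;
#' compute one thresholded binarized network map per lesion; sum them per
#' outcome group; compute VOR maps in both directions plus the
#' `vor_cutoff` likelihood maps; compute the within-group pairwise Dice
#' report with its label-permutation p-value; and summarize both VOR
#' directions over every configured atlas. A run manifest records every
#' parameter and input checksum; any stage error aborts with the stage
#' name, leaving the manifest marked incomplete.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the output `paths`, the validation
#'   `report`, the `dice` report and the region `tables`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- validate_inputs(config)
  if (!report$ok)
    lnm_abort(paste0("input validation failed:\n  ",
                     paste(report$problems, collapse = "\n  ")),
              "lnm_validation_error", problems = report$problems)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "run_manifest.txt")
  stage <- "setup"
  manifest <- list(status = "incomplete", stage = stage)
  flush_manifest <- function() write_keyvalue(manifest, manifest_path)

  result <- tryCatch({
    stage <- "load_cohort"
    cohort <- load_cohort(config$cohort_dir)
    say("loaded cohort: %d subjects x %d timepoints, %d brain voxels",
        cohort$n_subjects, cohort$n_timepoints, sum(cohort$brain_mask))

    stage <- "load_masks"
    man <- read_mask_manifest(config$mask_manifest)
    base <- dirname(config$mask_manifest)
    masks <- lapply(seq_len(nrow(man)), function(i) {
      p <- man$path[i]
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
      read_lesion_mask(p, man$subject_id[i], man$outcome[i],
                       config$mask_threshold)
    })
    mask_files <- vapply(seq_len(nrow(man)), function(i) {
      p <- man$path[i]
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
      p
    }, "")

    stage <- "lesion_maps"
    paths <- list()
    binary_maps <- vector("list", length(masks))
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      bm <- lesion_network_map(cohort, m, config$t_threshold, config$tail,
                               config$r_to_t_mode)
      binary_maps[[i]] <- bm
      out_nii <- file.path(config$out_dir,
                           sprintf("%s_binary.nii.gz", m$subject_id))
      write_volume(bm$values, bm$grid, out_nii, datatype = "uint8")
      write_sidecar(file.path(config$out_dir,
                              sprintf("%s_binary.txt", m$subject_id)),
                    list(subject_id = m$subject_id, outcome = m$outcome,
                         t_threshold = config$t_threshold, tail = config$tail,
                         r_to_t_mode = config$r_to_t_mode,
                         n_subjects = cohort$n_subjects,
                         n_voxels = sum(bm$values)))
      paths[[sprintf("binary_%s", m$subject_id)]] <- out_nii
      say("lesion map %s (%s): %d suprathreshold voxels",
          m$subject_id, m$outcome, sum(bm$values))
      if (sum(bm$values) == 0)
        say("  warning: lesion map %s is empty at t >= %g",
            m$subject_id, config$t_threshold)
    }

    stage <- "sum_maps"
    is_P <- man$outcome == "P"
    sum_P <- sum_maps(binary_maps[is_P], "P")
    sum_C <- sum_maps(binary_maps[!is_P], "C")
    for (g in list(sum_P, sum_C)) {
      p <- file.path(config$out_dir,
                     sprintf("sum_%s.nii.gz", g$group_label))
      write_volume(g$values, g$grid, p, datatype = "int16")
      paths[[sprintf("sum_%s", g$group_label)]] <- p
      say("sum map %s: n = %d, max overlap = %d",
          g$group_label, g$group_size, max(g$values))
    }

    stage <- "vor_maps"
    vors <- list(P = vor_map(sum_P, sum_C, "P_vs_C", config$zero_cell_policy),
                 C = vor_map(sum_P, sum_C, "C_vs_P", config$zero_cell_policy))
    for (lab in names(vors)) {
      v <- vors[[lab]]
      stem <- file.path(config$out_dir, sprintf("vor_%s", v$direction))
      write_volume(v$values, v$grid, paste0(stem, ".nii.gz"))
      write_volume(v$valid + 0, v$grid, paste0(stem, "_valid.nii.gz"),
                   datatype = "uint8")
      write_sidecar(paste0(stem, ".txt"),
                    list(direction = v$direction, policy = v$policy,
                         n_p = v$n_p, n_c = v$n_c,
                         vor_cutoff = config$vor_cutoff))
      paths[[sprintf("vor_%s", v$direction)]] <- paste0(stem, ".nii.gz")
      lk <- likelihood_map(v, config$vor_cutoff)
      lp <- file.path(config$out_dir,
                      sprintf("likelihood_%s.nii.gz", v$direction))
      write_volume(lk$values, lk$grid, lp, datatype = "uint8")
      paths[[sprintf("likelihood_%s", v$direction)]] <- lp
      say("VOR %s: %d valid voxels, %d at VOR >= %g",
          v$direction, sum(v$valid), sum(lk$values), config$vor_cutoff)
    }

    stage <- "dice"
    dice <- compare_group_dice(masks[is_P], masks[!is_P],
                               n_perm = config$n_perm, seed = config$seed)
    dice_tab <- data.frame(
      group = c("P", "C"),
      n_masks = c(sum(is_P), sum(!is_P)),
      mean_dice = c(dice$mean_P, dice$mean_C),
      sd_dice = c(dice$sd_P, dice$sd_C),
      perm_p_value = dice$p_value, n_perm = dice$n_perm)
    dice_path <- file.path(config$out_dir, "dice_report.tsv")
    utils::write.table(dice_tab, dice_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    dmat <- pairwise_dice(masks)$matrix
    utils::write.table(dmat, file.path(config$out_dir, "dice_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    paths$dice_report <- dice_path
    say("Dice: P mean %.4f (SD %.4f), C mean %.4f (SD %.4f), perm p = %.3f",
        dice$mean_P, dice$sd_P, dice$mean_C, dice$sd_C, dice$p_value)

    stage <- "atlas_tables"
    tables <- list()
    for (nm in names(config$atlases)) {
      a <- config$atlases[[nm]]
      atlas <- read_atlas(a$volume, a$table)
      tab <- dual_direction_table(vors$P, vors$C, atlas)
      tp <- file.path(config$out_dir, sprintf("region_table_%s.tsv", nm))
      write_region_table(tab, tp)
      tables[[nm]] <- tab
      paths[[sprintf("region_table_%s", nm)]] <- tp
      say("atlas '%s': %d regions summarized", nm, nrow(tab))
    }

    stage <- "manifest"
    inputs <- c(list_cohort_files(config$cohort_dir), mask_files,
                unlist(lapply(config$atlases, unlist), use.names = FALSE),
                config$mask_manifest)
    manifest <- c(
      list(status = "complete",
           t_threshold = config$t_threshold, tail = config$tail,
           zero_cell_policy = config$zero_cell_policy,
           vor_cutoff = config$vor_cutoff,
           r_to_t_mode = config$r_to_t_mode, n_perm = config$n_perm,
           seed = config$seed, mask_threshold = config$mask_threshold,
           n_subjects = cohort$n_subjects, n_P = sum(is_P),
           n_C = sum(!is_P)),
      stats::setNames(as.list(unname(tools::md5sum(inputs))),
                      sprintf("md5.input.%s", basename(inputs))),
      stats::setNames(
        as.list(unname(tools::md5sum(unlist(paths, use.names = FALSE)))),
        sprintf("md5.output.%s",
                basename(unlist(paths, use.names = FALSE)))))
    flush_manifest()
    list(paths = paths, report = report, dice = dice, tables = tables,
         manifest_path = manifest_path)
  }, lnm_error = function(e) {
    manifest$stage <<- stage
    flush_manifest()
    lnm_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                      conditionMessage(e)),
              c("lnm_stage_error", class(e)[1]))
  })
  invisible(result)
}

#' Rebuild region tables from an existing pipeline output directory
#'
#' Reads the VOR maps (values + validity volumes + sidecars) already in
#' `out_dir` and re-runs the atlas summarization, without touching the
#' cohort.
#'
#' @param config a `pipeline_config` whose `out_dir` holds a completed run.
#' @return invisibly, the named list of region tables.
#' @export
summarize_outputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  read_vor <- function(direction) {
    stem <- file.path(config$out_dir, sprintf("vor_%s", direction))
    if (!file.exists(paste0(stem, ".nii.gz")))
      lnm_abort(sprintf("no VOR map for direction %s under %s (run first)",
                        direction, config$out_dir), "lnm_config_error")
    vol <- read_volume(paste0(stem, ".nii.gz"))
    vld <- read_volume(paste0(stem, "_valid.nii.gz"))
    sc <- read_keyvalue(paste0(stem, ".txt"))
    structure(list(grid = vol$grid, values = vol$values,
                   valid = array(vld$values == 1, dim = vol$grid$shape),
                   direction = sc$direction, policy = sc$policy,
                   n_p = as.integer(sc$n_p), n_c = as.integer(sc$n_c),
                   provenance = sprintf("reloaded from %s", stem)),
              class = "vor_map")
  }
  vor_P <- read_vor("P_vs_C")
  vor_C <- read_vor("C_vs_P")
  tables <- list()
  for (nm in names(config$atlases)) {
    a <- config$atlases[[nm]]
    atlas <- read_atlas(a$volume, a$table)
    tab <- dual_direction_table(vor_P, vor_C, atlas)
    write_region_table(tab, file.path(config$out_dir,
                                      sprintf("region_table_%s.tsv", nm)))
    tables[[nm]] <- tab
  }
  invisible(tables)
}
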