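# Map algebra on binarized connectivity masks: thresholding, group
# summation, Dice overlap and the permutation test on group Dice means.

#' Threshold and binarize a t-map
#'
#' Value 1 where the voxel is valid and the tail condition holds
#' (inclusive `>=`), else 0. Invalid voxels can never enter the binary map.
#'
#' @param t_map [stat_map()] of kind `"t"`.
#' @param t_threshold threshold (inclusive).
#' @param tail `"two_sided"` (`|t| >= threshold`) or `"positive"`.
#' @return a [stat_map()] of kind `"binary"`, valid everywhere.
#' @export
threshold_binarize <- function(t_map, t_threshold = 5.1,
                               tail = c("two_sided", "positive")) {
  tail <- match.arg(tail)
  stopifnot(inherits(t_map, "stat_map"))
  if (t_map$kind != "t")
    lnm_abort("threshold_binarize expects a stat_map of kind 't'",
              "lnm_kind_error")
  v <- t_map$values
  hit <- if (tail == "two_sided") abs(v) >= t_threshold else v >= t_threshold
  out <- (t_map$valid & !is.na(hit) & hit) + 0
  stat_map(array(out, dim = t_map$grid$shape), t_map$grid, kind = "binary",
           valid = array(TRUE, dim = t_map$grid$shape),
           provenance = sprintf("%s -> threshold t >= %g (%s), binarized",
                                t_map$provenance, t_threshold, tail))
}

#' Sum binarized connectivity maps across a group
#'
#' Voxelwise count of maps equal to 1: if the binarized connectivity maps of
#' four lesions overlap at a voxel, that voxel holds 4 in the summed image.
#'
#' @param binary_maps list of [stat_map()]s of kind `"binary"` (>= 1),
#'   sharing one grid.
#' @param group_label `"P"` or `"C"`.
#' @return a `group_sum_map`: list with `grid`, `values` (integer array),
#'   `group_label`, `group_size` (number of maps summed).
#' @export
sum_maps <- function(binary_maps, group_label = c("P", "C")) {
  group_label <- match.arg(group_label)
  if (!length(binary_maps))
    lnm_abort("sum_maps needs at least one map", "lnm_config_error")
  grid <- binary_maps[[1L]]$grid
  acc <- array(0, dim = grid$shape)
  for (m in binary_maps) {
    stopifnot(inherits(m, "stat_map"))
    if (m$kind != "binary")
      lnm_abort("sum_maps expects stat_maps of kind 'binary'", "lnm_kind_error")
    assert_same_grid(grid, m$grid, "binary maps")
    v <- m$values
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  storage.mode(acc) <- "integer"
  structure(list(grid = grid, values = acc, group_label = group_label,
                 group_size = length(binary_maps)),
            class = "group_sum_map")
}

#' @export
print.group_sum_map <- function(x, ...) {
  cat(sprintf("<group_sum_map group=%s n=%d> max overlap %d\n",
              x$group_label, x$group_size, max(x$values)))
  invisible(x)
}

#' Dice overlap of two binary volumes
#'
#' `2 * |A intersect B| / (|A| + |B|)` on voxel counts. Two empty volumes
#' are an error (an empty mask signals an upstream fault), not 0 or 1.
#'
#' @param a,b binary 3-D arrays, [lesion_mask()]s, or binary [stat_map()]s.
#' @return value in `[0, 1]`.
#' @examples
#' a <- array(0, c(5, 5, 5)); a[1:4, 1:5, 1:5] <- 1 # 100 voxels
#' b <- array(0, c(5, 5, 5)); b[3:4, 1:5, 1:5] <- 1
#' b[5, 1:2, 1:5] <- 1                              # 60 voxels, overlap 50
#' dice_index(a, b)
#' @export
dice_index <- function(a, b) {
  av <- as_binary_array(a)
  bv <- as_binary_array(b)
  if (!identical(dim(av), dim(bv)))
    lnm_abort("dice_index inputs have different shapes", "lnm_grid_mismatch_error")
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0)
    lnm_abort("Dice undefined for two empty volumes", "lnm_undefined_dice_error")
  2 * sum(av & bv) / (na + nb)
}

as_binary_array <- function(x) {
  if (inherits(x, "lesion_mask")) x <- x$voxels
  if (inherits(x, "stat_map")) x <- x$values
  v <- as.array(x)
  v[is.na(v)] <- 0
  v > 0
}

#' Pairwise Dice indices within a set of masks
#'
#' All unordered pairs; the reported SD is the sample (n-1) SD over the
#' `n(n-1)/2` pair values, with the single-pair case reported as SD 0.
#'
#' @param masks list of [lesion_mask()]s (>= 2) on one grid.
#' @return list with `matrix` (symmetric, unit diagonal, mask ids as
#'   dimnames), `pairs` (upper-triangle values), `mean`, `sd`.
#' @export
pairwise_dice <- function(masks) {
  n <- length(masks)
  if (n < 2L)
    lnm_abort("pairwise_dice needs at least 2 masks", "lnm_config_error")
  grid <- masks[[1L]]$grid
  for (m in masks) assert_same_grid(grid, m$grid, "masks")
  ids <- vapply(masks, `[[`, "", "subject_id")
  D <- diag(1, n)
  dimnames(D) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- dice_index(masks[[i]], masks[[j]])
  pairs <- D[upper.tri(D)]
  list(matrix = D, pairs = pairs, mean = mean(pairs),
       sd = if (length(pairs) > 1L) stats::sd(pairs) else 0)
}

# Mean within-group pairwise Dice for a subset of indices, given the full
# precomputed Dice matrix.
group_pair_mean <- function(D, idx) {
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Permutation test on the group difference in mean pairwise Dice
#'
#' Pairwise Dice values within a group are not independent (each mask enters
#' many pairs), which invalidates a naive two-sample t-test; the group
#' contrast is therefore tested by permuting outcome labels over masks. The
#' statistic is the absolute difference of the two within-group mean
#' pairwise Dice values; the p-value uses the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` and is reproducible
#' given `seed`.
#'
#' @param masks_P,masks_C lists of [lesion_mask()]s (each >= 2).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `p_value`, `observed`, `mean_P`, `sd_P`, `mean_C`,
#'   `sd_C`, `n_perm`.
#' @export
compare_group_dice <- function(masks_P, masks_C, n_perm = 999, seed = 1L) {
  if (length(masks_P) < 2L || length(masks_C) < 2L)
    lnm_abort("each group needs at least 2 masks", "lnm_config_error")
  if (n_perm < 100L)
    lnm_abort("n_perm must be >= 100", "lnm_config_error")
  all_masks <- c(masks_P, masks_C)
  n <- length(all_masks)
  nP <- length(masks_P)
  pd <- pairwise_dice(all_masks)
  D <- pd$matrix
  obs_P <- group_pair_mean(D, seq_len(nP))
  obs_C <- group_pair_mean(D, (nP + 1L):n)
  observed <- abs(obs_P - obs_C)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, nP)
    abs(group_pair_mean(D, idx) - group_pair_mean(D, setdiff(seq_len(n), idx)))
  }, numeric(1)))
  within_P <- pairwise_dice(masks_P)
  within_C <- pairwise_dice(masks_C)
  list(p_value = (1 + sum(perm >= observed)) / (1 + n_perm),
       observed = observed,
       mean_P = within_P$mean, sd_P = within_P$sd,
       mean_C = within_C$mean, sd_C = within_C$sd,
       n_perm = as.integer(n_perm))
}
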