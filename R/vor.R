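# Voxelwise odds ratios (VOR) contrasting the two outcome groups.
#
# At a voxel, with N_P lesions in the outcome group of interest of which
# V_P show thresholded connectivity there, and N_C / V_C likewise for the
# complement group:
#
#   VOR = V_P * (N_C - V_C) / (V_C * (N_P - V_P))
#
# i.e. the odds ratio of the implicit 2x2 table (connected vs not, by
# group). The opposite direction swaps the group roles. The formula is
# undefined when V_C = 0 or V_P = N_P; policy "exclude" marks such voxels
# invalid (never fabricating odds), policy "haldane" adds the classical
# +0.5 continuity correction to all four cells.

#' Odds ratio for one voxel's 2x2 outcome-by-connectivity table
#'
#' @param v_p lesions of the group of interest connected at the voxel.
#' @param v_c lesions of the complement group connected at the voxel.
#' @param n_p,n_c group sizes.
#' @param policy `"exclude"` (default): a zero in `V_C` or `N_P - V_P`
#'   renders the voxel invalid (`NA`); `"haldane"`: +0.5 added to all four
#'   cells before the ratio.
#' @return a non-negative number, or `NA` for an excluded voxel.
#' @examples
#' vor_cell(4, 2, 11, 16) # 4 * (16 - 2) / (2 * (11 - 4)) = 4
#' @export
vor_cell <- function(v_p, v_c, n_p, n_c, policy = c("exclude", "haldane")) {
  policy <- match.arg(policy)
  if (n_p < 1 || n_c < 1 || v_p < 0 || v_c < 0 || v_p > n_p || v_c > n_c)
    lnm_abort("vor_cell requires 0 <= V <= N and N >= 1 for both groups",
              "lnm_domain_error")
  if (policy == "haldane")
    return((v_p + 0.5) * (n_c - v_c + 0.5) / ((v_c + 0.5) * (n_p - v_p + 0.5)))
  if (v_c == 0 || v_p == n_p) return(NA_real_)
  v_p * (n_c - v_c) / (v_c * (n_p - v_p))
}

#' Voxelwise odds-ratio map from two group sum maps
#'
#' Applies the 2x2 odds ratio at every voxel, with `V_P`/`V_C` read from
#' the summed binarized connectivity maps and `N_P`/`N_C` from their
#' `group_size` fields. Direction `"P_vs_C"` asks where lesions of group P
#' are more likely connected; `"C_vs_P"` swaps the group roles exactly.
#' Undefined voxels carry the `NA` sentinel (never 0) so that downstream
#' atlas means cannot silently absorb them.
#'
#' @param sum_P,sum_C `group_sum_map`s for groups P and C (from
#'   [sum_maps()]), on one grid.
#' @param direction `"P_vs_C"` or `"C_vs_P"`.
#' @param policy zero-cell policy, see [vor_cell()].
#' @return a `vor_map`: list with `grid`, `values`, `valid`, `direction`,
#'   `policy`, `n_p`, `n_c` (role-ordered group sizes), `provenance`.
#' @export
vor_map <- function(sum_P, sum_C, direction = c("P_vs_C", "C_vs_P"),
                    policy = c("exclude", "haldane")) {
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  stopifnot(inherits(sum_P, "group_sum_map"), inherits(sum_C, "group_sum_map"))
  assert_same_grid(sum_P$grid, sum_C$grid, "group sum maps")
  if (sum_P$group_label == sum_C$group_label)
    lnm_abort("sum_P and sum_C must come from different groups",
              "lnm_config_error")
  if (max(sum_P$values) > sum_P$group_size ||
      max(sum_C$values) > sum_C$group_size)
    lnm_abort("sum map exceeds its group size", "lnm_domain_error")
  if (direction == "P_vs_C") {
    a <- as.vector(sum_P$values); na <- sum_P$group_size
    b <- as.vector(sum_C$values); nb <- sum_C$group_size
  } else {
    a <- as.vector(sum_C$values); na <- sum_C$group_size
    b <- as.vector(sum_P$values); nb <- sum_P$group_size
  }
  if (policy == "haldane") {
    vals <- (a + 0.5) * (nb - b + 0.5) / ((b + 0.5) * (na - a + 0.5))
    valid <- rep(TRUE, length(vals))
  } else {
    valid <- b > 0 & a < na
    vals <- rep(NA_real_, length(a))
    vals[valid] <- a[valid] * (nb - b[valid]) / (b[valid] * (na - a[valid]))
  }
  grid <- sum_P$grid
  structure(list(grid = grid,
                 values = array(vals, dim = grid$shape),
                 valid = array(valid, dim = grid$shape),
                 direction = direction, policy = policy,
                 n_p = na, n_c = nb,
                 provenance = sprintf(
                   "VOR %s (N roles %d vs %d), zero-cell policy = %s",
                   direction, na, nb, policy)),
            class = "vor_map")
}

#' @export
print.vor_map <- function(x, ...) {
  cat(sprintf("<vor_map %s policy=%s> %d valid voxels, max %.3g\n",
              x$direction, x$policy, sum(x$valid),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Binary "at least k times as likely" map from a VOR map
#'
#' Value 1 where the voxel is valid and `VOR >= cutoff` (inclusive, so a
#' voxel exactly at 2.0 is "at least twice as likely"), else 0.
#'
#' @param vor a [vor_map()].
#' @param cutoff odds-ratio cutoff (default 2.0).
#' @return a [stat_map()] of kind `"binary"`.
#' @export
likelihood_map <- function(vor, cutoff = 2.0) {
  stopifnot(inherits(vor, "vor_map"))
  hit <- vor$valid & !is.na(vor$values) & vor$values >= cutoff
  stat_map(array(hit + 0, dim = vor$grid$shape), vor$grid, kind = "binary",
           valid = array(TRUE, dim = vor$grid$shape),
           provenance = sprintf("%s -> VOR >= %g", vor$provenance, cutoff))
}
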