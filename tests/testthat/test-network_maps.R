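# network_maps: thresholding semantics, group summation, Dice overlap and
# the label-permutation group test.

tmap <- function(vals, g, valid = NULL) {
  stat_map(array(vals, g$shape), g, "t", valid = valid)
}
bmap <- function(vals, g) stat_map(array(vals, g$shape), g, "binary")

test_that("threshold_binarize honours tails, inclusivity and validity", {
  g <- test_grid(c(3L, 1L, 1L))
  t1 <- tmap(c(4.9, 5.1, 6.0), g)
  expect_equal(as.vector(threshold_binarize(t1, 5.1, "positive")$values),
               c(0, 1, 1)) # inclusive boundary
  t2 <- tmap(c(-6, 6, 0), g)
  expect_equal(as.vector(threshold_binarize(t2, 5.1, "two_sided")$values),
               c(1, 1, 0))
  expect_equal(as.vector(threshold_binarize(t2, 5.1, "positive")$values),
               c(0, 1, 0))
  # invalid voxel with large t stays out
  t3 <- tmap(c(9, 9, 9), g, valid = array(c(FALSE, TRUE, TRUE), g$shape))
  expect_equal(as.vector(threshold_binarize(t3, 5.1)$values), c(0, 1, 1))
})

test_that("sum maps count overlapping binarized maps", {
  g <- test_grid(c(2L, 2L, 1L))
  ones <- bmap(c(1, 1, 0, 0), g)
  # four maps overlapping at a voxel -> value 4 there
  s4 <- sum_maps(list(ones, ones, ones, ones), "P")
  expect_equal(s4$values[1, 1, 1], 4L)
  expect_identical(s4$group_size, 4L)
  # one map: sum equals the map
  s1 <- sum_maps(list(ones), "C")
  expect_equal(as.vector(s1$values), as.vector(ones$values))
  # linearity: sum of disjoint sublists adds up
  other <- bmap(c(0, 1, 1, 0), g)
  sa <- sum_maps(list(ones, other), "P")
  expect_equal(sa$values,
               sum_maps(list(ones), "P")$values + sum_maps(list(other), "P")$values)
  # bound: max <= group size on random stacks
  set.seed(3)
  for (i in 1:10) {
    maps <- lapply(1:5, function(j) bmap(rbinom(4, 1, 0.5), g))
    expect_lte(max(sum_maps(maps, "P")$values), 5L)
  }
  expect_lnm_error(sum_maps(list(tmap(c(1, 2, 3, 4), g)), "P"), "lnm_kind_error")
})

test_that("Dice follows its formula, symmetry, and edge conventions", {
  shape <- c(10L, 10L, 2L)
  a <- mask_array(shape, 1:100)             # |A| = 100
  b <- mask_array(shape, 61:120)            # |B| = 60, overlap 40
  expect_equal(dice_index(a, b), 2 * 40 / 160) # hand count: 0.5
  expect_equal(dice_index(a, b), dice_index(b, a))
  expect_equal(dice_index(a, a), 1)
  expect_equal(dice_index(a, mask_array(shape, 150:160)), 0)
  expect_lnm_error(dice_index(mask_array(shape, integer(0)),
                              mask_array(shape, integer(0))),
                   "lnm_undefined_dice_error")
  # range on randomized pairs
  set.seed(5)
  for (i in 1:20) {
    x <- mask_array(shape, sample(200, 30))
    y <- mask_array(shape, sample(200, 30))
    d <- dice_index(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("pairwise Dice reports mean and sample SD over unordered pairs", {
  g <- test_grid(c(6L, 6L, 2L))
  mk <- function(idx, id) lesion_mask(mask_array(g$shape, idx), g, id, "P")
  # pair Dice values (0.5, 0, 0): two half-overlapping, one disjoint
  m1 <- mk(1:4, "a"); m2 <- mk(3:6, "b"); m3 <- mk(20:23, "c")
  pd <- pairwise_dice(list(m1, m2, m3))
  expect_equal(sort(pd$pairs), c(0, 0, 0.5))
  expect_equal(pd$mean, mean(c(0.5, 0, 0)), tolerance = 1e-12)
  expect_equal(pd$sd, stats::sd(c(0.5, 0, 0)), tolerance = 1e-12) # 0.2887
  # two identical masks: one pair, SD reported as 0
  pd2 <- pairwise_dice(list(mk(1:4, "a"), mk(1:4, "b")))
  expect_equal(pd2$mean, 1)
  expect_equal(pd2$sd, 0)
  # three mutually disjoint
  pd3 <- pairwise_dice(list(mk(1:2, "a"), mk(11:12, "b"), mk(31:32, "c")))
  expect_equal(pd3$mean, 0); expect_equal(pd3$sd, 0)
})

test_that("the permutation test is calibrated against brute-force enumeration", {
  g <- test_grid(c(8L, 8L, 2L))
  mk <- function(idx, id, oc) lesion_mask(mask_array(g$shape, idx), g, id, oc)
  # 6 masks: group P identical (pair Dice 1), group C mutually disjoint (0)
  P3 <- lapply(1:3, function(i) mk(1:4, sprintf("p%d", i), "P"))
  C3 <- list(mk(21:24, "c1", "C"), mk(41:44, "c2", "C"), mk(61:64, "c3", "C"))
  res <- compare_group_dice(P3, C3, n_perm = 1999, seed = 4)
  expect_equal(res$observed, 1)
  # brute force over all choose(6,3) = 20 labelings (independent oracle)
  masks <- c(P3, C3)
  D <- pairwise_dice(masks)$matrix
  splits <- utils::combn(6, 3)
  stats <- apply(splits, 2, function(idx) {
    a <- D[idx, idx][upper.tri(D[idx, idx])]
    b <- D[-idx, -idx][upper.tri(D[-idx, -idx])]
    abs(mean(a) - mean(b))
  })
  exact <- mean(stats >= res$observed)   # = 2/20
  expect_equal(exact, 0.1)
  mc_prop <- (res$p_value * (1 + res$n_perm) - 1) / res$n_perm
  expect_lt(abs(mc_prop - exact), 0.03)  # Monte-Carlo agreement
  # adequate group sizes separate the extreme case at alpha = 0.05
  P5 <- lapply(1:5, function(i) mk(1:4, sprintf("p%d", i), "P"))
  C5 <- lapply(1:5, function(i) mk((20 * i + 1):(20 * i + 4),
                                   sprintf("c%d", i), "C"))
  expect_lte(compare_group_dice(P5, C5, n_perm = 999, seed = 4)$p_value, 0.05)
})

test_that("the permutation test is deterministic and null-calibrated", {
  g <- test_grid(c(8L, 8L, 2L))
  mk <- function(idx, id, oc) lesion_mask(mask_array(g$shape, idx), g, id, oc)
  set.seed(10)
  ms <- lapply(1:4, function(i) mk(sample(100, 10), sprintf("m%d", i), "P"))
  # identical groups (same masks both sides) -> observed 0 -> p = 1
  same <- compare_group_dice(ms, ms, n_perm = 199, seed = 1)
  expect_equal(same$p_value, 1)
  # same seed twice -> identical p; p always in (0, 1]
  a <- compare_group_dice(ms[1:2], ms[3:4], n_perm = 199, seed = 12)
  b <- compare_group_dice(ms[1:2], ms[3:4], n_perm = 199, seed = 12)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0); expect_lte(a$p_value, 1)
})
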