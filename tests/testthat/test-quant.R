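test_that("marker segmentation recovers the ground-truth regions", {
  q <- simulate_quant_volume(reduction_fraction = 0, n_regions = 10,
                             n_volumes_per_group = 1, seed = 5)
  vol <- q$volumes[[1]]
  lab <- segment_marker_regions(vol)
  truth <- q$truth$label_arrays[[1]]
  expect_equal(max(lab), 10)
  for (r in 1:10) {
    tm <- truth == r
    jac <- max(vapply(seq_len(max(lab)), function(l) {
      sm <- lab == l
      sum(tm & sm) / sum(tm | sm)
    }, numeric(1)))
    expect_gte(jac, 0.8)
  }
})

test_that("segmentation edge cases error or empty out as specified", {
  vol <- structure(list(channels = list(marker = array(1, c(4, 8, 8)),
                                        target = array(1, c(4, 8, 8))),
                        voxel_size_um = c(0.4, 0.13, 0.13),
                        group_label = "control"), class = "labeled_volume")
  expect_error(segment_marker_regions(vol), "no threshold")
  q <- simulate_quant_volume(n_volumes_per_group = 1, seed = 2)
  lab <- segment_marker_regions(q$volumes[[1]], min_voxels = 1e6)
  expect_equal(max(lab), 0)
})

test_that("region intensity statistics are exact on constructed volumes", {
  dims <- c(4, 8, 8)
  masks <- array(0L, dims)
  masks[2, 2:3, 2:3] <- 1L
  masks[3, 6:7, 6:7] <- 2L
  vol <- structure(list(channels = list(target = array(7, dims)),
                        voxel_size_um = c(0.4, 0.13, 0.13),
                        group_label = "control"), class = "labeled_volume")
  rs <- region_intensity_stats(vol, masks)
  expect_equal(rs$regions$target_mean_intensity, c(7, 7))
  expect_equal(rs$volume_mean, 7)
  # linearity under channel gain
  vol2 <- vol
  vol2$channels$target <- vol$channels$target * 2
  expect_equal(region_intensity_stats(vol2, masks)$volume_mean, 14)
})

test_that("knockdown/control intensity ratio tracks the configured reduction", {
  q <- simulate_quant_volume(reduction_fraction = 0.09,
                             n_volumes_per_group = 20, seed = 5)
  vm <- vapply(seq_along(q$volumes), function(i) {
    lab <- segment_marker_regions(q$volumes[[i]])
    region_intensity_stats(q$volumes[[i]], lab)$volume_mean
  }, numeric(1))
  grp <- q$truth$groups
  norm <- normalize_to_control(vm, vm[grp == "control"])
  expect_equal(median(norm[grp == "control"]), 1.0)
  expect_equal(median(norm[grp == "knockdown"]), 0.91, tolerance = 0.03)
})

test_that("normalisation is idempotent and batch-independent", {
  set.seed(9)
  ctrl <- rnorm(10, 100, 5)
  kd <- rnorm(10, 90, 5)
  n1 <- normalize_to_control(kd, ctrl)
  ctrl_n <- normalize_to_control(ctrl, ctrl)
  expect_equal(median(ctrl_n), 1.0)
  expect_equal(normalize_to_control(n1, ctrl_n), n1)
  expect_error(normalize_to_control(kd, numeric(0)), "empty")
  expect_error(normalize_to_control(kd, c(0, 0, 0)), "zero")
})

test_that("dilation positivity recovers the configured carrier fraction", {
  q <- simulate_quant_volume(reduction_fraction = 0, n_volumes_per_group = 5,
                             dilation_signal_prob = 0.6, seed = 9)
  pf <- dilation_positive_fraction(q$volumes, q$truth$dilation_arrays,
                                   region_masks = q$truth$label_arrays)
  truth_pct <- 100 * mean(unlist(q$truth$dilation_positive))
  n <- attr(pf, "n")
  ci <- 196 * sqrt(0.6 * 0.4 / n)  # 1.96 * 100 * binomial SE
  expect_lte(abs(as.numeric(pf) - truth_pct), ci + 1e-9)
  # all-carrier and no-carrier limits
  q1 <- simulate_quant_volume(n_volumes_per_group = 2,
                              dilation_signal_prob = 1, seed = 3)
  expect_equal(as.numeric(dilation_positive_fraction(
    q1$volumes, q1$truth$dilation_arrays,
    region_masks = q1$truth$label_arrays)), 100)
  q0 <- simulate_quant_volume(n_volumes_per_group = 2,
                              dilation_signal_prob = 0, seed = 3)
  expect_equal(as.numeric(dilation_positive_fraction(
    q0$volumes, q0$truth$dilation_arrays,
    region_masks = q0$truth$label_arrays)), 0)
})

test_that("bending angle honours the collinear/perpendicular conventions", {
  d <- cbind(0:5, 0)
  expect_equal(bending_angle(d, cbind(6:10, 0)), 0, tolerance = 1e-8)
  expect_equal(bending_angle(d, cbind(5, 0:4)), 90, tolerance = 1e-8)
  th <- 25 * pi / 180
  cil <- cbind(5 + seq(0, 3, 0.3) * cos(th), seq(0, 3, 0.3) * sin(th))
  expect_equal(bending_angle(d, cil), 25, tolerance = 1)
  # rigid rotation and reflection invariance
  rot <- function(p, a) p %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(bending_angle(rot(d, 0.7), rot(cil, 0.7)), 25, tolerance = 1)
  refl <- cbind(d[, 1], -d[, 2])
  cil_r <- cbind(cil[, 1], -cil[, 2])
  expect_equal(bending_angle(refl, cil_r), 25, tolerance = 1)
  expect_error(bending_angle(cbind(c(1, 1), c(2, 2)), cil), "coincident")
})

test_that("Mann-Whitney comparison matches symmetry and enumeration facts", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_equal(same$p, 1)
  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p, 0.1)
  big <- compare_groups(rnorm(30), rnorm(30) + 10)
  expect_lt(big$p, 0.01)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney equals brute-force enumeration for all sizes <= 6", {
  set.seed(17)
  for (n1 in 3:6) {
    for (n2 in 3:6) {
      a <- rnorm(n1)
      b <- rnorm(n2, 0.5)
      got <- compare_groups(a, b)$p
      expect_equal(got, mw_enumeration_p(a, b), tolerance = 1e-12,
                   label = sprintf("p for n1=%d n2=%d", n1, n2))
    }
  }
})
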