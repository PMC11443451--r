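# Vesselness probability map, 3-class Otsu, hysteresis connectivity.

make_cylinder <- function(n = 24, spacing = 0.5, radius = 1, center = c(6, 6),
                          value = 1) {
  cx <- (seq_len(n) - 0.5) * spacing
  X <- array(rep(cx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cx, each = n), times = n), c(n, n, n))
  a <- array(0, c(n, n, n))
  a[(X - center[1])^2 + (Y - center[2])^2 <= radius^2] <- value
  as_volume(a, spacing)
}

test_that("cylinder axis voxels rank at the top of the vesselness map", {
  cyl <- make_cylinder(radius = 1)
  v <- vesselness_probability(cyl, scales_mm = 1)
  cx <- (seq_len(24) - 0.5) * 0.5
  X <- array(rep(cx, times = 24 * 24), c(24, 24, 24))
  Y <- array(rep(rep(cx, each = 24), times = 24), c(24, 24, 24))
  r2 <- (X - 6)^2 + (Y - 6)^2
  interior <- c(5:20)   # avoid volume-edge voxels
  axis_vals <- v$data[r2 <= 0.15][interior]
  expect_gt(min(axis_vals), quantile(v$data, 0.95))
  expect_true(all(v$data >= 0 & v$data <= 1))
})

test_that("constant volume yields an all-zero map with a warning", {
  flat <- as_volume(array(3, c(8, 8, 8)), c(1, 1, 1))
  expect_warning(v <- vesselness_probability(flat, 1), "constant")
  expect_true(all(v$data == 0))
})

test_that("a cylinder outranks a sphere of equal peak intensity", {
  n <- 24; sp <- 0.5
  cx <- (seq_len(n) - 0.5) * sp
  X <- array(rep(cx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cx, each = n), times = n), c(n, n, n))
  Z <- array(rep(cx, each = n * n), c(n, n, n))
  a <- array(0, c(n, n, n))
  a[(X - 3)^2 + (Y - 3)^2 <= 1] <- 1                     # cylinder along z
  a[(X - 9)^2 + (Y - 9)^2 + (Z - 6)^2 <= 1] <- 1          # sphere
  v <- vesselness_probability(as_volume(a, sp), 1)
  cyl_axis <- v$data[abs(X - 3) < 0.3 & abs(Y - 3) < 0.3 &
                       Z > 3 & Z < 9]
  sph_center <- v$data[abs(X - 9) < 0.3 & abs(Y - 9) < 0.3 &
                         abs(Z - 6) < 0.3]
  expect_gt(min(cyl_axis), max(sph_center))
})

test_that("3-class Otsu separates three point masses", {
  vals <- c(rep(0.1, 800), rep(0.5, 150), rep(0.9, 50))
  thr <- otsu_thresholds_3class(vals, 64)
  expect_gt(thr$lower, 0.1); expect_lte(thr$lower, 0.5)
  expect_gte(thr$upper, 0.5); expect_lt(thr$upper, 0.9)
  expect_equal(sum(thr$omega), 1)
})

test_that("Otsu matches the brute-force pair search exactly", {
  set.seed(SUITE_SEED)
  for (r in 1:10) {
    vals <- c(rnorm(300, 0.2, 0.05), rnorm(80, 0.5, 0.08),
              rnorm(30, 0.85, 0.04))
    thr <- otsu_thresholds_3class(vals, 32)
    bf <- bf_otsu3(vals, 32)
    expect_equal(thr$lower, bf$lower)
    expect_equal(thr$upper, bf$upper)
    expect_equal(thr$sigma_b2, bf$s, tolerance = 1e-12)
  }
})

test_that("Otsu is affine-equivariant and validates input", {
  set.seed(SUITE_SEED)
  vals <- runif(500)
  thr <- otsu_thresholds_3class(vals, 64)
  thr2 <- otsu_thresholds_3class(0.5 * vals, 64)
  expect_equal(thr2$lower, 0.5 * thr$lower, tolerance = 1e-12)
  expect_equal(thr2$upper, 0.5 * thr$upper, tolerance = 1e-12)
  expect_error(otsu_thresholds_3class(c(1, 1, 2)), "3 distinct")
  expect_error(otsu_thresholds_3class(runif(10), n_bins = 4), "n_bins")
})

test_that("hysteresis keeps connected mid-band voxels only", {
  a <- array(0, c(7, 7, 3))
  a[2, 2, 2] <- 0.95                       # seed
  a[5, 5, 2] <- 0.6                        # isolated mid-band voxel
  thr <- list(lower = 0.5, upper = 0.9)
  m <- hysteresis_binarize(as_volume(a, c(1, 1, 1)), thr)
  expect_identical(sum(m$data), 1)
  expect_identical(m$data[2, 2, 2], 1)

  # face-adjacent chain 0.95 - 0.7 - 0.6 is fully included
  a[3, 2, 2] <- 0.7; a[4, 2, 2] <- 0.6
  m2 <- hysteresis_binarize(as_volume(a, c(1, 1, 1)), thr)
  expect_identical(m2$data[3, 2, 2], 1)
  expect_identical(m2$data[4, 2, 2], 1)
  expect_identical(m2$data[5, 5, 2], 0)
})

test_that("hysteresis equals the BFS flood-fill oracle on random maps", {
  set.seed(SUITE_SEED)
  for (r in 1:10) {
    p <- array(runif(8^3), c(8, 8, 8))
    thr <- list(lower = 0.6, upper = 0.92)
    m <- hysteresis_binarize(as_volume(p, c(1, 1, 1)), thr)$data > 0
    oracle <- bfs_hysteresis(p, 0.6, 0.92)
    expect_identical(m, oracle)
    # sandwich invariant: strong subset mask subset weak
    expect_true(all(m[p > 0.92]))
    expect_false(any(m[p <= 0.6]))
  }
})

test_that("empty hysteresis result warns rather than fails", {
  p <- as_volume(array(0.1, c(5, 5, 5)), c(1, 1, 1))
  expect_warning(m <- hysteresis_binarize(p, list(lower = 0.5, upper = 0.9)),
                 "empty")
  expect_identical(sum(m$data), 0)
})

test_that("segmented vein masks overlap the truth (Dice >= 0.6) at defaults", {
  spec <- small_spec()
  sur <- make_surfaces(spec)
  for (s in 1:2) {
    subj <- generate_subject(spec, paste0("S", s), "young", 0L,
                             SUITE_SEED + s, sur)
    ribbon <- as_volume(subj$inner$data > 0 & subj$outer$data > 0,
                        spec$spacing)
    seg <- segment_veins(subj$qsm, mask = ribbon, scales_mm = c(0.5, 1.0))
    truth <- subj$vein_mask$data > 0
    est <- seg$mask$data > 0
    rb <- ribbon$data > 0
    dice <- 2 * sum(est & truth & rb) / (sum(est & rb) + sum(truth & rb))
    expect_gte(dice, 0.6)
  }
})
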