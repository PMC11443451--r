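# Phantom cohort generator: geometry, veins, metric fields, determinism.

test_that("flat slab gives planar surfaces with the exact thickness", {
  spec <- phantom_spec(grid_shape = c(32L, 16L, 32L), spacing = 0.5,
                       fold_amplitude = 0, thickness = 3, n_veins = 1L,
                       vein_min_sep = 2, vein_margin = 3)
  sur <- make_surfaces(spec)
  # inner + outer signed distances sum to the thickness everywhere
  expect_equal(max(abs(sur$inner$data + sur$outer$data - 3)), 0)
  # a flat column crosses >= 6 voxels of ribbon at 3 mm / 0.5 mm
  col <- sur$inner$data[16, 8, ] > 0 & sur$outer$data[16, 8, ] > 0
  expect_gte(sum(col), 6)
})

test_that("folded-surface signed distance matches brute-force search", {
  spec <- phantom_spec(grid_shape = c(56L, 24L, 48L), spacing = 0.5,
                       fold_amplitude = 3, fold_wavelength = 24,
                       thickness = 3, n_veins = 1L, vein_min_sep = 2,
                       vein_margin = 3)
  sur <- make_surfaces(spec)
  d <- dim(sur$outer$data)
  f <- function(x) spec$outer_level +
    spec$fold_amplitude * sin(2 * pi * x / spec$fold_wavelength)
  set.seed(SUITE_SEED)
  idx <- cbind(sample(d[1], 500, TRUE), sample(d[2], 500, TRUE),
               sample(d[3], 500, TRUE))
  xs <- seq(0, d[1] * 0.5, by = 0.01)   # dense sampling over the grid domain
  fx <- f(xs)
  err <- vapply(seq_len(500), function(r) {
    p <- (idx[r, ] - 0.5) * 0.5
    # nearest surface point has the voxel's y: minimize in x only
    bf <- sqrt(min((p[1] - xs)^2 + (p[3] - fx)^2))
    abs(abs(sur$outer$data[idx[r, 1], idx[r, 2], idx[r, 3]]) - bf)
  }, 0)
  expect_lt(max(err), sqrt(3) * 0.5)   # one voxel diagonal
  # sign: below the surface is positive (cortex side)
  below <- (idx[, 3] - 0.5) * 0.5 < f((idx[, 1] - 0.5) * 0.5)
  s <- sur$outer$data[idx]
  expect_true(all(s[below & abs(s) > 0.6] > 0))
  expect_true(all(s[!below & abs(s) > 0.6] < 0))
})

test_that("ribbon exiting the grid is fatal", {
  spec <- phantom_spec(grid_shape = c(32L, 16L, 16L), spacing = 0.5,
                       fold_amplitude = 3, thickness = 3,
                       outer_level = 7, n_veins = 1L, vein_min_sep = 2,
                       vein_margin = 3)
  expect_error(make_surfaces(spec), "ribbon exits grid")
})

test_that("vein cross-sections match the disc-counting oracle", {
  # radius 0.5 at 0.5 mm spacing: 1-5 voxel centers per slice
  spec <- phantom_spec(grid_shape = c(32L, 32L, 24L), spacing = 0.5,
                       fold_amplitude = 0, thickness = 3, n_veins = 1L,
                       vein_radius = 0.5, vein_min_sep = 2, vein_margin = 4,
                       vein_tilt_sd = 0)
  counts <- integer(0)
  for (s in 1:5) {
    set.seed(s)
    veins <- carve_veins(spec)
    per_slice <- apply(veins$mask$data, 3, sum)
    counts <- c(counts, per_slice)
    # oracle: count grid centers within the radius of the axis point
    ax <- veins$axes[1, 1:2]
    cx <- (seq_len(32) - 0.5) * 0.5
    oracle <- sum(outer((cx - ax[1])^2, (cx - ax[2])^2, `+`) <= 0.25 + 1e-12)
    expect_true(all(per_slice == oracle))
  }
  expect_true(all(counts >= 1 & counts <= 5))
})

test_that("vein placement respects separation and is seed-deterministic", {
  spec <- small_spec()
  set.seed(3); v1 <- carve_veins(spec)
  set.seed(3); v2 <- carve_veins(spec)
  expect_identical(v1$mask$data, v2$mask$data)
  sepa <- sqrt(sum((v1$axes[1, 1:2] - v1$axes[2, 1:2])^2))
  expect_gte(sepa, spec$vein_min_sep)
  # truth distance is 0 exactly on vein-mask voxels
  dist_truth <- pmax(v1$axis_distance$data - spec$vein_radius, 0)
  expect_true(all(dist_truth[v1$mask$data > 0] == 0))
  # infeasible separation is fatal and reports the achieved count
  bad <- small_spec(); bad$vein_min_sep <- 100
  set.seed(1)
  expect_error(carve_veins(bad), "achieved 1")
})

test_that("noise-free metric fields recover the programmed coefficients", {
  spec <- small_spec(qt1_subject_sd = 0, qt1_voxel_sd = 0,
                     qsm_subject_sd = 0, qsm_voxel_sd = 0,
                     qt1_dist_curv = 2.5)
  sur <- make_surfaces(spec)
  subj <- generate_subject(spec, "S1", "young", 0L, 11L, sur)
  rb <- !is.na(subj$depth_truth$data)
  for (a in 1:2) {
    sel <- rb & subj$area_labels$data == a & !(subj$vein_mask$data > 0)
    delta <- subj$depth_truth$data[sel] - 0.5
    D <- pmin(subj$dist_truth$data[sel], 10) - 5
    fit <- stats::lm(subj$qt1$data[sel] ~ delta + D + I(D^2))
    b <- coef(fit)
    expect_lt(abs(b["delta"] - spec$qt1_depth_slope) /
                abs(spec$qt1_depth_slope), 0.01)
    expect_lt(abs(b["D"] - spec$qt1_dist_slope_young) /
                abs(spec$qt1_dist_slope_young), 0.01)
    expect_lt(abs(b["I(D^2)"] - spec$qt1_dist_curv) / spec$qt1_dist_curv,
              0.01)
    expect_lt(abs(b["(Intercept)"] - spec$qt1_baseline[a]), 0.5)
  }
})

test_that("degenerate spec gives constant qT1 per area", {
  spec <- small_spec(qt1_subject_sd = 0, qt1_voxel_sd = 0,
                     qt1_depth_slope = 0, qt1_dist_slope_young = 0,
                     qt1_dist_slope_old = 0)
  sur <- make_surfaces(spec)
  subj <- generate_subject(spec, "S1", "young", 0L, 11L, sur)
  rb <- !is.na(subj$depth_truth$data) & !(subj$vein_mask$data > 0)
  for (a in 1:2) {
    v <- subj$qt1$data[rb & subj$area_labels$data == a]
    expect_equal(stats::sd(v), 0)
    expect_equal(v[1], spec$qt1_baseline[a])
  }
})

test_that("QSM sign mixture exercises both polarities and the floor", {
  spec <- small_spec()
  sur <- make_surfaces(spec)
  subj <- generate_subject(spec, "S1", "old", 1L, 13L, sur)
  rb <- !is.na(subj$depth_truth$data) & !(subj$vein_mask$data > 0)
  q <- subj$qsm$data[rb]
  expect_gt(mean(q > 0), 0.4)   # p_pos = 0.6 with magnitude flooring
  expect_gt(mean(q < 0), 0.2)
  expect_true(all(abs(q) >= spec$qsm_floor - 1e-12))
})

test_that("cohort structure, risk assignment and determinism", {
  spec <- tiny_cohort_spec(SUITE_SEED)
  rows <- generate_cohort(spec, callback = function(s)
    list(group = s$group, risk = s$risk, qt1_sum = sum(s$qt1$data)))
  man <- attr(rows, "manifest")
  expect_identical(nrow(man), 35L)
  expect_identical(sum(man$group == "young"), 18L)
  expect_identical(sum(man$group == "old"), 17L)
  expect_true(all(man$risk[man$group == "young"] == 0L))
  rows2 <- generate_cohort(spec, callback = function(s)
    list(group = s$group, risk = s$risk, qt1_sum = sum(s$qt1$data)))
  expect_identical(rows, rows2)   # bit-identical cohort under one seed
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(thickness = 1, spacing = 0.5), "thickness")
  expect_error(phantom_spec(vein_radius = 0.2, spacing = 0.5), "radius")
  expect_error(phantom_spec(qt1_voxel_sd = -1), "sd parameters")
  expect_error(phantom_spec(qt1_baseline = NaN), "non-finite")
})
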