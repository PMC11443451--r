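# Equi-volume laminar depths and compartment assignment.

test_that("equidistant depth fraction", {
  expect_equal(equidistant_depth(2, 2), 0.5)
  expect_equal(equidistant_depth(0, 3), 0)
  expect_equal(equidistant_depth(1, 3), 0.25)
  expect_error(equidistant_depth(0, 0), "degenerate")
  expect_error(equidistant_depth(-1, 2), "nonnegative")
})

test_that("equivolume_fraction formula, limits and the integration oracle", {
  expect_equal(equivolume_fraction(0.5, 1, 2), -1 + sqrt(2.5),
               tolerance = 1e-12)
  a <- seq(0, 1, by = 0.05)
  expect_equal(equivolume_fraction(a, 1, 1), a)           # flat limit
  expect_equal(equivolume_fraction(0, 3, 7), 0)
  expect_equal(equivolume_fraction(1, 3, 7), 1)
  expect_error(equivolume_fraction(0.5, -1, 2), "positive")

  # numeric frustum integration: area grows linearly from A_i at rho = 0
  for (pars in list(c(1, 2), c(2, 5), c(4, 1.5))) {
    Ai <- pars[1]; Ao <- pars[2]
    for (alpha in c(0.2, 0.5, 0.8)) {
      rho <- equivolume_fraction(alpha, Ai, Ao)
      vol <- stats::integrate(function(r) Ai + (Ao - Ai) * r, 0, rho)$value /
        stats::integrate(function(r) Ai + (Ao - Ai) * r, 0, 1)$value
      expect_equal(vol, alpha, tolerance = 1e-8)
    }
  }
})

test_that("equivolume_fraction and equivolume_alpha are mutual inverses", {
  set.seed(SUITE_SEED)
  for (r in 1:50) {
    Ai <- runif(1, 0.2, 5); Ao <- runif(1, 0.2, 5)
    alpha <- runif(20)
    rho <- equivolume_fraction(alpha, Ai, Ao)
    expect_true(all(diff(equivolume_fraction(sort(alpha), Ai, Ao)) >= 0))
    expect_equal(equivolume_alpha(rho, Ai, Ao), alpha, tolerance = 1e-8)
  }
})

test_that("flat phantom: equivolume equals equidistant to 1e-6", {
  spec <- phantom_spec(grid_shape = c(32L, 16L, 32L), spacing = 0.5,
                       fold_amplitude = 0, thickness = 3, n_veins = 1L,
                       vein_min_sep = 2, vein_margin = 3)
  sur <- make_surfaces(spec)
  de <- compute_depth_field(sur$inner, sur$outer, "equidistant")
  dv <- compute_depth_field(sur$inner, sur$outer, "equivolume")
  ok <- !is.na(de$data)
  expect_lt(max(abs(de$data[ok] - dv$data[ok])), 1e-6)
  expect_identical(attr(dv, "n_fallback"), 0L)
})

test_that("gyral crown: equivolume depth is deeper at the Euclidean midpoint", {
  # numeric volume integration on the known geometry: the outer side of a
  # crown holds more area, so half the wedge volume is passed before the
  # Euclidean midpoint
  spec <- phantom_spec(grid_shape = c(96L, 8L, 72L), spacing = 0.5,
                       fold_amplitude = 3, fold_wavelength = 32,
                       thickness = 6, n_veins = 1L, vein_min_sep = 2,
                       vein_margin = 4)
  sur <- make_surfaces(spec)
  de <- compute_depth_field(sur$inner, sur$outer, "equidistant")
  dv <- compute_depth_field(sur$inner, sur$outer, "equivolume")
  cx <- (seq_len(96) - 0.5) * 0.5
  crown <- array(rep(abs(cx - 8) <= 3, times = 8 * 72), dim(de$data))
  mid <- !is.na(de$data) & abs(de$data - 0.5) < 0.05 & crown
  expect_gt(mean(dv$data[mid] - de$data[mid]), 0.01)
  # oracle: spherical-wedge integration with the analytic crown curvature
  kappa <- spec$fold_amplitude * (2 * pi / spec$fold_wavelength)^2
  alpha_mid <- stats::integrate(function(r) 1 - kappa * r, 0, 3)$value /
    stats::integrate(function(r) 1 - kappa * r, 0, 6)$value
  expect_gt(alpha_mid, 0.5)   # the sign the implementation must reproduce
})

test_that("folded phantom: equivolume depth bins are more uniform", {
  # depth sampling finer than the bin width (anisotropic fine-z grid), so
  # bin-count CV reflects geometry rather than voxel aliasing
  spec <- phantom_spec(grid_shape = c(96L, 8L, 240L),
                       spacing = c(0.5, 0.5, 0.125),
                       fold_amplitude = 3, fold_wavelength = 32,
                       thickness = 6, n_veins = 1L, vein_min_sep = 2,
                       vein_margin = 4)
  sur <- make_surfaces(spec)
  de <- compute_depth_field(sur$inner, sur$outer, "equidistant")
  dv <- compute_depth_field(sur$inner, sur$outer, "equivolume")
  cv <- function(depth) {
    j <- assign_compartments(depth)$depth_index$data
    tb <- table(factor(j[!is.na(j)], levels = 1:21))
    stats::sd(tb) / mean(tb)
  }
  expect_lt(cv(dv), cv(de))
})

test_that("compartment assignment follows the 21-depth partition", {
  mk <- function(delta) {
    a <- array(NA_real_, c(1, 1, 1)); a[1] <- delta
    as_volume(a, c(1, 1, 1))
  }
  lab <- function(delta) {
    cc <- assign_compartments(mk(delta))
    list(j = cc$depth_index$data[1], comp = cc$compartment[1])
  }
  expect_identical(lab(0.5), list(j = 11, comp = "OM"))
  expect_identical(lab(0.02), list(j = 1, comp = "EXCLUDED"))
  expect_identical(lab(0.999), list(j = 21, comp = "EXCLUDED"))
  expect_identical(lab(1.0), list(j = 21, comp = "EXCLUDED"))
  # structural: 21 depths, 5 excluded, 4 compartments x 4 depths
  labs <- vapply(( (1:21) - 0.5) / 21, function(d) lab(d)$comp, "")
  expect_identical(labs[1:3], rep("EXCLUDED", 3))
  expect_identical(labs[20:21], rep("EXCLUDED", 2))
  expect_identical(as.integer(table(labs[4:19])[c("SF", "OM", "IM", "DP")]),
                   rep(4L, 4))
  expect_identical(labs[4:7], rep("SF", 4))
  expect_identical(labs[16:19], rep("DP", 4))
})

test_that("compartments are balanced on a flat phantom", {
  # z spacing chosen so that two voxel layers tile each of the 21 depth
  # bins exactly; otherwise bin-boundary aliasing dominates the counts
  sz <- 3 / 42
  spec <- phantom_spec(grid_shape = c(24L, 24L, 64L),
                       spacing = c(0.5, 0.5, sz),
                       fold_amplitude = 0, thickness = 3,
                       outer_level = 53 * sz, n_veins = 1L,
                       vein_min_sep = 2, vein_margin = 3)
  sur <- make_surfaces(spec)
  de <- compute_depth_field(sur$inner, sur$outer, "equidistant")
  comp <- assign_compartments(de)$compartment
  counts <- table(comp[!is.na(comp) & comp != "EXCLUDED"])
  expect_lt(diff(range(counts)) / mean(counts), 0.02)
})
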