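# Independent oracles and shared small fixtures for the test suite.
# Oracles deliberately use naive formulations (brute force, BFS, direct
# formula evaluation) and never call the code paths they check.

# canonical suite seed
SUITE_SEED <- 42L

# Brute-force nearest-vein distance: all-pairs search over voxel centers.
bf_distance_map <- function(mask, spacing) {
  d <- dim(mask)
  cx <- (seq_len(d[1]) - 0.5) * spacing[1]
  cy <- (seq_len(d[2]) - 0.5) * spacing[2]
  cz <- (seq_len(d[3]) - 0.5) * spacing[3]
  pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  vm <- pts[c(mask), , drop = FALSE]
  out <- apply(pts, 1, function(p) sqrt(min(colSums((t(vm) - p)^2))))
  array(out, d)
}

# Brute-force 3-class Otsu: direct sigma_B^2 evaluation for every pair.
bf_otsu3 <- function(values, n_bins) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(values, breaks = breaks, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  muT <- sum(w * mids)
  best <- list(s = -Inf)
  for (t1 in 1:(n_bins - 2)) for (t2 in (t1 + 1):(n_bins - 1)) {
    i1 <- 1:t1; i2 <- (t1 + 1):t2; i3 <- (t2 + 1):n_bins
    sb <- 0
    for (ii in list(i1, i2, i3)) {
      wk <- sum(w[ii])
      if (wk > 0) {
        mk <- sum(w[ii] * mids[ii]) / wk
        sb <- sb + wk * (mk - muT)^2
      }
    }
    if (sb > best$s) best <- list(s = sb, lower = breaks[t1 + 1],
                                  upper = breaks[t2 + 1])
  }
  best
}

# BFS flood fill from upper-threshold seeds through the weak band
# (26-connectivity): the hysteresis oracle.
bfs_hysteresis <- function(prob, lower, upper) {
  d <- dim(prob)
  strong <- which(prob > upper)
  weak <- prob > lower
  visited <- array(FALSE, d)
  visited[strong] <- TRUE
  queue <- strong
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    k <- (v - 1) %/% (d[1] * d[2])
    r <- (v - 1) %% (d[1] * d[2])
    j <- r %/% d[1]
    i <- r %% d[1]
    for (q in seq_len(nrow(nb))) {
      ii <- i + nb[q, 1]; jj <- j + nb[q, 2]; kk <- k + nb[q, 3]
      if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
          kk < 0 || kk >= d[3]) next
      w <- 1 + ii + d[1] * (jj + d[2] * kk)
      if (!visited[w] && weak[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  visited
}

# Independent step-down Holm evaluation, rank by rank.
bf_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, p[o[i]] * (m - i + 1))
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# Small folded-ribbon spec used across tests (24 x 24 x 20 mm at 0.5 mm).
small_spec <- function(...) {
  phantom_spec(n_young = 8L, n_old = 7L, grid_shape = c(48L, 48L, 40L),
               spacing = c(0.5, 0.5, 0.5), fold_amplitude = 2,
               fold_wavelength = 24, thickness = 3, n_veins = 2L,
               vein_min_sep = 10, vein_margin = 4, seed = SUITE_SEED, ...)
}

# 16^3 cohort spec for the parameter-recovery criterion (20 mm extent at
# 1.25 mm; one thick vein; paper-calibrated qT1 effects inherited).
tiny_cohort_spec <- function(seed, interaction = TRUE) {
  s <- phantom_spec(n_young = 18L, n_old = 17L, grid_shape = c(16L, 16L, 16L),
                    spacing = c(1.25, 1.25, 1.25), fold_amplitude = 1,
                    fold_wavelength = 10, thickness = 5, n_veins = 1L,
                    vein_radius = 1.25, vein_min_sep = 2, vein_margin = 4,
                    seed = seed)
  if (!interaction) {
    m <- (s$qt1_dist_slope_young + s$qt1_dist_slope_old) / 2
    s$qt1_dist_slope_young <- m
    s$qt1_dist_slope_old <- m
  }
  s
}

# Per-subject qT1 bin means over the whole ribbon from truth fields:
# the fast extraction used by the stats-recovery tests.
truth_bin_means <- function(subj, edges = c(0, 2, 4, 6, 8, 10)) {
  rb <- subj$inner$data > 0 & subj$outer$data > 0 & !(subj$vein_mask$data > 0)
  b <- bin_distance(subj$dist_truth$data[rb], edges)
  tapply(subj$qt1$data[rb], b, mean)
}

# Age x distance interaction p-value for one simulated cohort.
cohort_interaction_p <- function(seed, interaction = TRUE) {
  spec <- tiny_cohort_spec(seed, interaction)
  rows <- generate_cohort(spec, callback = truth_bin_means)
  Y <- do.call(rbind, rows)
  if (anyNA(Y)) return(NA_real_)
  man <- attr(rows, "manifest")
  a <- mixed_anova(Y, factor(man$group, levels = c("young", "old")),
                   data.frame(distance = colnames(Y)))
  a$p_uni[a$effect == "group:distance"]
}
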