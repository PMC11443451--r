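# Vein segmentation: multiscale Hessian tubularity -> vessel probability map,
# 3-class Otsu thresholds, hysteresis connectivity.

# Separable Gaussian convolution along one axis with replicate padding.
.conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- prod(dim(a)[-1])
  dim(a) <- c(n, m)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  ap <- a[idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * r)
  for (i in seq_len(n)) K[i, i:(i + 2L * r)] <- kernel
  out <- K %*% ap
  dim(out) <- dim(aperm(arr, perm))
  aperm(out, order(perm))
}

#' Gaussian smoothing of a volume (mm-scaled, separable)
#' @param vol a volume.
#' @param sigma_mm Gaussian SD in mm (isotropic in physical space).
#' @return Smoothed volume.
#' @keywords internal
gaussian_smooth <- function(vol, sigma_mm) {
  a <- vol$data
  for (axis in 1:3) {
    sv <- sigma_mm / vol$spacing[axis]
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    k <- k / sum(k)
    a <- .conv_axis(a, k, axis)
  }
  as_volume(a, vol$spacing)
}

# Central finite difference along an axis (replicate boundary), mm units.
.diff_axis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  lo <- pmax(seq_len(n) - 1L, 1L)
  hi <- pmin(seq_len(n) + 1L, n)
  ix <- function(idx) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    do.call(`[`, c(list(a), args, drop = FALSE))
  }
  (ix(hi) - ix(lo)) / (2 * h)
}

# Eigenvalues of a field of symmetric 3x3 matrices (vectorized closed form),
# returned sorted by increasing absolute value.
.sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-30
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detb / 2, -1), 1)) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2 <- 3 * q[nz] - l1 - l3
    e1[nz] <- l1; e2[nz] <- l2; e3[nz] <- l3
  }
  # 3-element sorting network on |eigenvalue|, vectorized
  swap <- function(u, v) {
    s <- abs(u) > abs(v)
    t <- u[s]; u[s] <- v[s]; v[s] <- t
    list(u, v)
  }
  p1 <- swap(e1, e2); e1 <- p1[[1]]; e2 <- p1[[2]]
  p2 <- swap(e2, e3); e2 <- p2[[1]]; e3 <- p2[[2]]
  p3 <- swap(e1, e2); e1 <- p3[[1]]; e2 <- p3[[2]]
  cbind(e1, e2, e3)
}

#' Multiscale Hessian vesselness probability map
#'
#' Frangi-type tubularity response for bright tubular structures (veins are
#' bright on QSM): per scale, the scale-normalized Hessian's eigenvalues
#' (|l1| <= |l2| <= |l3|) feed the plate/blob/structure terms with
#' alpha = beta = 0.5 and c at half the maximum Frobenius norm; responses are
#' combined across scales by the maximum and min-max rescaled to \[0, 1\].
#' The pipeline also accepts an externally supplied probability map in place
#' of this filter.
#'
#' @param vol susceptibility volume.
#' @param scales_mm one or more filter scales in mm.
#' @return A probability-map volume in \[0, 1\]; all zeros (with a warning)
#'   for a constant input.
#' @export
vesselness_probability <- function(vol, scales_mm = c(0.5, 1.0)) {
  stopifnot(is_volume(vol), length(scales_mm) >= 1)
  if (any(!is.finite(vol$data))) stop("vesselness input must be finite")
  rng <- range(vol$data)
  if (diff(rng) == 0) {
    warning("constant input volume: returning an all-zero vesselness map")
    return(as_volume(array(0, dim(vol$data)), vol$spacing))
  }
  s <- vol$spacing
  best <- array(0, dim(vol$data))
  for (sig in scales_mm) {
    sm <- gaussian_smooth(vol, sig)$data
    gx <- .diff_axis(sm, 1, s[1]); gy <- .diff_axis(sm, 2, s[2])
    gz <- .diff_axis(sm, 3, s[3])
    h11 <- .diff_axis(gx, 1, s[1]); h22 <- .diff_axis(gy, 2, s[2])
    h33 <- .diff_axis(gz, 3, s[3])
    h12 <- .diff_axis(gx, 2, s[2]); h13 <- .diff_axis(gx, 3, s[3])
    h23 <- .diff_axis(gy, 3, s[3])
    k <- sig^2   # gamma = 2 scale normalization
    ev <- .sym3_eigenvalues(k * c(h11), k * c(h22), k * c(h33),
                            k * c(h12), k * c(h13), k * c(h23))
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    S2 <- l1^2 + l2^2 + l3^2
    c2 <- (0.5 * sqrt(max(S2)))^2
    Ra2 <- l2^2 / pmax(l3^2, 1e-30)
    Rb2 <- l1^2 / pmax(abs(l2 * l3), 1e-30)
    v <- (1 - exp(-Ra2 / 0.5)) * exp(-Rb2 / 0.5) * (1 - exp(-S2 / (2 * c2)))
    v[l2 > 0 | l3 > 0] <- 0      # bright tubes: two large negative eigenvalues
    best <- pmax(best, array(v, dim(vol$data)))
  }
  rb <- range(best)
  if (diff(rb) > 0) best <- (best - rb[1]) / diff(rb)
  as_volume(best, vol$spacing)
}

#' 3-class Otsu thresholds
#'
#' Exhaustive search over all histogram bin-boundary pairs for the (lower,
#' upper) thresholds maximizing the between-class variance
#' `sigma_B^2 = sum_k omega_k (mu_k - mu_T)^2` of the three classes. Ties are
#' broken toward the smallest lower, then smallest upper threshold. The
#' histogram spans the observed range; callers should restrict `values` to a
#' brain/ribbon mask, since near-zero background otherwise dominates the
#' class weights.
#'
#' @param values numeric sample (probabilities or intensities).
#' @param n_bins histogram bins (>= 8).
#' @return List of class `"threshold_pair"`: `lower`, `upper`, and the class
#'   statistics (`omega`, `mu`, `sigma_b2`) at the optimum.
#' @export
otsu_thresholds_3class <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3L)
    stop("need at least 3 distinct values to form 3 classes")
  if (n_bins < 8L) stop("n_bins must be >= 8")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  muT <- cm[n_bins]

  best <- list(s = -Inf, t1 = NA_integer_, t2 = NA_integer_)
  for (t1 in 1:(n_bins - 2L)) {
    w1 <- cw[t1]; m1 <- cm[t1]
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- cw[t2] - w1; m2 <- cm[t2] - m1
    w3 <- 1 - cw[t2]; m3 <- muT - cm[t2]
    # sigma_B^2 = sum w_k mu_k^2 - mu_T^2, with empty classes excluded
    sb <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0) - muT^2
    j <- which.max(sb)
    if (sb[j] > best$s) best <- list(s = sb[j], t1 = t1, t2 = t2[j])
  }
  t1 <- best$t1; t2 <- best$t2
  w1 <- cw[t1]; w2 <- cw[t2] - cw[t1]; w3 <- 1 - cw[t2]
  m1 <- if (w1 > 0) cm[t1] / w1 else NA
  m2 <- if (w2 > 0) (cm[t2] - cm[t1]) / w2 else NA
  m3 <- if (w3 > 0) (muT - cm[t2]) / w3 else NA
  structure(list(lower = breaks[t1 + 1L], upper = breaks[t2 + 1L],
                 omega = c(w1, w2, w3), mu = c(m1, m2, m3),
                 sigma_b2 = best$s, n_bins = n_bins, breaks = breaks),
            class = "threshold_pair")
}

# 26-neighbour binary dilation via index shifting.
.dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xi <- seq_len(d[1]) - dx; yi <- seq_len(d[2]) - dy; zi <- seq_len(d[3]) - dz
    ok1 <- xi >= 1 & xi <= d[1]; ok2 <- yi >= 1 & yi <= d[2]
    ok3 <- zi >= 1 & zi <= d[3]
    out[ok1, ok2, ok3] <- out[ok1, ok2, ok3] |
      mask[xi[ok1], yi[ok2], zi[ok3]]
  }
  out
}

#' Hysteresis binarization of a probability map
#'
#' Voxels above the upper threshold are vessels; voxels at or below the lower
#' threshold are background; mid-band voxels are vessels only if connected
#' (26-neighbour, through voxels above the lower threshold) to a voxel above
#' the upper threshold.
#'
#' @param prob probability-map volume.
#' @param thresholds a `"threshold_pair"` (or list with `lower`, `upper`).
#' @return Binary mask volume; empty masks are allowed (with a warning).
#' @export
hysteresis_binarize <- function(prob, thresholds) {
  stopifnot(is_volume(prob))
  lo <- thresholds$lower; hi <- thresholds$upper
  if (!(lo < hi)) stop("need lower < upper threshold")
  strong <- prob$data > hi
  weak <- prob$data > lo
  if (!any(strong)) {
    warning("no voxels above the upper threshold: empty vein mask")
    return(as_volume(array(FALSE, dim(prob$data)), prob$spacing))
  }
  mask <- strong
  repeat {
    grown <- .dilate26(mask) & weak
    if (!any(grown & !mask)) break
    mask <- grown
  }
  as_volume(mask, prob$spacing)
}

#' Segment veins from a susceptibility volume
#'
#' The composed operation: vesselness probability map (unless one is
#' supplied), 3-class Otsu thresholds on the in-mask probability sample,
#' hysteresis binarization on the full map.
#'
#' @param qsm susceptibility volume (ignored if `prob` is given).
#' @param prob optional externally computed probability map.
#' @param mask optional ribbon/brain mask volume restricting the Otsu sample.
#' @param scales_mm vesselness scales in mm.
#' @param n_bins Otsu histogram bins.
#' @return List: `mask` (binary volume), `prob`, `thresholds`.
#' @export
segment_veins <- function(qsm, prob = NULL, mask = NULL,
                          scales_mm = c(0.5, 1.0), n_bins = 256L) {
  if (is.null(prob)) prob <- vesselness_probability(qsm, scales_mm)
  vals <- if (is.null(mask)) c(prob$data) else prob$data[mask$data > 0]
  thr <- otsu_thresholds_3class(vals, n_bins)
  list(mask = hysteresis_binarize(prob, thr), prob = prob, thresholds = thr)
}
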