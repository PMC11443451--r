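# Mixed-design repeated-measures ANOVA, from first principles.
#
# One between-subjects factor (age group) and any number of crossed
# within-subjects factors. Each within-subject effect is tested on
# orthonormal contrast scores Z = Y C (C a Kronecker product of per-factor
# orthonormal contrasts and normalized unit vectors), through two routes:
#   univariate: classical split-plot sums of squares (trace of the hypothesis
#     and residual SSCP matrices), with the Greenhouse-Geisser epsilon from
#     the pooled residual covariance of the scores;
#   multivariate: Hotelling-type exact F on the same scores,
#     DFd = N - g - p + 1, which reproduces the integer denominator df
#     pattern (4,30), (3,31), (1,33) at N = 35, g = 2.
# The weighted (sample-size) grand-mean contrast is used for within-effect
# main tests, which makes the sums-of-squares ledger exactly orthogonal: the
# corrected total SS equals the sum of every effect and error SS even with
# unequal group sizes.

#' Subjects x conditions cell-means matrix
#'
#' Pivots a long condition table (one metric) into the balanced matrix the
#' ANOVA consumes: rows are participants, columns are the
#' (area, compartment, distance bin) cross in a fixed order (bin fastest).
#'
#' @param tab condition table.
#' @param metric one of `"qT1"`, `"pQSM"`, `"nQSM"`.
#' @param bins distance-bin labels to keep (e.g. drop `"0-2"`).
#' @param areas,compartments optional level subsets.
#' @return List: `Y` (matrix, possibly with NAs), `group` (factor),
#'   `risk` (integer), `conditions` (data.frame of the column factors),
#'   `participants` (ids).
#' @export
cell_means_matrix <- function(tab, metric,
                              bins = NULL, areas = NULL,
                              compartments = .compartment_levels) {
  tab <- tab[tab$metric == metric, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for metric ", metric)
  if (is.null(areas)) areas <- sort(unique(tab$area))
  if (is.null(bins)) bins <- sort(unique(tab$distance_bin))
  tab <- tab[tab$area %in% areas & tab$compartment %in% compartments &
               tab$distance_bin %in% bins, , drop = FALSE]
  ids <- unique(tab$participant_id)
  cond <- expand.grid(distance_bin = bins, compartment = compartments,
                      area = areas, stringsAsFactors = FALSE)
  cond <- cond[, c("area", "compartment", "distance_bin")]
  key <- function(a, cp, b) paste(a, cp, b, sep = "|")
  ck <- key(cond$area, cond$compartment, cond$distance_bin)
  Y <- matrix(NA_real_, length(ids), nrow(cond),
              dimnames = list(ids, ck))
  idx <- cbind(match(tab$participant_id, ids),
               match(key(tab$area, tab$compartment, tab$distance_bin), ck))
  ok <- !is.na(idx[, 2])
  Y[idx[ok, , drop = FALSE]] <- tab$value[ok]
  first <- tab[!duplicated(tab$participant_id), ]
  group <- factor(first$group[match(ids, first$participant_id)],
                  levels = intersect(c("young", "old"),
                                     unique(first$group)))
  risk <- first$risk[match(ids, first$participant_id)]
  list(Y = Y, group = group, risk = as.integer(risk), conditions = cond,
       participants = ids)
}

# Column-orthonormal contrast matrix for a factor with L levels.
.orthonormal_contrasts <- function(L) {
  m <- stats::contr.helmert(L)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Kronecker contrast matrix for a within-effect subset, matching a condition
# ordering where the LAST factor in `levels` varies fastest.
.effect_contrast <- function(levels, in_effect) {
  mats <- mapply(function(L, on) {
    if (on) .orthonormal_contrasts(L) else matrix(1 / sqrt(L), L, 1)
  }, levels, in_effect, SIMPLIFY = FALSE)
  Reduce(kronecker, mats)
}

#' Greenhouse-Geisser epsilon
#'
#' `eps = tr(S)^2 / ((k - 1) tr(S^2))` for the covariance `S` of the
#' orthonormalized contrast scores of an effect with `k` levels, clipped to
#' `[1/(k - 1), 1]`. The corrected test uses `F` with
#' `(eps DFn, eps DFd)`.
#'
#' @param S symmetric positive semi-definite covariance of contrast scores.
#' @param k number of effect levels (`k - 1 = nrow(S)` for a main effect).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(S, k) {
  S <- as.matrix(S)
  tr <- sum(diag(S))
  if (tr <= 0) stop("zero-trace contrast covariance")
  e <- tr^2 / ((k - 1) * sum(S * S))
  min(max(e, 1 / (k - 1)), 1)
}

#' Generalized eta-squared
#'
#' `SS_effect / (SS_effect + SS_subjects_within_groups + sum(within error
#' SS))` — the variance-accounted measure comparable across designs, for
#' designs where all factors are manipulated and subjects are the only
#' measured unit.
#'
#' @param ss_effect effect sum of squares.
#' @param ss_subjects subjects-within-groups (between error) SS.
#' @param ss_within_error vector of all within-effect error SS.
#' @return Eta-squared in \[0, 1\].
#' @export
generalized_eta_squared <- function(ss_effect, ss_subjects, ss_within_error) {
  if (any(c(ss_effect, ss_subjects, ss_within_error) < -1e-8))
    stop("negative sum of squares")
  ss_effect / (ss_effect + ss_subjects + sum(ss_within_error))
}

#' Mixed-design repeated-measures ANOVA
#'
#' @param Y subjects x conditions matrix of cell means (no missing values;
#'   impute or drop first).
#' @param group between-subjects factor (one level set, e.g. young/old).
#' @param within data.frame describing the condition columns, one column per
#'   within factor, ordered so the last factor varies fastest (as produced by
#'   [cell_means_matrix()]).
#' @return An `anova_table` data.frame with one row per effect: multivariate
#'   `DFn/DFd/F/p`, univariate `F/df/p`, Greenhouse-Geisser `epsilon` and
#'   corrected p, the SS ledger entries, and generalized eta-squared. The
#'   subjects-within-groups SS and the corrected total SS are attached as
#'   attributes (the ledger conservation check).
#' @export
mixed_anova <- function(Y, group, within) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) {
    bad <- rownames(Y)[apply(is.na(Y), 1, any)]
    stop("missing cells for subjects: ", paste(bad, collapse = ", "),
         " (impute or drop before the ANOVA)")
  }
  group <- droplevels(factor(group))
  g <- nlevels(group)
  N <- nrow(Y)
  if (g < 1L || any(table(group) < 2L)) stop("need >= 2 subjects per group")
  wnames <- names(within)
  levels_per <- vapply(within, function(f) length(unique(f)), 1L)
  k_total <- prod(levels_per)
  if (ncol(Y) != k_total) stop("condition columns do not match the design")

  n_g <- as.vector(table(group))
  Gi <- split(seq_len(N), group)

  # between part: unit-contrast scores
  u <- matrix(1 / sqrt(k_total), k_total, 1)
  z0 <- as.vector(Y %*% u)
  gm <- vapply(Gi, function(i) mean(z0[i]), 0)
  grand <- mean(z0)
  ss_between <- sum(n_g * (gm - grand)^2)
  ss_subjects <- sum((z0 - gm[as.integer(group)])^2)
  df_between <- g - 1L
  df_subjects <- N - g

  subsets <- unlist(lapply(seq_along(wnames), function(m)
    utils::combn(wnames, m, simplify = FALSE)), recursive = FALSE)

  rows <- list()

  add_row <- function(name, DFn_mv, DFd_mv, F_mv, p_mv, DFn_u, DFd_u, F_u,
                      p_u, eps, p_gg, SS, SS_err) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = name, DFn_mv = DFn_mv, DFd_mv = DFd_mv, F_mv = F_mv,
      p_mv = p_mv, DFn_uni = DFn_u, DFd_uni = DFd_u, F_uni = F_u,
      p_uni = p_u, gg_epsilon = eps, p_gg = p_gg, SS = SS, SS_error = SS_err,
      eta2_G = NA_real_, stringsAsFactors = FALSE)
  }

  # between-subjects effect, tested univariately on subject means
  F_b <- if (ss_subjects <= 0) stop("zero error SS: degenerate data") else
    (ss_between / df_between) / (ss_subjects / df_subjects)
  add_row(levels_name <- "group", df_between, df_subjects, F_b,
          stats::pf(F_b, df_between, df_subjects, lower.tail = FALSE),
          df_between, df_subjects, F_b,
          stats::pf(F_b, df_between, df_subjects, lower.tail = FALSE),
          NA_real_, NA_real_, ss_between, ss_subjects)

  for (S in subsets) {
    C <- .effect_contrast(levels_per, wnames %in% S)
    p <- ncol(C)
    Z <- Y %*% C
    B <- do.call(rbind, lapply(Gi, function(i)
      colMeans(Z[i, , drop = FALSE])))
    R <- Z - B[as.integer(group), , drop = FALSE]
    E <- crossprod(R)
    dfe <- N - g
    trE <- sum(diag(E))
    scale_ref <- sum(Y^2) + 1e-300

    m <- colMeans(Z)                      # weighted grand mean
    H_main <- N * tcrossprod(m)
    ss_main <- sum(diag(H_main))

    # effect x group (Helmert contrasts between group means, weighted)
    if (g > 1L) {
      Lg <- .orthonormal_contrasts(g)      # g x (g-1)
      W <- diag(n_g, nrow = g)
      # hypothesis SSCP for L B = 0 with cell-means coding: (X'X)^-1 = W^-1
      LB <- t(Lg) %*% B
      Minv <- solve(t(Lg) %*% solve(W) %*% Lg)
      H_int <- t(LB) %*% Minv %*% LB
      ss_int <- sum(diag(H_int))
      df_int <- p * (g - 1L)
    }

    test_effect <- function(name, H, q) {
      ssh <- sum(diag(H))
      DFn_u <- p * q
      DFd_u <- p * dfe
      if (ssh / scale_ref < 1e-24 && trE / scale_ref < 1e-24) {
        # contrast scores are identically zero: null-effect degenerate
        add_row(name, p * q, dfe - p + 1, 0, 1, DFn_u, DFd_u, 0, 1,
                NA_real_, 1, 0, 0)
        return(invisible())
      }
      if (trE <= 0) stop("zero error SS for effect ", name,
                         ": degenerate data")
      F_u <- (ssh / DFn_u) / (trE / DFd_u)
      p_u <- stats::pf(F_u, DFn_u, DFd_u, lower.tail = FALSE)
      Sm <- E / dfe
      eps <- gg_epsilon(Sm, k = p + 1L)
      p_gg <- stats::pf(F_u, eps * DFn_u, eps * DFd_u, lower.tail = FALSE)
      # multivariate exact F (hypothesis rank q = 1 for the designs here)
      DFd_mv <- dfe - p + 1L
      F_mv <- p_mv <- NA_real_
      if (DFd_mv >= 1) {
        U <- tryCatch(sum(diag(H %*% solve(E))), error = function(e) NA_real_)
        if (is.finite(U) && q == 1L) {
          F_mv <- U * DFd_mv / p
          p_mv <- stats::pf(F_mv, p, DFd_mv, lower.tail = FALSE)
        } else if (is.finite(U)) {
          # Hotelling-Lawley approximation for q > 1
          s <- min(p, q)
          df1 <- p * q
          df2 <- s * (dfe - p - 1) + 2
          F_mv <- U * df2 / (s * df1)
          p_mv <- stats::pf(F_mv, df1, df2, lower.tail = FALSE)
          DFd_mv <- df2
        }
      }
      add_row(name, p * q, DFd_mv, F_mv, p_mv, DFn_u, DFd_u, F_u, p_u,
              eps, p_gg, ssh, trE)
    }

    nm <- paste(S, collapse = ":")
    test_effect(nm, H_main, 1L)
    if (g > 1L) test_effect(paste0("group:", nm), H_int, g - 1L)
  }

  tab <- do.call(rbind, rows)
  # within-error SS: one per contrast set (the two effects of a set share E)
  within_err <- tab$SS_error[!grepl("^group:", tab$effect) &
                               tab$effect != "group"]
  tab$eta2_G <- vapply(seq_len(nrow(tab)), function(i)
    generalized_eta_squared(tab$SS[i], ss_subjects, within_err), 0)
  attr(tab, "ss_subjects") <- ss_subjects
  attr(tab, "ss_total") <- sum(Y^2) - N * k_total * mean(Y)^2
  attr(tab, "n") <- N
  attr(tab, "group_sizes") <- n_g
  class(tab) <- c("anova_table", "data.frame")
  tab
}
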