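# Monotone multiple imputation by regression with parameter draws, and the
# D2 rule for pooling F statistics across completed datasets.

#' Monotone multiple imputation of cell-means columns
#'
#' For each incomplete column, in monotone order (fewest missing first), a
#' linear regression on the complete predictor columns of the same
#' (area, compartment) stratum plus the group indicator is fitted on the
#' observed rows; for every completed dataset, the residual variance is drawn
#' from its scaled inverse chi-square distribution, the coefficients from
#' their sampling distribution, and the missing entries are filled with the
#' drawn regression prediction plus residual noise. With fewer complete
#' cases than predictors + 2 the model falls back to intercept + group with a
#' warning.
#'
#' @param cells output of [cell_means_matrix()] (`Y`, `group`, `conditions`).
#' @param m number of completed datasets.
#' @param seed RNG seed.
#' @return List of `m` completed matrices; identical copies when nothing is
#'   missing.
#' @export
monotone_impute <- function(cells, m = 5L, seed = 1L) {
  Y <- cells$Y
  group <- cells$group
  cond <- cells$conditions
  miss_per_col <- colSums(is.na(Y))
  target <- which(miss_per_col > 0)
  if (!length(target)) return(replicate(m, Y, simplify = FALSE))
  target <- target[order(miss_per_col[target])]
  gnum <- as.numeric(group == levels(group)[1])

  set.seed(seed)
  out <- vector("list", m)
  for (l in seq_len(m)) {
    Yl <- Y
    for (j in target) {
      same <- which(cond$area == cond$area[j] &
                      cond$compartment == cond$compartment[j])
      preds <- setdiff(same[colSums(is.na(Yl[, same, drop = FALSE])) == 0], j)
      obs <- which(!is.na(Yl[, j]))
      misr <- which(is.na(Yl[, j]))
      X <- cbind(1, gnum, Yl[, preds, drop = FALSE])
      if (length(obs) < ncol(X) + 2L) {
        warning("too few complete cases for column ", colnames(Y)[j],
                ": falling back to intercept + group")
        X <- cbind(1, gnum)
      }
      # drop collinear columns defensively
      qrX <- qr(X[obs, , drop = FALSE])
      keep <- qrX$pivot[seq_len(qrX$rank)]
      Xo <- X[obs, keep, drop = FALSE]
      Xm <- X[misr, keep, drop = FALSE]
      fit <- stats::lm.fit(Xo, Yl[obs, j])
      q <- ncol(Xo)
      dfres <- length(obs) - q
      if (dfres < 1L) stop("no residual degrees of freedom for imputation")
      rss <- sum(fit$residuals^2)
      sig2 <- rss / stats::rchisq(1, dfres)
      XtXinv <- chol2inv(chol(crossprod(Xo)))
      beta <- fit$coefficients +
        drop(chol(sig2 * XtXinv) %*% stats::rnorm(q))
      Yl[misr, j] <- drop(Xm %*% beta) +
        stats::rnorm(length(misr), 0, sqrt(sig2))
    }
    out[[l]] <- Yl
  }
  out
}

#' Pool ANOVA tables across imputations (D2 combination)
#'
#' Per effect, the F statistics of the `m` completed-data ANOVAs are combined
#' through the D2 rule for chi-square statistics (`d_l = DFn * F_l`): with
#' `dbar` their mean and `r = (1 + 1/m) var(sqrt(d))`,
#' `D2 = (dbar/k - (m+1)/(m-1) r) / (1 + r)` referred to
#' `F(k, k^(-3/m) (m-1) (1 + 1/r)^2)`. Identical tables pool to their common
#' F. Both the univariate and multivariate paths are pooled; per-imputation
#' ranges are retained.
#'
#' @param tables list of `anova_table`s with identical effect lists.
#' @return Data.frame with pooled `F` and `p` per effect and path, plus the
#'   per-imputation F range.
#' @export
pool_imputed_anova <- function(tables) {
  if (length(tables) < 2L) stop("need m >= 2 tables to pool")
  eff <- tables[[1]]$effect
  for (t in tables[-1])
    if (!identical(t$effect, eff)) stop("mismatched effect lists")
  m <- length(tables)

  d2 <- function(Fs, k) {
    d <- k * Fs
    dbar <- mean(d)
    r <- (1 + 1 / m) * stats::var(sqrt(d))
    if (!is.finite(r) || r < 1e-12) {
      D2 <- dbar / k
      nu <- Inf
    } else {
      D2 <- max((dbar / k - (m + 1) / (m - 1) * r) / (1 + r), 0)
      nu <- k^(-3 / m) * (m - 1) * (1 + 1 / r)^2
    }
    c(F = D2, df2 = nu, p = stats::pf(D2, k, nu, lower.tail = FALSE))
  }

  res <- lapply(seq_along(eff), function(i) {
    Fu <- vapply(tables, function(t) t$F_uni[i], 0)
    Fm <- vapply(tables, function(t) t$F_mv[i], 0)
    k_u <- tables[[1]]$DFn_uni[i]
    k_m <- tables[[1]]$DFn_mv[i]
    pu <- d2(Fu, k_u)
    pm <- if (all(is.finite(Fm))) d2(Fm, k_m) else c(F = NA, df2 = NA, p = NA)
    data.frame(effect = eff[i],
               F_uni = pu["F"], df1_uni = k_u, df2_uni = pu["df2"],
               p_uni = pu["p"],
               F_mv = pm["F"], df1_mv = k_m, df2_mv = pm["df2"],
               p_mv = pm["p"],
               F_uni_min = min(Fu), F_uni_max = max(Fu),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
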