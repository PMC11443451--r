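# Random-intercept linear mixed models by profiled maximum likelihood, and
# likelihood-ratio comparisons of nested fixed-effect designs.

#' Fit a random-intercept model by profiled ML
#'
#' `y = X beta + b_participant + e`, `b ~ N(0, sigma_b^2)`,
#' `e ~ N(0, sigma^2)`. For fixed variance ratio
#' `lambda = sigma_b^2 / sigma^2` the GLS estimates and the profiled ML
#' log-likelihood have closed forms under the compound-symmetry covariance;
#' `lambda` is maximized by a 1-D search on the log scale (with the boundary
#' `lambda = 0`, i.e. ordinary least squares, always evaluated).
#'
#' @param formula fixed-effects formula (response on the left).
#' @param data data.frame.
#' @param id participant identifier column name.
#' @return List of class `"lmm_fit"`: `beta`, `sigma2`, `sigma_b2`, `lambda`,
#'   `loglik` (ML), `n_fixed`, `n_obs`, `formula`.
#' @export
fit_random_intercept <- function(formula, data, id = "participant_id") {
  vars <- unique(c(all.vars(formula), id))
  use <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[use, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  pid <- factor(d[[id]])
  blocks <- split(seq_along(y), pid)
  if (any(lengths(blocks) < 2L))
    stop("need >= 2 observations per participant")
  N <- length(y)

  prof <- function(lambda) {
    A <- matrix(0, ncol(X), ncol(X))
    b <- numeric(ncol(X))
    yy <- 0
    logdet <- 0
    for (ix in blocks) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      w <- lambda / (1 + lambda * ni)
      sx <- colSums(Xi)
      sy <- sum(yi)
      A <- A + crossprod(Xi) - w * tcrossprod(sx)
      b <- b + crossprod(Xi, yi) - w * sx * sy
      yy <- yy + sum(yi^2) - w * sy^2
      logdet <- logdet + log(1 + lambda * ni)
    }
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    rss <- max(yy - 2 * sum(beta * b) + drop(t(beta) %*% A %*% beta), 1e-12)
    sigma2 <- rss / N
    ll <- -0.5 * (N * log(2 * pi * sigma2) + logdet + N)
    list(ll = ll, beta = drop(beta), sigma2 = sigma2)
  }

  f <- function(loglam) prof(exp(loglam))$ll
  opt <- stats::optimize(f, c(-12, 12), maximum = TRUE, tol = 1e-8)
  cand <- list(c(lambda = 0, ll = prof(0)$ll),
               c(lambda = exp(opt$maximum), ll = opt$objective))
  best <- cand[[which.max(vapply(cand, function(z) z["ll"], 0))]]
  lambda <- unname(best["lambda"])
  if (lambda > exp(11.5))
    warning("variance ratio at the search boundary")
  fit <- prof(lambda)
  if (!is.finite(fit$ll))
    stop("singular fixed-effect design: cannot fit the random-intercept model")
  structure(list(beta = fit$beta, sigma2 = fit$sigma2,
                 sigma_b2 = lambda * fit$sigma2, lambda = lambda,
                 loglik = fit$ll, n_fixed = ncol(X), n_obs = N,
                 formula = formula), class = "lmm_fit")
}

#' Likelihood-ratio comparison of nested random-intercept models
#'
#' `chi^2 = 2 (l_big - l_small)` on the difference in fixed-effect parameter
#' count. Both fits must come from the same rows.
#'
#' @param fit_big,fit_small `"lmm_fit"` objects, big nesting small.
#' @return List: `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(fit_big, fit_small) {
  if (fit_big$n_obs != fit_small$n_obs)
    stop("models were fitted on different rows")
  df <- fit_big$n_fixed - fit_small$n_fixed
  if (df <= 0) stop("models are not nested (big must add fixed parameters)")
  chisq <- max(2 * (fit_big$loglik - fit_small$loglik), 0)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
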