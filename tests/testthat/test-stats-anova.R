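# Mixed-design ANOVA: df structure, oracles, GG epsilon, eta squared.

full_within <- function() {
  w <- expand.grid(distance = paste0("b", 1:5),
                   depth = c("SF", "OM", "IM", "DP"),
                   area = c("A1", "A2"), stringsAsFactors = FALSE)
  w[, c("area", "depth", "distance")]
}

test_that("multivariate df reproduce the (4,30)/(3,31)/(1,33) pattern", {
  set.seed(SUITE_SEED)
  Y <- matrix(rnorm(35 * 40), 35, 40)
  grp <- factor(rep(c("young", "old"), c(18, 17)), levels = c("young", "old"))
  a <- mixed_anova(Y, grp, full_within())
  df <- function(e) unlist(a[a$effect == e, c("DFn_mv", "DFd_mv")],
                           use.names = FALSE)
  expect_equal(df("group"), c(1, 33))
  expect_equal(df("depth"), c(3, 31))
  expect_equal(df("distance"), c(4, 30))
  expect_equal(df("group:distance"), c(4, 30))
  expect_equal(df("group:area:distance"), c(4, 30))
  expect_equal(df("area"), c(1, 33))
})

test_that("toy 2x2 design matches the hand-computed decomposition", {
  # groups a: subjects (1,2), (3,5); b: (2,2), (4,7)
  Y <- matrix(c(1, 2, 3, 5, 2, 2, 4, 7), 4, 2, byrow = TRUE)
  g <- factor(c("a", "a", "b", "b"))
  a <- mixed_anova(Y, g, data.frame(w = c("w1", "w2")))
  # frozen hand computation (contrast scores z = (y2 - y1)/sqrt(2)):
  # SS_w = 4 * 1.125 = 4.5; SS_wg = 0; E = 2.5; F_w = 3.6
  # u-scores: SS_g = 2, SS_subj = 18.5, F_g = 0.216216...
  expect_equal(a$SS[a$effect == "w"], 4.5, tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "group:w"], 0, tolerance = 1e-10)
  expect_equal(a$SS_error[a$effect == "w"], 2.5, tolerance = 1e-10)
  expect_equal(a$F_uni[a$effect == "w"], 3.6, tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "group"], 2, tolerance = 1e-10)
  expect_equal(a$SS_error[a$effect == "group"], 18.5, tolerance = 1e-10)
  expect_equal(a$F_uni[a$effect == "group"], 2 / (18.5 / 2),
               tolerance = 1e-10)
  # eta2_G against the ledger definition
  expect_equal(a$eta2_G[a$effect == "w"], 4.5 / (4.5 + 18.5 + 2.5),
               tolerance = 1e-10)
})

test_that("univariate path agrees with the base-R split-plot aov oracle", {
  set.seed(SUITE_SEED + 1)
  n_per <- 4
  w <- expand.grid(f1 = c("l1", "l2"), f2 = c("m1", "m2", "m3"),
                   stringsAsFactors = FALSE)[, c("f1", "f2")]
  w <- w[order(w$f1, w$f2), ]
  Y <- matrix(rnorm(2 * n_per * 6), 2 * n_per, 6)
  g <- factor(rep(c("a", "b"), each = n_per))
  mine <- mixed_anova(Y, g, w)
  long <- data.frame(y = as.vector(t(Y)),
                     subj = factor(rep(seq_len(2 * n_per), each = 6)),
                     grp = rep(g, each = 6),
                     f1 = factor(rep(w$f1, 2 * n_per)),
                     f2 = factor(rep(w$f2, 2 * n_per)))
  oracle <- summary(stats::aov(y ~ grp * f1 * f2 +
                                 Error(subj / (f1 * f2)), data = long))
  get_f <- function(stratum, term) {
    tb <- oracle[[stratum]][[1]]
    tb[trimws(rownames(tb)) == term, "F value"]
  }
  expect_equal(mine$F_uni[mine$effect == "group"], get_f("Error: subj", "grp"),
               tolerance = 1e-8)
  expect_equal(mine$F_uni[mine$effect == "f1"], get_f("Error: subj:f1", "f1"),
               tolerance = 1e-8)
  expect_equal(mine$F_uni[mine$effect == "group:f1"],
               get_f("Error: subj:f1", "grp:f1"), tolerance = 1e-8)
  expect_equal(mine$F_uni[mine$effect == "f2"], get_f("Error: subj:f2", "f2"),
               tolerance = 1e-8)
  expect_equal(mine$F_uni[mine$effect == "f1:f2"],
               get_f("Error: subj:f1:f2", "f1:f2"), tolerance = 1e-8)
  expect_equal(mine$F_uni[mine$effect == "group:f1:f2"],
               get_f("Error: subj:f1:f2", "grp:f1:f2"), tolerance = 1e-8)
})

test_that("SS ledger conserves total variance (unequal groups)", {
  set.seed(SUITE_SEED + 2)
  Y <- matrix(rnorm(35 * 40, sd = 3), 35, 40)
  grp <- factor(rep(c("young", "old"), c(18, 17)))
  a <- mixed_anova(Y, grp, full_within())
  within_err <- a$SS_error[!grepl("^group", a$effect)]
  ledger <- sum(a$SS) + attr(a, "ss_subjects") + sum(within_err)
  expect_lt(abs(ledger - attr(a, "ss_total")) / attr(a, "ss_total"), 1e-8)
})

test_that("identical values across distance bins give F = 0, p = 1", {
  set.seed(SUITE_SEED + 3)
  base <- matrix(rnorm(10 * 2), 10, 2)
  Y <- base[, rep(1:2, each = 5)]           # area differs, bins identical
  w <- expand.grid(distance = paste0("b", 1:5), area = c("A1", "A2"),
                   stringsAsFactors = FALSE)[, c("area", "distance")]
  g <- factor(rep(c("a", "b"), each = 5))
  a <- mixed_anova(Y, g, w)
  expect_equal(a$F_uni[a$effect == "distance"], 0)
  expect_equal(a$p_uni[a$effect == "distance"], 1)
  expect_equal(a$F_mv[a$effect == "distance"], 0)
})

test_that("missing cells and degenerate groups are fatal", {
  Y <- matrix(rnorm(8), 4, 2)
  Y[2, 1] <- NA
  g <- factor(c("a", "a", "b", "b"))
  expect_error(mixed_anova(Y, g, data.frame(w = c("w1", "w2"))),
               "missing cells")
  expect_error(mixed_anova(matrix(rnorm(6), 3, 2), factor(c("a", "a", "b")),
                           data.frame(w = c("w1", "w2"))), ">= 2 subjects")
})

test_that("gg_epsilon formula, bounds, and corrected p", {
  expect_equal(gg_epsilon(diag(4), k = 5), 1)
  expect_equal(gg_epsilon(diag(c(1, 0, 0, 0)), k = 5), 0.25)
  expect_error(gg_epsilon(matrix(0, 2, 2), k = 3), "zero-trace")
  set.seed(SUITE_SEED)
  for (r in 1:20) {
    A <- matrix(rnorm(16), 4, 4)
    S <- crossprod(A)
    e <- gg_epsilon(S, k = 5)
    direct <- sum(diag(S))^2 / (4 * sum(S * S))
    expect_equal(e, min(max(direct, 0.25), 1))
    expect_gte(e, 0.25); expect_lte(e, 1)
  }
  # sphericity violation shrinks the corrected p toward conservatism
  set.seed(SUITE_SEED + 4)
  Y <- matrix(rnorm(12 * 5), 12, 5)
  Y[, 1] <- Y[, 1] * 4                      # break sphericity
  g <- factor(rep(c("a", "b"), each = 6))
  a <- mixed_anova(Y, g, data.frame(distance = paste0("b", 1:5)))
  expect_lt(a$gg_epsilon[a$effect == "distance"], 1)
  expect_gte(a$p_gg[a$effect == "distance"],
             a$p_uni[a$effect == "distance"])
})

test_that("generalized_eta_squared formula and boundaries", {
  expect_equal(generalized_eta_squared(10, 0, 0), 1)
  expect_equal(generalized_eta_squared(5, 10, c(2, 3)), 0.25)
  expect_error(generalized_eta_squared(-1, 1, 1), "negative")
})
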