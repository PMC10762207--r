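test_that("a two-level binomial toy recovers its proportions", {
  toy <- data.frame(depth = factor(c(5, 5, 60, 60)),
                    succ = c(9, 11, 39, 41), trials = rep(50, 4))
  tr <- suppressMessages(
    fit_trend(toy, "succ", trials = "trials",
              family = "binomial-overdispersed", focal = "depth"))
  expect_equal(tr$emmeans$estimate, c(0.2, 0.8), tolerance = 1e-6)
  expect_lt(tr$baseline_contrasts$p.value[1], 0.001)
  expect_true(all(tr$emmeans$lower <= tr$emmeans$estimate &
                    tr$emmeans$estimate <= tr$emmeans$upper))
})

test_that("a constant response yields equal means and p = 1 contrasts", {
  d <- data.frame(depth = factor(rep(c(5, 15, 30), each = 4)),
                  y = rep(0.5, 12))
  tr <- fit_trend(d, "y", family = "gaussian", focal = "depth")
  expect_equal(diff(range(tr$emmeans$estimate)), 0, tolerance = 1e-12)
  expect_equal(tr$contrasts$p.value, rep(1, 3), tolerance = 1e-6)
})

test_that("back-transformed marginal means stay inside (0, 1)", {
  set.seed(14)
  d <- data.frame(depth = factor(rep(c(5, 15, 30, 60), each = 8)),
                  catchment = rep(c("C1", "C2"), 16))
  d$y <- plogis(qlogis(0.2) + 0.4 * as.integer(d$depth) + rnorm(32, 0, 0.3))
  tr <- fit_trend(d, "y", family = "gaussian-logit", focal = "depth")
  expect_true(all(tr$emmeans$estimate > 0 & tr$emmeans$estimate < 1))
  expect_true(all(tr$emmeans$lower > 0 & tr$emmeans$upper < 1))
  # adjusted p never smaller than unadjusted
  raw <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(tr$model, "depth"), method = "pairwise", adjust = "none"))
  expect_true(all(tr$contrasts$p.value >= raw$p.value - 1e-12))
})

test_that("collinearity reduction applies the mean-|r| removal rule", {
  set.seed(3)
  v1 <- rnorm(60)
  env <- data.frame(v1 = v1, v2 = v1 + rnorm(60, 0, 0.01), v3 = rnorm(60))
  kept <- reduce_collinear(env)
  expect_equal(length(kept), 2L)
  expect_true("v3" %in% kept)
  expect_true(any(c("v1", "v2") %in% kept))
  # all below threshold: identity
  set.seed(4)
  ind <- as.data.frame(matrix(rnorm(300), 100))
  expect_equal(reduce_collinear(ind), names(ind))
  # brute-force oracle on a correlated chain
  set.seed(5)
  z <- rnorm(200)
  chain <- data.frame(v1 = z + rnorm(200, 0, 0.3),
                      v2 = z + rnorm(200, 0, 0.3),
                      v3 = z + rnorm(200, 0, 0.3))
  oracle <- function(env, thr = 0.8) {
    keep <- names(env)
    repeat {
      r <- abs(cor(env[, keep, drop = FALSE])); diag(r) <- 0
      if (length(keep) < 2 || max(r) <= thr) break
      inv <- which(apply(r > thr, 1, any))
      mr <- rowMeans(r)[inv]
      keep <- keep[-inv[which.max(mr + seq_along(mr) * 1e-12)]]
    }
    keep
  }
  expect_identical(reduce_collinear(chain), oracle(chain))
  expect_warning(reduce_collinear(data.frame(a = rep(1, 10), b = rnorm(10),
                                             d = rnorm(10))), "constant")
})

test_that("forward selection keeps signal and controls the null", {
  hits <- 0L
  for (s in 1:8) {
    set.seed(s)
    X <- data.frame(X1 = rnorm(50), X2 = rnorm(50))
    Y <- cbind(2 * X$X1 + rnorm(50, 0, 0.5), -X$X1 + rnorm(50, 0, 0.5))
    sel <- forward_select(Y, X, alpha = 0.1, n_perm = 99, seed = s)
    if ("X1" %in% sel) hits <- hits + 1L
  }
  expect_equal(hits, 8L)
  # single strong predictor: trivially selected
  set.seed(9)
  X <- data.frame(X1 = rnorm(40))
  Y <- cbind(X$X1 + rnorm(40, 0, 0.3))
  expect_identical(forward_select(Y, X, n_perm = 99, seed = 1), "X1")
  # determinism
  a <- forward_select(Y, X, n_perm = 99, seed = 5)
  b <- forward_select(Y, X, n_perm = 99, seed = 5)
  expect_identical(a, b)
})

test_that("pcnm reproduces the two-point solution and transect ordering", {
  p2 <- pcnm(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(ncol(p2$vectors), 1L)
  expect_equal(p2$values[1], 0.5, tolerance = 1e-10)
  expect_equal(unname(p2$vectors[, 1]), c(1, -1) / sqrt(2), tolerance = 1e-10)
  # eigenvector count is at most n - 1
  set.seed(15)
  pts <- matrix(runif(20), 10, 2)
  expect_lte(ncol(pcnm(pts)$vectors), 9L)
  # on a transect with truncation spanning it, the leading eigenvector is
  # monotone in space
  tr <- pcnm(cbind(1:20, 0), truncation = 25)
  expect_gte(abs(cor(tr$vectors[, 1], 1:20, method = "spearman")), 0.99)
  expect_error(pcnm(matrix(0, 3, 2)), "identical")
})

test_that("rda adjusted R2 follows the Ezekiel formula and matches vegan", {
  set.seed(16)
  X <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(6), 3, 2)
  expect_equal(rda_adj_r2(X %*% B, X)$adj_r2, 1, tolerance = 1e-10)
  Y <- matrix(rnorm(10 * 2), 10)
  r <- rda_adj_r2(Y, X[, 1:2])
  expect_equal(r$adj_r2, 1 - (1 - r$r2) * 9 / 7, tolerance = 1e-12)
  # independent implementation in vegan agrees
  set.seed(17)
  Y2 <- matrix(rnorm(50 * 4), 50)
  X2 <- matrix(rnorm(50 * 3), 50)
  expect_equal(rda_adj_r2(Y2, X2)$adj_r2,
               vegan::RsquareAdj(vegan::rda(Y2, X2))$adj.r.squared,
               tolerance = 1e-10)
  # orthogonal design: R2 = 0, negative adjustment reported raw
  Yc <- scale(Y, scale = FALSE)
  Xo <- qr.resid(qr(cbind(1, Yc)), matrix(rnorm(10 * 2), 10))
  ro <- rda_adj_r2(Y, Xo)
  expect_equal(ro$r2, 0, tolerance = 1e-10)
  expect_lt(ro$adj_r2, 0)
  expect_error(rda_adj_r2(Y, cbind(X[, 1], X[, 1])), "rank-deficient")
})

test_that("variance partitioning satisfies its algebraic identities", {
  set.seed(18)
  Y <- matrix(rnorm(100 * 4), 100)
  X1 <- matrix(rnorm(100 * 3), 100)
  X2 <- matrix(rnorm(100 * 3), 100)
  vp <- variance_partition(Y, a = X1, b = X2)
  expect_equal(sum(vp$fractions$raw), vp$total_adj_r2, tolerance = 1e-10)
  # duplicated matrix: unique fractions vanish, shared is the single adjR2
  vd <- variance_partition(Y, a = X1, b = X1 %*% diag(3))
  uq <- vd$fractions$raw[vd$fractions$component %in% c("a", "b")]
  expect_equal(uq, c(0, 0), tolerance = 1e-8)
  expect_equal(vd$fractions$raw[vd$fractions$component == "a&b"],
               rda_adj_r2(Y, X1)$adj_r2, tolerance = 1e-8)
  # symmetry under swapping
  vs <- variance_partition(Y, b = X2, a = X1)
  raw_a <- vp$fractions$raw[vp$fractions$component == "a"]
  raw_a_swapped <- vs$fractions$raw[vs$fractions$component == "a"]
  expect_equal(raw_a, raw_a_swapped, tolerance = 1e-12)
  # three-matrix identity
  X3 <- matrix(rnorm(100 * 2), 100)
  v3 <- variance_partition(Y, a = X1, b = X2, c = X3)
  expect_equal(sum(v3$fractions$raw), v3$total_adj_r2, tolerance = 1e-10)
  # agreement with vegan::varpart on the two-matrix fractions
  vv <- vegan::varpart(Y, X1, X2)$part$indfract$Adj.R.square
  ours <- vp$fractions$raw[match(c("a", "b", "a&b"),
                                 vp$fractions$component)]
  expect_equal(ours, vv[1:3], tolerance = 1e-8)
})

test_that("orthogonal predictors share no variance", {
  set.seed(19)
  n <- 200
  Z1 <- scale(matrix(rnorm(n * 2), n))
  Z2 <- qr.resid(qr(cbind(1, Z1)), matrix(rnorm(n * 2), n))
  Y <- Z1 %*% matrix(c(1, 0, 0, 1), 2) + Z2 %*% matrix(c(0, 1, 1, 0), 2) +
    matrix(rnorm(n * 2, 0, 0.5), n)
  vp <- variance_partition(Y, a = Z1, b = Z2)
  shared <- vp$fractions$raw[vp$fractions$component == "a&b"]
  expect_lt(abs(shared), 0.02)
})

test_that("hierarchical partitioning sums to the full-model adjusted R2", {
  set.seed(20)
  Y <- matrix(rnorm(80 * 3), 80)
  X <- data.frame(a = rnorm(80), b = rnorm(80), d = rnorm(80))
  hp <- hierarchical_partition(Y, X)
  expect_equal(sum(hp$contribution), attr(hp, "total_adj_r2"),
               tolerance = 1e-8)
  # single predictor: contribution equals its adjusted R2
  h1 <- hierarchical_partition(Y, X["a"])
  expect_equal(h1$contribution, rda_adj_r2(Y, as.matrix(X$a))$adj_r2,
               tolerance = 1e-12)
  # orthogonal predictors: contribution equals the unique fraction
  n <- 150
  u <- scale(rnorm(n)); v <- qr.resid(qr(cbind(1, u)), rnorm(n))
  Yo <- cbind(u + rnorm(n, 0, 0.4), v + rnorm(n, 0, 0.4))
  hpo <- hierarchical_partition(Yo, data.frame(u = u, v = v))
  vpo <- variance_partition(Yo, u = as.matrix(u), v = as.matrix(v))
  expect_equal(hpo$contribution[1],
               vpo$fractions$raw[vpo$fractions$component == "u"] +
                 vpo$fractions$raw[vpo$fractions$component == "u&v"] / 2,
               tolerance = 1e-10)
  expect_error(hierarchical_partition(Y, X, max_p = 2), "group")
})
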