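test_that("Wilks' lambda: no-separation case, 1D hand oracle, monotonicity", {
  # identical group distributions: between-group scatter is zero
  w <- wilks_lambda(data.frame(v = c(0, 1, 0, 1)), c("a", "a", "b", "b"))
  expect_equal(w$lambda, 1)
  expect_equal(w$statistic, 0)

  # hand oracle: groups {0,1} vs {2,3}; W = 1, T = 5, lambda = 0.2,
  # F = ((1 - 0.2)/0.2) * (n - 2)/(g - 1) = 4 * 2 = 8 on (1, 2) df
  w <- wilks_lambda(data.frame(v = c(0, 1, 2, 3)), c("a", "a", "b", "b"))
  expect_equal(w$lambda, 0.2)
  expect_equal(w$statistic, 8)
  expect_equal(w$df1, 1)
  expect_equal(w$df2, 2)
  expect_equal(w$p.value, stats::pf(8, 1, 2, lower.tail = FALSE))

  # adding variables can only decrease lambda
  set.seed(40)
  X <- cbind(c(0, 1, 2, 3, 4, 5) + rnorm(6, sd = 0.1), matrix(rnorm(18), 6, 3))
  g <- rep(c("a", "b"), each = 3)
  l1 <- wilks_lambda(X, g, subset = 1)$lambda
  l12 <- wilks_lambda(X, g, subset = 1:2)$lambda
  l123 <- wilks_lambda(X, g, subset = 1:3)$lambda
  expect_lte(l12, l1 + 1e-12)
  expect_lte(l123, l12 + 1e-12)
})

test_that("stepwise selection finds the discriminating variable and respects caps", {
  # a single candidate with no real separation never qualifies
  set.seed(41)
  X <- matrix(rnorm(20), 20, 1)
  g <- rep(c("a", "b"), 10)
  expect_message(sel <- stepwise_select(X, g), "no variable")
  expect_length(sel$selected, 0)

  # variable 1 carries all separation; the rest are pure noise
  set.seed(42)
  n <- 15
  X <- cbind(c(rnorm(n, 0, 0.5), rnorm(n, 6, 0.5)), matrix(rnorm(2 * n * 6), 2 * n, 6))
  g <- rep(c("a", "b"), each = n)
  sel <- stepwise_select(X, g)
  expect_equal(sel$selected[1], 1L)
  expect_true(all(sel$trace$lambda >= 0))
  # the lambda trace never increases as variables enter
  entered <- sel$trace[sel$trace$action == "enter", ]
  expect_true(all(diff(entered$lambda) <= 1e-12))

  # hard cap on the number of entered variables
  set.seed(43)
  Xb <- cbind(rep(c(0, 8), each = 12) + rnorm(24, sd = 0.3),
              matrix(rep(c(0, 4), each = 12) + rnorm(24 * 9, sd = 0.8), 24, 9))
  gb <- rep(c("a", "b"), each = 12)
  expect_lte(length(stepwise_select(Xb, gb, max_vars = 6)$selected), 6)
  expect_lte(length(stepwise_select(Xb, gb, max_vars = 2)$selected), 2)
})

test_that("classifier separates distant clouds and matches the closed-form rule", {
  set.seed(44)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  g <- rep(c("a", "b"), each = 20)
  fit <- fit_classifier(X, g)
  expect_equal(fit$tables$resubstitution$accuracy_pct, c(100, 100))

  # equal-covariance two-group data: the decision rule must match the
  # closed-form midpoint-hyperplane oracle w'x > w'(mu1 + mu2)/2
  set.seed(45)
  X <- rbind(matrix(rnorm(60), 30, 2), sweep(matrix(rnorm(60), 30, 2), 2, c(-2, 1)))
  colnames(X) <- c("v1", "v2")
  g <- factor(rep(c("a", "b"), each = 30))
  fit <- fit_classifier(X, g)
  mu <- fit$group_means
  w <- fit$pooled_inverse %*% (mu[2, ] - mu[1, ])
  thresh <- drop(crossprod(w, (mu[1, ] + mu[2, ]) / 2))
  oracle <- ifelse(X %*% w - thresh > 0, "b", "a")
  margin <- abs(X %*% w - thresh)
  pred <- as.character(predict(fit, X))
  expect_equal(pred[margin > 1e-8], oracle[margin > 1e-8])

  # independent library cross-check on the same fit
  ld <- MASS::lda(X, grouping = g, prior = c(0.5, 0.5))
  expect_equal(pred, as.character(predict(ld, as.data.frame(X))$class))

  expect_error(fit_classifier(cbind(X[, 1], X[, 1]), g), "singular")
})

test_that("classification is invariant to affine rescaling of a selected variable", {
  set.seed(46)
  X <- rbind(matrix(rnorm(40), 20, 2), sweep(matrix(rnorm(40), 20, 2), 2, c(-3, 2)))
  g <- rep(c("a", "b"), each = 20)
  p0 <- predict(fit_classifier(X, g), X)
  X2 <- X
  X2[, 1] <- 1000 * X[, 1] - 7
  p1 <- predict(fit_classifier(X2, g), X2)
  expect_equal(p0, p1)
})

test_that("leave-one-out cross-validation behaves and never beats resubstitution on the pinned fixture", {
  # duplicate-rich, well-separated groups: LOO stays perfect
  X <- matrix(rep(c(0, 0, 10, 10), each = 6) + rep(c(0, 0.1), 12), ncol = 1)
  g <- rep(c("a", "b"), each = 12)
  cv <- loo_crossvalidate(X, g, selection = 1)
  expect_equal(cv$table$accuracy_pct, c(100, 100))

  # pinned overlapping fixture: cross-validated accuracy <= resubstitution
  set.seed(47)
  X <- rbind(matrix(rnorm(30 * 4), 30, 4), sweep(matrix(rnorm(30 * 4), 30, 4), 2, rep(1.2, 4)))
  g <- rep(c("a", "b"), each = 30)
  fit <- fit_classifier(X, g, selection = 1:4)
  cv <- loo_crossvalidate(X, g, selection = 1:4)
  overall <- function(tab) {
    num <- as.matrix(tab[, c("a", "b")])
    sum(diag(num)) / sum(num)
  }
  expect_lte(overall(cv$table), overall(fit$tables$resubstitution))
  # confusion marginals always equal group sizes
  expect_equal(rowSums(as.matrix(cv$table[, c("a", "b")])), c(30, 30),
               ignore_attr = TRUE)

  expect_error(loo_crossvalidate(X[c(1, 2, 31, 32), ], g[c(1, 2, 31, 32)]),
               "at least 3")
})

test_that("pairwise Mahalanobis distances match the formula oracle", {
  # identical group means -> D2 = 0
  X <- matrix(c(1, -1, 1, -1), 4, 1)
  m0 <- mahalanobis_pairwise(X, c("a", "a", "b", "b"))
  expect_equal(m0$d2, 0)

  # 1D oracle: means 0 and 2, pooled variance 1 -> D2 = 4
  d <- 1 / sqrt(2)
  X <- matrix(c(-d, d, 2 - d, 2 + d), 4, 1)
  m <- mahalanobis_pairwise(X, c("a", "a", "b", "b"))
  expect_equal(m$d2, 4)

  # symmetric and non-negative across three groups, p-values in [0, 1]
  set.seed(48)
  X <- rbind(matrix(rnorm(24), 12, 2), sweep(matrix(rnorm(24), 12, 2), 2, c(3, 0)),
             sweep(matrix(rnorm(24), 12, 2), 2, c(0, 3)))
  g <- rep(c("a", "b", "c"), each = 12)
  mp <- mahalanobis_pairwise(X, g)
  expect_equal(nrow(mp), 3)
  expect_true(all(mp$d2 >= 0))
  expect_true(all(mp$p.value >= 0 & mp$p.value <= 1))
})
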