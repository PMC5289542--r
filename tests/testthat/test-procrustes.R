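test_that("centroid size matches closed form, homogeneity, and brute force", {
  sq <- tibble::tibble(x = c(-0.5, 0.5, 0.5, -0.5), y = c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(centroid_size(sq), sqrt(2))

  set.seed(7)
  cfg <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  for (k in c(0.1, 3, 42)) {
    expect_equal(centroid_size(dplyr::mutate(cfg, x = k * x, y = k * y)),
                 k * centroid_size(cfg))
  }

  # brute-force oracle: explicit double loop over squared distances to centroid
  cx <- mean(cfg$x); cy <- mean(cfg$y)
  acc <- 0
  for (i in seq_len(nrow(cfg))) acc <- acc + (cfg$x[i] - cx)^2 + (cfg$y[i] - cy)^2
  expect_equal(centroid_size(cfg), sqrt(acc))

  expect_error(centroid_size(tibble::tibble(x = c(1, 1), y = c(2, 2))), "coincident")
})

test_that("pairwise alignment recovers similarity transforms and bars reflection", {
  set.seed(21)
  a <- random_curve(20)
  b <- rigid_motion(a, 1.1, 4, -7, scale = 2.5)
  fit <- align_pair(a, b)
  expect_lt(fit$residual, 1e-10)
  expect_lt(max(abs(as.matrix(fit$aligned) - as.matrix(a))), 1e-9)

  # mirror image cannot be matched with reflections excluded
  mirrored <- dplyr::mutate(a, x = -x)
  expect_gt(align_pair(a, mirrored)$residual, 0.1)
  fitm <- align_pair(a, mirrored)
  expect_equal(det(fitm$rotation), 1)

  expect_error(align_pair(a, tibble::tibble(x = rep(1, 20), y = rep(2, 20))),
               "degenerate")
})

test_that("pairwise alignment matches an independent closed-form solution", {
  # independent oracle: complex-arithmetic full Procrustes fit
  oracle <- function(a, b) {
    za <- complex(real = a$x, imaginary = a$y)
    zb <- complex(real = b$x, imaginary = b$y)
    za <- za - mean(za)
    zb <- zb - mean(zb)
    beta <- sum(za * Conj(zb)) / sum(Mod(zb)^2)
    sqrt(sum(Mod(za - beta * zb)^2))
  }
  set.seed(33)
  for (i in 1:10) {
    a <- random_curve(15)
    b <- random_curve(15)
    expect_equal(align_pair(a, b)$residual, oracle(a, b), tolerance = 1e-9)
  }
})

test_that("GPA centres, unit-sizes, and aligns identical shapes exactly", {
  set.seed(5)
  shape <- random_curve(30)
  configs <- lapply(1:6, function(i)
    rigid_motion(shape, runif(1, -pi, pi), rnorm(1), rnorm(1), runif(1, 0.5, 3)))
  ali <- gpa(configs)
  for (m in ali$aligned) {
    mm <- as.matrix(m)
    expect_lt(max(abs(colMeans(mm))), 1e-10)
    expect_equal(sqrt(sum(mm^2)), 1, tolerance = 1e-10)
  }
  ref <- as.matrix(ali$aligned[[1]])
  for (m in ali$aligned[-1]) expect_lt(max(abs(as.matrix(m) - ref)), 1e-9)
  expect_lt(max(abs(as.matrix(ali$consensus) - ref)), 1e-9)
  # consensus is the arithmetic mean of the aligned configurations
  avg <- Reduce(`+`, lapply(ali$aligned, as.matrix)) / length(ali$aligned)
  expect_lt(max(abs(avg - as.matrix(ali$consensus))), 1e-10)
})

test_that("two-configuration GPA agrees with the pairwise fit", {
  set.seed(8)
  a <- random_curve(18)
  b <- random_curve(18)
  ali <- gpa(list(a, b))
  # after GPA the two shapes are already at their pairwise-optimal relative
  # rotation: an ordinary Procrustes fit between them has nothing to rotate
  ua <- as.matrix(ali$aligned[[1]])
  ub <- as.matrix(ali$aligned[[2]])
  direct <- align_pair(ua, ub)
  expect_lt(max(abs(direct$rotation - diag(2))), 1e-6)
})

test_that("GPA is invariant to input order and pre-applied similarity transforms", {
  set.seed(13)
  base <- lapply(1:5, function(i) random_curve(22))
  ali <- gpa(base)
  pd <- function(a) {
    n <- length(a$aligned)
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      sqrt(sum((as.matrix(a$aligned[[i]]) - as.matrix(a$aligned[[j]]))^2))))
  }
  d0 <- pd(ali)
  for (rep in 1:3) {
    perm <- sample(5)
    d1 <- pd(gpa(base[perm]))
    # d1[i, j] is the distance between base[perm[i]] and base[perm[j]]
    expect_lt(max(abs(d1 - d0[perm, perm])), 1e-9)
  }
  # pre-applied similarity transforms change the result only by the global
  # rotational gauge (pinned to the first specimen's input pose); after
  # undoing that one rotation the aligned shapes coincide
  moved <- lapply(base, function(m)
    rigid_motion(m, runif(1, -pi, pi), rnorm(1), rnorm(1), runif(1, 0.2, 4)))
  ali2 <- gpa(moved)
  gauge <- align_pair(ali$consensus, ali2$consensus)
  for (i in 1:5) {
    fixed <- as.matrix(ali2$aligned[[i]]) %*% gauge$rotation
    expect_lt(max(abs(fixed - as.matrix(ali$aligned[[i]]))), 1e-9)
  }
})

test_that("summed squared residuals to the consensus never increase over iterations", {
  set.seed(17)
  configs <- lapply(1:8, function(i) random_curve(15))
  unit <- lapply(configs, function(p) {
    m <- as.matrix(p)
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  # replicate the GPA loop, tracking the residual at each iteration
  rot <- function(a_c, b_c) {
    sv <- svd(crossprod(b_c, a_c))
    s <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    sv$u %*% s %*% t(sv$v)
  }
  consensus <- unit[[1]]
  resid <- c()
  for (it in 1:20) {
    unit <- lapply(unit, function(m) m %*% rot(consensus, m))
    consensus <- Reduce(`+`, unit) / length(unit)
    consensus <- consensus / sqrt(sum(consensus^2))
    resid <- c(resid, sum(vapply(unit, function(m) sum((m - consensus)^2), numeric(1))))
  }
  expect_true(all(diff(resid) <= 1e-12))
})
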