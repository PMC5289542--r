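test_that("phi transform: collinear curves, turning-number theorem, quarter circle", {
  line <- tibble::tibble(x = c(0, 1, 2, 3.5, 7), y = c(0, 0, 0, 0, 0))
  expect_equal(phi_transform(line)$values, rep(0, 3))

  # anti-clockwise convex polygon: total turning is 2*pi
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  hex <- tibble::tibble(x = cos(t), y = sin(t))
  phi <- phi_transform(hex, open = FALSE)
  expect_equal(phi$values[length(phi$values)], 2 * pi, tolerance = 1e-9)

  # quarter circle: total curvature pi/2. With m chords the open-curve
  # construction accumulates (m - 1) of the m equal turn increments, so the
  # discrete total is (m - 1)/m * pi/2 exactly; at fine sampling it converges
  # to the closed-form total curvature
  t <- seq(0, pi / 2, length.out = 101)
  quarter <- tibble::tibble(x = cos(t), y = sin(t))
  phi <- phi_transform(quarter)
  expect_equal(phi$values[length(phi$values)], (99 / 100) * pi / 2,
               tolerance = 1e-12)
  t <- seq(0, pi / 2, length.out = 3001)
  phi <- phi_transform(tibble::tibble(x = cos(t), y = sin(t)))
  expect_equal(phi$values[length(phi$values)], pi / 2, tolerance = 1e-3)

  expect_error(phi_transform(tibble::tibble(x = c(0, 0, 1), y = c(0, 0, 1))),
               "coincident")
})

test_that("phi representation is invariant to translation, rotation and scale", {
  set.seed(2)
  crv <- random_curve(40)
  v0 <- phi_transform(crv)$values
  for (i in 1:10) {
    moved <- rigid_motion(crv, runif(1, -pi, pi), rnorm(1), rnorm(1),
                          scale = runif(1, 0.1, 5))
    expect_lt(max(abs(phi_transform(moved)$values - v0)), 1e-10)
  }
})

test_that("inverse_phi is the exact inverse of phi_transform", {
  straight <- inverse_phi(list(values = rep(0, 3), step_lengths = rep(1, 4),
                               start_point = c(0, 0), start_angle = 0))
  expect_equal(straight, tibble::tibble(x = as.numeric(0:4), y = rep(0, 5)))

  set.seed(14)
  for (i in 1:25) {
    crv <- random_curve(sample(10:60, 1))
    phi <- phi_transform(crv)
    back <- inverse_phi(phi)
    expect_lt(max(abs(as.matrix(back) - as.matrix(crv))), 1e-9)
    # phi of the reconstruction equals the input phi
    expect_lt(max(abs(phi_transform(back)$values - phi$values)), 1e-9)
  }

  expect_error(inverse_phi(list(values = 1:3, step_lengths = 1:3,
                                start_point = c(0, 0), start_angle = 0)),
               "step length")
})

test_that("eigenshape decomposition satisfies its invariants and matches eigen()", {
  set.seed(30)
  X <- matrix(rnorm(8 * 15), 8, 15)
  model <- eigenshape_decompose(X)
  expect_equal(sum(model$variance_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(model$variance_fractions) <= 1e-12))
  # orthonormal eigenshapes
  g <- crossprod(model$eigenshapes)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  # per-axis scores have zero mean
  sc <- as.matrix(model$scores[, -1])
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  # cumulative variance non-decreasing and reaching 1 at full rank
  cum <- cumsum(model$variance_fractions)
  expect_true(all(diff(cum) >= -1e-12))
  expect_equal(cum[length(cum)], 1, tolerance = 1e-10)

  # independent oracle: eigen-decomposition of the covariance matrix
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  k <- length(model$eigenvalues)
  expect_equal(model$eigenvalues, ev$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k)) {
    # axes agree up to sign
    expect_lt(min(max(abs(model$eigenshapes[, j] - ev$vectors[, j])),
                  max(abs(model$eigenshapes[, j] + ev$vectors[, j]))), 1e-7)
  }
})

test_that("duplicating every specimen leaves eigenshapes and fractions unchanged", {
  set.seed(31)
  X <- matrix(rnorm(6 * 10), 6, 10)
  m1 <- eigenshape_decompose(X)
  m2 <- eigenshape_decompose(rbind(X, X))
  k <- length(m1$variance_fractions)
  expect_equal(m2$variance_fractions[seq_len(k)], m1$variance_fractions,
               tolerance = 1e-8)
  expect_lt(max(abs(m2$eigenshapes[, seq_len(k)] - m1$eigenshapes)), 1e-7)
})

test_that("rank-two generative data yields exactly two modes matching the truth", {
  set.seed(32)
  p <- 12
  u1 <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  mean_vec <- rnorm(p)
  a <- rnorm(20, sd = 3)
  b <- rnorm(20, sd = 1)
  X <- sweep(outer(a, u1[, 1]) + outer(b, u1[, 2]), 2, -mean_vec)
  model <- eigenshape_decompose(X)
  expect_gt(model$eigenvalues[2], 1e-8)
  expect_lt(model$eigenvalues[3], 1e-16)
  # leading two-axis subspace spans the generating modes
  proj <- model$eigenshapes[, 1:2] %*% crossprod(model$eigenshapes[, 1:2], u1)
  expect_lt(max(abs(proj - u1)), 1e-8)
})

test_that("projection is consistent with stored scores and inverts at full rank", {
  set.seed(33)
  X <- matrix(rnorm(9 * 14), 9, 14)
  model <- eigenshape_decompose(X)
  # projecting the mean -> all-zero scores
  expect_lt(max(abs(as.matrix(project(model, model$mean_phi)))), 1e-12)
  # training scores match stored scores
  re <- as.matrix(project(model, X))
  expect_lt(max(abs(re - as.matrix(model$scores[, -1]))), 1e-10)
  # full-rank reconstruction returns each phi
  recon <- sweep(re %*% t(model$eigenshapes), 2, model$mean_phi, FUN = "+")
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_error(project(model, rnorm(5)), "does not match")
})

test_that("shape models along an axis are symmetric about the mean shape", {
  set.seed(34)
  X <- matrix(rnorm(8 * 12), 8, 12)
  model <- eigenshape_decompose(X)
  mean_shape <- shape_model(model, 1, 0)
  # score 0 reconstructs the mean phi
  expect_lt(max(abs(phi_transform(mean_shape)$values - model$mean_phi)), 1e-9)
  # +c and -c displace phi symmetrically about the mean
  plus <- phi_transform(shape_model(model, 1, 0.4))$values
  minus <- phi_transform(shape_model(model, 1, -0.4))$values
  expect_lt(max(abs((plus + minus) / 2 - model$mean_phi)), 1e-9)
  expect_error(shape_model(model, 99, 1), "outside")
})

test_that("ES1 shape models order vault height with the generating elongation", {
  spec <- list(group = "g", n = 12, noise_sd = 0, components = list(list(
    weight = 1, elongation = c(1.3, 0.3), obliquity = c(0, 0),
    depression_depth = c(0, 0), depression_center = c(0.6, 0),
    depression_width = 0.08)))
  coh <- generate_cohort(spec, seed = 4, total_points = 120)
  model <- outline_eigenshapes(coh)
  el <- vapply(coh$params, `[[`, numeric(1), "elongation")
  s <- model$scores$ES1
  # orient the axis along elongation, then compare extreme reconstructions
  sgn <- sign(stats::cor(el, s))
  hi <- shape_model(model, 1, sgn * max(sgn * s))
  lo <- shape_model(model, 1, sgn * min(sgn * s))
  ratio <- function(p) diff(range(p$y)) / diff(range(p$x))
  expect_gt(ratio(hi), ratio(lo))
})

test_that("segment submodels restrict the decomposition to one segment", {
  set.seed(35)
  X <- matrix(rnorm(10 * 20), 10, 20)
  layout <- list(occipital = 1:6, parietal = 7:12, frontal = 13:20)
  # degenerate layout equals the full decomposition
  full <- eigenshape_decompose(X)
  whole <- segment_submodel(X, list(all = 1:20), "all")
  expect_equal(whole$eigenvalues, full$eigenvalues)
  expect_equal(whole$eigenshapes, full$eigenshapes)

  for (seg in names(layout)) {
    sub <- segment_submodel(X, layout, seg)
    expect_equal(sum(sub$variance_fractions), 1, tolerance = 1e-10)
  }
  expect_error(segment_submodel(X, layout, "nasal"), "unknown segment")

  # cohort deformed only in the parietal (plus faint digitizing noise):
  # the parietal submodel concentrates its variance on ES1, the frontal
  # submodel sees only noise with a flat spectrum
  base <- baseline_vault(120)
  set.seed(36)
  coh <- dplyr::bind_rows(lapply(1:10, function(i) {
    sp <- base
    sp$id <- paste0("s", i)
    pts <- as.matrix(sp$points[[1]])
    s <- seq(0, 1, length.out = nrow(pts))
    bump <- rnorm(1, 0, 0.1)
    pts[, 2] <- pts[, 2] * (1 + bump * exp(-0.5 * ((s - 0.45) / 0.05)^2))
    sp$points[[1]] <- tibble::tibble(x = pts[, 1], y = pts[, 2])
    apply_modification(sp, noise_sd = 0.002)
  }))
  prep <- outline_phis(coh)
  par_sub <- segment_submodel(prep$phis, prep$layout, "parietal")
  fro_sub <- segment_submodel(prep$phis, prep$layout, "frontal")
  expect_gt(par_sub$variance_fractions[1], fro_sub$variance_fractions[1])
  expect_gt(par_sub$variance_fractions[1] * sum(par_sub$eigenvalues),
            fro_sub$variance_fractions[1] * sum(fro_sub$eigenvalues))
})
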