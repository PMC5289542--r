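# shared geometric fixtures, built in code

# dense semicircle of radius 1 from (1, 0) anti-clockwise to (-1, 0)
semicircle <- function(n = 400) {
  t <- seq(0, pi, length.out = n)
  tibble::tibble(x = cos(t), y = sin(t))
}

# random open curve with well-separated consecutive points
random_curve <- function(n = 30) {
  steps <- matrix(stats::rnorm(2 * (n - 1)), ncol = 2)
  steps <- steps + sign(steps) * 0.2  # keep steps away from zero
  tibble::tibble(x = cumsum(c(0, steps[, 1])), y = cumsum(c(0, steps[, 2])))
}

rigid_motion <- function(points, theta, dx, dy, scale = 1) {
  m <- as.matrix(as.data.frame(points)[, 1:2])
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- scale * m %*% t(rot)
  tibble::tibble(x = m[, 1] + dx, y = m[, 2] + dy)
}

# one-row specimen tibble from raw points and 1-based anchors
make_specimen <- function(points, anchors, id = "s", group = "g") {
  lm <- as.integer(anchors)
  names(lm) <- c("occiput", "lambda", "bregma", "glabella")
  tibble::tibble(id = id, group = group,
                 points = list(tibble::as_tibble(as.data.frame(points)[, 1:2]) |>
                                 stats::setNames(c("x", "y"))),
                 landmarks = list(lm))
}

# small three-group synthetic cohort for structural pipeline tests
small_cohort <- function(n = 6, seed = 42, total_points = 100) {
  generate_study_cohorts(n = n, seed = seed, total_points = total_points)
}
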