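#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid — the standard geometric-morphometric size measure used to scale
#' configurations to unit size.
#'
#' @param points Two-column data frame or matrix of x/y coordinates.
#' @return A positive number.
#' @examples
#' centroid_size(data.frame(x = c(-0.5, 0.5, 0.5, -0.5), y = c(-0.5, -0.5, 0.5, 0.5)))
#' @export
centroid_size <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  stopifnot(nrow(pts) >= 2)
  centered <- sweep(pts, 2, colMeans(pts))
  cs <- sqrt(sum(centered^2))
  if (cs <= 0) stop("centroid_size: all points coincident (zero size)", call. = FALSE)
  cs
}

# optimal rotation (no reflection) taking centered b onto centered a
.opt_rotation <- function(a_c, b_c) {
  m <- crossprod(b_c, a_c)
  sv <- svd(m)
  s <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% s %*% t(sv$v)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Translates, scales, and rotates (no reflection: all specimens are
#' digitized in the same lateral view) configuration `b` to minimize the
#' summed squared distance to `a`.
#'
#' @param a,b Two-column data frames or matrices with equal point counts.
#' @return A list with `aligned` (tibble of transformed `b`), `residual`
#'   (root-sum-of-squares distance to `a` at the optimum), `rotation`
#'   (2x2 matrix), `scale`, and `translation`.
#' @export
align_pair <- function(a, b) {
  A <- as.matrix(as.data.frame(a)[, 1:2])
  B <- as.matrix(as.data.frame(b)[, 1:2])
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A)
  cb <- colMeans(B)
  A_c <- sweep(A, 2, ca)
  B_c <- sweep(B, 2, cb)
  if (sqrt(sum(A_c^2)) <= 0 || sqrt(sum(B_c^2)) <= 0) {
    stop("align_pair: degenerate (zero-size) configuration", call. = FALSE)
  }
  R <- .opt_rotation(A_c, B_c)
  BR <- B_c %*% R
  s <- sum(BR * A_c) / sum(B_c^2)
  fitted <- sweep(s * BR, 2, ca, FUN = "+")
  res <- sqrt(sum((fitted - A)^2))
  list(aligned = tibble::tibble(x = fitted[, 1], y = fitted[, 2]),
       residual = res, rotation = R, scale = s, translation = ca - cb)
}

#' Generalized Procrustes alignment of a set of configurations
#'
#' Iterative generalized least-squares superimposition: each configuration is
#' centred at the origin and scaled to exactly unit centroid size, then
#' rotated to the running consensus; the consensus is the arithmetic mean of
#' the aligned configurations, re-normalized to unit size, and iteration
#' stops when its root-mean-square change falls below `tol`. The rotational
#' gauge freedom is removed by rotating the final consensus (and with it all
#' aligned specimens) onto the first configuration's orientation, so results
#' are reproducible and order-stable up to that global rotation.
#'
#' @param configs A list of two-column matrices/data frames, or a specimen
#'   tibble holding a `points` list-column; all must share one point count.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `gpa_alignment`: list with `aligned` (list of
#'   point tibbles), `consensus` (tibble), `centroid_sizes` (named numeric),
#'   `ids`, `iterations`, `final_change`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (is.data.frame(configs) && "points" %in% names(configs)) {
    ids <- if ("id" %in% names(configs)) configs$id else as.character(seq_len(nrow(configs)))
    configs <- configs$points
  } else {
    ids <- names(configs)
    if (is.null(ids)) ids <- as.character(seq_along(configs))
  }
  mats <- lapply(configs, function(p) as.matrix(as.data.frame(p)[, 1:2]))
  k <- unique(vapply(mats, nrow, integer(1)))
  stopifnot(length(mats) >= 2, length(k) == 1)

  sizes <- vapply(mats, centroid_size, numeric(1))
  names(sizes) <- ids
  unit <- lapply(mats, function(m) {
    c0 <- sweep(m, 2, colMeans(m))
    c0 / sqrt(sum(c0^2))
  })

  consensus <- unit[[1]]
  iter <- 0L
  change <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    unit <- lapply(unit, function(m) m %*% .opt_rotation(consensus, m))
    new_cons <- Reduce(`+`, unit) / length(unit)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    change <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) break
  }
  if (change >= tol) {
    stop("gpa: no convergence after ", max_iter,
         " iterations (last consensus RMS change ", format(change), ")", call. = FALSE)
  }

  # pin orientation to the first specimen's original pose
  first_unit <- {
    c0 <- sweep(mats[[1]], 2, colMeans(mats[[1]]))
    c0 / sqrt(sum(c0^2))
  }
  Rfix <- .opt_rotation(first_unit, consensus)
  consensus <- consensus %*% Rfix
  unit <- lapply(unit, function(m) m %*% Rfix)
  consensus <- Reduce(`+`, unit) / length(unit)

  structure(list(
    aligned = lapply(unit, function(m) tibble::tibble(x = m[, 1], y = m[, 2])),
    consensus = tibble::tibble(x = consensus[, 1], y = consensus[, 2]),
    centroid_sizes = sizes,
    ids = ids,
    iterations = iter,
    final_change = change
  ), class = "gpa_alignment")
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat("  specimens: ", length(x$aligned),
      "   semi-landmarks: ", nrow(x$consensus), "\n", sep = "")
  cat("  iterations: ", x$iterations,
      "   final consensus RMS change: ", format(x$final_change, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gpa_alignment <- function(x, ...) {
  tibble::tibble(id = x$ids, centroid_size = unname(x$centroid_sizes))
}

#' @export
glance.gpa_alignment <- function(x, ...) {
  tibble::tibble(n = length(x$aligned), n_points = nrow(x$consensus),
                 iterations = x$iterations, final_change = x$final_change)
}
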