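#' Zahn-Roskies phi-function of a digitized curve
#'
#' Converts an ordered point sequence to its cumulative tangent-angle
#' representation: the signed turning angle between successive chords,
#' accumulated from the start of the curve, in radians. For an open curve of
#' n points there are n - 2 interior turning angles; for a closed curve the
#' closing chord and the wrap-around turn are included (n values), so a
#' convex polygon traversed anti-clockwise accumulates a total of 2*pi. The
#' step lengths and start pose are recorded so the transform is exactly
#' invertible with [inverse_phi()].
#'
#' The representation is invariant to translation and rotation of the input
#' curve, and to uniform scaling once step lengths are ignored — which is why
#' it is the natural substrate for covariance-based shape decomposition.
#'
#' @param points Two-column data frame or matrix of ordered coordinates.
#' @param open Logical; `TRUE` (default) for an open curve.
#' @return An object of class `phi_function`: list with `values` (cumulative
#'   turning angles), `step_lengths`, `start_point`, `start_angle`, `open`.
#' @examples
#' phi_transform(data.frame(x = 0:3, y = c(0, 0, 0, 0)))$values  # collinear: all 0
#' @export
phi_transform <- function(points, open = TRUE) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  n <- nrow(pts)
  stopifnot(n >= 3)
  d <- diff(pts)
  if (!open) d <- rbind(d, pts[1, ] - pts[n, ])
  len <- sqrt(rowSums(d^2))
  tol <- 1e-12 * sum(len)
  if (any(len <= tol)) {
    stop("phi_transform: coincident consecutive points at index ",
         which(len <= tol)[1], call. = FALSE)
  }
  headings <- atan2(d[, 2], d[, 1])
  turns <- diff(headings)
  if (!open) turns <- c(turns, headings[1] - headings[length(headings)])
  # wrap to (-pi, pi]
  turns <- turns - 2 * pi * floor((turns + pi) / (2 * pi))
  structure(list(
    values = cumsum(turns),
    step_lengths = len[seq_len(n - 1L)],
    start_point = pts[1, ],
    start_angle = headings[1],
    open = open
  ), class = "phi_function")
}

#' Reconstruct coordinates from a phi-function
#'
#' Exact inverse of [phi_transform()] for open curves: chains steps of the
#' recorded lengths in directions given by the start angle plus the
#' accumulated turning angles.
#'
#' @param phi A `phi_function` (or a list with the same fields).
#' @return A tibble of `x`/`y` coordinates.
#' @export
inverse_phi <- function(phi) {
  nv <- length(phi$values)
  ns <- length(phi$step_lengths)
  if (ns != nv + 1L) {
    stop("inverse_phi: need exactly one more step length (", ns,
         ") than phi values (", nv, ")", call. = FALSE)
  }
  headings <- phi$start_angle + c(0, phi$values)
  dx <- phi$step_lengths * cos(headings)
  dy <- phi$step_lengths * sin(headings)
  tibble::tibble(
    x = phi$start_point[1] + c(0, cumsum(dx)),
    y = phi$start_point[2] + c(0, cumsum(dy))
  )
}

#' Eigenshape decomposition of a set of phi-functions
#'
#' Mean-centres the specimen-by-variable matrix of phi values and performs a
#' singular value decomposition — equivalent to a principal component
#' analysis of the covariance matrix (divisor n - 1) of the phi-functions.
#' The right singular vectors are the eigenshapes ES1, ES2, ...; specimen
#' coordinates on them are the eigenscores. The sign of each eigenshape is
#' fixed so its largest-magnitude loading is positive, pinning the SVD sign
#' ambiguity for reproducible scores and plots.
#'
#' @param phis Numeric matrix (specimens in rows, phi variables in columns),
#'   optionally with row names as specimen ids; or a list of equal-length
#'   phi-value vectors.
#' @param layout Optional named list of integer column index ranges giving
#'   where each outline segment sits within the phi vector, e.g.
#'   `list(occipital = 1:58, ...)`.
#' @param groups Optional per-specimen group labels carried into the scores.
#' @return An object of class `eigenshape_model`: `mean_phi`, `eigenshapes`
#'   (p x k, orthonormal columns), `eigenvalues` (descending),
#'   `variance_fractions` (sum to 1), `scores` (tibble: id, group, ES1..ESk),
#'   `segment_layout`, `n`, `p`.
#' @export
eigenshape_decompose <- function(phis, layout = NULL, groups = NULL) {
  X <- if (is.list(phis) && !is.matrix(phis)) do.call(rbind, phis) else as.matrix(phis)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n >= 3)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  mean_phi <- colMeans(X)
  Xc <- sweep(X, 2, mean_phi)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total <= .Machine$double.eps * p) {
    warning("eigenshape_decompose: zero-variance data; all eigenvalues are 0")
    frac <- rep(0, length(ev))
  } else {
    frac <- ev / total
  }
  k <- min(n - 1L, p)
  V <- sv$v[, seq_len(k), drop = FALSE]
  ev <- ev[seq_len(k)]
  frac <- frac[seq_len(k)]
  # pin sign: largest-magnitude loading of each axis is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("ES", seq_len(k))
  score_tbl <- tibble::tibble(id = ids)
  if (!is.null(groups)) score_tbl$group <- groups
  score_tbl <- dplyr::bind_cols(score_tbl, tibble::as_tibble(scores))

  structure(list(
    mean_phi = mean_phi,
    eigenshapes = V,
    eigenvalues = ev,
    variance_fractions = frac,
    scores = score_tbl,
    segment_layout = layout,
    n = n, p = p
  ), class = "eigenshape_model")
}

#' Project phi-functions onto a fitted eigenshape model
#'
#' Eigenscores are the inner products of the mean-centred phi vector with
#' the model's eigenshapes.
#'
#' @param model An `eigenshape_model`.
#' @param phi A numeric phi vector, a matrix of such rows, or a
#'   `phi_function`.
#' @return A tibble with one row per input and columns `ES1..ESk`.
#' @export
project <- function(model, phi) {
  stopifnot(inherits(model, "eigenshape_model"))
  if (inherits(phi, "phi_function")) phi <- phi$values
  X <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1)
  if (ncol(X) != model$p) {
    stop("project: phi length ", ncol(X), " does not match model (", model$p, ")",
         call. = FALSE)
  }
  sc <- sweep(X, 2, model$mean_phi) %*% model$eigenshapes
  colnames(sc) <- paste0("ES", seq_len(ncol(sc)))
  tibble::as_tibble(sc)
}

#' Model shape along a morphospace axis
#'
#' Reconstructs the outline (or one of its segments) corresponding to the
#' mean phi displaced by `score` along one eigenshape, i.e. the shape a
#' specimen with that eigenscore (and zeros elsewhere) would have. The phi
#' vector only encodes turning angles, so a pose — step lengths, start point
#' and start angle — must be supplied or defaulted (equal unit steps from the
#' origin, initial heading of `pi/2` so the curve rises from the baseline).
#'
#' @param model An `eigenshape_model`.
#' @param axis Axis number (1 = ES1, ...).
#' @param score Eigenscore displacement along the axis.
#' @param segment Segment name when the model carries a `segment_layout`
#'   spanning several segments; `NULL` reconstructs the full phi vector.
#' @param pose Optional list with `step_lengths`, `start_point`,
#'   `start_angle`.
#' @return A tibble of `x`/`y` coordinates.
#' @export
shape_model <- function(model, axis, score, segment = NULL, pose = NULL) {
  stopifnot(inherits(model, "eigenshape_model"))
  if (axis < 1 || axis > ncol(model$eigenshapes)) {
    stop("shape_model: axis ", axis, " outside retained axes 1..",
         ncol(model$eigenshapes), call. = FALSE)
  }
  phi_full <- model$mean_phi + score * model$eigenshapes[, axis]
  if (!is.null(segment)) {
    if (is.null(model$segment_layout) || is.null(model$segment_layout[[segment]])) {
      stop("shape_model: unknown segment ", dQuote(segment), call. = FALSE)
    }
    segs <- segment
  } else if (!is.null(model$segment_layout)) {
    segs <- names(model$segment_layout)
  } else {
    segs <- NA_character_
  }

  default_pose <- function(phi) {
    list(step_lengths = rep(1 / (length(phi) + 1L), length(phi) + 1L),
         start_point = c(0, 0), start_angle = pi / 2)
  }

  pieces <- list()
  at <- NULL
  for (sg in segs) {
    phi <- if (is.na(sg)) phi_full else phi_full[model$segment_layout[[sg]]]
    pz <- pose
    if (is.null(pz) && !is.na(sg) && !is.null(model$poses[[sg]])) pz <- model$poses[[sg]]
    if (is.null(pz)) pz <- default_pose(phi)
    if (!is.null(at)) pz$start_point <- at  # glue segments at shared joints
    pts <- inverse_phi(list(values = phi, step_lengths = pz$step_lengths,
                            start_point = pz$start_point,
                            start_angle = pz$start_angle, open = TRUE))
    at <- as.numeric(pts[nrow(pts), ])
    pieces[[length(pieces) + 1L]] <-
      if (length(pieces)) pts[-1, , drop = FALSE] else pts
  }
  dplyr::bind_rows(pieces)
}

#' Eigenshape decomposition restricted to one outline segment
#'
#' Runs [eigenshape_decompose()] on the phi coordinates of a single segment
#' (frontal, parietal or occipital), as used for the per-segment analyses of
#' binding-style differences.
#'
#' @param phis Specimen-by-variable phi matrix (full composite vector).
#' @param layout Named list of integer column indices per segment.
#' @param segment Segment name present in `layout`.
#' @param groups Optional group labels.
#' @return An `eigenshape_model` fitted to the segment's columns.
#' @export
segment_submodel <- function(phis, layout, segment, groups = NULL) {
  if (is.null(layout[[segment]])) {
    stop("segment_submodel: unknown segment ", dQuote(segment),
         "; layout has ", paste(names(layout), collapse = ", "), call. = FALSE)
  }
  X <- if (is.list(phis) && !is.matrix(phis)) do.call(rbind, phis) else as.matrix(phis)
  eigenshape_decompose(X[, layout[[segment]], drop = FALSE],
                       layout = stats::setNames(list(seq_along(layout[[segment]])), segment),
                       groups = groups)
}

#' @export
print.eigenshape_model <- function(x, ...) {
  cat("Eigenshape model: ", x$n, " specimens, ", x$p, " phi variables, ",
      ncol(x$eigenshapes), " axes\n", sep = "")
  k <- min(5L, length(x$variance_fractions))
  cat("  variance fractions: ",
      paste0("ES", seq_len(k), "=", sprintf("%.1f%%", 100 * x$variance_fractions[seq_len(k)]),
             collapse = " "), if (length(x$variance_fractions) > k) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.eigenshape_model <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fractions,
    cumulative = cumsum(x$variance_fractions)
  )
}

#' @export
glance.eigenshape_model <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, k = ncol(x$eigenshapes),
                 total_variance = sum(x$eigenvalues))
}

#' Serialize an eigenshape model to JSON
#'
#' @param model An `eigenshape_model`.
#' @param path File path to write; `NULL` returns the JSON string.
#' @return Invisibly, the JSON string.
#' @export
export_eigenshape_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "eigenshape_model"))
  obj <- list(
    mean_phi = model$mean_phi,
    eigenshapes = model$eigenshapes,
    eigenvalues = model$eigenvalues,
    variance_fractions = model$variance_fractions,
    scores = model$scores,
    segment_layout = model$segment_layout,
    n = model$n, p = model$p
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Restore an eigenshape model exported with [export_eigenshape_model()]
#'
#' @param source Path or JSON string.
#' @return An `eigenshape_model`.
#' @export
import_eigenshape_model <- function(source) {
  obj <- jsonlite::fromJSON(source)
  structure(list(
    mean_phi = as.numeric(obj$mean_phi),
    eigenshapes = as.matrix(obj$eigenshapes),
    eigenvalues = as.numeric(obj$eigenvalues),
    variance_fractions = as.numeric(obj$variance_fractions),
    scores = tibble::as_tibble(obj$scores),
    segment_layout = lapply(obj$segment_layout, as.integer),
    n = as.integer(obj$n), p = as.integer(obj$p)
  ), class = "eigenshape_model")
}
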