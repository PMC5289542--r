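#' Rotate specimens so the cranial base line is horizontal
#'
#' The cranial base is demarcated by the line from glabella through a
#' posterior baseline reference (porion, or the occiput baseline point when
#' porion is not digitized). Each specimen is rigidly rotated about its
#' glabella so this line is horizontal with the vault above it. Point order
#' and landmark indices are unchanged; no translation is applied, so a
#' specimen that is already baseline-horizontal is returned bit-identical up
#' to floating point.
#'
#' @param specimens Specimen tibble from [attach_metadata()].
#' @param baseline_ref The second baseline point: `"occiput"` (default, the
#'   first anchor), an integer point index applied to all specimens, or a
#'   list of length-2 numeric vectors (explicit coordinates per specimen).
#' @return The specimen tibble with rotated `points`.
#' @export
orient_to_baseline <- function(specimens, baseline_ref = "occiput") {
  stopifnot(is.data.frame(specimens))
  out <- specimens
  for (r in seq_len(nrow(specimens))) {
    pts <- as.matrix(specimens$points[[r]][, c("x", "y")])
    lm <- specimens$landmarks[[r]]
    glab <- pts[lm[["glabella"]], ]
    ref <- if (identical(baseline_ref, "occiput")) {
      pts[lm[["occiput"]], ]
    } else if (is.numeric(baseline_ref) && length(baseline_ref) == 1L) {
      pts[as.integer(baseline_ref), ]
    } else {
      as.numeric(baseline_ref[[r]])
    }
    v <- ref - glab
    if (sqrt(sum(v^2)) < 1e-12 * max(1, max(abs(pts)))) {
      stop("orient_to_baseline: glabella and baseline reference coincide for ",
           dQuote(specimens$id[r]), call. = FALSE)
    }
    theta <- atan2(v[2], v[1])
    rot <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
    centered <- sweep(pts, 2, glab)
    newpts <- centered %*% t(rot)
    newpts <- sweep(newpts, 2, glab, FUN = "+")
    # vault must sit above the baseline; flip by pi if the rotation put it below
    if (mean(newpts[, 2]) < glab[2]) {
      newpts <- sweep(sweep(newpts, 2, glab), 2, c(1, 1), FUN = "*") * -1
      newpts <- sweep(newpts, 2, glab, FUN = "+")
    }
    out$points[[r]] <- tibble::tibble(x = newpts[, 1], y = newpts[, 2])
  }
  out
}

#' Split vault outlines into the three homologous open segments
#'
#' Splits each outline at its anchors into occipital (occiput to lambda),
#' parietal (lambda to bregma) and frontal (bregma to glabella) open curves,
#' each inclusive of both endpoint landmarks. The straight inferior base
#' segment from glabella back to the occiput carries no curvature and is
#' excluded.
#'
#' @param specimens Specimen tibble from [attach_metadata()].
#' @return A long tibble with columns `id`, `group`, `segment` (factor with
#'   levels occipital, parietal, frontal in traversal order) and `points`.
#' @export
split_segments <- function(specimens) {
  stopifnot(is.data.frame(specimens))
  rows <- list()
  seg_levels <- c("occipital", "parietal", "frontal")
  for (r in seq_len(nrow(specimens))) {
    pts <- specimens$points[[r]]
    lm <- specimens$landmarks[[r]]
    idx <- list(
      occipital = lm[["occiput"]]:lm[["lambda"]],
      parietal = lm[["lambda"]]:lm[["bregma"]],
      frontal = lm[["bregma"]]:lm[["glabella"]]
    )
    for (seg in seg_levels) {
      if (length(idx[[seg]]) < 2L) {
        stop("split_segments: segment ", seg, " of specimen ",
             dQuote(specimens$id[r]), " has fewer than 2 points", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = specimens$id[r],
        group = specimens$group[r],
        segment = seg,
        points = list(pts[idx[[seg]], , drop = FALSE])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$segment <- factor(out$segment, levels = seg_levels)
  out
}

#' Resample an open curve to equally spaced points
#'
#' Places `m` semi-landmarks at equal arc-length spacing along the
#' piecewise-linear curve through the input points. The first and last
#' output points equal the original endpoints exactly.
#'
#' @param points Two-column data frame or matrix of ordered x/y coordinates.
#' @param m Number of output points (>= 2).
#' @return A tibble with columns `x` and `y` and `m` rows.
#' @examples
#' resample_equal_arc(data.frame(x = c(0, 1), y = c(0, 0)), 3)
#' @export
resample_equal_arc <- function(points, m) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  if (m < 2L) stop("resample_equal_arc: m must be >= 2", call. = FALSE)
  d <- sqrt(rowSums(diff(pts)^2))
  total <- sum(d)
  if (total <= 0) stop("resample_equal_arc: zero-length segment", call. = FALSE)
  s <- c(0, cumsum(d))
  target <- seq(0, total, length.out = m)
  xs <- stats::approx(s, pts[, 1], xout = target, ties = "ordered")$y
  ys <- stats::approx(s, pts[, 2], xout = target, ties = "ordered")$y
  # pin endpoints bit-exactly
  xs[1] <- pts[1, 1]; ys[1] <- pts[1, 2]
  xs[m] <- pts[nrow(pts), 1]; ys[m] <- pts[nrow(pts), 2]
  tibble::tibble(x = xs, y = ys)
}

#' Harmonize semi-landmark counts across specimens
#'
#' Ensures every homologous segment carries the same number of equidistant
#' semi-landmarks across all specimens. Under the default `"max"` policy the
#' harmonized count for each segment is the maximum raw point count observed
#' for that segment over specimens, so the specimen with the most complex
#' curvature sets the sampling density; `"fixed"` resamples every segment to
#' the counts supplied in `fixed`.
#'
#' @param segments Long segment tibble from [split_segments()].
#' @param policy `"max"` (default) or `"fixed"`.
#' @param fixed Named integer vector (`occipital`, `parietal`, `frontal`)
#'   used when `policy = "fixed"`.
#' @return A tibble like `segments` with resampled `points` and an integer
#'   `n_points` column; the per-segment harmonized counts are attached as
#'   attribute `"counts"` (see [segment_counts()]).
#' @export
harmonize_counts <- function(segments, policy = c("max", "fixed"), fixed = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  raw <- vapply(segments$points, nrow, integer(1))
  counts <- if (policy == "max") {
    tapply(raw, segments$segment, max)
  } else {
    stopifnot(!is.null(fixed), all(levels(segments$segment) %in% names(fixed)))
    fixed[levels(segments$segment)]
  }
  counts <- stats::setNames(as.integer(counts), levels(segments$segment))
  out <- segments
  out$points <- lapply(seq_len(nrow(segments)), function(r) {
    m <- counts[[as.character(segments$segment[r])]]
    resample_equal_arc(segments$points[[r]], m)
  })
  out$n_points <- vapply(out$points, nrow, integer(1))
  attr(out, "counts") <- counts
  out
}

#' Harmonized per-segment semi-landmark counts
#'
#' @param segments Result of [harmonize_counts()].
#' @return Named integer vector of counts.
#' @export
segment_counts <- function(segments) attr(segments, "counts")
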