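#' Baseline unmodified cranial vault outline
#'
#' A smooth convex vault arc (half-oval) over a horizontal cranial base of
#' length 2, traversed anti-clockwise from the occiput baseline point at
#' (1, 0), over lambda and bregma, to glabella at (-1, 0) — the traversal
#' order used when digitizing a cranium in left lateral view. Points are
#' spaced at equal arc length, and the four landmark anchors sit at fixed
#' arc fractions (occiput 0, lambda 0.30, bregma 0.60, glabella 1), which
#' guarantees landmark homology across synthetic specimens.
#'
#' @param total_points Number of outline points (default 200, the sampling
#'   density used for the vault outline).
#' @param height Vault height as a fraction of the base half-length
#'   (default 0.7, a shallow unmodified profile).
#' @param id Specimen identifier.
#' @param group Group label.
#' @return A one-row specimen tibble (`id`, `group`, `points`, `landmarks`)
#'   as produced by [attach_metadata()].
#' @export
baseline_vault <- function(total_points = 200L, height = 0.7,
                           id = "synthetic", group = "modern") {
  if (total_points < 8L) stop("baseline_vault: total_points must be >= 8", call. = FALSE)
  # dense half-ellipse, then equal-arc resampling so landmark arc fractions hold
  t <- seq(0, pi, length.out = 2048L)
  dense <- cbind(cos(t), height * sin(t))
  pts <- resample_equal_arc(dense, total_points)
  lm_frac <- c(occiput = 0, lambda = 0.30, bregma = 0.60, glabella = 1)
  lm <- as.integer(round(lm_frac * (total_points - 1L))) + 1L
  names(lm) <- names(lm_frac)
  tibble::tibble(id = id, group = group,
                 points = list(pts), landmarks = list(lm))
}

#' Deform a vault outline by a parametric cranial-modification model
#'
#' Applies, in order: vertical elongation about the baseline (annular
#' binding raises the vault); a shear tilting superior points posteriorly
#' (oblique annular profiles); a smooth localized depression around the
#' bregma region (the vertical bandage of the two-bandage technique); and
#' per-point radial jitter emulating digitizing noise. Landmark indices are
#' preserved. Noise uses the current RNG state, so wrap calls in
#' `set.seed()` (or use [generate_cohort()]) for reproducibility.
#'
#' @param specimen One-row specimen tibble from [baseline_vault()].
#' @param elongation Vault height multiplier (1 = unchanged).
#' @param obliquity Shear angle in radians; positive tilts the frontal and
#'   parietal postero-superiorly.
#' @param depression_depth Fraction of local vault height removed at the
#'   bandage locus, in `[0, 0.5]`.
#' @param depression_center Arc-fraction position of the depression (0.60 is
#'   bregma; smaller is pre-bregmatic, larger post-bregmatic).
#' @param depression_width Arc-fraction standard deviation of the Gaussian
#'   depression profile (> 0).
#' @param noise_sd Radial jitter standard deviation as a fraction of scale.
#' @return The specimen tibble with deformed `points`.
#' @export
apply_modification <- function(specimen, elongation = 1, obliquity = 0,
                               depression_depth = 0, depression_center = 0.60,
                               depression_width = 0.08, noise_sd = 0) {
  if (depression_depth < 0 || depression_depth > 0.5) {
    stop("apply_modification: depression_depth must be in [0, 0.5]", call. = FALSE)
  }
  if (depression_width <= 0) stop("apply_modification: depression_width must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("apply_modification: noise_sd must be >= 0", call. = FALSE)
  if (elongation <= 0) stop("apply_modification: elongation must be > 0", call. = FALSE)

  pts <- as.matrix(specimen$points[[1]][, c("x", "y")])
  n <- nrow(pts)
  s <- (seq_len(n) - 1) / (n - 1)  # arc fraction along the vault

  y <- pts[, 2] * elongation
  y <- y * (1 - depression_depth * exp(-0.5 * ((s - depression_center) / depression_width)^2))
  x <- pts[, 1] + tan(obliquity) * y
  if (noise_sd > 0) {
    # smooth radial error field: digitizing error on a smooth outline is
    # spatially correlated, so independent per-point jitter (which would
    # dominate the turning angles at 200-point chord lengths) is not a
    # faithful stand-in; a few low-frequency harmonics with total sd
    # noise_sd are
    k <- 1:6
    a <- stats::rnorm(length(k))
    b <- stats::rnorm(length(k))
    f <- colSums(a * cos(outer(pi * k, s)) + b * sin(outer(pi * k, s)))
    f <- f / stats::sd(f) * noise_sd
    x <- x * (1 + f)
    y <- y * (1 + f)
  }
  out <- specimen
  out$points[[1]] <- tibble::tibble(x = x, y = y)
  out
}

#' Default cohort presets for the three study conditions
#'
#' Parameter distributions emulating the three morphologies: `modern`
#' (unmodified shallow vaults, digitizing noise only), `hungary`
#' (two-bandage technique: moderate elongation, a bregmatic depression whose
#' position varies from pre- to post-bregmatic, low spreads), and `georgia`
#' (annular binding with diverse styles: a mixture of tall/vertical and
#' oblique components plus a minority depressed component, with wide
#' parameter spreads). Each parameter entry is `c(mean, sd)`.
#'
#' @param n Specimens per cohort (default 20).
#' @return Named list of cohort specs consumable by [generate_cohort()].
#' @export
cohort_presets <- function(n = 20L) {
  list(
    modern = list(
      group = "modern", n = n, noise_sd = 0.005,
      components = list(list(
        weight = 1,
        elongation = c(1.00, 0.04), obliquity = c(0, 0),
        depression_depth = c(0, 0), depression_center = c(0.60, 0),
        depression_width = 0.08))),
    hungary = list(
      group = "hungary", n = n, noise_sd = 0.005,
      components = list(list(
        weight = 1,
        elongation = c(1.25, 0.06), obliquity = c(0.08, 0.04),
        depression_depth = c(0.12, 0.03), depression_center = c(0.62, 0.03),
        depression_width = 0.12))),
    georgia = list(
      group = "georgia", n = n, noise_sd = 0.005,
      components = list(
        list(weight = 0.45,  # tall, vertical annular profile
             elongation = c(1.60, 0.15), obliquity = c(0, 0.05),
             depression_depth = c(0, 0), depression_center = c(0.60, 0),
             depression_width = 0.08),
        list(weight = 0.45,  # oblique annular profile
             elongation = c(1.25, 0.10), obliquity = c(0.35, 0.08),
             depression_depth = c(0, 0), depression_center = c(0.60, 0),
             depression_width = 0.08),
        list(weight = 0.10,  # minority two-bandage style
             elongation = c(1.35, 0.10), obliquity = c(0.05, 0.05),
             depression_depth = c(0.15, 0.05), depression_center = c(0.60, 0.05),
             depression_width = 0.12)))
  )
}

.draw_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a seeded cohort of synthetic cranial outlines
#'
#' Draws per-specimen modification parameters from a cohort spec (see
#' [cohort_presets()]) and applies them to the baseline vault. The cohort is
#' a pure function of the spec and its seed.
#'
#' @param spec A cohort spec: list with `group`, `n`, `seed` (optional here,
#'   can be given via the `seed` argument), `noise_sd`, `components` (list
#'   of mixture components with `weight` and `c(mean, sd)` parameter
#'   entries).
#' @param seed Integer seed (overrides `spec$seed`).
#' @param total_points Outline points per specimen (default 200).
#' @return A specimen tibble (one row per specimen) with an additional
#'   `params` list-column recording the generating parameters.
#' @export
generate_cohort <- function(spec, seed = spec$seed, total_points = 200L) {
  stopifnot(!is.null(spec$group), !is.null(spec$n), spec$n >= 1)
  if (is.null(seed)) stop("generate_cohort: a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  weights <- vapply(spec$components, `[[`, numeric(1), "weight")
  comp_idx <- sample.int(length(spec$components), spec$n, replace = TRUE,
                         prob = weights)
  base <- baseline_vault(total_points, group = spec$group)
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    cm <- spec$components[[comp_idx[i]]]
    pars <- list(
      elongation = .draw_trunc(1, cm$elongation[1], cm$elongation[2], lower = 0.5),
      obliquity = .draw_trunc(1, cm$obliquity[1], cm$obliquity[2],
                              lower = -0.6, upper = 0.6),
      depression_depth = .draw_trunc(1, cm$depression_depth[1], cm$depression_depth[2],
                                     lower = 0, upper = 0.5),
      depression_center = .draw_trunc(1, cm$depression_center[1], cm$depression_center[2],
                                      lower = 0.35, upper = 0.85),
      depression_width = cm$depression_width,
      noise_sd = if (is.null(spec$noise_sd)) 0 else spec$noise_sd
    )
    sp <- base
    sp$id <- sprintf("%s_%03d", spec$group, i)
    sp <- apply_modification(sp,
      elongation = pars$elongation, obliquity = pars$obliquity,
      depression_depth = pars$depression_depth,
      depression_center = pars$depression_center,
      depression_width = pars$depression_width,
      noise_sd = pars$noise_sd)
    sp$params <- list(pars)
    rows[[i]] <- sp
  }
  dplyr::bind_rows(rows)
}

#' Generate the three default cohorts
#'
#' @param n Specimens per group.
#' @param seed Integer base seed; each cohort uses `seed`, `seed + 1`,
#'   `seed + 2` in preset order so groups are independent draws.
#' @param total_points Outline points per specimen.
#' @return A specimen tibble covering the modern, hungary and georgia groups.
#' @export
generate_study_cohorts <- function(n = 20L, seed = 1L, total_points = 200L) {
  presets <- cohort_presets(n)
  dplyr::bind_rows(lapply(seq_along(presets), function(i) {
    generate_cohort(presets[[i]], seed = as.integer(seed) + i - 1L,
                    total_points = total_points)
  }))
}

#' Write a cohort to a TPS file with its sidecar metadata config
#'
#' Emits `<path>.tps` and `<path>.yaml`; the sidecar records the landmark
#' indices and the id-to-group table so [read_cohort()] (or [read_tps()] +
#' [attach_metadata()]) closes the loop for end-to-end runs.
#'
#' @param cohort Specimen tibble from [generate_cohort()].
#' @param path Output path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
cohort_to_tps <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  tps <- paste0(path, ".tps")
  meta <- paste0(path, ".yaml")
  write_tps(tibble::tibble(id = cohort$id, points = cohort$points), tps)
  lm <- cohort$landmarks[[1]]
  yaml::write_yaml(list(
    landmarks = as.list(lm),
    groups = stats::setNames(as.list(cohort$group), cohort$id)
  ), meta)
  invisible(c(tps = tps, meta = meta))
}

#' Read a cohort written by [cohort_to_tps()]
#'
#' @param path Path prefix used in [cohort_to_tps()].
#' @return A specimen tibble.
#' @export
read_cohort <- function(path) {
  recs <- read_tps(paste0(path, ".tps"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  lm <- unlist(meta$landmarks)
  groups <- tibble::tibble(id = names(meta$groups),
                           group = unlist(meta$groups, use.names = FALSE))
  attach_metadata(recs, landmarks = lm[c("occiput", "lambda", "bregma", "glabella")],
                  groups = groups)
}
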