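# default analysis configuration: thresholds of the study procedure
.default_config <- function() {
  list(
    total_points = 200L,
    harmonize_policy = "max",
    harmonize_fixed = NULL,
    gpa_tol = 1e-10,
    gpa_max_iter = 100L,
    p_enter = 0.01,
    p_remove = 0.10,
    max_vars = 6L,
    priors = "equal",
    mahalanobis_alpha = 0.05,
    segment_selection = "all",   # segment runs: all usable eigenshapes
    reselect_in_cv = FALSE
  )
}

.merge_config <- function(config) {
  cfg <- .default_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

# segmentation -> harmonization -> GPA -> per-segment phi, composite vector.
# Segments share joint landmarks; duplicated joints are dropped when segments
# are concatenated into one configuration.
.prepare_phis <- function(specimens, cfg) {
  segs <- split_segments(specimens)
  segs <- harmonize_counts(segs,
                           policy = cfg$harmonize_policy,
                           fixed = cfg$harmonize_fixed)
  counts <- segment_counts(segs)
  ids <- unique(segs$id)
  seg_names <- levels(segs$segment)

  configs <- lapply(ids, function(sid) {
    pieces <- lapply(seg_names, function(sg) {
      as.matrix(segs$points[[which(segs$id == sid & segs$segment == sg)]])
    })
    # drop the joint vertex duplicated at the head of the 2nd and 3rd pieces
    do.call(rbind, c(pieces[1], lapply(pieces[-1], function(m) m[-1, , drop = FALSE])))
  })
  names(configs) <- ids

  ali <- gpa(configs, tol = cfg$gpa_tol, max_iter = cfg$gpa_max_iter)

  # segment row ranges within the concatenated configuration
  ends <- cumsum(c(counts[1], counts[-1] - 1L))
  starts <- c(1L, utils::head(ends, -1L))
  point_ranges <- Map(seq, starts, ends)
  names(point_ranges) <- seg_names

  phi_rows <- lapply(ali$aligned, function(cfg_pts) {
    m <- as.matrix(cfg_pts)
    unlist(lapply(point_ranges, function(rg) {
      phi_transform(m[rg, , drop = FALSE], open = TRUE)$values
    }), use.names = FALSE)
  })
  phis <- do.call(rbind, phi_rows)
  rownames(phis) <- ids

  # phi-column layout: each segment of m points contributes m - 2 values
  lens <- vapply(point_ranges, function(rg) length(rg) - 2L, integer(1))
  ph_ends <- cumsum(lens)
  ph_starts <- c(1L, utils::head(ph_ends, -1L) + 1L)
  layout <- Map(seq, ph_starts, ph_ends)
  names(layout) <- seg_names

  # mean pose per segment (step lengths, start point, circular-mean start
  # heading over aligned specimens) so shape models can be drawn in
  # anatomical orientation rather than an arbitrary one
  poses <- lapply(point_ranges, function(rg) {
    steps <- sapply(ali$aligned, function(cfg_pts) {
      sqrt(rowSums(diff(as.matrix(cfg_pts)[rg, , drop = FALSE])^2))
    })
    starts <- t(sapply(ali$aligned, function(cfg_pts) {
      as.numeric(as.matrix(cfg_pts)[rg[1], ])
    }))
    angles <- vapply(ali$aligned, function(cfg_pts) {
      m <- as.matrix(cfg_pts)[rg[1:2], , drop = FALSE]
      atan2(m[2, 2] - m[1, 2], m[2, 1] - m[1, 1])
    }, numeric(1))
    list(step_lengths = rowMeans(steps),
         start_point = colMeans(starts),
         start_angle = atan2(mean(sin(angles)), mean(cos(angles))))
  })

  groups <- specimens$group[match(ids, specimens$id)]
  list(phis = phis, layout = layout, groups = groups, ids = ids,
       alignment = ali, counts = counts, segments = segs, poses = poses)
}

.variance_table <- function(model, analysis) {
  tbl <- tidy(model)
  tbl$analysis <- analysis
  dplyr::relocate(tbl, "analysis")
}

.discriminant_block <- function(scores, groups, cfg, selection_mode) {
  X <- as.matrix(scores)
  # drop numerically negligible axes (relative eigenscore variance below 1e-8,
  # i.e. rank-deficient directions) before any scatter-matrix work
  v <- apply(X, 2, stats::var)
  usable <- which(v > 1e-8 * max(v))
  if (selection_mode == "stepwise") {
    sel <- stepwise_select(X[, usable, drop = FALSE], groups,
                           cfg$p_enter, cfg$p_remove, cfg$max_vars)
    selected <- usable[sel$selected]
    trace <- sel$trace
    trace$variable <- usable[trace$variable]
    if (!length(selected)) {
      selected <- usable[seq_len(min(length(usable), cfg$max_vars))]
    }
  } else {
    # all usable eigenshapes, capped so the pooled within-group covariance
    # stays nonsingular in every leave-one-out fold (p <= n - 1 - g)
    n <- nrow(X)
    g <- nlevels(factor(groups))
    selected <- usable[seq_len(min(length(usable), n - g - 2L))]
    trace <- NULL
  }
  fit <- fit_classifier(X, groups, selected, priors = cfg$priors)
  cv <- loo_crossvalidate(X, groups, selection = selected,
                          reselect = cfg$reselect_in_cv, priors = cfg$priors,
                          p_enter = cfg$p_enter, p_remove = cfg$p_remove,
                          max_vars = cfg$max_vars)
  list(model = fit, selected = selected, trace = trace,
       resubstitution = fit$tables$resubstitution,
       cross_validation = cv$table,
       mahalanobis = fit$mahalanobis)
}

#' Fit the eigenshape model of a set of outlines
#'
#' The shape-analysis stage on its own: segmentation at the landmarks,
#' semi-landmark harmonization, Procrustes alignment, phi-function
#' conversion, and eigenshape decomposition of the composite phi vectors —
#' without any discriminant step, so it also works on a single cohort
#' (e.g. for parameter-recovery checks).
#'
#' @param specimens Specimen tibble.
#' @param config As in [run_whole_outline()].
#' @return An `eigenshape_model` with segment layout and per-specimen scores.
#' @export
outline_eigenshapes <- function(specimens, config = list()) {
  cfg <- .merge_config(config)
  stopifnot(is.data.frame(specimens), nrow(specimens) >= 3)
  prep <- .prepare_phis(specimens, cfg)
  model <- eigenshape_decompose(prep$phis, layout = prep$layout, groups = prep$groups)
  model$poses <- prep$poses
  model
}

#' Composite phi-functions of a set of outlines
#'
#' Runs the pipeline through segmentation, harmonization, Procrustes
#' alignment and phi conversion, returning the raw specimen-by-variable phi
#' matrix together with the segment column layout — the direct input of
#' [eigenshape_decompose()] and [segment_submodel()].
#'
#' @param specimens Specimen tibble.
#' @param config As in [run_whole_outline()].
#' @return A list: `phis` (matrix with specimen ids as row names), `layout`
#'   (named list of column indices per segment), `groups`, `alignment`
#'   (the `gpa_alignment`), `counts` (harmonized per-segment point counts).
#' @export
outline_phis <- function(specimens, config = list()) {
  cfg <- .merge_config(config)
  stopifnot(is.data.frame(specimens), nrow(specimens) >= 2)
  prep <- .prepare_phis(specimens, cfg)
  prep[c("phis", "layout", "groups", "alignment", "counts", "poses")]
}

#' Whole-outline eigenshape and discriminant analysis
#'
#' Runs the full pipeline on a specimen tibble: segment the vault at its
#' landmarks, harmonize semi-landmark counts, Procrustes-align the
#' concatenated configurations to unit centroid size, convert each aligned
#' segment to its phi-function, decompose the composite phi vectors into
#' eigenshapes, then select discriminating eigenshapes stepwise and report
#' classification, leave-one-out cross-validation, and pairwise Mahalanobis
#' distances.
#'
#' @param specimens Specimen tibble ([attach_metadata()], [generate_cohort()]
#'   or [read_cohort()]).
#' @param config Named list overriding the defaults: `harmonize_policy`
#'   ("max"/"fixed"), `harmonize_fixed`, `gpa_tol`, `gpa_max_iter`,
#'   `p_enter` (0.01), `p_remove` (0.10), `max_vars` (6), `priors`,
#'   `reselect_in_cv`.
#' @return An object of class `analysis_report`: list with `eigenshape`
#'   (the fitted `eigenshape_model`), `variance_table`, `scores_table`,
#'   `classification` (resubstitution/cross-validation tibbles + selected
#'   axes), `mahalanobis_table`, `alignment`, `provenance`.
#' @export
run_whole_outline <- function(specimens, config = list()) {
  cfg <- .merge_config(config)
  stopifnot(is.data.frame(specimens), nrow(specimens) >= 3)
  if (any(table(specimens$group) < 3)) {
    stop("run_whole_outline: every group needs at least 3 specimens", call. = FALSE)
  }
  prep <- .prepare_phis(specimens, cfg)
  model <- eigenshape_decompose(prep$phis, layout = prep$layout, groups = prep$groups)
  model$poses <- prep$poses
  disc <- .discriminant_block(model$scores[, -(1:2)], prep$groups, cfg, "stepwise")

  structure(list(
    eigenshape = model,
    alignment = prep$alignment,
    variance_table = .variance_table(model, "whole_outline"),
    scores_table = model$scores,
    classification = list(
      selected = disc$selected,
      stepwise_trace = disc$trace,
      resubstitution = disc$resubstitution,
      cross_validation = disc$cross_validation
    ),
    mahalanobis_table = disc$mahalanobis,
    discriminant = disc$model,
    provenance = list(config = cfg, n = nrow(specimens),
                      groups = table(specimens$group),
                      segment_counts = as.list(prep$counts),
                      gpa_iterations = prep$alignment$iterations,
                      version = as.character(utils::packageVersion("eigenvault")))
  ), class = "analysis_report")
}

#' Per-segment eigenshape and discriminant analyses
#'
#' Shares the segmentation, harmonization and Procrustes alignment with the
#' whole-outline analysis, then fits an independent eigenshape submodel per
#' segment (frontal, parietal, occipital) and a discriminant analysis per
#' segment. Segment runs default to using all usable eigenshapes (capped so
#' the pooled covariance stays nonsingular) rather than stepwise selection;
#' set `config$segment_selection = "stepwise"` for the stepwise variant.
#'
#' @param specimens Specimen tibble; typically restricted to the two
#'   modified groups via the `groups` argument.
#' @param config As in [run_whole_outline()].
#' @param groups Optional character vector of group labels to keep.
#' @return An object of class `segment_report`: named list per segment of
#'   lists with `eigenshape`, `variance_table`, `classification`,
#'   `mahalanobis_table`; plus `provenance`.
#' @export
run_segments <- function(specimens, config = list(), groups = NULL) {
  cfg <- .merge_config(config)
  if (!is.null(groups)) specimens <- specimens[specimens$group %in% groups, ]
  stopifnot(nrow(specimens) >= 3)
  if (any(table(specimens$group) < 3)) {
    stop("run_segments: every group needs at least 3 specimens", call. = FALSE)
  }
  prep <- .prepare_phis(specimens, cfg)
  out <- list()
  for (seg in names(prep$layout)) {
    sub <- segment_submodel(prep$phis, prep$layout, seg, groups = prep$groups)
    sub$poses <- prep$poses[seg]
    disc <- .discriminant_block(sub$scores[, -(1:2)], prep$groups, cfg,
                                cfg$segment_selection)
    out[[seg]] <- list(
      eigenshape = sub,
      variance_table = .variance_table(sub, seg),
      classification = list(
        selected = disc$selected,
        resubstitution = disc$resubstitution,
        cross_validation = disc$cross_validation
      ),
      mahalanobis_table = disc$mahalanobis
    )
  }
  out$provenance <- list(config = cfg, n = nrow(specimens),
                         groups = table(specimens$group),
                         segment_counts = as.list(prep$counts),
                         version = as.character(utils::packageVersion("eigenvault")))
  structure(out, class = "segment_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Whole-outline eigenshape analysis report\n")
  cat("  specimens:", x$provenance$n, " groups:",
      paste(names(x$provenance$groups), x$provenance$groups, sep = "=", collapse = " "), "\n")
  vf <- x$eigenshape$variance_fractions
  cat(sprintf("  ES1 %.1f%%  ES2 %.1f%%  ES3 %.1f%% (cumulative %.1f%%)\n",
              100 * vf[1], 100 * vf[2], 100 * vf[3], 100 * sum(vf[1:3])))
  cat("  selected eigenshapes:", paste(x$classification$selected, collapse = ", "), "\n")
  cat("  resubstitution:\n")
  print(x$classification$resubstitution)
  cat("  cross-validation:\n")
  print(x$classification$cross_validation)
  invisible(x)
}

#' Write an analysis report to JSON and CSV files
#'
#' Writes `report.json` (canonical, full precision) plus CSV renderings of
#' the variance, score, classification and Mahalanobis tables into `dir`.
#'
#' @param report `analysis_report` or `segment_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the JSON file.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report, "analysis_report")) {
    obj <- list(
      variance_table = report$variance_table,
      scores_table = report$scores_table,
      classification = list(
        selected = report$classification$selected,
        resubstitution = report$classification$resubstitution,
        cross_validation = report$classification$cross_validation
      ),
      mahalanobis_table = report$mahalanobis_table,
      provenance = report$provenance[c("n", "segment_counts", "gpa_iterations", "version")]
    )
    utils::write.csv(report$variance_table, file.path(dir, "variance.csv"), row.names = FALSE)
    utils::write.csv(report$scores_table, file.path(dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(report$classification$resubstitution,
                     file.path(dir, "resubstitution.csv"), row.names = FALSE)
    utils::write.csv(report$classification$cross_validation,
                     file.path(dir, "cross_validation.csv"), row.names = FALSE)
    utils::write.csv(report$mahalanobis_table,
                     file.path(dir, "mahalanobis.csv"), row.names = FALSE)
  } else {
    segs <- setdiff(names(report), "provenance")
    obj <- lapply(report[segs], function(s) list(
      variance_table = s$variance_table,
      classification = list(
        selected = s$classification$selected,
        resubstitution = s$classification$resubstitution,
        cross_validation = s$classification$cross_validation
      ),
      mahalanobis_table = s$mahalanobis_table
    ))
    obj$provenance <- report$provenance[c("n", "segment_counts", "version")]
    for (seg in segs) {
      utils::write.csv(report[[seg]]$variance_table,
                       file.path(dir, paste0(seg, "_variance.csv")), row.names = FALSE)
      utils::write.csv(report[[seg]]$classification$resubstitution,
                       file.path(dir, paste0(seg, "_resubstitution.csv")), row.names = FALSE)
      utils::write.csv(report[[seg]]$classification$cross_validation,
                       file.path(dir, paste0(seg, "_cross_validation.csv")), row.names = FALSE)
    }
  }
  js <- file.path(dir, "report.json")
  jsonlite::write_json(obj, js, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(js)
}
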