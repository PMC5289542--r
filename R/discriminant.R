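# scatter matrices on a variable subset
.scatter <- function(X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  grand <- colMeans(X)
  Tm <- crossprod(sweep(X, 2, grand))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  list(W = W, T = Tm, g = g)
}

# lambda = det(W)/det(T) computed as det(solve(T, W)): the eigenvalues of
# T^-1 W lie in (0, 1], which avoids determinant underflow when many axes
# carry tiny variance
.wilks_stat <- function(X, groups) {
  s <- .scatter(X, groups)
  if (rcond(s$T) < 1e-12) return(NA_real_)
  lam <- det(solve(s$T, s$W))
  min(max(lam, 0), 1)
}

#' Wilks' lambda and Rao's F for group separation
#'
#' Wilks' lambda is the ratio of the determinant of the within-group scatter
#' matrix to that of the total scatter matrix on the chosen variables; values
#' near 0 indicate strong group separation, 1 indicates none. Significance
#' uses Rao's F approximation (exact for 1 or 2 variables, or 2 groups).
#'
#' @param data Numeric matrix or data frame of scores (specimens in rows).
#' @param groups Group labels, one per row.
#' @param subset Integer or character vector of columns to use; default all.
#' @return A list: `lambda`, `statistic` (F), `df1`, `df2`, `p.value`,
#'   `n`, `n_groups`, `n_vars`.
#' @examples
#' wilks_lambda(data.frame(x = c(0, 1, 2, 3)), c("a", "a", "b", "b"))
#' @export
wilks_lambda <- function(data, groups, subset = NULL) {
  X <- as.matrix(as.data.frame(data))
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  g <- factor(groups)
  n <- nrow(X)
  ng <- nlevels(g)
  p <- ncol(X)
  stopifnot(ng >= 2, all(table(g) >= 2), p >= 1)

  s <- .scatter(X, g)
  if (rcond(s$T) < 1e-12 || rcond(s$W) < 1e-14) {
    stop("wilks_lambda: singular scatter matrix; use fewer variables", call. = FALSE)
  }
  lambda <- det(solve(s$T, s$W))
  lambda <- min(max(lambda, 0), 1)

  q <- ng - 1
  denom <- p^2 + q^2 - 5
  s_exp <- if (denom > 0) sqrt((p^2 * q^2 - 4) / denom) else 1
  m <- n - 1 - (p + ng) / 2
  df1 <- p * q
  df2 <- m * s_exp - df1 / 2 + 1
  lam_s <- lambda^(1 / s_exp)
  Fst <- if (lambda >= 1) 0 else ((1 - lam_s) / lam_s) * (df2 / df1)
  pval <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  list(lambda = lambda, statistic = Fst, df1 = df1, df2 = df2,
       p.value = pval, n = n, n_groups = ng, n_vars = p)
}

# partial F for entering variable x given current subset S (possibly empty)
.f_enter <- function(X, g, S, x) {
  n <- nrow(X)
  ng <- nlevels(g)
  lam_S <- if (length(S)) .wilks_stat(X[, S, drop = FALSE], g) else 1
  lam_Sx <- .wilks_stat(X[, c(S, x), drop = FALSE], g)
  if (is.na(lam_S) || is.na(lam_Sx) || lam_Sx <= 0) return(NULL)
  df2 <- n - ng - length(S)
  if (df2 < 1) return(NULL)
  Fst <- (lam_S / lam_Sx - 1) * df2 / (ng - 1)
  list(lambda = lam_Sx, statistic = Fst,
       p.value = stats::pf(Fst, ng - 1, df2, lower.tail = FALSE))
}

#' Stepwise Wilks'-lambda variable selection
#'
#' Classic stepwise discriminant selection: at each step the candidate
#' variable minimizing the resulting Wilks' lambda is entered if the partial
#' F-to-enter is significant at `p_enter`; after every entry, any included
#' variable whose partial F-to-remove exceeds `p_remove` is dropped.
#' Selection stops when no candidate qualifies or `max_vars` variables are
#' in the model. Ties on lambda are broken toward the lower column index, so
#' the procedure is deterministic.
#'
#' @param data Numeric matrix or data frame of scores.
#' @param groups Group labels.
#' @param p_enter Significance required to enter a variable (default 0.01).
#' @param p_remove Significance above which an entered variable is removed
#'   (default 0.10).
#' @param max_vars Maximum number of variables retained (default 6).
#' @return A list: `selected` (integer column indices in entry order, may be
#'   empty), `trace` (tibble: step, action, variable, lambda, statistic,
#'   p.value).
#' @export
stepwise_select <- function(data, groups, p_enter = 0.01, p_remove = 0.10,
                            max_vars = 6L) {
  X <- as.matrix(as.data.frame(data))
  g <- factor(groups)
  n <- nrow(X)
  ng <- nlevels(g)
  S <- integer(0)
  trace <- list()
  step <- 0L

  repeat {
    if (length(S) >= max_vars) break
    cand <- setdiff(seq_len(ncol(X)), S)
    if (!length(cand)) break
    best <- NULL
    best_x <- NA_integer_
    for (x in cand) {
      fe <- .f_enter(X, g, S, x)
      if (is.null(fe)) next
      if (is.null(best) || fe$lambda < best$lambda - 1e-15) {
        best <- fe
        best_x <- x
      }
    }
    if (is.null(best) || best$p.value >= p_enter) break
    S <- c(S, best_x)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, action = "enter", variable = best_x,
      lambda = best$lambda, statistic = best$statistic, p.value = best$p.value)

    # removal pass
    repeat {
      if (length(S) < 2L) break
      worst <- NULL
      worst_x <- NA_integer_
      for (x in S) {
        fr <- .f_enter(X, g, setdiff(S, x), x)
        if (is.null(fr)) next
        if (is.null(worst) || fr$p.value > worst$p.value) {
          worst <- fr
          worst_x <- x
        }
      }
      if (is.null(worst) || worst$p.value <= p_remove) break
      S <- setdiff(S, worst_x)
      step <- step + 1L
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, action = "remove", variable = worst_x,
        lambda = .wilks_stat(X[, S, drop = FALSE], g),
        statistic = worst$statistic, p.value = worst$p.value)
    }
  }

  trace <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(step = integer(), action = character(), variable = integer(),
                   lambda = numeric(), statistic = numeric(), p.value = numeric())
  if (!length(S)) {
    message("stepwise_select: no variable met the entry criterion; empty selection")
  }
  list(selected = S, trace = trace)
}

# pooled within-group covariance and group means on a subset
.pooled_stats <- function(X, g) {
  n <- nrow(X)
  ng <- nlevels(g)
  means <- do.call(rbind, lapply(levels(g),
                                 function(lev) colMeans(X[g == lev, , drop = FALSE])))
  rownames(means) <- levels(g)
  W <- .scatter(X, g)$W
  Sp <- W / (n - ng)
  list(means = means, pooled = Sp, counts = as.integer(table(g)))
}

.confusion <- function(truth, predicted) {
  levs <- levels(truth)
  tab <- table(truth = truth, predicted = factor(predicted, levels = levs))
  acc <- 100 * diag(tab) / rowSums(tab)
  tbl <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "group")
  tbl$accuracy_pct <- round(as.numeric(acc), 1)
  tbl
}

# lightweight pooled-covariance LDA fit (no diagnostics); used by both
# fit_classifier and the leave-one-out loop
.fit_lda <- function(X0, g, selection, priors) {
  X <- X0[, selection, drop = FALSE]
  st <- .pooled_stats(X, g)
  Sinv <- tryCatch(solve(st$pooled), error = function(e)
    stop("singular pooled covariance; use fewer variables", call. = FALSE))
  pri <- if (identical(priors, "equal")) {
    rep(1 / nlevels(g), nlevels(g))
  } else if (identical(priors, "proportional")) {
    st$counts / sum(st$counts)
  } else {
    stopifnot(length(priors) == nlevels(g))
    priors / sum(priors)
  }
  names(pri) <- levels(g)
  structure(list(
    selected = selection,
    group_means = st$means,
    pooled_covariance = st$pooled,
    pooled_inverse = Sinv,
    priors = pri,
    levels = levels(g),
    counts = stats::setNames(st$counts, levels(g)),
    n = nrow(X)
  ), class = "discriminant_model")
}

#' Fit a linear discriminant classifier on selected eigenshapes
#'
#' Gaussian linear discriminant rule with pooled within-group covariance:
#' each specimen is assigned to the group maximizing
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log prior_k`. With equal priors and
#' two groups this reduces to nearest-Mahalanobis-mean assignment. The
#' resubstitution confusion table, Wilks' lambda of the selected variables,
#' and pairwise Mahalanobis distances are computed at fit time.
#'
#' @param data Numeric matrix or data frame of scores.
#' @param groups Group labels.
#' @param selection Columns to use (default: all).
#' @param priors `"equal"` (default), `"proportional"`, or a numeric vector.
#' @return An object of class `discriminant_model` with fields `selected`,
#'   `group_means`, `pooled_covariance`, `priors`, `wilks`, `tables`
#'   (element `resubstitution`), `mahalanobis`, `levels`, `n`.
#' @export
fit_classifier <- function(data, groups, selection = NULL, priors = "equal") {
  X0 <- as.matrix(as.data.frame(data))
  g <- factor(groups)
  if (is.null(selection)) selection <- seq_len(ncol(X0))
  stopifnot(length(selection) >= 1)
  model <- tryCatch(.fit_lda(X0, g, selection, priors), error = function(e)
    stop("fit_classifier: ", conditionMessage(e), call. = FALSE))

  pred <- predict(model, X0)
  model$tables <- list(resubstitution = .confusion(g, pred))
  model$wilks <- wilks_lambda(X0, g, subset = selection)
  model$mahalanobis <- mahalanobis_pairwise(X0, g, selection = selection)
  model
}

#' Classify new specimens with a fitted discriminant model
#'
#' @param object A `discriminant_model`.
#' @param newdata Score matrix/data frame on the full (unselected) variable
#'   set, or already restricted to the selected columns.
#' @param ... Unused.
#' @return Factor of predicted group labels.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))
  if (ncol(X) != length(object$selected)) X <- X[, object$selected, drop = FALSE]
  M <- object$group_means
  Sinv <- object$pooled_inverse
  disc <- X %*% Sinv %*% t(M)
  disc <- sweep(disc, 2, 0.5 * rowSums((M %*% Sinv) * M))
  disc <- sweep(disc, 2, log(object$priors), FUN = "+")
  factor(object$levels[max.col(disc, ties.method = "first")],
         levels = object$levels)
}

#' Leave-one-out cross-validated classification
#'
#' Classifies each specimen with a discriminant model fitted on all other
#' specimens. By default the variable selection is made once on the full
#' data and reused inside every fold (the common presentation of stepwise
#' discriminant cross-validation tables); `reselect = TRUE` instead reruns
#' the stepwise selection within each fold, a stricter protocol.
#'
#' @param data Score matrix/data frame.
#' @param groups Group labels (every group needs >= 3 specimens).
#' @param selection Columns to use when `reselect = FALSE`; default: stepwise
#'   selection on the full data with the supplied thresholds.
#' @param reselect Rerun stepwise selection in each fold.
#' @param priors As in [fit_classifier()].
#' @param p_enter,p_remove,max_vars Stepwise thresholds used when selecting.
#' @return A list: `table` (cross-validated confusion tibble with
#'   `accuracy_pct`), `predicted` (factor), `selection`.
#' @export
loo_crossvalidate <- function(data, groups, selection = NULL, reselect = FALSE,
                              priors = "equal", p_enter = 0.01, p_remove = 0.10,
                              max_vars = 6L) {
  X <- as.matrix(as.data.frame(data))
  g <- factor(groups)
  if (any(table(g) < 3)) {
    stop("loo_crossvalidate: every group needs at least 3 specimens", call. = FALSE)
  }
  if (is.null(selection) && !reselect) {
    selection <- stepwise_select(X, g, p_enter, p_remove, max_vars)$selected
    if (!length(selection)) selection <- seq_len(min(ncol(X), max_vars))
  }
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    sel_i <- if (reselect) {
      s <- stepwise_select(X[-i, , drop = FALSE], g[-i], p_enter, p_remove, max_vars)$selected
      if (length(s)) s else seq_len(min(ncol(X), max_vars))
    } else selection
    fit <- .fit_lda(X[-i, , drop = FALSE], droplevels(g[-i]), sel_i, priors)
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE]))
  }
  pred <- factor(pred, levels = levels(g))
  list(table = .confusion(g, pred), predicted = pred, selection = selection)
}

#' Pairwise Mahalanobis distances between group means
#'
#' Squared Mahalanobis distance between each pair of group means under the
#' pooled within-group covariance, with the Hotelling-type F statistic
#' (degrees of freedom p and n - g - p + 1) and its p-value.
#'
#' @param data Score matrix/data frame.
#' @param groups Group labels.
#' @param selection Columns to use; default all.
#' @return A tibble: `group1`, `group2`, `d2`, `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
mahalanobis_pairwise <- function(data, groups, selection = NULL) {
  X <- as.matrix(as.data.frame(data))
  g <- factor(groups)
  if (is.null(selection)) selection <- seq_len(ncol(X))
  X <- X[, selection, drop = FALSE]
  st <- .pooled_stats(X, g)
  Sinv <- tryCatch(solve(st$pooled), error = function(e)
    stop("mahalanobis_pairwise: singular pooled covariance", call. = FALSE))
  n <- nrow(X)
  ng <- nlevels(g)
  p <- ncol(X)
  levs <- levels(g)
  out <- list()
  for (i in seq_len(ng - 1)) {
    for (j in seq((i + 1), ng)) {
      dmu <- st$means[i, ] - st$means[j, ]
      d2 <- drop(t(dmu) %*% Sinv %*% dmu)
      ni <- st$counts[i]
      nj <- st$counts[j]
      df2 <- n - ng - p + 1
      Fst <- d2 * (ni * nj * df2) / ((ni + nj) * p * (n - ng))
      pv <- if (df2 >= 1) stats::pf(Fst, p, df2, lower.tail = FALSE) else NA_real_
      out[[length(out) + 1L]] <- tibble::tibble(
        group1 = levs[i], group2 = levs[j], d2 = d2,
        statistic = Fst, df1 = p, df2 = df2, p.value = pv)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Linear discriminant model on ", length(x$selected), " variable(s): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  Wilks' lambda = ", format(x$wilks$lambda, digits = 4),
      " (F = ", format(x$wilks$statistic, digits = 4),
      ", p = ", format(x$wilks$p.value, digits = 3), ")\n", sep = "")
  cat("  resubstitution table:\n")
  print(x$tables$resubstitution)
  invisible(x)
}

#' @export
tidy.discriminant_model <- function(x, ...) {
  tbl <- x$tables$resubstitution
  tbl
}

#' @export
glance.discriminant_model <- function(x, ...) {
  tab <- x$tables$resubstitution
  num <- as.matrix(tab[, setdiff(names(tab), c("group", "accuracy_pct"))])
  tibble::tibble(
    n = x$n,
    n_groups = length(x$levels),
    n_selected = length(x$selected),
    wilks_lambda = x$wilks$lambda,
    wilks_p = x$wilks$p.value,
    overall_accuracy_pct = round(100 * sum(diag(num)) / sum(num), 1)
  )
}
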