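#' Read a TPS landmark/outline file
#'
#' Parses the plain-text TPS format produced by the tpsDig family of
#' digitizing tools. Both `LM=`-headed and `POINTS=`-headed blocks are
#' accepted; when a record carries `CURVES=` sub-blocks (outline digitizing
#' mode), the curve points are concatenated after the landmark points in file
#' order. A `SCALE=` line, if present, multiplies the coordinates on load so
#' that all records are in canonical units.
#'
#' Parsing is tolerant of trailing whitespace, blank lines, and CR/LF line
#' endings. Unrecognized `KEY=value` lines are preserved verbatim in the
#' `extras` list-column so that [write_tps()] round-trips them.
#'
#' @param source Path to a TPS file, or a character vector of lines (useful
#'   for testing and for text already in memory).
#' @return A tibble with one row per record and columns `id` (character),
#'   `image` (character, `NA` if absent), `scale` (numeric, `NA` if absent;
#'   already applied to the coordinates), `n_points` (integer), `points`
#'   (list of two-column `x`/`y` tibbles) and `extras` (list of character
#'   vectors of preserved lines).
#' @seealso [write_tps()], [attach_metadata()]
#' @examples
#' recs <- read_tps(c("LM=2", "0 0", "1 0", "ID=a"))
#' recs$points[[1]]
#' @export
read_tps <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- sub("[ \t]+$", "", lines)

  recs <- list()
  i <- 1L
  n <- length(lines)
  is_blank <- function(x) !nzchar(trimws(x))
  header_rx <- "^[ \t]*(LM|POINTS)[ \t]*=[ \t]*([0-9]+)[ \t]*$"

  while (i <= n) {
    if (is_blank(lines[i])) {
      i <- i + 1L
      next
    }
    m <- regmatches(lines[i], regexec(header_rx, lines[i]))[[1]]
    if (length(m) == 0L) {
      stop("tps parse error at line ", i, ": expected an LM= or POINTS= header, got: ",
           dQuote(lines[i]), call. = FALSE)
    }
    declared <- as.integer(m[3])
    i <- i + 1L

    xs <- numeric(0)
    ys <- numeric(0)
    id <- NA_character_
    image <- NA_character_
    scale <- NA_real_
    extras <- character(0)
    curves_left <- 0L
    curve_declared <- 0L

    repeat {
      if (i > n) break
      ln <- lines[i]
      if (is_blank(ln)) {
        i <- i + 1L
        next
      }
      if (grepl(header_rx, ln) && curves_left == 0L) break
      if (grepl("^[ \t]*CURVES[ \t]*=[ \t]*([0-9]+)[ \t]*$", ln)) {
        curves_left <- as.integer(sub("^[ \t]*CURVES[ \t]*=[ \t]*([0-9]+)[ \t]*$", "\\1", ln))
        i <- i + 1L
        next
      }
      if (curves_left > 0L && grepl(header_rx, ln)) {
        # POINTS= sub-block inside a CURVES group
        curve_declared <- curve_declared +
          as.integer(regmatches(ln, regexec(header_rx, ln))[[1]][3])
        curves_left <- curves_left - 1L
        i <- i + 1L
        next
      }
      if (grepl("^[ \t]*ID[ \t]*=", ln)) {
        id <- trimws(sub("^[ \t]*ID[ \t]*=", "", ln))
        i <- i + 1L
        next
      }
      if (grepl("^[ \t]*IMAGE[ \t]*=", ln)) {
        image <- trimws(sub("^[ \t]*IMAGE[ \t]*=", "", ln))
        i <- i + 1L
        next
      }
      if (grepl("^[ \t]*SCALE[ \t]*=", ln)) {
        scale <- suppressWarnings(as.numeric(trimws(sub("^[ \t]*SCALE[ \t]*=", "", ln))))
        if (is.na(scale) || scale <= 0) {
          stop("tps parse error at line ", i, ": SCALE must be a positive number",
               call. = FALSE)
        }
        i <- i + 1L
        next
      }
      if (grepl("^[ \t]*[A-Za-z][A-Za-z0-9_]*[ \t]*=", ln)) {
        extras <- c(extras, trimws(ln))
        i <- i + 1L
        next
      }
      toks <- strsplit(trimws(ln), "[ \t,]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) != 2L || anyNA(vals)) {
        stop("tps parse error at line ", i, ": expected two numeric coordinates, got: ",
             dQuote(ln), call. = FALSE)
      }
      xs <- c(xs, vals[1])
      ys <- c(ys, vals[2])
      i <- i + 1L
    }

    expected <- declared + curve_declared
    if (length(xs) != expected) {
      stop("tps parse error in record ", if (is.na(id)) length(recs) + 1L else dQuote(id),
           ": declared ", expected, " points but found ", length(xs), call. = FALSE)
    }
    if (length(xs) && !all(is.finite(xs) & is.finite(ys))) {
      stop("tps parse error in record ", if (is.na(id)) length(recs) + 1L else dQuote(id),
           ": non-finite coordinate", call. = FALSE)
    }
    if (!is.na(scale)) {
      xs <- xs * scale
      ys <- ys * scale
    }
    recs[[length(recs) + 1L]] <- list(
      id = if (is.na(id)) paste0("record_", length(recs) + 1L) else id,
      image = image, scale = scale, n_points = length(xs),
      points = tibble::tibble(x = xs, y = ys), extras = extras
    )
  }

  tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    image = vapply(recs, `[[`, character(1), "image"),
    scale = vapply(recs, `[[`, numeric(1), "scale"),
    n_points = vapply(recs, `[[`, integer(1), "n_points"),
    points = lapply(recs, `[[`, "points"),
    extras = lapply(recs, `[[`, "extras")
  )
}

#' Write records to a TPS file
#'
#' Emits the tpsDig `LM=` dialect. Coordinates are written with 12
#' significant digits, which round-trips through [read_tps()] at emitted
#' precision. If a record carries a `scale`, coordinates are divided by it on
#' output and a `SCALE=` line is written, mirroring the multiplication
#' applied on load.
#'
#' @param records A tibble as returned by [read_tps()] (columns `id`,
#'   `points`; optionally `image`, `scale`, `extras`).
#' @param sink Path to write to, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of emitted lines.
#' @export
write_tps <- function(records, sink = NULL) {
  stopifnot(is.data.frame(records), all(c("id", "points") %in% names(records)))
  out <- character(0)
  for (r in seq_len(nrow(records))) {
    pts <- records$points[[r]]
    if (nrow(pts) && !all(is.finite(pts$x) & is.finite(pts$y))) {
      stop("write_tps: non-finite coordinate in record ", dQuote(records$id[r]),
           call. = FALSE)
    }
    scale <- if ("scale" %in% names(records)) records$scale[r] else NA_real_
    xs <- pts$x
    ys <- pts$y
    if (!is.na(scale)) {
      xs <- xs / scale
      ys <- ys / scale
    }
    out <- c(out, sprintf("LM=%d", nrow(pts)),
             sprintf("%.12g %.12g", xs, ys),
             paste0("ID=", records$id[r]))
    if ("image" %in% names(records) && !is.na(records$image[r])) {
      out <- c(out, paste0("IMAGE=", records$image[r]))
    }
    if (!is.na(scale)) {
      out <- c(out, sprintf("SCALE=%.12g", scale))
    }
    if ("extras" %in% names(records) && length(records$extras[[r]])) {
      out <- c(out, records$extras[[r]])
    }
  }
  if (!is.null(sink)) writeLines(out, sink)
  invisible(out)
}

#' Attach group labels and landmark anchors to TPS records
#'
#' The TPS format does not standardize where anatomical landmarks sit within
#' an outline, nor group membership, so both come from a sidecar
#' configuration. The four anchors are, in traversal order (anti-clockwise in
#' left lateral view): the occiput point on the cranial base line, lambda,
#' bregma, and glabella.
#'
#' @param records Tibble from [read_tps()].
#' @param landmarks Either an integer vector of length 4 (1-based indices
#'   into each record's points, applied to all records), or a data frame
#'   with columns `id`, `occiput`, `lambda`, `bregma`, `glabella` giving
#'   per-specimen indices.
#' @param groups Either a named character vector mapping id prefixes (regular
#'   expressions anchored at the start) to group labels, e.g.
#'   `c(GEO = "georgia", HUN = "hungary")`, or a data frame with columns
#'   `id` and `group`.
#' @return A tibble of outline specimens with columns `id`, `group`,
#'   `points` (list of x/y tibbles) and `landmarks` (list of named integer
#'   vectors `occiput`, `lambda`, `bregma`, `glabella`).
#' @examples
#' recs <- read_tps(c("LM=4", "0 0", "1 1", "2 1", "3 0", "ID=GEO-1"))
#' attach_metadata(recs, landmarks = c(1, 2, 3, 4), groups = c(GEO = "georgia"))
#' @export
attach_metadata <- function(records, landmarks, groups) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)

  lm_for <- function(id) {
    if (is.data.frame(landmarks)) {
      row <- landmarks[landmarks$id == id, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop("attach_metadata: no landmark entry for specimen ", dQuote(id),
             call. = FALSE)
      }
      c(occiput = as.integer(row$occiput), lambda = as.integer(row$lambda),
        bregma = as.integer(row$bregma), glabella = as.integer(row$glabella))
    } else {
      lm <- as.integer(landmarks)
      stopifnot(length(lm) == 4L)
      names(lm) <- c("occiput", "lambda", "bregma", "glabella")
      lm
    }
  }

  group_for <- function(id) {
    if (is.data.frame(groups)) {
      g <- groups$group[groups$id == id]
      if (length(g) == 1L) g else NA_character_
    } else {
      hit <- which(vapply(names(groups), function(p) grepl(paste0("^", p), id),
                          logical(1)))
      if (length(hit)) unname(groups[[hit[1]]]) else NA_character_
    }
  }

  ids <- records$id
  glabs <- vapply(ids, group_for, character(1), USE.NAMES = FALSE)
  if (anyNA(glabs)) {
    stop("attach_metadata: no group mapping for id(s): ",
         paste(dQuote(ids[is.na(glabs)]), collapse = ", "), call. = FALSE)
  }

  lms <- lapply(ids, lm_for)
  bad <- character(0)
  for (r in seq_len(n)) {
    lm <- lms[[r]]
    np <- nrow(records$points[[r]])
    ok <- lm["occiput"] >= 1L && lm["occiput"] < lm["lambda"] &&
      lm["lambda"] < lm["bregma"] && lm["bregma"] < lm["glabella"] &&
      lm["glabella"] <= np && np >= 4L
    if (!ok) {
      bad <- c(bad, sprintf(
        "%s (indices %d < %d < %d < %d must be strictly increasing within 1..%d)",
        ids[r], lm["occiput"], lm["lambda"], lm["bregma"], lm["glabella"], np))
    }
  }
  if (length(bad)) {
    stop("attach_metadata: landmark ordering invariant violated for:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }

  tibble::tibble(
    id = ids,
    group = glabs,
    points = records$points,
    landmarks = lms
  )
}
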