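#' Marked point patterns
#'
#' A marked point pattern is a tibble of points — columns `x`, `y`, an
#' optional categorical `mark` and an optional numeric `value` — carrying
#' its rectangular observation window `[0, X) x [0, Y)` (pixel units) as an
#' attribute. It is the central container of the analysis stage: a
#' classified patch grid becomes one point per patch at the patch center,
#' marked with the patch class, and all summary statistics operate on it.
#'
#' @param points data frame with columns `x`, `y` and optionally `mark`
#'   (categorical) and `value` (numeric).
#' @param window numeric `c(xmin, xmax, ymin, ymax)`.
#' @return An `mpp` tibble with a `window` attribute.
#' @examples
#' p <- mpp(data.frame(x = c(1, 3), y = c(1, 2), mark = c("a", "b")),
#'          window = c(0, 4, 0, 4))
#' intensity(p)
#' @export
mpp <- function(points, window) {
  points <- as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop_validation("a point pattern needs columns x and y")
  }
  window <- as.numeric(window)
  if (length(window) != 4L || window[2L] <= window[1L] || window[4L] <= window[3L]) {
    stop_validation("window must be c(xmin, xmax, ymin, ymax) with positive extent")
  }
  if (nrow(points) > 0L) {
    inside <- points$x >= window[1L] & points$x <= window[2L] &
      points$y >= window[3L] & points$y <= window[4L]
    if (!all(inside)) {
      stop_validation("%d point(s) lie outside the window", sum(!inside))
    }
  }
  structure(points, window = window,
            class = c("mpp", class(tibble())))
}

#' @export
print.mpp <- function(x, ...) {
  w <- pattern_window(x)
  cat(sprintf("<marked point pattern> %d point(s) in [%g, %g) x [%g, %g)\n",
              nrow(x), w[1L], w[2L], w[3L], w[4L]))
  if ("mark" %in% names(x) && nrow(x) > 0L) {
    tab <- table(x$mark)
    cat("marks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  NextMethod()
}

#' @rdname mpp
#' @param x an object to coerce / query.
#' @export
pattern_window <- function(x) {
  w <- attr(x, "window")
  if (is.null(w)) stop_validation("pattern has no window attribute; build it with mpp()")
  w
}

window_area <- function(x) {
  w <- pattern_window(x)
  (w[2L] - w[1L]) * (w[4L] - w[3L])
}

window_sides <- function(x) {
  w <- pattern_window(x)
  c(w[2L] - w[1L], w[4L] - w[3L])
}

# Accept an mpp or a plain data frame plus explicit window.
as_mpp <- function(pattern, window = NULL) {
  if (inherits(pattern, "mpp") && is.null(window)) return(pattern)
  mpp(pattern, window %||% attr(pattern, "window") %||%
        stop_validation("supply a window for a plain data frame pattern"))
}

#' Build a marked point pattern from a classified patch grid
#'
#' Replaces each grid cell by a point at its patch center
#' ([patch_center()]) marked with the cell's class, inside the window
#' `[0, n_cols * w) x [0, n_rows * w)`. Optionally restricts to a subset
#' of classes. Points produced this way form a perfect lattice with
#' spacing `w`; summary statistics consequently show strong regularity at
#' range `w` (a step in K, Clark-Evans R near 2) which is a property of
#' the construction, not of the landscape — interpret them at r > w.
#'
#' @param label_grid integer matrix of class labels (n_rows x n_cols), or a
#'   labeled [patch_set()] restricted to one scene.
#' @param w patch size in pixels.
#' @param include_classes subset of classes to keep (default all).
#' @return An [mpp()] with a categorical `mark` column.
#' @examples
#' pattern_from_labels(matrix(c(1, 1, 2, 1), 2, 2), w = 10)
#' @export
pattern_from_labels <- function(label_grid, w = 10, include_classes = NULL) {
  if (inherits(label_grid, "patch_set")) {
    info <- dplyr::filter(label_grid$info, !is.na(.data$label))
    if (dplyr::n_distinct(info$scene_id) > 1L) {
      stop_validation("patch set spans several scenes; filter to one before building a pattern")
    }
    grid <- matrix(NA_integer_, max(info$i) + 1L, max(info$j) + 1L)
    grid[cbind(info$i + 1L, info$j + 1L)] <- info$label
    label_grid <- grid
  }
  stopifnot(is.matrix(label_grid))
  n_rows <- nrow(label_grid); n_cols <- ncol(label_grid)
  cells <- tibble(
    i = rep(seq_len(n_rows) - 1L, times = n_cols),
    j = rep(seq_len(n_cols) - 1L, each = n_rows),
    mark = as.vector(label_grid)
  )
  cells <- dplyr::filter(cells, !is.na(.data$mark))
  if (!is.null(include_classes)) {
    cells <- dplyr::filter(cells, .data$mark %in% include_classes)
    if (nrow(cells) == 0L) warn("no cells carry the requested classes; empty pattern")
  }
  ctr <- patch_center(cells$i, cells$j, w)
  mpp(tibble(x = ctr$x, y = ctr$y, mark = cells$mark),
      window = c(0, n_cols * w, 0, n_rows * w))
}

#' Split a marked pattern into per-mark sub-patterns
#'
#' A marked pattern is a superposition of sub-patterns, one per mark value,
#' all sharing the parent window.
#'
#' @param pattern an [mpp()] with a `mark` column.
#' @return Named list of `mpp`s, one per observed mark.
#' @export
split_by_mark <- function(pattern) {
  pattern <- as_mpp(pattern)
  if (nrow(pattern) == 0L) return(list())
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  marks <- sort(unique(pattern$mark))
  w <- pattern_window(pattern)
  setNames(lapply(marks, function(m) {
    mpp(as_tibble(pattern)[pattern$mark == m, , drop = FALSE], window = w)
  }), as.character(marks))
}

#' Intensity of a point pattern
#'
#' `intensity()` returns the overall intensity lambda = n / |W| (points per
#' unit area); `per_type_intensity()` the per-mark intensities lambda_i,
#' which sum to lambda; `mark_probabilities()` the empirical mark
#' distribution p_l = n_l / n.
#'
#' @param pattern an [mpp()] (or data frame with `window`).
#' @param window window for plain data frames.
#' @return `intensity()`: a number. `per_type_intensity()` and
#'   `mark_probabilities()`: a tibble with one row per mark.
#' @export
intensity <- function(pattern, window = NULL) {
  pattern <- as_mpp(pattern, window)
  a <- window_area(pattern)
  if (a <= 0) stop_validation("window has zero area")
  nrow(pattern) / a
}

#' @rdname intensity
#' @export
per_type_intensity <- function(pattern, window = NULL) {
  pattern <- as_mpp(pattern, window)
  a <- window_area(pattern)
  if (a <= 0) stop_validation("window has zero area")
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  dplyr::count(as_tibble(pattern), .data$mark, name = "n") |>
    dplyr::mutate(intensity = .data$n / a)
}

#' @rdname intensity
#' @export
mark_probabilities <- function(pattern, window = NULL) {
  pattern <- as_mpp(pattern, window)
  if (nrow(pattern) == 0L) stop_validation("mark probabilities of an empty pattern")
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  dplyr::count(as_tibble(pattern), .data$mark, name = "n") |>
    dplyr::mutate(p = .data$n / sum(.data$n))
}

#' Write / read a point pattern as CSV
#'
#' One point per row with header `x,y,mark[,value]`; the window is recorded
#' in a leading comment line `# window xmin xmax ymin ymax` so the file is
#' self-contained.
#'
#' @param pattern an [mpp()].
#' @param path CSV file path.
#' @return `write_pattern()` returns `path` invisibly; `read_pattern()` the
#'   reconstructed [mpp()].
#' @export
write_pattern <- function(pattern, path) {
  pattern <- as_mpp(pattern)
  w <- pattern_window(pattern)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window %.17g %.17g %.17g %.17g", w[1L], w[2L], w[3L], w[4L]), con)
  write.csv(as_tibble(pattern), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# window")) {
    stop_validation("'%s' lacks the '# window xmin xmax ymin ymax' header line", path)
  }
  w <- as.numeric(strsplit(trimws(sub("# window", "", first)), "\\s+")[[1L]])
  pts <- read.csv(path, comment.char = "#")
  mpp(pts, window = w)
}
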