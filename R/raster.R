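#' Raster scenes
#'
#' A `raster_scene` is one co-registered image of the study area: an
#' H x W x C array of finite real intensities plus a scene identifier and an
#' integer time index (0 for the reference acquisition, 1, 2, ... for later
#' passes over the same area). All geometry downstream is in pixel units,
#' with the origin at the top-left corner, x running along columns and y
#' down the rows; windows are half-open `[0, X) x [0, Y)`.
#'
#' @param pixels numeric matrix (H x W, promoted to one channel) or
#'   H x W x C array of finite intensities.
#' @param scene_id opaque identifier string.
#' @param time_index non-negative integer; position of the scene in its
#'   temporal series.
#' @return A `raster_scene` object.
#' @examples
#' sc <- raster_scene(matrix(runif(400), 20, 20))
#' dim(sc$pixels)
#' @export
raster_scene <- function(pixels, scene_id = "scene", time_index = 0L) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop_validation("`pixels` must be an H x W matrix or H x W x C array, got %s dimension(s)",
                    paste(length(dim(pixels)) %||% 1L))
  }
  d <- dim(pixels)
  if (any(d < 1L)) stop_validation("all raster dimensions must be positive, got %s",
                                   paste(d, collapse = " x "))
  bad <- which(!is.finite(pixels))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stop_validation("non-finite pixel at [%d, %d, %d]", idx[1L], idx[2L], idx[3L])
  }
  storage.mode(pixels) <- "double"
  time_index <- check_count(time_index, "time_index", lower = 0L)
  structure(
    list(pixels = pixels, scene_id = as.character(scene_id), time_index = time_index),
    class = "raster_scene"
  )
}

#' @export
print.raster_scene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_scene> %s (t = %d): %d x %d px, %d channel(s), range [%.4g, %.4g]\n",
              x$scene_id, x$time_index, d[1L], d[2L], d[3L],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

scene_dims <- function(scene) {
  d <- dim(scene$pixels)
  list(H = d[1L], W = d[2L], C = d[3L])
}

#' Read a raster scene from disk
#'
#' Supported formats: `png` and `tiff` (read with the \pkg{png} / \pkg{tiff}
#' packages; a GeoTIFF is read as a plain TIFF and only the first `channels`
#' bands are kept), `csv` (a grayscale matrix of intensities) and `rds`
#' (a saved H x W\[ x C\] array). Grayscale inputs are promoted to one
#' channel. The format is guessed from the file extension when not given.
#'
#' @param path file to read.
#' @param format one of `"png"`, `"tiff"`, `"csv"`, `"rds"`, or `NULL` to
#'   guess from the extension.
#' @param channels keep only the first `channels` bands (default all).
#' @param scene_id,time_index metadata attached to the returned scene;
#'   `scene_id` defaults to the file name.
#' @return A [raster_scene()].
#' @export
load_scene <- function(path, format = NULL, channels = NULL,
                       scene_id = NULL, time_index = 0L) {
  if (!file.exists(path)) abort(sprintf("cannot read scene: no such file '%s'", path),
                                class = "markscape_io_error")
  format <- format %||% tolower(tools::file_ext(path))
  if (format %in% c("tif", "geotiff")) format <- "tiff"
  px <- switch(format,
    png  = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    csv  = as.matrix(read.csv(path, header = FALSE)),
    rds  = readRDS(path),
    stop_validation("unsupported scene format '%s'", format)
  )
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  if (!is.array(px) || length(dim(px)) != 3L) {
    stop_validation("'%s' does not contain an H x W or H x W x C raster (got %d dimension(s))",
                    path, length(dim(px)) %||% 1L)
  }
  if (!is.null(channels)) {
    channels <- check_count(channels, "channels", lower = 1L)
    px <- px[, , seq_len(min(channels, dim(px)[3L])), drop = FALSE]
  }
  raster_scene(px, scene_id = scene_id %||% basename(path), time_index = time_index)
}

#' Write a raster scene to disk
#'
#' `rds` preserves intensities bit-exactly; `png` clips to \[0, 1\] and
#' quantizes to 8 bits.
#'
#' @param scene a [raster_scene()].
#' @param path output file; format guessed from the extension unless given.
#' @param format `"rds"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path, format = NULL) {
  stopifnot(inherits(scene, "raster_scene"))
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "rds") {
    saveRDS(scene$pixels, path)
  } else if (format == "png") {
    px <- pmin(pmax(scene$pixels, 0), 1)
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    png::writePNG(px, path)
  } else {
    stop_validation("unsupported output format '%s'", format)
  }
  invisible(path)
}

#' Patch centers in pixel coordinates
#'
#' The point standing in for grid cell (i, j) of a tiling with patch size
#' `w` is the center of the cell's pixel footprint:
#' x = j w + w/2, y = i w + w/2. Indices are zero-based, i down the rows and
#' j along the columns.
#'
#' @param i,j zero-based row / column indices (vectors recycle).
#' @param w patch size in pixels.
#' @return A tibble with columns `x`, `y`.
#' @examples
#' patch_center(0, 0, 10) # (5, 5)
#' @export
patch_center <- function(i, j, w) {
  check_number(w, "w", lower = 1e-12)
  if (any(i < 0) || any(j < 0)) stop_validation("grid indices must be non-negative")
  tibble(x = j * w + w / 2, y = i * w + w / 2)
}

#' Tile a scene into fixed-size patches
#'
#' Cuts the scene into disjoint `w x w` patches on a regular grid of
#' `floor(H/w) x floor(W/w)` cells. Trailing rows/columns that do not fill a
#' complete patch are dropped, so all patches are identically sized and the
#' retained patches tile the cropped scene exactly. Each patch is paired
#' with its center point ([patch_center()]), the coordinate every
#' downstream point-pattern statistic uses.
#'
#' @param scene a [raster_scene()].
#' @param w patch size in pixels; must not exceed either scene dimension.
#' @return A `patch_set`: patches as a `w x w x C x n` array plus a tibble
#'   manifest (`scene_id`, `time_index`, `i`, `j`, `x`, `y`, `label`,
#'   `provenance`), in row-major cell order.
#' @examples
#' sc <- raster_scene(matrix(runif(400), 20, 20))
#' ps <- extract_patch_grid(sc, 10)
#' ps$info[, c("i", "j", "x", "y")]
#' @export
extract_patch_grid <- function(scene, w) {
  stopifnot(inherits(scene, "raster_scene"))
  w <- check_count(w, "w", lower = 1L)
  d <- scene_dims(scene)
  if (w > min(d$H, d$W)) {
    stop_validation("patch size w = %d exceeds the scene's shorter side (%d)",
                    w, min(d$H, d$W))
  }
  n_rows <- d$H %/% w
  n_cols <- d$W %/% w
  cells <- tidyr::expand_grid(i = seq_len(n_rows) - 1L, j = seq_len(n_cols) - 1L)
  # reshape-and-permute tiling: row p within patch, grid row i, column q
  # within patch, grid column j, channel c -> (p, q, c, cell) with cells in
  # row-major (i, then j) order matching `cells`
  cropped <- scene$pixels[seq_len(n_rows * w), seq_len(n_cols * w), , drop = FALSE]
  patches <- aperm(array(cropped, dim = c(w, n_rows, w, n_cols, d$C)),
                   c(1L, 3L, 5L, 4L, 2L))
  dim(patches) <- c(w, w, d$C, n_rows * n_cols)
  ctr <- patch_center(cells$i, cells$j, w)
  info <- tibble(
    scene_id = scene$scene_id, time_index = scene$time_index,
    i = cells$i, j = cells$j, x = ctr$x, y = ctr$y,
    label = NA_integer_, provenance = NA_character_
  )
  patch_set(patches, info, w = w)
}

#' Construct a patch set
#'
#' A `patch_set` couples an array of equally sized image patches with a
#' tibble manifest (one row per patch). It is the unit of data exchanged
#' between the tiling, augmentation and classifier stages.
#'
#' @param patches `w x w x C x n` array.
#' @param info tibble with at least `scene_id`, `i`, `j`; `label` is an
#'   integer class in `0..L-1` or `NA` for unlabeled patches, `provenance`
#'   one of `"manual"`, `"propagated"`, `"pseudo"` or `NA`.
#' @param w patch size (defaults to `dim(patches)[1]`).
#' @return A `patch_set` object.
#' @export
patch_set <- function(patches, info, w = dim(patches)[1L]) {
  stopifnot(is.array(patches), length(dim(patches)) == 4L)
  info <- as_tibble(info)
  if (dim(patches)[4L] != nrow(info)) {
    stop_validation("manifest has %d rows but patch array holds %d patches",
                    nrow(info), dim(patches)[4L])
  }
  if (!all(c("scene_id", "i", "j") %in% names(info))) {
    stop_validation("patch manifest needs columns scene_id, i, j")
  }
  if (!"label" %in% names(info)) info$label <- NA_integer_
  if (!"provenance" %in% names(info)) info$provenance <- NA_character_
  key <- paste(info$scene_id, info$i, info$j)
  if (anyDuplicated(key)) stop_validation("duplicate (scene_id, i, j) in patch manifest")
  structure(list(patches = patches, info = info, w = as.integer(w)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  nl <- sum(!is.na(x$info$label))
  cat(sprintf("<patch_set> %d patch(es) of %d x %d x %d, %d labeled, %d scene(s)\n",
              d[4L], d[1L], d[2L], d[3L], nl, dplyr::n_distinct(x$info$scene_id)))
  invisible(x)
}

n_patches <- function(ps) dim(ps$patches)[4L]

# Row-subset a patch_set, keeping array and manifest aligned.
subset_patches <- function(ps, idx) {
  patch_set(ps$patches[, , , idx, drop = FALSE], ps$info[idx, , drop = FALSE], w = ps$w)
}

# Concatenate patch sets with identical patch geometry.
bind_patch_sets <- function(sets) {
  sets <- sets[vapply(sets, n_patches, 1L) > 0L]
  if (!length(sets)) stop_validation("no patches to bind")
  dims <- vapply(sets, function(s) dim(s$patches)[1:3], numeric(3))
  if (any(dims != dims[, 1L])) stop_validation("patch sets have mismatched patch shapes")
  arr <- array(unlist(lapply(sets, function(s) s$patches), use.names = FALSE),
               dim = c(dims[, 1L], sum(vapply(sets, n_patches, 1L))))
  info <- dplyr::bind_rows(lapply(sets, function(s) s$info))
  patch_set(arr, info, w = sets[[1L]]$w)
}

#' Write / read a patch set
#'
#' Stores the patch array as RDS next to a CSV manifest
#' (`scene_id,time_index,i,j,x,y,label,provenance[,split]`).
#'
#' @param ps a [patch_set()].
#' @param dir output directory (created if missing).
#' @return `write_patch_set()` returns `dir` invisibly; `read_patch_set()`
#'   the reconstructed `patch_set`.
#' @export
write_patch_set <- function(ps, dir) {
  stopifnot(inherits(ps, "patch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ps$patches, file.path(dir, "patches.rds"))
  write.csv(ps$info, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(dir) {
  patches <- readRDS(file.path(dir, "patches.rds"))
  info <- as_tibble(read.csv(file.path(dir, "manifest.csv"),
                             colClasses = c(scene_id = "character")))
  patch_set(patches, info)
}
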