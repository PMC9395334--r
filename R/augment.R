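#' Train/test/validation split specification
#'
#' Fractions must be positive and sum to 1. Assignment is made at the
#' grid-cell level: all temporal copies of a cell (reference and every
#' replicate) land in the same split, which is the only leak-free way to
#' split a multi-temporal stack of near-identical patches.
#'
#' @param train,test,validation split fractions, summing to 1.
#' @param seed integer seed for the cell shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train = 0.7, test = 0.2, validation = 0.1, seed = 1L) {
  fr <- c(train = train, test = test, validation = validation)
  if (any(fr <= 0) || any(fr >= 1)) stop_validation("split fractions must lie in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop_validation("split fractions must sum to 1, got %g", sum(fr))
  structure(list(fractions = fr, seed = as.integer(seed)), class = "split_spec")
}

# Largest-remainder apportionment of n cells to the three splits.
split_sizes <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    # ties broken in declaration order (train, test, validation)
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes
}

# Assign each unique cell (i, j) to a split; returns a tibble (i, j, split).
assign_cells <- function(cells, spec) {
  cells <- dplyr::distinct(cells, .data$i, .data$j)
  n <- nrow(cells)
  sizes <- split_sizes(n, spec$fractions)
  if (any(sizes == 0L)) {
    warn(sprintf("split sizes %s leave at least one split empty at n = %d",
                 paste(sizes, collapse = "/"), n))
  }
  perm <- with_seed(spec$seed, sample.int(n))
  cells$split <- rep(names(spec$fractions), times = sizes)[order(perm)]
  cells
}

#' Propagate reference labels across a co-registered series
#'
#' The temporal augmentation scheme: because every scene in the series
#' images the same landscape, a patch labeled on the reference scene can be
#' assigned the identical label in each replicate. Every labeled reference
#' cell contributes one patch per scene, so `n_labeled` cells and `k`
#' replicates yield exactly `n_labeled * (k + 1)` labeled patches.
#' Reference patches carry provenance `"manual"`, replicate patches
#' `"propagated"`. Split assignment is made once per grid cell and shared
#' by all temporal copies, so no cell straddles splits.
#'
#' @param series a `scene_series` from [generate_series()] (or any list with
#'   `reference`, `replicates`, `w`).
#' @param reference_labels tibble with columns `i`, `j`, `label` (zero-based
#'   grid indices, integer labels in `0..L-1`), or a labeled [patch_set()]
#'   whose manifest provides them.
#' @param split a [split_spec()], or `NULL` for no split column.
#' @return A labeled [patch_set()] covering every scene of the series.
#' @export
propagate_labels <- function(series, reference_labels, split = NULL) {
  labels <- if (inherits(reference_labels, "patch_set")) {
    dplyr::filter(reference_labels$info, !is.na(.data$label))
  } else {
    as_tibble(reference_labels)
  }
  if (!all(c("i", "j", "label") %in% names(labels))) {
    stop_validation("reference labels need columns i, j, label")
  }
  labels <- dplyr::distinct(labels, .data$i, .data$j, .keep_all = TRUE)
  grid_rows <- nrow(series$class_map %||% matrix(0, 0, 0))
  scenes <- series_scenes(series)
  tiled <- purrr::map(scenes, extract_patch_grid, w = series$w)
  nr <- max(tiled[[1L]]$info$i) + 1L
  nc <- max(tiled[[1L]]$info$j) + 1L
  if (any(labels$i < 0 | labels$i >= nr | labels$j < 0 | labels$j >= nc)) {
    stop_validation("reference labels index cells outside the %d x %d grid", nr, nc)
  }
  if (!is.null(split)) labels <- dplyr::left_join(labels, assign_cells(labels, split),
                                                  by = c("i", "j"))
  labeled <- purrr::imap(tiled, function(ps, s) {
    idx <- match(paste(labels$i, labels$j), paste(ps$info$i, ps$info$j))
    out <- subset_patches(ps, idx)
    out$info$label <- as.integer(labels$label)
    out$info$provenance <- if (s == 1L) "manual" else "propagated"
    if (!is.null(split)) out$info$split <- labels$split
    out
  })
  bind_patch_sets(labeled)
}

#' Expand a dataset by classifier pseudo-labeling
#'
#' Tiles each scene, classifies every patch with a trained model, and keeps
#' the argmax label. Patches whose top class probability falls below
#' `min_confidence` are dropped; the default (`NULL`) keeps all. Output
#' patches carry provenance `"pseudo"`.
#'
#' @param model a trained [patch_cnn][build_classifier()].
#' @param scenes a list of [raster_scene()]s (or a single scene).
#' @param w patch size in pixels.
#' @param min_confidence drop patches with top probability below this, or
#'   `NULL` to keep all.
#' @return A labeled [patch_set()] of pseudo-labeled patches.
#' @export
pseudo_label_expand <- function(model, scenes, w, min_confidence = NULL) {
  if (inherits(scenes, "raster_scene")) scenes <- list(scenes)
  if (!isTRUE(model$trained)) stop_state("classifier has not been trained")
  out <- purrr::map(scenes, function(sc) {
    ps <- extract_patch_grid(sc, w)
    pred <- classify_patches(model, ps)
    keep <- if (is.null(min_confidence)) rep(TRUE, nrow(pred)) else
      pred$confidence >= min_confidence
    if (!any(keep)) return(patch_set(ps$patches[, , , 0, drop = FALSE],
                                     ps$info[0, ], w = ps$w))
    ps <- subset_patches(ps, which(keep))
    ps$info$label <- pred$label[keep]
    ps$info$provenance <- "pseudo"
    ps
  })
  out <- out[vapply(out, n_patches, 1L) > 0L]
  if (!length(out)) {
    warn("no patches met the confidence threshold")
    empty <- extract_patch_grid(scenes[[1L]], w)
    return(patch_set(empty$patches[, , , 0, drop = FALSE], empty$info[0, ], w = w))
  }
  bind_patch_sets(out)
}

#' Split a labeled patch set into train/test/validation
#'
#' Partitions at the grid-cell level: all patches sharing (i, j) — i.e. the
#' temporal copies of one cell — are assigned together, so co-registered
#' near-duplicates never straddle train and test. The partition is
#' exhaustive, disjoint and reproducible under the spec's seed. If the
#' patch set already carries a `split` column (from [propagate_labels()])
#' it is honoured.
#'
#' @param patches a labeled [patch_set()].
#' @param split a [split_spec()].
#' @return Named list of `patch_set`s: `train`, `test`, `validation`.
#' @export
split_dataset <- function(patches, split = split_spec()) {
  stopifnot(inherits(patches, "patch_set"))
  if (n_patches(patches) == 0L) stop_validation("cannot split an empty patch set")
  info <- patches$info
  if (!"split" %in% names(info) || anyNA(info$split)) {
    cells <- assign_cells(info, split)
    info$split <- cells$split[match(paste(info$i, info$j), paste(cells$i, cells$j))]
    patches$info <- info
  }
  purrr::map(setNames(nm = c("train", "test", "validation")), function(s) {
    subset_patches(patches, which(info$split == s))
  })
}
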