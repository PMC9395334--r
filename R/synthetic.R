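#' Configuration of the synthetic multi-temporal scene generator
#'
#' The generator emulates the study setting downstream stages are built for:
#' a fixed landscape of L land-cover classes imaged repeatedly, each
#' acquisition differently affected by illumination and atmospheric
#' conditions. A single class map (the "true" landscape, constant over the
#' series) is rendered once as the reference scene and then perturbed into
#' co-registered replicates by an affine intensity change, additive white
#' noise and an optional blur. Intensities live on the \[0, 1\] scale used
#' by 8-bit imagery.
#'
#' Defaults describe a 6-class landscape of 10 x 10-pixel cells with
#' clearly distinct class colors (within-class texture sd 0.05, i.e. small
#' against the between-class contrasts) and three replicate acquisitions
#' with moderate inter-acquisition variation: brightness offsets up to
#' +/-0.08, gain within +/-8%, and sensor noise sd 0.04.
#'
#' @param n_rows,n_cols class-map grid dimensions (cells).
#' @param w patch size in pixels per cell side.
#' @param n_classes number of land-cover classes L (>= 2).
#' @param channels image channels C.
#' @param method class-map generator: `"voronoi"` (compact regions around
#'   random seed sites) or `"smoothed"` (quantile-thresholded smoothed noise,
#'   diffuse gradients).
#' @param sites_per_class Voronoi seed sites per class.
#' @param smooth_radius smoothing radius (cells) for the `"smoothed"` method.
#' @param class_means L x C matrix of class mean intensities (rows recycle
#'   over channels); default picks L well-separated colors.
#' @param texture_sd within-patch i.i.d. noise sd (per class, recycled).
#' @param n_replicates number of perturbed replicate scenes k.
#' @param offset_range,gain_range per-replicate brightness offset is drawn
#'   uniformly from `[-offset_range, offset_range]` and gain from
#'   `[1 - gain_range, 1 + gain_range]`.
#' @param noise_sd per-replicate additive white noise sd.
#' @param blur_radius box-blur radius in pixels (0 = none).
#' @param seed integer seed; all randomness in the series flows from it
#'   through per-scene derived streams.
#' @return A `synthetic_scene_config` list.
#' @export
synthetic_scene_config <- function(n_rows = 24, n_cols = 24, w = 10,
                                   n_classes = 6, channels = 3,
                                   method = c("voronoi", "smoothed"),
                                   sites_per_class = 3, smooth_radius = 2,
                                   class_means = NULL, texture_sd = 0.05,
                                   n_replicates = 3,
                                   offset_range = 0.08, gain_range = 0.08,
                                   noise_sd = 0.04, blur_radius = 0,
                                   seed = 1L) {
  n_rows <- check_count(n_rows, "n_rows", 1L)
  n_cols <- check_count(n_cols, "n_cols", 1L)
  w <- check_count(w, "w", 1L)
  n_classes <- check_count(n_classes, "n_classes", 2L)
  channels <- check_count(channels, "channels", 1L)
  check_number(texture_sd, "texture_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(offset_range, "offset_range", lower = 0)
  check_number(gain_range, "gain_range", lower = 0, upper = 1)
  if (is.null(class_means)) class_means <- default_class_means(n_classes, channels)
  class_means <- matrix(class_means, nrow = n_classes, ncol = channels)
  structure(list(
    n_rows = n_rows, n_cols = n_cols, w = w, n_classes = n_classes,
    channels = channels, method = match.arg(method),
    sites_per_class = sites_per_class, smooth_radius = smooth_radius,
    class_means = class_means, texture_sd = rep_len(texture_sd, n_classes),
    n_replicates = check_count(n_replicates, "n_replicates", 0L),
    offset_range = offset_range, gain_range = gain_range,
    noise_sd = noise_sd, blur_radius = blur_radius, seed = as.integer(seed)
  ), class = "synthetic_scene_config")
}

# Well-separated default palette: forest, water, field, bare soil,
# built-up, wetland (values on [0,1]).
default_class_means <- function(L, C) {
  base <- rbind(
    c(0.10, 0.35, 0.10),  # forest
    c(0.05, 0.15, 0.45),  # water
    c(0.70, 0.65, 0.20),  # field
    c(0.60, 0.45, 0.30),  # bare soil
    c(0.55, 0.55, 0.55),  # built-up
    c(0.25, 0.50, 0.40)   # wetland
  )
  if (L > nrow(base)) {
    extra <- matrix(rep(seq(0.15, 0.85, length.out = L - nrow(base)), 3),
                    ncol = 3)
    base <- rbind(base, extra)
  }
  m <- base[seq_len(L), , drop = FALSE]
  if (C == 1L) matrix(rowMeans(m), ncol = 1L) else m[, rep_len(seq_len(3L), C), drop = FALSE]
}

#' Generate a class map
#'
#' Draws an `n_rows x n_cols` integer grid of true class labels in
#' `0..L-1`. `"voronoi"` places `L * sites_per_class` random seed sites
#' (at least one per class) and labels each cell by its nearest site,
#' giving compact contiguous regions; `"smoothed"` thresholds a box-smoothed
#' Gaussian noise field at its `L - 1` equally spaced quantiles, giving
#' diffuse gradients with roughly equal class shares. If a draw misses a
#' class it is retried a bounded number of times; a map that cannot contain
#' all classes (fewer cells than classes) is returned with a warning.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_classes number of classes L (>= 2).
#' @param method `"voronoi"` or `"smoothed"`.
#' @param sites_per_class,smooth_radius method parameters.
#' @param seed integer seed.
#' @param max_retry resampling attempts when a class comes out empty.
#' @return Integer matrix with values in `0..L-1`.
#' @examples
#' table(generate_class_map(20, 20, 4, seed = 7))
#' @export
generate_class_map <- function(n_rows, n_cols, n_classes,
                               method = c("voronoi", "smoothed"),
                               sites_per_class = 3, smooth_radius = 2,
                               seed = NULL, max_retry = 20L) {
  n_rows <- check_count(n_rows, "n_rows", 1L)
  n_cols <- check_count(n_cols, "n_cols", 1L)
  n_classes <- check_count(n_classes, "n_classes", 2L)
  method <- match.arg(method)
  n_cells <- n_rows * n_cols
  with_seed(seed, {
    for (attempt in seq_len(max(1L, max_retry))) {
      cm <- switch(method,
        voronoi = class_map_voronoi(n_rows, n_cols, n_classes, sites_per_class),
        smoothed = class_map_smoothed(n_rows, n_cols, n_classes, smooth_radius)
      )
      if (length(unique(as.vector(cm))) == n_classes) return(cm)
      if (n_cells < n_classes) break
    }
    warn(sprintf("class map holds %d of %d classes (grid of %d cell(s))",
                 length(unique(as.vector(cm))), n_classes, n_cells))
    cm
  })
}

class_map_voronoi <- function(n_rows, n_cols, L, sites_per_class) {
  n_sites <- L * max(1L, as.integer(sites_per_class))
  sx <- runif(n_sites, 0, n_cols)
  sy <- runif(n_sites, 0, n_rows)
  site_class <- rep_len(seq_len(L) - 1L, n_sites)
  cj <- rep(seq_len(n_cols) - 0.5, each = n_rows)
  ci <- rep(seq_len(n_rows) - 0.5, times = n_cols)
  d2 <- outer(cj, sx, "-")^2 + outer(ci, sy, "-")^2
  matrix(site_class[max.col(-d2, ties.method = "first")], n_rows, n_cols)
}

class_map_smoothed <- function(n_rows, n_cols, L, radius) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- box_smooth(z, max(0L, as.integer(radius)))
  cuts <- quantile(z, probs = seq_len(L - 1L) / L, names = FALSE)
  matrix(findInterval(z, cuts), n_rows, n_cols)
}

# Separable box smoothing with edge renormalization.
box_smooth <- function(z, radius) {
  if (radius <= 0L) return(z)
  k <- rep(1, 2L * radius + 1L)
  smooth1 <- function(m) {
    padded <- rbind(matrix(0, radius, ncol(m)), m, matrix(0, radius, ncol(m)))
    ones <- rbind(matrix(0, radius, ncol(m)), matrix(1, nrow(m), ncol(m)),
                  matrix(0, radius, ncol(m)))
    num <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    den <- apply(ones, 2, function(col) stats::filter(col, k, sides = 2))
    (num / den)[radius + seq_len(nrow(m)), , drop = FALSE]
  }
  t(smooth1(t(smooth1(z))))
}

#' Render a class map as a raster scene
#'
#' Each `w x w` cell is drawn from its class texture distribution: the
#' class mean color plus i.i.d. Gaussian noise of the class's texture sd.
#' With zero sd every patch is constant at its class mean.
#'
#' @param class_map integer matrix of labels in `0..L-1`.
#' @param class_means L x C matrix of class mean intensities.
#' @param texture_sd per-class noise sd (recycled to L).
#' @param w patch size in pixels.
#' @param seed integer seed.
#' @param scene_id,time_index scene metadata.
#' @return A [raster_scene()] of `n_rows * w` x `n_cols * w` x C pixels.
#' @export
render_scene <- function(class_map, class_means, texture_sd = 0.05, w = 10,
                         seed = NULL, scene_id = "synthetic", time_index = 0L) {
  stopifnot(is.matrix(class_map))
  L <- max(class_map) + 1L
  if (min(class_map) < 0L) stop_validation("class labels must be >= 0")
  if (!is.matrix(class_means)) class_means <- matrix(class_means, nrow = L)
  if (nrow(class_means) < L) {
    stop_validation("class_means has %d row(s) but the map holds labels up to %d",
                    nrow(class_means), L - 1L)
  }
  C <- ncol(class_means)
  texture_sd <- rep_len(texture_sd, nrow(class_means))
  n_rows <- nrow(class_map); n_cols <- ncol(class_map)
  w <- check_count(w, "w", 1L)
  with_seed(seed, {
    # mean image: expand each cell to w x w, per channel
    px <- array(0, dim = c(n_rows * w, n_cols * w, C))
    rows <- rep(seq_len(n_rows), each = w)
    cols <- rep(seq_len(n_cols), each = w)
    sd_map <- matrix(texture_sd[class_map + 1L], n_rows, n_cols)
    for (c in seq_len(C)) {
      mu <- matrix(class_means[class_map + 1L, c], n_rows, n_cols)
      px[, , c] <- mu[rows, cols] + rnorm(length(rows) * length(cols)) *
        sd_map[rows, cols]
    }
    raster_scene(px, scene_id = scene_id, time_index = time_index)
  })
}

#' Perturb a scene into a replicate acquisition
#'
#' Applies `gain * pixels + offset + noise`, then an optional box blur —
#' a minimal stand-in for illumination/atmospheric differences between
#' acquisitions of the same landscape. Dimensions are preserved and the
#' time index is incremented (or set explicitly).
#'
#' @param scene a [raster_scene()].
#' @param gain multiplicative intensity change.
#' @param offset additive brightness offset.
#' @param noise_sd additive white noise sd.
#' @param blur_radius box-blur radius in pixels (0 = none).
#' @param seed integer seed.
#' @param time_index new time index; default `scene$time_index + 1`.
#' @return A perturbed [raster_scene()].
#' @export
perturb_scene <- function(scene, gain = 1, offset = 0, noise_sd = 0,
                          blur_radius = 0, seed = NULL, time_index = NULL) {
  stopifnot(inherits(scene, "raster_scene"))
  check_number(gain, "gain"); check_number(offset, "offset")
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    px <- gain * scene$pixels + offset
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    if (blur_radius > 0) {
      for (c in seq_len(dim(px)[3L])) {
        px[, , c] <- box_smooth(px[, , c], as.integer(blur_radius))
      }
    }
    raster_scene(px, scene_id = scene$scene_id,
                 time_index = time_index %||% (scene$time_index + 1L))
  })
}

#' Generate a co-registered multi-temporal scene series
#'
#' Draws one class map, renders it as the reference scene (time 0), and
#' produces `n_replicates` perturbed replicates (times 1..k) that share the
#' class map exactly: patch (i, j) has the same true label in every scene.
#' Each scene consumes its own RNG stream derived from the config seed, so
#' a series is reproducible as a whole.
#'
#' @param config a [synthetic_scene_config()].
#' @return A `scene_series`: list with `reference`, `replicates` (list),
#'   `class_map`, `w`, and the `config`.
#' @examples
#' ser <- generate_series(synthetic_scene_config(n_rows = 6, n_cols = 6,
#'                                               n_replicates = 2, seed = 3))
#' length(ser$replicates)
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "synthetic_scene_config"))
  cm <- generate_class_map(config$n_rows, config$n_cols, config$n_classes,
                           method = config$method,
                           sites_per_class = config$sites_per_class,
                           smooth_radius = config$smooth_radius,
                           seed = derive_seed(config$seed, 0L))
  reference <- render_scene(cm, config$class_means, config$texture_sd,
                            w = config$w, seed = derive_seed(config$seed, 1L),
                            scene_id = "reference", time_index = 0L)
  replicates <- purrr::map(seq_len(config$n_replicates), function(t) {
    s <- derive_seed(config$seed, 1L + t)
    pars <- with_seed(s, list(
      gain = runif(1, 1 - config$gain_range, 1 + config$gain_range),
      offset = runif(1, -config$offset_range, config$offset_range)
    ))
    rep_scene <- perturb_scene(reference, gain = pars$gain, offset = pars$offset,
                               noise_sd = config$noise_sd,
                               blur_radius = config$blur_radius,
                               seed = derive_seed(s, 7L), time_index = t)
    rep_scene$scene_id <- sprintf("replicate_%d", t)
    rep_scene
  })
  structure(list(reference = reference, replicates = replicates,
                 class_map = cm, w = config$w, config = config),
            class = "scene_series")
}

#' @export
print.scene_series <- function(x, ...) {
  d <- dim(x$reference$pixels)
  cat(sprintf("<scene_series> 1 reference + %d replicate(s), %d x %d x %d px, %d classes\n",
              length(x$replicates), d[1L], d[2L], d[3L], max(x$class_map) + 1L))
  invisible(x)
}

series_scenes <- function(series) c(list(series$reference), series$replicates)

#' Write a scene series to disk
#'
#' Scenes as RDS arrays, the class map as CSV, the config as JSON.
#'
#' @param series a `scene_series`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in series_scenes(series)) {
    write_scene(sc, file.path(dir, sprintf("scene_t%02d.rds", sc$time_index)))
  }
  write.table(series$class_map, file.path(dir, "class_map.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  cfg <- series$config
  cfg$class_means <- as.vector(cfg$class_means)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
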