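# Second-order summary statistics for marked point patterns in a
# rectangular window. All estimators are written against the pairwise
# distance representation of the ball count E_o(N(b(o, r) \ {o})):
# a pair (u, v) contributes at range r iff d_uv <= r (or through a kernel
# k_h(d_uv - r) for the density-type statistics).

# ---- shared machinery -------------------------------------------------

default_r_grid <- function(pattern, n_r = 512L, positive = FALSE) {
  rmax <- min(window_sides(pattern)) / 4
  r <- seq(0, rmax, length.out = n_r)
  if (positive) r[r > 0] else r
}

epanechnikov <- function(t, h) {
  k <- 0.75 / h * (1 - (t / h)^2)
  ifelse(abs(t) < h, k, 0)
}

stoyan_bandwidth <- function(pattern) 0.15 / sqrt(intensity(pattern))

torus_diff <- function(coord, side) {
  d <- abs(outer(coord, coord, "-"))
  pmin(d, side - d)
}

# Unordered pair distances and translation-correction weights, sorted by
# distance. correction: none -> w = 1; translation -> w = |W| / |W ∩ W_h|;
# toroidal -> torus metric, w = 1.
pair_distances <- function(pattern, correction) {
  n <- nrow(pattern)
  sides <- window_sides(pattern)
  if (correction == "toroidal") {
    dx <- torus_diff(pattern$x, sides[1L])
    dy <- torus_diff(pattern$y, sides[2L])
    dmat <- sqrt(dx^2 + dy^2)
    wmat <- matrix(1, n, n)
  } else {
    dx <- abs(outer(pattern$x, pattern$x, "-"))
    dy <- abs(outer(pattern$y, pattern$y, "-"))
    dmat <- sqrt(dx^2 + dy^2)
    wmat <- if (correction == "translation") {
      prod(sides) / ((sides[1L] - dx) * (sides[2L] - dy))
    } else {
      matrix(1, n, n)
    }
  }
  up <- upper.tri(dmat)
  ord <- order(dmat[up])
  iu <- row(dmat)[up][ord]
  iv <- col(dmat)[up][ord]
  list(d = dmat[up][ord], w = wmat[up][ord], iu = iu, iv = iv)
}

check_correction <- function(correction) {
  match.arg(correction, c("translation", "none", "toroidal"))
}

check_rmax <- function(pattern, r) {
  bound <- min(window_sides(pattern)) / 2
  if (max(r) > bound + 1e-12) {
    stop_validation("max(r) = %g exceeds half the shorter window side (%g)",
                    max(r), bound)
  }
  if (is.unsorted(r, strictly = TRUE) || any(r < 0)) {
    stop_validation("r grid must be strictly increasing and non-negative")
  }
  r
}

sppa_fn <- function(df, statistic, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  attr(out, "statistic") <- statistic
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c("sppa_fn", class(tibble()))
  out
}

# ---- K and cross-K ----------------------------------------------------

#' Ripley's K-function
#'
#' Estimates K(r), the expected number of further points within distance r
#' of a typical point, scaled by the intensity:
#' `K(r) = |W| / (n (n - 1)) * sum over ordered pairs of 1(d <= r) e(u, v)`.
#' The translation correction weights each pair by
#' `|W| / |W intersect W_shifted|` (unbiased on rectangles); `"toroidal"`
#' measures distances on the torus with unit weights; `"none"` applies no
#' correction (useful for oracle comparisons). Under complete spatial
#' randomness K(r) = pi r^2.
#'
#' @param pattern an [mpp()] (or data frame plus `window`).
#' @param r strictly increasing non-negative distance grid; the maximum must
#'   not exceed half the shorter window side. Default: 512 values up to a
#'   quarter of the shorter side.
#' @param correction `"translation"` (default), `"none"`, or `"toroidal"`.
#' @param window window for plain data frames.
#' @return An `sppa_fn` tibble with columns `r`, `estimate`, `theoretical`.
#' @export
k_function <- function(pattern, r = NULL,
                       correction = c("translation", "none", "toroidal"),
                       window = NULL) {
  pattern <- as_mpp(pattern, window)
  correction <- match.arg(correction)
  n <- nrow(pattern)
  if (n < 2L) stop_validation("K-function needs at least 2 points, got %d", n)
  r <- check_rmax(pattern, r %||% default_r_grid(pattern))
  pd <- pair_distances(pattern, correction)
  cw <- c(0, cumsum(pd$w))
  est <- window_area(pattern) / (n * (n - 1)) * 2 * cw[findInterval(r, pd$d) + 1L]
  sppa_fn(tibble(r = r, estimate = est, theoretical = pi * r^2),
          statistic = "K", correction = correction)
}

#' Bivariate cross-K function
#'
#' Estimates K_ij(r), the expected number of type-j points within distance
#' r of a typical type-i point, scaled by lambda_i:
#' `K_ij(r) = |W| / (n_i n_j) * sum over pairs (u in i, v in j, u != v) of
#' 1(d <= r) e(u, v)`. For `type_i == type_j` this reduces to the ordinary
#' [k_function()] of the sub-pattern. With a symmetric correction
#' K_ij = K_ji. Under independence of the two components K_ij(r) = pi r^2.
#'
#' @inheritParams k_function
#' @param type_i,type_j mark values of the two components.
#' @return An `sppa_fn` tibble.
#' @export
cross_k_function <- function(pattern, type_i, type_j, r = NULL,
                             correction = c("translation", "none", "toroidal"),
                             window = NULL) {
  pattern <- as_mpp(pattern, window)
  correction <- match.arg(correction)
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  ii <- which(pattern$mark == type_i)
  jj <- which(pattern$mark == type_j)
  if (!length(ii)) stop_validation("no points of type '%s'", type_i)
  if (!length(jj)) stop_validation("no points of type '%s'", type_j)
  if (identical(type_i, type_j)) {
    sub <- mpp(as_tibble(pattern)[ii, ], pattern_window(pattern))
    out <- k_function(sub, r = r, correction = correction)
    attr(out, "statistic") <- "K_ij"
    attr(out, "types") <- c(type_i, type_j)
    return(out)
  }
  r <- check_rmax(pattern, r %||% default_r_grid(pattern))
  sides <- window_sides(pattern)
  if (correction == "toroidal") {
    dxa <- abs(outer(pattern$x[ii], pattern$x[jj], "-"))
    dya <- abs(outer(pattern$y[ii], pattern$y[jj], "-"))
    dmat <- sqrt(pmin(dxa, sides[1L] - dxa)^2 + pmin(dya, sides[2L] - dya)^2)
    wmat <- 1
  } else {
    dxa <- abs(outer(pattern$x[ii], pattern$x[jj], "-"))
    dya <- abs(outer(pattern$y[ii], pattern$y[jj], "-"))
    dmat <- sqrt(dxa^2 + dya^2)
    wmat <- if (correction == "translation") {
      prod(sides) / ((sides[1L] - dxa) * (sides[2L] - dya))
    } else 1
  }
  ord <- order(dmat)
  dsort <- dmat[ord]
  wsort <- (dmat * 0 + wmat)[ord]
  cw <- c(0, cumsum(wsort))
  est <- window_area(pattern) / (length(ii) * length(jj)) *
    cw[findInterval(r, dsort) + 1L]
  sppa_fn(tibble(r = r, estimate = est, theoretical = pi * r^2),
          statistic = "K_ij", correction = correction, types = c(type_i, type_j))
}

# ---- pair correlation -------------------------------------------------

#' Pair correlation function
#'
#' Kernel estimate of g(r), the non-cumulative second-order density:
#' `g(r) = sum over ordered pairs of k_h(d - r) e(u, v) /
#' (2 pi r lambda^2 |W|)` with the Epanechnikov kernel and
#' `lambda^2 = n (n - 1) / |W|^2`. Under CSR g = 1; g > 1 indicates
#' clustering and g < 1 inhibition at range r. The default bandwidth is
#' Stoyan's rule `h = 0.15 / sqrt(lambda)`. r = 0 is dropped from the grid
#' (1/r singularity).
#'
#' @inheritParams k_function
#' @param bandwidth kernel half-width h (default Stoyan's rule).
#' @return An `sppa_fn` tibble; the bandwidth is recorded as an attribute.
#' @export
pair_correlation <- function(pattern, r = NULL, bandwidth = NULL,
                             correction = c("translation", "none", "toroidal"),
                             window = NULL) {
  pattern <- as_mpp(pattern, window)
  correction <- match.arg(correction)
  n <- nrow(pattern)
  if (n < 2L) stop_validation("pair correlation needs at least 2 points")
  r <- r %||% default_r_grid(pattern, positive = TRUE)
  if (any(r == 0)) {
    warn("r = 0 dropped from the pair correlation grid")
    r <- r[r > 0]
  }
  r <- check_rmax(pattern, r)
  h <- bandwidth %||% stoyan_bandwidth(pattern)
  check_number(h, "bandwidth", lower = 1e-300)
  pd <- pair_distances(pattern, correction)
  area <- window_area(pattern)
  lambda2 <- n * (n - 1) / area^2
  est <- vapply(r, function(ri) {
    lo <- findInterval(ri - h, pd$d) + 1L
    hi <- findInterval(ri + h, pd$d)
    if (hi < lo) return(0)
    idx <- lo:hi
    2 * sum(epanechnikov(pd$d[idx] - ri, h) * pd$w[idx]) /
      (2 * pi * ri * lambda2 * area)
  }, numeric(1))
  sppa_fn(tibble(r = r, estimate = est, theoretical = 1),
          statistic = "g", correction = correction, bandwidth = h)
}

# ---- nearest-neighbour machinery, J-function, Clark-Evans -------------

nn_distances <- function(pattern, metric = c("euclidean", "toroidal")) {
  metric <- match.arg(metric)
  n <- nrow(pattern)
  sides <- window_sides(pattern)
  if (metric == "toroidal") {
    dx <- torus_diff(pattern$x, sides[1L])
    dy <- torus_diff(pattern$y, sides[2L])
    dmat <- sqrt(dx^2 + dy^2)
  } else {
    dmat <- as.matrix(dist(cbind(pattern$x, pattern$y)))
  }
  diag(dmat) <- Inf
  apply(dmat, 1L, min)
}

boundary_distance <- function(x, y, w) {
  pmin(x - w[1L], w[2L] - x, y - w[3L], w[4L] - y)
}

# Reduced-sample (border-corrected) estimate of a distance distribution:
# observations `d` censored at boundary distances `b`.
border_cdf <- function(d, b, r) {
  vapply(r, function(ri) {
    denom <- sum(b > ri)
    if (denom == 0L) return(NA_real_)
    sum(d <= ri & b > ri) / denom
  }, numeric(1))
}

#' J-function
#'
#' `J(r) = (1 - G(r)) / (1 - F(r))`, where G is the nearest-neighbour
#' distance distribution and F the empty-space function, both estimated
#' with the reduced-sample border correction; F is evaluated from a regular
#' dummy grid (default 100 x 100). J = 1 under CSR, J > 1 for inhibited
#' (regular) patterns and J < 1 for clustered patterns at small r. Values
#' of r where F(r) has reached 1 (or the border denominators are empty)
#' are reported as `NA`, never interpolated.
#'
#' @inheritParams k_function
#' @param dummy_dim dummy grid resolution per side for F (>= 100).
#' @return An `sppa_fn` tibble with columns `r`, `estimate`, `theoretical`,
#'   `G`, `F`.
#' @export
j_function <- function(pattern, r = NULL, dummy_dim = 100L, window = NULL) {
  pattern <- as_mpp(pattern, window)
  n <- nrow(pattern)
  if (n < 1L) stop_validation("J-function needs at least 1 point")
  dummy_dim <- max(100L, as.integer(dummy_dim))
  r <- check_rmax(pattern, r %||% default_r_grid(pattern))
  w <- pattern_window(pattern)
  nnd <- if (n >= 2L) nn_distances(pattern, "euclidean") else rep(Inf, n)
  bd <- boundary_distance(pattern$x, pattern$y, w)
  G <- border_cdf(nnd, bd, r)
  gx <- seq(w[1L], w[2L], length.out = dummy_dim + 1L)
  gx <- (gx[-1L] + gx[-length(gx)]) / 2
  gy <- seq(w[3L], w[4L], length.out = dummy_dim + 1L)
  gy <- (gy[-1L] + gy[-length(gy)]) / 2
  dummy <- tidyr::expand_grid(x = gx, y = gy)
  # nearest data point per dummy point, chunked to bound memory
  ed <- numeric(nrow(dummy))
  chunk <- 4096L
  for (s in seq(1L, nrow(dummy), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(dummy))
    dd <- outer(dummy$x[idx], pattern$x, "-")^2 + outer(dummy$y[idx], pattern$y, "-")^2
    ed[idx] <- sqrt(matrixStats_rowMins(dd))
  }
  bd_dummy <- boundary_distance(dummy$x, dummy$y, w)
  Fhat <- border_cdf(ed, bd_dummy, r)
  est <- ifelse(!is.na(Fhat) & !is.na(G) & Fhat < 1, (1 - G) / (1 - Fhat), NA_real_)
  sppa_fn(tibble(r = r, estimate = est, theoretical = 1, G = G, F = Fhat),
          statistic = "J", correction = "border", dummy_dim = dummy_dim)
}

# Row minima without extra dependencies.
matrixStats_rowMins <- function(m) do.call(pmin, c(asplit(m, 2L), list(na.rm = FALSE)))

#' Clark-Evans test of complete spatial randomness
#'
#' Compares the observed mean nearest-neighbour distance `d_obs` with its
#' CSR expectation `d_exp = 1 / (2 sqrt(lambda))`. The index
#' `R = d_obs / d_exp` is 1 under CSR, < 1 for clustered and > 1 for
#' regular patterns; the z statistic `(d_obs - d_exp) / se` with
#' `se = 0.26136 / sqrt(n lambda)` is referred to the standard normal
#' (two-sided). The toroidal metric removes the positive edge bias of
#' uncorrected euclidean nearest-neighbour distances and is recommended
#' for calibration against CSR.
#'
#' @inheritParams k_function
#' @param metric `"euclidean"` or `"toroidal"` nearest-neighbour distances.
#' @return A `clark_evans` object; see [tidy()] / [glance()] methods.
#' @export
clark_evans_test <- function(pattern, metric = c("euclidean", "toroidal"),
                             window = NULL) {
  pattern <- as_mpp(pattern, window)
  metric <- match.arg(metric)
  n <- nrow(pattern)
  if (n < 2L) stop_validation("Clark-Evans test needs at least 2 points, got %d", n)
  lambda <- intensity(pattern)
  d_obs <- mean(nn_distances(pattern, metric))
  d_exp <- 1 / (2 * sqrt(lambda))
  se <- 0.26136 / sqrt(n * lambda)
  z <- (d_obs - d_exp) / se
  structure(list(n = n, lambda = lambda, d_obs = d_obs, d_exp = d_exp,
                 R = d_obs / d_exp, z = z,
                 p_value = 2 * pnorm(-abs(z)), metric = metric),
            class = "clark_evans")
}

#' @export
print.clark_evans <- function(x, ...) {
  cat(sprintf("Clark-Evans CSR test (%s metric)\n", x$metric))
  cat(sprintf("  n = %d, lambda = %.6g\n", x$n, x$lambda))
  cat(sprintf("  R = %.4f  (dbar_obs = %.5g, dbar_exp = %.5g)\n", x$R, x$d_obs, x$d_exp))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' @method tidy clark_evans
#' @export
tidy.clark_evans <- function(x, ...) {
  tibble(statistic = "clark_evans", R = x$R, z = x$z, p.value = x$p_value,
         d_obs = x$d_obs, d_exp = x$d_exp, metric = x$metric)
}

#' @method glance clark_evans
#' @export
glance.clark_evans <- function(x, ...) {
  tibble(n = x$n, lambda = x$lambda, R = x$R, z = x$z, p.value = x$p_value)
}

# ---- mark connection and mark correlation -----------------------------

# Kernel-weighted pair sums at each r: calls `f(idx, kern)` on the indices
# of sorted pairs within the bandwidth window and their kernel weights.
kernel_pair_scan <- function(pd, r, h, f) {
  lapply(seq_along(r), function(k) {
    lo <- findInterval(r[k] - h, pd$d) + 1L
    hi <- findInterval(r[k] + h, pd$d)
    if (hi < lo) return(f(integer(0), numeric(0)))
    idx <- lo:hi
    f(idx, epanechnikov(pd$d[idx] - r[k], h))
  })
}

#' Mark connection function
#'
#' `p_lm(r)` is the conditional probability that an ordered pair of points
#' a distance r apart carries marks (l, m). It is estimated as a
#' kernel-weighted ratio over ordered pairs:
#' `p_lm(r) = sum 1(m_u = l, m_v = m) k_h(d - r) / sum k_h(d - r)`,
#' which guarantees values in \[0, 1\] and `sum over (l, m) of p_lm = 1`
#' wherever the denominator is positive (elsewhere `NA`). Under independent
#' marking, p_lm(r) = p_l p_m; larger values indicate positive association
#' of the two types at range r, smaller values negative association.
#'
#' @inheritParams pair_correlation
#' @param l,m mark values of the ordered pair.
#' @return An `sppa_fn` tibble; `theoretical` is the product `p_l * p_m`.
#' @export
mark_connection <- function(pattern, l, m, r = NULL, bandwidth = NULL,
                            window = NULL) {
  pattern <- as_mpp(pattern, window)
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  marks <- pattern$mark
  if (!l %in% marks) stop_validation("unknown mark value '%s'", l)
  if (!m %in% marks) stop_validation("unknown mark value '%s'", m)
  out <- mark_connection_matrix(pattern, r = r, bandwidth = bandwidth)
  sel <- dplyr::filter(out, .data$l == !!as.character(l), .data$m == !!as.character(m))
  sppa_fn(dplyr::select(sel, "r", "estimate", "theoretical"),
          statistic = "p_lm", bandwidth = attr(out, "bandwidth"),
          types = c(l, m))
}

#' Array of mark connection functions
#'
#' All ordered pairs (l, m) at once, sharing one kernel denominator, so the
#' mass identity `sum over (l, m) of p_lm(r) = 1` holds by construction at
#' every defined r, and p_lm = p_ml because the kernel is symmetric.
#'
#' @inheritParams pair_correlation
#' @return A tibble with columns `r`, `l`, `m`, `estimate`, `theoretical`
#'   (`p_l * p_m`), of class `sppa_fn_matrix`.
#' @export
mark_connection_matrix <- function(pattern, r = NULL, bandwidth = NULL,
                                   window = NULL) {
  pattern <- as_mpp(pattern, window)
  if (!"mark" %in% names(pattern)) stop_validation("pattern has no mark column")
  n <- nrow(pattern)
  if (n < 2L) stop_validation("mark connection needs at least 2 points")
  r <- r %||% default_r_grid(pattern, positive = TRUE)
  r <- check_rmax(pattern, r)
  h <- bandwidth %||% stoyan_bandwidth(pattern)
  check_number(h, "bandwidth", lower = 1e-300)
  lev <- sort(unique(as.character(pattern$mark)))
  L <- length(lev)
  mk <- match(as.character(pattern$mark), lev)
  pd <- pair_distances(pattern, "none")
  # unordered pair -> unordered mark-pair id {a, b}, a <= b
  a <- pmin(mk[pd$iu], mk[pd$iv])
  b <- pmax(mk[pd$iu], mk[pd$iv])
  pair_id <- (a - 1L) * L + b
  p_marg <- as.vector(table(factor(mk, levels = seq_len(L)))) / n
  per_r <- kernel_pair_scan(pd, r, h, function(idx, kern) {
    if (!length(kern) || sum(kern) <= 0) return(matrix(NA_real_, L, L))
    q <- rowsum(kern, pair_id[idx])
    tot <- sum(q)   # denominator from the same accumulated sums
    Q <- matrix(0, L, L)
    ids <- as.integer(rownames(q))
    Q[cbind((ids - 1L) %/% L + 1L, (ids - 1L) %% L + 1L)] <- q
    # ordered-pair probabilities: the ordered denominator is 2 * tot and
    # the (l, m) numerator is q_lm for l != m but 2 q_ll on the diagonal,
    # so p_lm = q_lm / (2 tot) off-diagonal and p_ll = q_ll / tot
    P <- (Q + t(Q)) / 2
    diag(P) <- diag(Q)
    P / tot
  })
  grid <- tidyr::expand_grid(r = r, l = lev, m = lev)
  grid$estimate <- unlist(lapply(per_r, function(Pk) {
    # expand_grid varies m fastest within l: row-major over (l, m)
    as.vector(t(Pk))
  }), use.names = FALSE)
  grid$theoretical <- p_marg[match(grid$l, lev)] * p_marg[match(grid$m, lev)]
  out <- sppa_fn(grid, statistic = "p_lm_matrix", bandwidth = h)
  class(out) <- c("sppa_fn_matrix", class(out))
  out
}

#' Mark correlation function
#'
#' For numeric marks, `k_mm(r)` is the kernel-weighted mean of the product
#' of the marks of point pairs a distance r apart, divided by the mean
#' product over all distinct pairs:
#' `k_mm(r) = [sum m_u m_v k_h(d - r) / sum k_h(d - r)] / mu2`,
#' `mu2 = mean over distinct pairs of (m_u m_v)`. The pairwise
#' normalisation makes the constant-mark identity `k_mm = 1` exact at any
#' n. k_mm = 1 under mark independence; > 1 indicates mutual stimulation
#' (positive mark correlation) at range r, < 1 mutual inhibition.
#'
#' @inheritParams pair_correlation
#' @param value_col column holding the numeric marks (default `"value"`).
#' @return An `sppa_fn` tibble; undefined r (empty kernel window) are `NA`.
#' @export
mark_correlation <- function(pattern, r = NULL, bandwidth = NULL,
                             value_col = "value", window = NULL) {
  pattern <- as_mpp(pattern, window)
  if (!value_col %in% names(pattern)) {
    stop_validation("pattern has no numeric mark column '%s'", value_col)
  }
  v <- as.numeric(pattern[[value_col]])
  n <- nrow(pattern)
  if (n < 2L) stop_validation("mark correlation needs at least 2 points")
  r <- r %||% default_r_grid(pattern, positive = TRUE)
  r <- check_rmax(pattern, r)
  h <- bandwidth %||% stoyan_bandwidth(pattern)
  check_number(h, "bandwidth", lower = 1e-300)
  pd <- pair_distances(pattern, "none")
  prod_pairs <- v[pd$iu] * v[pd$iv]
  mu2 <- mean(prod_pairs)
  if (abs(mu2) < 1e-300) {
    stop_validation("mean pairwise mark product is zero; k_mm normalisation undefined")
  }
  # normalizing the pair products up front makes the constant-mark
  # identity k_mm = 1 exact in floating point, not just to rounding
  prod_norm <- prod_pairs / mu2
  est <- unlist(kernel_pair_scan(pd, r, h, function(idx, kern) {
    tot <- sum(kern)
    if (tot <= 0) return(NA_real_)
    sum(prod_norm[idx] * kern) / tot
  }), use.names = FALSE)
  sppa_fn(tibble(r = r, estimate = est, theoretical = 1),
          statistic = "k_mm", bandwidth = h)
}

# ---- Monte Carlo envelopes --------------------------------------------

#' Monte Carlo simulation envelopes
#'
#' Pointwise envelope bands for a summary statistic under a null model:
#' `"csr"` re-simulates the same number of points uniformly in the window
#' (binomial/conditioned CSR), `"random_labeling"` permutes the marks while
#' holding every location fixed. The band at each r is the `rank`-th
#' smallest / largest simulated value over `n_sim` seeded simulations
#' (pointwise coverage `1 - 2 rank / (n_sim + 1)`).
#'
#' @param pattern an [mpp()].
#' @param statistic one of `"K"`, `"g"`, `"J"`, `"K_ij"`, `"p_lm"`,
#'   `"k_mm"`.
#' @param null `"csr"` (locations) or `"random_labeling"` (marks). Mark
#'   statistics require `"random_labeling"`; unmarked statistics `"csr"`.
#' @param n_sim number of simulations (>= `2 * rank`).
#' @param rank which extreme forms the band.
#' @param seed integer seed.
#' @param r distance grid (default: the statistic's own default).
#' @param ... passed to the statistic (e.g. `type_i`, `l`, `bandwidth`).
#' @return A tibble with columns `r`, `observed`, `theoretical`, `lo`,
#'   `hi`, of class `sppa_envelope`.
#' @export
envelope <- function(pattern, statistic = c("K", "g", "J", "K_ij", "p_lm", "k_mm"),
                     null = c("csr", "random_labeling"),
                     n_sim = 99L, rank = 5L, seed = NULL, r = NULL, ...) {
  pattern <- as_mpp(pattern)
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  n_sim <- check_count(n_sim, "n_sim", 1L)
  rank <- check_count(rank, "rank", 1L)
  if (n_sim < 2L * rank) stop_validation("n_sim (%d) must be >= 2 * rank (%d)", n_sim, 2L * rank)
  marked_stat <- statistic %in% c("K_ij", "p_lm", "k_mm")
  if (marked_stat && null == "csr") {
    stop_validation("'%s' is a mark statistic; use null = 'random_labeling'", statistic)
  }
  if (!marked_stat && null == "random_labeling") {
    stop_validation("'%s' ignores marks; random labeling would leave it constant", statistic)
  }
  stat_fun <- switch(statistic,
    K = function(p, ...) k_function(p, r = r, ...),
    g = function(p, ...) pair_correlation(p, r = r, ...),
    J = function(p, ...) j_function(p, r = r, ...),
    K_ij = function(p, ...) cross_k_function(p, r = r, ...),
    p_lm = function(p, ...) mark_connection(p, r = r, ...),
    k_mm = function(p, ...) mark_correlation(p, r = r, ...)
  )
  obs <- stat_fun(pattern, ...)
  r_used <- obs$r
  r <- r_used
  sims <- vapply(seq_len(n_sim), function(s) {
    sim_pat <- if (null == "csr") {
      simulate_csr_n(nrow(pattern), pattern_window(pattern),
                     seed = derive_seed(seed, s))
    } else {
      randomize_marks(pattern, mode = "permute", seed = derive_seed(seed, s))
    }
    stat_fun(sim_pat, ...)$estimate
  }, numeric(length(r_used)))
  lo <- apply(sims, 1L, function(v) sort(v, na.last = NA)[rank])
  hi <- apply(sims, 1L, function(v) sort(v, decreasing = TRUE, na.last = NA)[rank])
  out <- tibble(r = r_used, observed = obs$estimate,
                theoretical = obs$theoretical, lo = lo, hi = hi)
  attr(out, "statistic") <- statistic
  attr(out, "null") <- null
  attr(out, "n_sim") <- n_sim
  attr(out, "rank") <- rank
  class(out) <- c("sppa_envelope", class(tibble()))
  out
}

#' Write a summary-function estimate as CSV
#'
#' Columns `r,estimate,theoretical[,lo,hi]` with a JSON metadata sidecar
#' (statistic, correction, bandwidth).
#'
#' @param fn an `sppa_fn` or `sppa_envelope` tibble.
#' @param path CSV output path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_summary_fn <- function(fn, path) {
  write.csv(as_tibble(fn), path, row.names = FALSE)
  meta <- list(statistic = attr(fn, "statistic"),
               correction = attr(fn, "correction"),
               bandwidth = attr(fn, "bandwidth"),
               types = attr(fn, "types"),
               n_sim = attr(fn, "n_sim"), rank = attr(fn, "rank"),
               null = attr(fn, "null"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
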