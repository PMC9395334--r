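# Seeded simulators of the reference point processes used for testing and
# Monte Carlo envelopes.

#' Simulate a homogeneous Poisson process (CSR)
#'
#' The point count is Poisson(lambda * |W|) and coordinates are uniform on
#' the window — the "absolute randomness" reference model every test in
#' the package calibrates against. [simulate_csr_n()] is the conditional
#' variant placing exactly n uniform points (binomial process), used by
#' envelopes conditioned on the observed count.
#'
#' @param lambda intensity (points per unit area), >= 0.
#' @param window numeric `c(xmin, xmax, ymin, ymax)`.
#' @param seed integer seed; same seed, same pattern.
#' @return An unmarked [mpp()].
#' @examples
#' nrow(simulate_poisson(100, c(0, 1, 0, 1), seed = 1))
#' @export
simulate_poisson <- function(lambda, window = c(0, 1, 0, 1), seed = NULL) {
  check_number(lambda, "lambda", lower = 0)
  area <- (window[2L] - window[1L]) * (window[4L] - window[3L])
  with_seed(seed, {
    n <- rpois(1L, lambda * area)
    simulate_csr_n(n, window, seed = NULL)
  })
}

#' @rdname simulate_poisson
#' @param n exact number of points to place.
#' @export
simulate_csr_n <- function(n, window = c(0, 1, 0, 1), seed = NULL) {
  n <- check_count(n, "n", lower = 0L)
  with_seed(seed, {
    mpp(tibble(x = runif(n, window[1L], window[2L]),
               y = runif(n, window[3L], window[4L])),
        window = window)
  })
}

#' Simulate a Matern cluster process
#'
#' Parents form a Poisson process of intensity `kappa` on the window
#' dilated by the cluster radius `rho` (so the offspring process is
#' stationary inside the analysis window, with no artificial edge
#' depletion); each parent receives Poisson(`mu`) offspring uniform in its
#' radius-`rho` disc, and offspring falling outside the window are
#' discarded. The retained count has expectation `kappa * mu * |W|`.
#' The canonical clustered ("attraction") reference model.
#'
#' @param kappa parent intensity.
#' @param mu mean offspring per parent.
#' @param rho cluster (disc) radius.
#' @inheritParams simulate_poisson
#' @return An unmarked [mpp()].
#' @export
simulate_matern_cluster <- function(kappa, mu, rho, window = c(0, 1, 0, 1),
                                    seed = NULL) {
  check_number(kappa, "kappa", lower = 0)
  check_number(mu, "mu", lower = 0)
  check_number(rho, "rho", lower = 0)
  with_seed(seed, {
    dil <- window + c(-rho, rho, -rho, rho)
    area_dil <- (dil[2L] - dil[1L]) * (dil[4L] - dil[3L])
    n_par <- rpois(1L, kappa * area_dil)
    px <- runif(n_par, dil[1L], dil[2L])
    py <- runif(n_par, dil[3L], dil[4L])
    n_off <- rpois(n_par, mu)
    cx <- rep(px, n_off)
    cy <- rep(py, n_off)
    m <- length(cx)
    rad <- rho * sqrt(runif(m))
    ang <- runif(m, 0, 2 * pi)
    x <- cx + rad * cos(ang)
    y <- cy + rad * sin(ang)
    keep <- x >= window[1L] & x < window[2L] & y >= window[3L] & y < window[4L]
    mpp(tibble(x = x[keep], y = y[keep]), window = window)
  })
}

#' Simulate simple sequential inhibition (SSI)
#'
#' Uniform proposals are accepted only if at least `delta` away from every
#' previously accepted point, producing a regular ("repulsion") pattern
#' with a hard minimum spacing. Stops after `n` acceptances or
#' `max_attempts` proposals; an infeasible packing returns the partial
#' pattern with a warning, never an error.
#'
#' @param n target number of points.
#' @param delta inhibition (minimum inter-point) distance.
#' @param max_attempts proposal budget (default `1000 * n`).
#' @inheritParams simulate_poisson
#' @return An unmarked [mpp()]; the achieved count is `nrow()` of it.
#' @export
simulate_ssi <- function(n, delta, window = c(0, 1, 0, 1), seed = NULL,
                         max_attempts = NULL) {
  n <- check_count(n, "n", lower = 0L)
  check_number(delta, "delta", lower = 0)
  max_attempts <- max_attempts %||% max(1000L * n, 1000L)
  with_seed(seed, {
    x <- numeric(0); y <- numeric(0)
    attempts <- 0L
    while (length(x) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      cx <- runif(1L, window[1L], window[2L])
      cy <- runif(1L, window[3L], window[4L])
      if (length(x) == 0L || min((x - cx)^2 + (y - cy)^2) >= delta^2) {
        x <- c(x, cx); y <- c(y, cy)
      }
    }
    if (length(x) < n) {
      warn(sprintf("SSI placed %d of %d points within %d attempts (delta = %g)",
                   length(x), n, max_attempts, delta))
    }
    mpp(tibble(x = x, y = y), window = window)
  })
}

#' Randomize the marks of a pattern
#'
#' The random-labeling null: coordinates are held fixed bit-for-bit and
#' only marks change. `"permute"` shuffles the observed marks (preserving
#' the mark multiset exactly), `"iid"` draws marks independently from the
#' supplied probabilities.
#'
#' @param pattern a marked [mpp()].
#' @param mode `"permute"` or `"iid"`.
#' @param p named (or ordered) probabilities for `"iid"`, summing to 1.
#' @param seed integer seed.
#' @param window window for plain data frames.
#' @return An [mpp()] with the same locations and new marks.
#' @export
randomize_marks <- function(pattern, mode = c("permute", "iid"), p = NULL,
                            seed = NULL, window = NULL) {
  pattern <- as_mpp(pattern, window)
  mode <- match.arg(mode)
  out <- as_tibble(pattern)
  with_seed(seed, {
    if (mode == "permute") {
      if (!"mark" %in% names(out)) stop_validation("pattern has no marks to permute")
      out$mark <- sample(out$mark)
    } else {
      if (is.null(p)) stop_validation("iid mark randomization needs probabilities `p`")
      if (abs(sum(p) - 1) > 1e-9) stop_validation("probabilities must sum to 1, got %g", sum(p))
      values <- names(p) %||% (seq_along(p) - 1L)
      out$mark <- sample(values, nrow(out), replace = TRUE, prob = p)
    }
    mpp(out, pattern_window(pattern))
  })
}
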