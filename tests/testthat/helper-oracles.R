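# Naive O(n^2) reference implementations of every summary statistic,
# written as explicit double loops with no shared code with the package.
# These are the independent oracles the vectorized estimators are checked
# against.

oracle_pair_dist <- function(xu, yu, xv, yv, window = NULL, toroidal = FALSE) {
  dx <- abs(xu - xv); dy <- abs(yu - yv)
  if (toroidal) {
    X <- window[2] - window[1]; Y <- window[4] - window[3]
    dx <- min(dx, X - dx); dy <- min(dy, Y - dy)
  }
  sqrt(dx^2 + dy^2)
}

oracle_trans_weight <- function(xu, yu, xv, yv, window) {
  X <- window[2] - window[1]; Y <- window[4] - window[3]
  (X * Y) / ((X - abs(xu - xv)) * (Y - abs(yu - yv)))
}

oracle_k <- function(x, y, window, r, correction = "none") {
  n <- length(x)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  sapply(r, function(ri) {
    s <- 0
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      d <- oracle_pair_dist(x[u], y[u], x[v], y[v], window,
                            toroidal = correction == "toroidal")
      if (d <= ri) {
        e <- if (correction == "translation") {
          oracle_trans_weight(x[u], y[u], x[v], y[v], window)
        } else 1
        s <- s + e
      }
    }
    area / (n * (n - 1)) * s
  })
}

oracle_cross_k <- function(x, y, marks, ti, tj, window, r, correction = "none") {
  iu <- which(marks == ti); jv <- which(marks == tj)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  sapply(r, function(ri) {
    s <- 0
    for (u in iu) for (v in jv) {
      if (u == v) next
      d <- oracle_pair_dist(x[u], y[u], x[v], y[v], window,
                            toroidal = correction == "toroidal")
      if (d <= ri) {
        e <- if (correction == "translation") {
          oracle_trans_weight(x[u], y[u], x[v], y[v], window)
        } else 1
        s <- s + e
      }
    }
    area / (length(iu) * length(jv)) * s
  })
}

oracle_epan <- function(t, h) if (abs(t) < h) 0.75 / h * (1 - (t / h)^2) else 0

oracle_g <- function(x, y, window, r, h, correction = "none") {
  n <- length(x)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  lambda2 <- n * (n - 1) / area^2
  sapply(r, function(ri) {
    s <- 0
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      d <- oracle_pair_dist(x[u], y[u], x[v], y[v])
      e <- if (correction == "translation") {
        oracle_trans_weight(x[u], y[u], x[v], y[v], window)
      } else 1
      s <- s + oracle_epan(d - ri, h) * e
    }
    s / (2 * pi * ri * lambda2 * area)
  })
}

oracle_plm <- function(x, y, marks, l, m, r, h) {
  n <- length(x)
  sapply(r, function(ri) {
    num <- 0; den <- 0
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      kh <- oracle_epan(oracle_pair_dist(x[u], y[u], x[v], y[v]) - ri, h)
      den <- den + kh
      if (marks[u] == l && marks[v] == m) num <- num + kh
    }
    if (den > 0) num / den else NA_real_
  })
}

oracle_kmm <- function(x, y, value, r, h) {
  n <- length(x)
  mu2 <- 0; np <- 0
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    mu2 <- mu2 + value[u] * value[v]; np <- np + 1
  }
  mu2 <- mu2 / np
  sapply(r, function(ri) {
    num <- 0; den <- 0
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      kh <- oracle_epan(oracle_pair_dist(x[u], y[u], x[v], y[v]) - ri, h)
      den <- den + kh
      num <- num + kh * value[u] * value[v]
    }
    if (den > 0) (num / den) / mu2 else NA_real_
  })
}

oracle_clark_evans <- function(x, y, window, toroidal = FALSE) {
  n <- length(x)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  nnd <- sapply(seq_len(n), function(u) {
    min(sapply(seq_len(n)[-u], function(v) {
      oracle_pair_dist(x[u], y[u], x[v], y[v], window, toroidal)
    }))
  })
  lambda <- n / area
  mean(nnd) * 2 * sqrt(lambda)
}

# small random marked fixture on the unit square
make_fixture <- function(n, seed, n_marks = 3, window = c(0, 1, 0, 1)) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = runif(n, window[1], window[2]),
      y = runif(n, window[3], window[4]),
      mark = sample(letters[seq_len(n_marks)], n, replace = TRUE),
      value = runif(n)
    )
  })
}
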