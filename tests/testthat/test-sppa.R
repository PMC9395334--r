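r_small <- seq(0.02, 0.24, length.out = 12)

test_that("K matches the naive double-loop oracle under every correction", {
  for (seed in c(1, 2, 3)) {
    p <- make_fixture(50, seed = seed)
    pat <- mpp(p, c(0, 1, 0, 1))
    for (corr in c("none", "translation", "toroidal")) {
      est <- k_function(pat, r = r_small, correction = corr)$estimate
      expect_equal(est, oracle_k(p$x, p$y, c(0, 1, 0, 1), r_small, corr),
                   tolerance = 1e-10)
    }
  }
})

test_that("the two-point pattern has the hand-computed step K", {
  pat <- mpp(tibble::tibble(x = c(0.3, 0.6), y = c(0.5, 0.5)), c(0, 1, 0, 1))
  k <- k_function(pat, r = c(0.1, 0.2, 0.29, 0.3, 0.4), correction = "none")
  expect_equal(k$estimate, c(0, 0, 0, 1, 1))
})

test_that("K is non-decreasing and bounded-r is enforced", {
  pat <- mpp(make_fixture(80, seed = 4), c(0, 1, 0, 1))
  k <- k_function(pat)
  expect_true(all(diff(k$estimate) >= 0))
  expect_error(k_function(pat, r = c(0.1, 0.6)), "half the shorter",
               class = "markscape_validation_error")
  expect_error(k_function(mpp(tibble::tibble(x = 0.5, y = 0.5), c(0, 1, 0, 1))),
               class = "markscape_validation_error")
})

test_that("cross-K matches its oracle, is symmetric, and reduces to K", {
  for (seed in c(5, 6)) {
    p <- make_fixture(60, seed = seed)
    pat <- mpp(p, c(0, 1, 0, 1))
    for (corr in c("none", "translation")) {
      kij <- cross_k_function(pat, "a", "b", r = r_small, correction = corr)
      expect_equal(kij$estimate,
                   oracle_cross_k(p$x, p$y, p$mark, "a", "b", c(0, 1, 0, 1),
                                  r_small, corr), tolerance = 1e-10)
      kji <- cross_k_function(pat, "b", "a", r = r_small, correction = corr)
      expect_equal(kij$estimate, kji$estimate, tolerance = 1e-10)
    }
    kaa <- cross_k_function(pat, "a", "a", r = r_small)
    sub <- mpp(p[p$mark == "a", ], c(0, 1, 0, 1))
    expect_equal(kaa$estimate, k_function(sub, r = r_small)$estimate)
  }
  pat <- mpp(make_fixture(20, seed = 1), c(0, 1, 0, 1))
  expect_error(cross_k_function(pat, "a", "zz", r = r_small),
               class = "markscape_validation_error")
})

test_that("the pair correlation matches its oracle and integrates its kernel", {
  for (seed in c(7, 8)) {
    p <- make_fixture(50, seed = seed)
    pat <- mpp(p, c(0, 1, 0, 1))
    for (corr in c("none", "translation")) {
      g <- pair_correlation(pat, r = r_small, bandwidth = 0.05, correction = corr)
      expect_equal(g$estimate,
                   oracle_g(p$x, p$y, c(0, 1, 0, 1), r_small, 0.05, corr),
                   tolerance = 1e-10)
    }
  }
  # Epanechnikov kernel has unit mass at any bandwidth
  for (h in c(0.01, 0.1, 1)) {
    tt <- seq(-h, h, length.out = 20001)
    mass <- sum(markscape:::epanechnikov(tt, h)) * (tt[2] - tt[1])
    expect_equal(mass, 1, tolerance = 1e-4)
  }
  pat <- mpp(make_fixture(30, seed = 2), c(0, 1, 0, 1))
  expect_warning(g0 <- pair_correlation(pat, r = c(0, 0.1), bandwidth = 0.05),
                 "r = 0")
  expect_equal(nrow(g0), 1L)
})

test_that("clustered patterns push g above 1 at short range", {
  vals <- vapply(1:5, function(s) {
    p <- simulate_matern_cluster(25, 8, 0.04, seed = 40 + s)
    mean(pair_correlation(p, r = c(0.02, 0.03, 0.04))$estimate)
  }, 1)
  expect_gt(mean(vals), 1.5)
})

test_that("the J-function separates inhibition from clustering", {
  rj <- seq(0.01, 0.05, length.out = 5)
  ssi <- simulate_ssi(300, 0.04, seed = 31)
  j_ssi <- j_function(ssi, r = rj)
  expect_true(all(j_ssi$estimate[rj < 0.04] >= 1, na.rm = TRUE))

  clu <- simulate_matern_cluster(30, 10, 0.03, seed = 32)
  j_clu <- j_function(clu, r = rj)
  expect_lt(mean(j_clu$estimate, na.rm = TRUE), 1)

  # G (uncorrected ecdf) and K are the monotone components
  nnd <- markscape:::nn_distances(ssi, "euclidean")
  expect_true(all(diff(stats::ecdf(nnd)(rj)) >= 0))
})

test_that("Clark-Evans is exact on the unit lattice and matches its oracle", {
  lat <- mpp(expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5)), c(0, 10, 0, 10))
  ce <- clark_evans_test(lat, metric = "toroidal")
  expect_equal(ce$R, 2, tolerance = 1e-13)
  expect_equal(ce$lambda, 1)

  p <- make_fixture(40, seed = 9)
  pat <- mpp(p, c(0, 1, 0, 1))
  for (metric in c("euclidean", "toroidal")) {
    ce2 <- clark_evans_test(pat, metric = metric)
    expect_equal(ce2$R, oracle_clark_evans(p$x, p$y, c(0, 1, 0, 1),
                                           metric == "toroidal"),
                 tolerance = 1e-10)
  }
  expect_true(tidy(ce)$R == ce$R)
  expect_equal(glance(ce)$n, 100L)

  # clustering shortens nearest-neighbour distances
  Rs <- vapply(1:5, function(s) {
    clark_evans_test(simulate_matern_cluster(25, 10, 0.03, seed = 50 + s),
                     "toroidal")$R
  }, 1)
  expect_true(all(Rs < 1))
})

test_that("mark connection estimates match the ordered-pair oracle", {
  for (seed in c(11, 12)) {
    p <- make_fixture(40, seed = seed)
    pat <- mpp(p, c(0, 1, 0, 1))
    for (pair in list(c("a", "a"), c("a", "b"), c("c", "b"))) {
      est <- mark_connection(pat, pair[1], pair[2], r = r_small,
                             bandwidth = 0.08)$estimate
      expect_equal(est, oracle_plm(p$x, p$y, p$mark, pair[1], pair[2],
                                   r_small, 0.08), tolerance = 1e-10)
    }
  }
  pat <- mpp(make_fixture(30, seed = 3), c(0, 1, 0, 1))
  expect_error(mark_connection(pat, "a", "zz", r = r_small),
               class = "markscape_validation_error")
})

test_that("the mark connection matrix conserves mass and is symmetric", {
  for (seed in c(13, 14)) {
    pat <- mpp(make_fixture(60, seed = seed, n_marks = 4), c(0, 1, 0, 1))
    mat <- mark_connection_matrix(pat, r = r_small, bandwidth = 0.08)
    mass <- dplyr::summarise(dplyr::group_by(mat, r), s = sum(estimate))
    expect_equal(mass$s, rep(1, length(r_small)), tolerance = 1e-9)
    wide <- dplyr::arrange(mat, r, l, m)
    flipped <- dplyr::arrange(dplyr::rename(mat, l = m, m = l), r, l, m)
    expect_equal(wide$estimate, flipped$estimate, tolerance = 1e-10)
    # matrix entries agree with single-pair calls
    one <- mark_connection(pat, "b", "d", r = r_small, bandwidth = 0.08)
    entry <- dplyr::filter(mat, l == "b", m == "d")
    expect_equal(one$estimate, entry$estimate)
  }
})

test_that("degenerate markings give degenerate mark connections", {
  p <- make_fixture(30, seed = 15)
  p$mark <- "a"
  pat <- mpp(p, c(0, 1, 0, 1))
  paa <- mark_connection(pat, "a", "a", r = r_small, bandwidth = 0.08)
  expect_true(all(paa$estimate[!is.na(paa$estimate)] == 1))

  # two spatially separated mark blocks never mix at short range
  blocks <- tibble::tibble(
    x = c(runif(25, 0, 0.2), runif(25, 0.8, 1)),
    y = runif(50),
    mark = rep(c("L", "R"), each = 25)
  )
  pb <- mpp(blocks, c(0, 1, 0, 1))
  plr <- mark_connection(pb, "L", "R", r = seq(0.02, 0.2, by = 0.02),
                         bandwidth = 0.02)
  expect_true(all(plr$estimate[!is.na(plr$estimate)] < 1e-12))
})

test_that("mark correlation matches its oracle and its constant-mark identity", {
  for (seed in c(16, 17)) {
    p <- make_fixture(40, seed = seed)
    pat <- mpp(p, c(0, 1, 0, 1))
    est <- mark_correlation(pat, r = r_small, bandwidth = 0.08)$estimate
    expect_equal(est, oracle_kmm(p$x, p$y, p$value, r_small, 0.08),
                 tolerance = 1e-10)
  }
  p <- make_fixture(50, seed = 18)
  p$value <- 7
  kc <- mark_correlation(mpp(p, c(0, 1, 0, 1)), r = r_small)
  expect_true(all(kc$estimate[!is.na(kc$estimate)] == 1))

  p$value <- 0
  expect_error(mark_correlation(mpp(p, c(0, 1, 0, 1)), r = r_small),
               class = "markscape_validation_error")

  # marks tracking a smooth spatial field correlate positively at short range
  sm <- make_fixture(400, seed = 19)
  sm$value <- sin(2 * pi * sm$x) + sin(2 * pi * sm$y) + 3 +
    withr::with_seed(20, rnorm(400, sd = 0.05))
  ks <- mark_correlation(mpp(sm, c(0, 1, 0, 1)), r = c(0.02, 0.04, 0.06))
  expect_gt(mean(ks$estimate), 1)
})

test_that("envelopes are seeded, respect the null's invariants, and cover CSR", {
  pat <- simulate_csr_n(100, seed = 60)
  e1 <- envelope(pat, "K", null = "csr", n_sim = 19, rank = 2, seed = 5,
                 r = r_small)
  e2 <- envelope(pat, "K", null = "csr", n_sim = 19, rank = 2, seed = 5,
                 r = r_small)
  expect_identical(e1, e2)
  expect_true(all(e1$lo <= e1$hi))
  expect_error(envelope(pat, "K", n_sim = 5, rank = 3),
               class = "markscape_validation_error")
  expect_error(envelope(pat, "K", null = "random_labeling", n_sim = 19, rank = 2),
               class = "markscape_validation_error")

  mk <- randomize_marks(pat, "iid", p = c(a = 0.5, b = 0.5), seed = 6)
  expect_error(envelope(mk, "p_lm", null = "csr", n_sim = 19, rank = 2,
                        l = "a", m = "b"),
               class = "markscape_validation_error")
  ep <- envelope(mk, "p_lm", null = "random_labeling", n_sim = 19, rank = 2,
                 seed = 7, r = r_small, l = "a", m = "b")
  expect_true(all(is.finite(ep$observed)))

  # random labeling holds coordinates fixed
  rl <- randomize_marks(mk, "permute", seed = 8)
  expect_identical(rl$x, mk$x)
  expect_identical(rl$y, mk$y)
})

test_that("patch-center lattices show the documented regularity artefact", {
  cm <- matrix(0L, 12, 12)
  pat <- pattern_from_labels(cm, w = 10)
  ce <- clark_evans_test(pat, metric = "toroidal")
  expect_equal(ce$R, 2, tolerance = 1e-12)
  k <- k_function(pat, r = c(5, 9.99, 10, 14), correction = "toroidal")
  expect_equal(k$estimate[1:2], c(0, 0))
  expect_gt(k$estimate[3], 0)
})

test_that("summary functions serialize with their metadata sidecar", {
  pat <- simulate_csr_n(50, seed = 70)
  k <- k_function(pat, r = r_small)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_fn(k, path)
  back <- utils::read.csv(path)
  expect_equal(back$estimate, k$estimate)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$statistic, "K")
  expect_equal(meta$correction, "translation")
})
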