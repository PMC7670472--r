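test_that("discretization: integer series under matching uniform bins is the identity", {
  x <- rep(0:3, 10)
  s <- discretize(x, n_bins = 4, method = "uniform")
  expect_identical(s$symbols, as.integer(x))
  # constant series collapses to a single bin (quantile warns)
  expect_warning(s0 <- discretize(rep(2.5, 40), n_bins = 4), "constant")
  expect_true(all(s0$symbols == 0L))
  expect_error(discretize(1:10, n_bins = 1), "n_bins")
})

test_that("quantile bins have near-equal occupancy on continuous draws", {
  x <- withr::with_seed(1, rnorm(1000))
  s <- discretize(x, n_bins = 8)
  occ <- tabulate(s$symbols + 1L, 8)
  expect_lte(max(abs(occ - 125)), 1)
})

test_that("uniform binning sends interior boundary values to the lower bin", {
  # edges at 0, 1, 2, 3: the value 1.0 belongs to bin 0, 2.0 to bin 1
  s <- discretize(c(0, 1, 1.5, 2, 3), n_bins = 3, method = "uniform")
  expect_identical(s$symbols, c(0L, 0L, 1L, 1L, 2L))
})

test_that("entropy closed forms and permutation invariance", {
  expect_equal(shannon_entropy(symbol_series(rep(0:3, 25))), 2.0)
  expect_equal(shannon_entropy(symbol_series(rep(0L, 50))), 0)
  # frequencies (1/2, 1/4, 1/4)
  expect_equal(shannon_entropy(symbol_series(c(rep(0L, 2), 1L, 2L))), 1.5)
  # relabeling symbols leaves entropy unchanged
  x <- withr::with_seed(2, sample(0:4, 300, replace = TRUE))
  perm <- c(3L, 0L, 4L, 1L, 2L)
  expect_equal(shannon_entropy(symbol_series(x, 5)),
               shannon_entropy(symbol_series(perm[x + 1], 5)),
               tolerance = 1e-12)
  # matches the independent table-based recomputation
  expect_equal(shannon_entropy(symbol_series(x, 5)), oracle_entropy(x),
               tolerance = 1e-12)
})

test_that("transfer entropy vanishes for a constant target and for self-predictable targets", {
  x <- symbol_series(withr::with_seed(3, sample(0:1, 300, TRUE)), 2)
  y_const <- symbol_series(rep(0L, 300), 2)
  expect_equal(as.numeric(transfer_entropy(x, y_const, 1)), 0)
  # alternating source, target its 1-lag copy: the target's own past already
  # determines its present, so conditioning removes all apparent transfer
  xa <- symbol_series(rep(c(0L, 1L), 150), 2)
  ya <- symbol_series(rep(c(1L, 0L), 150), 2)  # exact 1-lag copy of xa
  expect_identical(ya$symbols[2:300], xa$symbols[1:299])
  expect_equal(as.numeric(transfer_entropy(xa, ya, 1)), 0)
})

test_that("lagged-copy transfer entropy approaches 1 bit and matches the brute-force oracle", {
  n <- 10000
  x <- withr::with_seed(4, sample(0:1, n, TRUE))
  y <- c(0L, x[-n])
  te <- transfer_entropy(symbol_series(x, 2), symbol_series(y, 2), 1)
  expect_equal(as.numeric(te), 1.0, tolerance = 0.02)
  expect_equal(as.numeric(te), oracle_te(x, y, 1, 2, 2), tolerance = 1e-12)
  expect_equal(attr(te, "n_eff"), n - 1L)
})

test_that("plug-in TE equals exhaustive joint-table summation on random inputs", {
  for (i in 1:12) {
    cfg <- withr::with_seed(100 + i, {
      bx <- sample(2:6, 1); by <- sample(2:6, 1)
      n <- sample(500:1500, 1); lag <- sample(1:3, 1)
      list(bx = bx, by = by, lag = lag,
           x = sample(0:(bx - 1), n, TRUE), y = sample(0:(by - 1), n, TRUE))
    })
    te <- transfer_entropy(symbol_series(cfg$x, cfg$bx),
                           symbol_series(cfg$y, cfg$by), cfg$lag,
                           min_length = 50)
    expect_gte(as.numeric(te), 0)
    expect_equal(as.numeric(te),
                 oracle_te(cfg$x, cfg$y, cfg$lag, cfg$bx, cfg$by),
                 tolerance = 1e-12)
  }
})

test_that("missing values are dropped pairwise-complete, not fabricated", {
  n <- 800
  x <- withr::with_seed(5, sample(0:1, n, TRUE))
  y <- c(0L, x[-n])
  x_na <- x; x_na[sample(n, 100)] <- NA
  te <- transfer_entropy(symbol_series(x_na, 2), symbol_series(y, 2), 1,
                         min_length = 50)
  expect_lt(attr(te, "n_eff"), n - 1L)
  expect_gt(as.numeric(te), 0.5)
})

test_that("series shorter than the embedding minimum raise an informative error", {
  s <- symbol_series(rep(0:1, 10), 2)
  expect_error(transfer_entropy(s, s, 1, min_length = 100), "at least 100")
  expect_error(transfer_entropy(s, s, 0), "lag")
})

test_that("the shuffle threshold is deterministic given its seed and separates signal from null", {
  n <- 1200
  x <- withr::with_seed(6, sample(0:3, n, TRUE))
  y <- c(0L, x[-n])
  sx <- symbol_series(x, 4); sy <- symbol_series(y, 4)
  t1 <- shuffle_threshold(sx, sy, 1, n_shuffles = 20, seed = 9)
  t2 <- shuffle_threshold(sx, sy, 1, n_shuffles = 20, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # a deterministic copy is detected far above the null
  tt <- te_test(sx, sy, 1, n_shuffles = 100, seed = 3)
  expect_true(tt$significant)
  expect_gt(tt$te / tt$threshold, 5)
  # an independent pair is (almost always) not
  y_ind <- symbol_series(withr::with_seed(7, sample(0:3, n, TRUE)), 4)
  tt0 <- te_test(sx, y_ind, 1, n_shuffles = 100, seed = 3)
  expect_false(tt0$significant)
  expect_error(shuffle_threshold(sx, sy, 1, n_shuffles = 5), "n_shuffles")
})
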