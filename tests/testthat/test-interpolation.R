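test_that("linear interpolation reproduces hand-computed gradient values", {
  expect_equal(interpolate_linear(c(0, 2), c(2, 4), 1), 3)
  expect_equal(interpolate_linear(c(0, 2), c(2, 4), 0), 2)
  # bracketing pair (3,7),(6,1): 7 + (4-3) * (1-7)/(6-3) = 5
  expect_equal(interpolate_linear(c(0, 3, 6), c(1, 7, 1), 4), 5)
  expect_error(interpolate_linear(c(0, 3), c(1, 2), 4), "span")
  expect_error(interpolate_linear(c(0, 3), c(1, 2), -1), "span")
})

test_that("all three methods satisfy the interpolation condition at nodes", {
  set.seed(101)
  for (rep in 1:12) {
    s <- random_series()
    q <- s$months
    expect_equal(interpolate_linear(s$months, s$values, q), s$values,
      tolerance = 1e-12
    )
    expect_equal(interpolate_pchip(s$months, s$values, q), s$values,
      tolerance = 1e-12
    )
    expect_equal(interpolate_barycentric(s$months, s$values, q), s$values,
      tolerance = 1e-9
    )
  }
})

test_that("PCHIP zeroes the derivative at slope sign changes (no overshoot)", {
  # local max at (1, 1): the interpolant must not exceed the node value
  q <- seq(0, 2, by = 0.01)
  y <- interpolate_pchip(c(0, 1, 2), c(0, 1, 0), q)
  expect_true(all(y <= 1 + 1e-12))
  expect_equal(interpolate_pchip(c(0, 1, 2), c(0, 1, 0), 1), 1)
})

test_that("PCHIP agrees with an independent reference implementation", {
  skip_if_not_installed("pracma")
  x <- c(0, 3, 9, 12)
  y <- c(1, 2, 8, 9)
  q <- seq(0, 12, by = 0.5)
  expect_equal(interpolate_pchip(x, y, q), pracma::pchip(x, y, q),
    tolerance = 1e-9
  )
  # non-monotone irregular series
  set.seed(7)
  for (rep in 1:10) {
    s <- random_series()
    q <- seq(min(s$months), max(s$months), by = 0.25)
    expect_equal(
      interpolate_pchip(s$months, s$values, q),
      pracma::pchip(s$months, s$values, q),
      tolerance = 1e-9
    )
  }
})

test_that("barycentric interpolation reproduces polynomials and Lagrange form", {
  x <- 0:3
  expect_equal(interpolate_barycentric(x, x^2, 1), 1, tolerance = 1e-9)
  q <- seq(0, 3, by = 0.1)
  expect_equal(interpolate_barycentric(x, x^2, q), q^2, tolerance = 1e-9)
  # direct Lagrange oracle
  xs <- c(0, 3, 6)
  ys <- c(1, 7, 1)
  expect_equal(
    interpolate_barycentric(xs, ys, 4),
    lagrange_oracle(xs, ys, 4),
    tolerance = 1e-9
  )
  set.seed(11)
  for (rep in 1:10) {
    s <- random_series(n_obs = sample(3:7, 1))
    q <- runif(5, min(s$months), max(s$months))
    expect_equal(
      interpolate_barycentric(s$months, s$values, q),
      vapply(q, function(qq) lagrange_oracle(s$months, s$values, qq), numeric(1)),
      tolerance = 1e-7
    )
  }
  expect_error(interpolate_barycentric(c(0, 1), c(1, 2), 0.5, max_nodes = 1), "nodes")
})

test_that("the three methods coincide on two nodes", {
  q <- seq(0, 5, by = 0.5)
  a <- interpolate_linear(c(0, 5), c(2, 7), q)
  b <- interpolate_pchip(c(0, 5), c(2, 7), q)
  d <- interpolate_barycentric(c(0, 5), c(2, 7), q)
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(a, d, tolerance = 1e-9)
})

test_that("linear and PCHIP stay within bracketing node values; barycentric need not", {
  set.seed(13)
  for (rep in 1:8) {
    s <- random_series()
    for (i in seq_len(length(s$months) - 1)) {
      q <- seq(s$months[i], s$months[i + 1], length.out = 9)
      lo <- min(s$values[i:(i + 1)]) - 1e-9
      hi <- max(s$values[i:(i + 1)]) + 1e-9
      expect_true(all(dplyr::between(interpolate_linear(s$months, s$values, q), lo, hi)))
      expect_true(all(dplyr::between(interpolate_pchip(s$months, s$values, q), lo, hi)))
    }
  }
  # Runge-style oscillation: a spike forces the global polynomial outside
  # the data range (here it undershoots the minimum between nodes)
  x <- 0:6
  y <- c(1, 1, 1, 10, 1, 1, 1)
  q <- seq(0, 6, by = 0.05)
  p <- interpolate_barycentric(x, y, q)
  expect_true(min(p) < min(y) - 0.5 || max(p) > max(y) + 0.5)
})

test_that("fill_timeline flags real months and fills the gaps", {
  # no missing months: identity
  tl <- fill_timeline(0:3, c(1, 2, 3, 4), method = "linear", upto_month = 3)
  expect_true(all(tl$is_real))
  expect_equal(tl$value, c(1, 2, 3, 4))

  tl <- fill_timeline(c(0, 3, 6), c(10, 13, 10), method = "linear", upto_month = 6)
  expect_equal(nrow(tl), 7)
  expect_equal(sum(!tl$is_real), 4)
  expect_equal(tl$month[!tl$is_real], c(1, 2, 4, 5))
  expect_equal(tl$value[tl$month == 1], 11)

  # real months keep exact observed values under every method
  set.seed(17)
  s <- random_series()
  for (m in c("linear", "pchip", "barycentric")) {
    tl <- fill_timeline(s$months, s$values, method = m, upto_month = max(s$months))
    expect_equal(tl$value[tl$is_real], s$values)
    expect_equal(nrow(tl), max(s$months) - min(s$months) + 1)
  }
  expect_error(fill_timeline(c(0, 3, 6), c(1, 2, 3), upto_month = 5), "observed")
})
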