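random_window <- function(r = 12, seed = 1) {
  set.seed(seed)
  assemble_features(
    exp(rnorm(r + 1, log(100), 0.1)),
    sample(c(TRUE, FALSE), r + 1, replace = TRUE),
    age = 60, sex = 1, marker = "glucose_ac"
  )
}

test_that("the longitudinal block honours its shape and activation contracts", {
  m <- glp_model("glucose_ac", seed = 3)
  w <- random_window()
  out <- libc_forward(m, w)
  expect_equal(dim(out$condensed), c(13, 5))
  expect_length(out$next_step, 5)
  expect_true(all(out$condensed >= 0)) # terminal ReLU
  expect_equal(out$condensed[13, ], out$next_step)
  expect_error(libc_forward(m, w[, 1:4]), "5 features")
  expect_error(libc_forward(m, w[1:5, ]), "r \\+ 1")
  # batch input
  X <- array(0, c(2, 13, 5))
  X[1, , ] <- w
  X[2, , ] <- random_window(seed = 2)
  ob <- libc_forward(m, X)
  expect_equal(dim(ob$condensed), c(2, 13, 5))
  expect_equal(ob$condensed[1, , ], out$condensed, tolerance = 1e-12)
})

test_that("the regressor computes W2 relu(W1 v + b1) + b2", {
  m <- glp_model("ua", seed = 4)
  # zero weights -> zero output
  m0 <- m
  m0$params$W1[] <- 0
  m0$params$b1[] <- 0
  m0$params$W2[] <- 0
  m0$params$b2[] <- 0
  expect_equal(regressor_forward(m0, rep(1, 5)), 0)
  # hand-set weights, manual arithmetic
  mh <- m
  mh$params$W1 <- matrix(c(
    1, 0, 0, 0, 1,
    0, -1, 1, 0, 0
  ), nrow = 5, ncol = 2)
  mh$params$b1 <- c(0.5, -0.25)
  mh$params$W2 <- matrix(c(2, -3), 2, 1)
  mh$params$b2 <- 0.1
  v <- c(0.2, 0.4, 1, 0, 0.6)
  h <- pmax(c(
    1 * 0.2 + 0 + 0 + 0 + 1 * 0.6 + 0.5,
    0 - 1 * 0.4 + 1 * 1 + 0 + 0 - 0.25
  ), 0)
  expect_equal(regressor_forward(mh, v), 2 * h[1] - 3 * h[2] + 0.1)
  expect_length(regressor_forward(m, matrix(runif(10), 2, 5)), 2)
  expect_error(regressor_forward(m, 1:3), "width")
})

test_that("direction-tied weights make the block symmetric under time reversal", {
  m <- glp_model("wbc", seed = 5)
  p <- m$params
  p$b_Wx <- p$f_Wx
  p$b_Wh <- p$f_Wh
  p$b_b <- p$f_b
  # condensing map invariant under swapping the two direction blocks
  p$Wc[6:10, ] <- p$Wc[1:5, ]
  m$params <- p
  w <- random_window(seed = 6)
  fwd <- libc_forward(m, w)$condensed
  rev_out <- libc_forward(m, w[13:1, ])$condensed
  expect_equal(rev_out, fwd[13:1, ], tolerance = 1e-12)
})

test_that("fixed weights and input give bit-stable outputs", {
  m <- glp_model("ldl", seed = 7)
  w <- random_window(seed = 8)
  a <- rollout(m, w, g = 3)
  b <- rollout(m, w, g = 3)
  expect_identical(a$progress_out, b$progress_out)
  expect_identical(a$progress_emb, b$progress_emb)
})

test_that("rollout with g = 0 is a single pass through block and regressor", {
  m <- glp_model("glucose_ac", seed = 9)
  w <- random_window(seed = 10)
  r0 <- rollout(m, w, g = 0)
  lf <- libc_forward(m, w)
  expect_equal(r0$progress_emb, lf$next_step, tolerance = 1e-14)
  expect_equal(r0$progress_out, regressor_forward(m, lf$next_step),
    tolerance = 1e-14
  )
  expect_equal(nrow(r0$steps), 1)
})

test_that("rollout equals a hand-written window-shifting loop", {
  tab <- default_thresholds()
  m <- glp_model("glucose_ac", seed = 11)
  w <- random_window(seed = 12)
  g <- 3
  # independent oracle: explicit loop using only the public single-pass API
  win <- w
  emb <- NULL
  for (s in 0:g) {
    nxt <- libc_forward(m, win)$next_step
    emb <- nxt
    if (s < g) {
      newrow <- c(
        nxt[1], win[13, "age"], win[13, "sex"], 0,
        discretize(denormalize_value(nxt[1]), "glucose_ac", tab) /
          length(tab$glucose_ac$cuts)
      )
      win <- rbind(win[2:13, ], newrow)
      rownames(win) <- NULL
    }
  }
  rl <- rollout(m, w, g = g)
  expect_equal(rl$progress_emb, emb, tolerance = 1e-12)
  expect_equal(rl$progress_out, regressor_forward(m, emb), tolerance = 1e-12)
  expect_equal(nrow(rl$steps), g + 1)
})

test_that("batched rollout with heterogeneous gaps equals per-sample rollout", {
  m <- glp_model("glucose_ac", seed = 13)
  B <- 5
  gvec <- c(0L, 2L, 6L, 1L, 4L)
  X <- array(0, c(B, 13, 5))
  for (i in 1:B) X[i, , ] <- random_window(seed = 20 + i)
  batch <- rollout(m, X, gvec)
  for (i in 1:B) {
    single <- rollout(m, matrix(X[i, , ], 13, 5), g = gvec[i])
    expect_equal(batch$progress_emb[i, ], single$progress_emb, tolerance = 1e-12)
    expect_equal(batch$progress_out[i], single$progress_out, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences through the rollout", {
  set.seed(31)
  p <- labprogress:::init_params()
  B <- 3
  X <- array(stats::runif(B * 13 * 5), c(B, 13, 5))
  X[, , 4] <- round(X[, , 4])
  X[, , 3] <- 1
  gvec <- c(0L, 2L, 5L)
  y <- stats::runif(B)
  tab <- default_thresholds()
  lg <- labprogress:::loss_and_grads(X, gvec, y, p, "glucose_ac", tab)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(seq_along(p[[nm]]), min(3, length(p[[nm]])))) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- labprogress:::loss_and_grads(X, gvec, y, pp, "glucose_ac", tab)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- labprogress:::loss_and_grads(X, gvec, y, pp, "glucose_ac", tab)$loss
      expect_equal(lg$grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip through the YAML format", {
  m <- glp_model("ua", seed = 14)
  m$stage <- "two_stage"
  path <- withr::local_tempfile(fileext = ".yaml")
  write_glp_model(m, path)
  back <- read_glp_model(path)
  expect_equal(back$marker, "ua")
  expect_equal(back$stage, "two_stage")
  w <- random_window(seed = 15)
  expect_equal(
    rollout(back, w, 2)$progress_out,
    rollout(m, w, 2)$progress_out,
    tolerance = 1e-12
  )
})

test_that("tidy and glance summarise a model", {
  m <- glp_model("wbc", seed = 16)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$n), sum(lengths(m$params)))
  gl <- glance(m)
  expect_equal(gl$marker, "wbc")
  expect_true(is.na(gl$final_loss))
})
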