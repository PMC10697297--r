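test_that("r_squared matches hand arithmetic and its boundary cases", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 3), y), 0)
  expect_equal(r_squared(c(1, 2, 5), y), -1) # 1 - 4/2
  expect_error(r_squared(1:3, c(2, 2, 2)), "identical")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("stage-1 learns a constant-valued series to near-zero loss", {
  months <- seq(0, 45, by = 3)
  obs <- tidyr::crossing(patient_id = 1:8, month = months) |>
    dplyr::mutate(marker = "glucose_ac", value = 100)
  patients <- tibble::tibble(patient_id = 1:8, age = 60, sex = 1)
  cfg <- train_config(epochs = 50, seed = 2)
  fr <- stage1_dataset(obs, patients, "glucose_ac", cfg)
  m <- train_stage1(fr, cfg)
  expect_lt(tail(m$loss[[1]]$loss, 1), 1e-4)
})

test_that("training is reproducible and its loss decreases over epochs", {
  co <- tiny_cohort()
  cfg <- train_config(epochs = 8, seed = 3)
  fr <- stage1_dataset(co$observations, co$patients, "glucose_ac", cfg)
  m1 <- train_stage1(fr, cfg)
  m2 <- train_stage1(fr, cfg)
  expect_identical(m1$params, m2$params)
  trace <- m1$loss[[1]]$loss
  expect_lt(tail(trace, 1), trace[1])
  expect_error(
    train_stage1(take_patients(fr, integer(0)), cfg),
    "empty frame set"
  )
})

test_that("stage 2 with all-zero gaps reproduces the stage-1 gradient path", {
  co <- tiny_cohort(seed = 77)
  cfg <- train_config(epochs = 3, seed = 9)
  fr <- stage1_dataset(co$observations, co$patients, "ldl", cfg)
  init <- glp_model("ldl", seed = cfg$seed)
  m1 <- train_stage1(fr, cfg, model = init)
  # same windows and targets presented as a stage-2 set with g = 0
  s2 <- structure(
    list(
      X = fr$X, y = fr$y, g = rep(0L, length(fr$y)),
      patient_id = fr$patient_id, marker = "ldl", r = 12L, g_max = 6L,
      interpolation = "linear"
    ),
    class = "glp_stage2_set"
  )
  m2 <- train_stage2(s2, init, cfg)
  expect_equal(m1$params, m2$params, tolerance = 1e-14)
})

test_that("zero-epoch stages collapse the regimes onto each other", {
  co <- tiny_cohort(seed = 78)
  cfg_sup <- train_config(epochs = 2, seed = 4, regime = "supervised")
  fr <- stage1_dataset(co$observations, co$patients, "wbc", cfg_sup)
  s2 <- stage2_dataset(co$observations, co$patients, "wbc", cfg_sup)
  sup <- train_glp(fr, s2, cfg_sup)
  two_no_s2 <- train_glp(fr, s2, train_config(
    epochs = 2, seed = 4,
    regime = "two_stage", epochs_stage2 = 0
  ))
  expect_equal(sup$params, two_no_s2$params, tolerance = 1e-14)
  ssl <- train_glp(fr, s2, train_config(epochs = 2, seed = 4, regime = "ssl"))
  two_no_s1 <- train_glp(fr, s2, train_config(
    epochs = 2, seed = 4,
    regime = "two_stage", epochs_stage1 = 0
  ))
  expect_equal(ssl$params, two_no_s1$params, tolerance = 1e-14)
})

test_that("stage-2 guards and hybrid preconditions hold", {
  co <- tiny_cohort(seed = 79)
  cfg <- train_config(epochs = 1, seed = 6)
  fr <- stage1_dataset(co$observations, co$patients, "ua", cfg)
  s2 <- stage2_dataset(co$observations, co$patients, "ua", cfg)
  bad <- s2
  bad$g[1] <- 99L
  init <- glp_model("ua", seed = 1)
  expect_error(train_stage2(bad, init, cfg), "g_max")
  empty <- take_patients(s2, integer(0))
  expect_error(train_hybrid(fr, empty, cfg), "non-empty")
  m <- train_hybrid(fr, s2, cfg)
  expect_s3_class(m, "glp_model")
  expect_true(is.finite(evaluate_forecast(m, s2)))
  m2 <- train_hybrid(fr, s2, cfg)
  expect_identical(m$params, m2$params)
})

test_that("cross-validation partitions patients without leakage", {
  co <- simulate_pretext_cohort(cohort_config(
    n_patients = 15, seed = 80, visit_dropout_prob = 0,
    span_months_range = c(18, 36)
  ))
  cfg <- train_config(
    epochs = 1, seed = 7, n_folds = 5, n_repeats = 5,
    batch_size = 64
  )
  ids <- sort(unique(co$observations$patient_id))
  for (i in 1:5) {
    sp <- labprogress:::make_split(ids, cfg, cfg$seed + 104729L * i)
    expect_length(intersect(sp$test_ids, sp$train_ids), 0)
    expect_setequal(c(sp$test_ids, sp$train_ids), ids)
    # folds partition the training patients
    expect_length(sp$folds, length(sp$train_ids))
    expect_setequal(unique(sp$folds), 1:5)
  }
  ev <- cross_validate(co, cfg, marker = "glucose_ac")
  expect_equal(nrow(ev), 25) # n_folds x n_repeats entries
  expect_true(all(ev$r2 <= 1))
  expect_equal(attr(ev, "mean_r2"), mean(ev$r2))
  expect_error(
    cross_validate(tiny_cohort(n = 3, seed = 1), cfg),
    "too few"
  )
})

test_that("the ablation grid shares splits and averages consistently", {
  # dropout-free visits keep every patient's stage-2 gap small, so each
  # test split retains enough eligible forecasting targets
  co <- simulate_pretext_cohort(cohort_config(
    n_patients = 10, seed = 81, visit_dropout_prob = 0,
    span_months_range = c(18, 36)
  ))
  cfg <- train_config(epochs = 1, seed = 8, n_folds = 1, n_repeats = 2)
  ab <- ablation_grid(co,
    regimes = c("supervised", "ssl"), methods = "linear",
    certain_range = c(0L, 1L), cfg = cfg, marker = "glucose_ac"
  )
  expect_equal(nrow(ab$results), 2 * 1 * 2 * cfg$n_folds * cfg$n_repeats)
  expect_equal(nrow(ab$summary), 4)
  # averaging the per-fold rows reproduces the summary exactly
  manual <- ab$results |>
    dplyr::group_by(regime, interpolation, certain) |>
    dplyr::summarise(mean_r2 = mean(r2), .groups = "drop")
  expect_equal(
    dplyr::arrange(manual, regime, certain)$mean_r2,
    dplyr::arrange(ab$summary, regime, certain)$mean_r2,
    tolerance = 1e-12
  )
  # identical splits across cells: recompute and compare
  ids <- sort(unique(co$observations$patient_id))
  sp1 <- labprogress:::make_split(ids, cfg, cfg$seed + 104729L)
  sp2 <- labprogress:::make_split(ids, cfg, cfg$seed + 104729L)
  expect_identical(sp1$test_ids, sp2$test_ids)
})
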