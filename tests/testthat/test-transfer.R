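downstream_fixture <- function(n_pos = 12, n_neg = 40, effect_size = 1, seed = 3) {
  simulate_downstream_cohort(cohort_config(seed = seed),
    n_pos = n_pos,
    n_neg = n_neg, effect_size = effect_size
  )
}

test_that("downsampling balances classes exactly and reproducibly", {
  d <- downstream_fixture(n_pos = 42, n_neg = 441)
  b <- balance_downsample(d, seed = 2)
  expect_equal(nrow(b), 84)
  expect_equal(sum(b$event_label == "positive"), 42)
  expect_identical(b, balance_downsample(d, seed = 2))
  # already balanced input: all records kept
  eq <- downstream_fixture(n_pos = 10, n_neg = 10)
  expect_equal(
    sort(balance_downsample(eq, seed = 1)$patient_id),
    sort(eq$patient_id)
  )
  none <- d[d$event_label == "negative", ]
  expect_error(balance_downsample(none), "no positive")
})

test_that("episodic records expand into carry-back windows", {
  d <- downstream_fixture()
  ef <- episodic_to_frame(d[1, ], "glucose_ac", r = 12)
  expect_equal(dim(ef$features), c(13, 5))
  expect_equal(sum(ef$features[, "certain"]), 1) # exactly one real month
  expect_true(ef$features[13, "certain"] == 1)
  expect_equal(length(unique(ef$features[, "value"])), 1) # constant carry-back
  expect_equal(
    unname(denormalize_value(ef$features[13, "value"])),
    d$glucose_ac[1],
    tolerance = 1e-9
  )
  expect_equal(ef$g, d$gap_months[1])
  z <- episodic_to_frame(d[1, ], "glucose_ac", r = 12, fill = "zero")
  expect_equal(z$features[1:12, "value"], rep(0, 12))
  d_na <- d[1, ]
  d_na$ldl <- NA_real_
  expect_error(episodic_to_frame(d_na, "ldl"), "no value")
})

fixture_models <- function(markers = c(
                             "chol_hdl", "ldl", "ldl_hdl",
                             "glucose_ac", "wbc", "ua"
                           )) {
  ms <- lapply(seq_along(markers), function(i) glp_model(markers[i], seed = 100 + i))
  names(ms) <- markers
  ms
}

test_that("representation extraction is frozen and has fixed widths", {
  d <- downstream_fixture(n_pos = 4, n_neg = 6)
  d$gap_months <- pmin(d$gap_months, 8L) # keep the test quick
  models <- fixture_models()
  before <- lapply(models, `[[`, "params")
  reps <- extract_representations(models, d, horizon = "g")
  after <- lapply(models, `[[`, "params")
  expect_identical(before, after) # extraction never mutates parameters
  expect_equal(nrow(reps), 10)
  expect_length(grep("^emb_", names(reps)), 30)
  expect_length(grep("^out_", names(reps)), 6)
  expect_length(grep("^orig_", names(reps)), 8) # 6 markers + age + sex
})

test_that("a zero-gap patient's representations equal a single pass", {
  d <- downstream_fixture(n_pos = 2, n_neg = 2)
  d$gap_months <- c(0L, 3L, 5L, 2L)
  models <- fixture_models(c("glucose_ac", "ua"))
  reps <- extract_representations(models[1], d, horizon = "g")
  w <- episodic_to_frame(d[1, ], "glucose_ac")$features
  direct <- libc_forward(models$glucose_ac, w)$next_step
  expect_equal(unlist(reps[1, paste0("emb_glucose_ac_", 1:5)]),
    direct,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_equal(reps$out_glucose_ac[1],
    regressor_forward(models$glucose_ac, direct),
    tolerance = 1e-12
  )
  # halved horizon rolls to floor(g/2)
  rh <- extract_representations(models[1], d, horizon = "g_half")
  manual <- rollout(models$glucose_ac, episodic_to_frame(d[3, ], "glucose_ac")$features,
    g = 2
  )
  expect_equal(rh$out_glucose_ac[3], manual$progress_out, tolerance = 1e-12)
})

test_that("confusion metrics match the hand-built matrix", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)
  met <- labprogress:::confusion_metrics(truth, pred, prob = pred)
  expect_equal(unname(met["sensitivity"]), 0.8)
  expect_equal(unname(met["specificity"]), 0.9)
  expect_equal(unname(met["accuracy"]), 0.85)
  expect_equal(unname(met["precision"]), 8 / 9)
  expect_equal(unname(met["f1"]), 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
})

test_that("the four classifier families separate a separable cloud", {
  set.seed(21)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  # informative dimensions are noise-free so every train/test split sees
  # the same two class points; tree thresholds cannot land on a held-out
  # extreme
  X <- cbind(y * 8, -y * 8, matrix(rnorm(2 * n), n))
  rep_out <- run_classifiers(X, y, n_repeats = 2, n_folds = 3, seed = 1)
  expect_true(all(rep_out$metrics$accuracy == 1))
  expect_true(all(rep_out$metrics$auroc == 1))
  expect_equal(rep_out$kappa, 1) # full agreement on a separable problem
  expect_error(run_classifiers(X, rep(1, n)), "two classes")
})

test_that("label-shuffled features score inside the chance band", {
  set.seed(22)
  n <- 80
  X <- matrix(rnorm(n * 4), n)
  y <- sample(rep(c(0, 1), each = n / 2))
  rep_out <- run_classifiers(X, y, n_repeats = 2, n_folds = 4, seed = 2)
  # 95% null band for AUC (Hanley-McNeil variance at AUC = 0.5)
  band <- 1.96 * sqrt((n / 2 + n / 2 + 1) / (12 * (n / 2)^2))
  expect_true(all(abs(rep_out$metrics$auroc - 0.5) < 2 * band))
})

test_that("Cohen's kappa matches hand values, a reference and the null", {
  expect_equal(mean_pairwise_kappa(list(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))), 1)
  expect_equal(mean_pairwise_kappa(list(c(1, 1, 0, 0), c(0, 0, 1, 1))), -1)
  expect_error(mean_pairwise_kappa(list(c(1, 0), c(1, 0, 1))), "mismatch")
  # agreement with an independent implementation
  set.seed(23)
  a <- sample(0:1, 40, replace = TRUE)
  b <- sample(0:1, 40, replace = TRUE)
  expect_equal(
    mean_pairwise_kappa(list(a, b)),
    e1071::classAgreement(table(a, b))$kappa,
    tolerance = 1e-12
  )
  # independent random predictions agree only at chance level
  ks <- replicate(1000, mean_pairwise_kappa(list(
    sample(0:1, 30, replace = TRUE), sample(0:1, 30, replace = TRUE)
  )))
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("snapshot export inverts normalization at three horizons", {
  d <- downstream_fixture(n_pos = 3, n_neg = 3)
  d$gap_months <- pmin(d$gap_months, 6L)
  models <- fixture_models(c("glucose_ac", "ua"))
  snap <- snapshot_export(models, d)
  expect_equal(nrow(snap), 6 * 3) # patients x horizons
  expect_equal(levels(snap$horizon), c("0", "g/2", "g"))
  reps0 <- extract_representations(models, d, horizon = "zero")
  expect_equal(
    snap$glucose_ac[snap$horizon == "0"],
    denormalize_value(reps0$out_glucose_ac),
    tolerance = 1e-12
  )
})
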