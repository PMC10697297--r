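#' Training configuration
#'
#' Collects the hyperparameters of the two-stage training procedure and
#' its evaluation protocol. Defaults follow the study design: 50 epochs
#' per stage with the Adam optimizer, a 12-month window, a maximum
#' forecasting gap of `r/2` months, an 80:20 patient-level train/test
#' split, 5-fold cross-validation and 5 repetitions.
#'
#' @param epochs Epochs per training stage (default 50).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-2).
#' @param regime One of `"supervised"` (stage 1 only), `"ssl"` (stage 2
#'   from fresh weights), `"hybrid"` (interleaved), `"two_stage"`.
#' @param interpolation Interpolation method for stage-1 frames.
#' @param certain_min Minimum real observations per stage-1 frame (0-5).
#' @param r Window span in months.
#' @param g_max Maximum stage-2 gap (default `floor(r/2)`).
#' @param seed Integer seed governing initialization and batching.
#' @param n_folds Cross-validation folds (default 5; 1 means no inner
#'   folds, train on the whole training split).
#' @param n_repeats Repetitions of the whole procedure (default 5).
#' @param test_fraction Held-out patient fraction (default 0.2).
#' @param epochs_stage1,epochs_stage2 Stage-specific epoch overrides
#'   (default `epochs`); zero epochs leaves the stage out entirely.
#' @param clip_norm Global gradient-norm clip applied to every update
#'   (default 1). Backpropagation through the autoregressive rollout can
#'   produce occasional exploding gradients that permanently kill ReLU
#'   units; clipping is the standard recurrent-network safeguard.
#' @param n_restarts Random restarts for stages that begin from random
#'   weights (default 3). Each candidate initialization is trained for a
#'   burn-in fifth of the epoch budget and the one with the lowest
#'   training loss continues; small recurrent networks on unscaled
#'   log1p inputs otherwise fall into a mean-prediction basin for a
#'   noticeable fraction of seeds. Stages that refine an already trained
#'   model never re-initialize.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, learning_rate = 1e-2,
                         regime = c("two_stage", "supervised", "ssl", "hybrid"),
                         interpolation = c("linear", "pchip", "barycentric"),
                         certain_min = 0L, r = 12L, g_max = floor(r / 2),
                         seed = 1L, n_folds = 5L, n_repeats = 5L,
                         test_fraction = 0.2,
                         epochs_stage1 = epochs, epochs_stage2 = epochs,
                         clip_norm = 1, n_restarts = 3L) {
  regime <- match.arg(regime)
  interpolation <- match.arg(interpolation)
  stopifnot(
    epochs >= 0L, batch_size >= 1L, learning_rate > 0,
    test_fraction > 0, test_fraction < 1, n_folds >= 1L, n_repeats >= 1L,
    certain_min >= 0L, r >= 1L, g_max >= 0L
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, regime = regime,
      interpolation = interpolation, certain_min = as.integer(certain_min),
      r = as.integer(r), g_max = as.integer(g_max), seed = as.integer(seed),
      n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
      test_fraction = test_fraction,
      epochs_stage1 = as.integer(epochs_stage1),
      epochs_stage2 = as.integer(epochs_stage2),
      clip_norm = clip_norm, n_restarts = as.integer(n_restarts)
    ),
    class = "train_config"
  )
}

patient_static <- function(patients, id) {
  row <- patients[patients$patient_id == id, ]
  list(age = row$age[1L], sex = row$sex[1L])
}

#' Build the stage-1 training set for one marker
#'
#' For each patient, the marker's observations are interpolated onto the
#' monthly grid up to the second-to-last observation, framed into
#' `(r+1)`-month sliding windows with next-month targets, filtered by the
#' certainty criterion, and encoded into feature matrices.
#'
#' @param observations Long tibble `patient_id, marker, month, value`.
#' @param patients Tibble `patient_id, age, sex`.
#' @param marker Marker name.
#' @param cfg A [train_config()].
#' @param thresholds Threshold table for the discrete encoding.
#' @return A list of class `glp_frames`: `X` (`N x (r+1) x 5` array), `y`
#'   (normalized targets), `n_real`, `patient_id`, plus the settings used.
#' @export
stage1_dataset <- function(observations, patients, marker, cfg = train_config(),
                           thresholds = default_thresholds()) {
  obs <- observations[observations$marker == marker, ]
  ids <- unique(obs$patient_id)
  Xl <- list()
  yl <- nl <- pl <- c()
  for (id in ids) {
    o <- obs[obs$patient_id == id, ]
    o <- o[order(o$month), ]
    if (nrow(o) < 3L) next
    anc <- locate_anchors(o$month, o$value)
    tl <- fill_timeline(o$month, o$value,
      method = cfg$interpolation, upto_month = anc$tm
    )
    tl$value <- pmax(tl$value, 0) # polynomial interpolation may undershoot
    fr <- build_stage1_frames(tl, r = cfg$r, certain_min = cfg$certain_min)
    if (nrow(fr) == 0L) next
    st <- patient_static(patients, id)
    for (i in seq_len(nrow(fr))) {
      Xl[[length(Xl) + 1L]] <- assemble_features(
        fr$values[[i]], fr$is_real[[i]], st$age, st$sex, marker, thresholds
      )
      yl <- c(yl, normalize_value(max(fr$target_value[i], 0)))
      nl <- c(nl, fr$n_real[i])
      pl <- c(pl, id)
    }
  }
  N <- length(Xl)
  X <- array(0, c(N, cfg$r + 1L, N_FEAT))
  for (i in seq_len(N)) X[i, , ] <- Xl[[i]]
  structure(
    list(
      X = X, y = yl, n_real = nl, patient_id = pl, marker = marker,
      r = cfg$r, interpolation = cfg$interpolation,
      certain_min = cfg$certain_min
    ),
    class = "glp_frames"
  )
}

#' Build the stage-2 (self-supervised) set for one marker
#'
#' One sample per eligible patient: the final real-anchored window ending
#' at the second-to-last observation, the gap `g` to the last observation
#' and that observation (normalized) as target. Patients whose filled
#' span is shorter than the window or whose gap exceeds `g_max` are
#' excluded.
#'
#' @inheritParams stage1_dataset
#' @return A list of class `glp_stage2_set`: `X`, `y`, `g`, `patient_id`.
#' @export
stage2_dataset <- function(observations, patients, marker, cfg = train_config(),
                           thresholds = default_thresholds()) {
  obs <- observations[observations$marker == marker, ]
  ids <- unique(obs$patient_id)
  Xl <- list()
  yl <- gl <- pl <- c()
  for (id in ids) {
    o <- obs[obs$patient_id == id, ]
    o <- o[order(o$month), ]
    if (nrow(o) < 3L) next
    anc <- locate_anchors(o$month, o$value)
    tl <- fill_timeline(o$month, o$value,
      method = cfg$interpolation, upto_month = anc$tm
    )
    tl$value <- pmax(tl$value, 0)
    s2 <- build_stage2_sample(tl, anc, r = cfg$r, g_max = cfg$g_max)
    if (is.null(s2)) next
    st <- patient_static(patients, id)
    Xl[[length(Xl) + 1L]] <- assemble_features(
      s2$values, s2$is_real, st$age, st$sex, marker, thresholds
    )
    yl <- c(yl, normalize_value(s2$target_value))
    gl <- c(gl, s2$g)
    pl <- c(pl, id)
  }
  N <- length(Xl)
  X <- array(0, c(N, cfg$r + 1L, N_FEAT))
  for (i in seq_len(N)) X[i, , ] <- Xl[[i]]
  structure(
    list(
      X = X, y = yl, g = as.integer(gl), patient_id = pl, marker = marker,
      r = cfg$r, g_max = cfg$g_max, interpolation = cfg$interpolation
    ),
    class = "glp_stage2_set"
  )
}

# Shared seeded minibatch loop; stage-1 batches are gvec = 0. Both stages
# consume the same RNG stream layout so that the degenerate cases
# (stage 2 with all g = 0; zero epochs in either stage) coincide exactly
# with their counterparts.
run_epochs <- function(model, X, gvec, y, cfg, epochs, state = NULL) {
  N <- dim(X)[1L]
  if (is.null(state)) state <- adam_init(model$params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    losses <- c()
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, N)]
      lg <- loss_and_grads(
        X[idx, , , drop = FALSE], gvec[idx], y[idx],
        model$params, model$marker, model$thresholds
      )
      lg$grads <- clip_grads(lg$grads, cfg$clip_norm)
      up <- adam_step(model$params, lg$grads, state, lr = cfg$learning_rate)
      model$params <- up$p
      state <- up$state
      losses <- c(losses, lg$loss)
    }
    trace[ep] <- mean(losses)
  }
  list(model = model, state = state, trace = trace)
}

# Seeded training with optional random restarts. Restarts apply only when
# `model` is untrained (stage "init"): candidate r_i re-initializes from
# seed model$seed + 1000 * (r_i - 1), trains a burn-in fifth of the
# budget under an identical RNG stream, and the lowest-loss candidate
# continues with its optimizer state. A model already refined by an
# earlier stage is never re-initialized.
train_seeded <- function(model, X, gvec, y, cfg, epochs, thresholds) {
  if (model$stage == "init" && cfg$n_restarts > 1L && epochs > 2L) {
    burn <- min(epochs, max(2L, epochs %/% 5L))
    best <- NULL
    for (r_i in seq_len(cfg$n_restarts)) {
      cand <- if (r_i == 1L) {
        model
      } else {
        glp_model(model$marker,
          r = model$r, thresholds = model$thresholds,
          seed = model$seed + 1000L * (r_i - 1L)
        )
      }
      set.seed(cfg$seed + 1L)
      res <- run_epochs(cand, X, gvec, y, cfg, burn)
      score <- utils::tail(res$trace, 1L)
      if (is.null(best) || score < best$score) {
        best <- list(res = res, score = score)
      }
    }
    set.seed(cfg$seed + 2L)
    res2 <- run_epochs(
      best$res$model, X, gvec, y, cfg, epochs - burn,
      state = best$res$state
    )
    list(model = res2$model, trace = c(best$res$trace, res2$trace))
  } else {
    set.seed(cfg$seed + 1L)
    res <- run_epochs(model, X, gvec, y, cfg, epochs)
    list(model = res$model, trace = res$trace)
  }
}

#' Stage-1 supervised training on interpolated frames
#'
#' Minimizes the mean squared error between the regressor's next-month
#' prediction and the normalized target over minibatches with Adam, for
#' `epochs_stage1` epochs.
#'
#' @param frames A [stage1_dataset()].
#' @param cfg A [train_config()].
#' @param model Optional starting model; a fresh seeded [glp_model()] is
#'   created when omitted.
#' @param thresholds Threshold table used when `model` is created here.
#' @return A trained `glp_model` with a recorded per-epoch loss trace.
#' @export
train_stage1 <- function(frames, cfg = train_config(), model = NULL,
                         thresholds = default_thresholds()) {
  stopifnot(inherits(frames, "glp_frames"))
  if (dim(frames$X)[1L] == 0L) stop("empty frame set", call. = FALSE)
  if (is.null(model)) {
    model <- glp_model(frames$marker,
      r = frames$r, thresholds = thresholds,
      seed = cfg$seed
    )
  }
  if (cfg$epochs_stage1 == 0L) {
    return(model)
  }
  res <- train_seeded(
    model, frames$X, rep(0L, dim(frames$X)[1L]), frames$y,
    cfg, cfg$epochs_stage1, thresholds
  )
  model <- res$model
  model$stage <- "stage1"
  model$loss[[length(model$loss) + 1L]] <- list(stage = "stage1", loss = res$trace)
  model
}

#' Stage-2 autoregressive self-supervised training
#'
#' Each batch is rolled out autoregressively: the model's own next-month
#' predictions are appended to the window until each sample's prediction
#' target is reached (`g + 1` passes), the prediction at the sample's own
#' gap is passed through the regressor, and the MSE against the last real
#' observation is minimized. With all gaps zero this is exactly the
#' stage-1 update on the same windows.
#'
#' @param samples A [stage2_dataset()].
#' @param init The stage-1 model whose parameters are refined (a fresh
#'   seeded model under the `"ssl"` regime).
#' @param cfg A [train_config()].
#' @return The updated `glp_model`.
#' @export
train_stage2 <- function(samples, init, cfg = train_config()) {
  stopifnot(inherits(samples, "glp_stage2_set"), inherits(init, "glp_model"))
  if (dim(samples$X)[1L] == 0L) stop("empty stage-2 sample set", call. = FALSE)
  if (any(samples$g > cfg$g_max)) {
    stop("sample with g > g_max present; framing should have filtered it",
      call. = FALSE
    )
  }
  model <- init
  if (cfg$epochs_stage2 == 0L) {
    return(model)
  }
  res <- train_seeded(
    model, samples$X, samples$g, samples$y, cfg, cfg$epochs_stage2,
    init$thresholds
  )
  model <- res$model
  model$stage <- if (init$stage == "init") "ssl" else "two_stage"
  model$loss[[length(model$loss) + 1L]] <- list(stage = "stage2", loss = res$trace)
  model
}

#' Hybrid training: interleaved supervised and self-supervised batches
#'
#' Each epoch alternates stage-1 (interpolated-frame) and stage-2
#' (rollout) minibatches under a single Adam optimizer state.
#'
#' @inheritParams train_stage1
#' @param samples A [stage2_dataset()].
#' @return A trained `glp_model`.
#' @export
train_hybrid <- function(frames, samples, cfg = train_config(), model = NULL,
                         thresholds = default_thresholds()) {
  stopifnot(inherits(frames, "glp_frames"), inherits(samples, "glp_stage2_set"))
  if (dim(frames$X)[1L] == 0L || dim(samples$X)[1L] == 0L) {
    stop("hybrid training needs non-empty stage-1 and stage-2 sets", call. = FALSE)
  }
  if (is.null(model)) {
    model <- glp_model(frames$marker,
      r = frames$r, thresholds = thresholds,
      seed = cfg$seed
    )
  }
  if (model$stage == "init" && cfg$n_restarts > 1L && cfg$epochs > 2L) {
    burn <- min(cfg$epochs, max(2L, cfg$epochs %/% 5L))
    best <- NULL
    for (r_i in seq_len(cfg$n_restarts)) {
      cand <- if (r_i == 1L) {
        model
      } else {
        glp_model(model$marker,
          r = model$r, thresholds = model$thresholds,
          seed = model$seed + 1000L * (r_i - 1L)
        )
      }
      set.seed(cfg$seed + 1L)
      res <- run_hybrid_epochs(cand, frames, samples, cfg, burn)
      score <- utils::tail(res$trace, 1L)
      if (is.null(best) || score < best$score) best <- list(res = res, score = score)
    }
    set.seed(cfg$seed + 2L)
    res2 <- run_hybrid_epochs(
      best$res$model, frames, samples, cfg,
      cfg$epochs - burn,
      state = best$res$state
    )
    model <- res2$model
    trace <- c(best$res$trace, res2$trace)
  } else {
    set.seed(cfg$seed + 1L)
    res <- run_hybrid_epochs(model, frames, samples, cfg, cfg$epochs)
    model <- res$model
    trace <- res$trace
  }
  model$stage <- "hybrid"
  model$loss[[length(model$loss) + 1L]] <- list(stage = "hybrid", loss = trace)
  model
}

# One interleaved epoch loop: alternating stage-1 and stage-2 minibatches
# under a shared optimizer state.
run_hybrid_epochs <- function(model, frames, samples, cfg, epochs, state = NULL) {
  if (is.null(state)) state <- adam_init(model$params)
  N1 <- dim(frames$X)[1L]
  N2 <- dim(samples$X)[1L]
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    p1 <- sample.int(N1)
    p2 <- sample.int(N2)
    b1 <- split(p1, ceiling(seq_along(p1) / cfg$batch_size))
    b2 <- split(p2, ceiling(seq_along(p2) / cfg$batch_size))
    nb <- max(length(b1), length(b2))
    losses <- c()
    for (i in seq_len(nb)) {
      i1 <- b1[[(i - 1L) %% length(b1) + 1L]]
      lg <- loss_and_grads(
        frames$X[i1, , , drop = FALSE], rep(0L, length(i1)), frames$y[i1],
        model$params, model$marker, model$thresholds
      )
      lg$grads <- clip_grads(lg$grads, cfg$clip_norm)
      up <- adam_step(model$params, lg$grads, state, lr = cfg$learning_rate)
      model$params <- up$p
      state <- up$state
      i2 <- b2[[(i - 1L) %% length(b2) + 1L]]
      lg2 <- loss_and_grads(
        samples$X[i2, , , drop = FALSE], samples$g[i2], samples$y[i2],
        model$params, model$marker, model$thresholds
      )
      lg2$grads <- clip_grads(lg2$grads, cfg$clip_norm)
      up <- adam_step(model$params, lg2$grads, state, lr = cfg$learning_rate)
      model$params <- up$p
      state <- up$state
      losses <- c(losses, lg$loss, lg2$loss)
    }
    trace[ep] <- mean(losses)
  }
  list(model = model, state = state, trace = trace)
}

#' Train a progress forecaster under a named regime
#'
#' Dispatches on `cfg$regime`: `"supervised"` (stage 1 only), `"ssl"`
#' (stage 2 from fresh weights), `"two_stage"` (stage 1 then stage 2),
#' `"hybrid"` (interleaved).
#'
#' @inheritParams train_hybrid
#' @return A trained `glp_model`.
#' @export
train_glp <- function(frames, samples, cfg = train_config(),
                      thresholds = default_thresholds()) {
  switch(cfg$regime,
    supervised = train_stage1(frames, cfg, thresholds = thresholds),
    ssl = {
      model <- glp_model(samples$marker,
        r = samples$r, thresholds = thresholds,
        seed = cfg$seed
      )
      train_stage2(samples, model, cfg)
    },
    two_stage = {
      m1 <- train_stage1(frames, cfg, thresholds = thresholds)
      train_stage2(samples, m1, cfg)
    },
    hybrid = train_hybrid(frames, samples, cfg, thresholds = thresholds)
  )
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: 1 is a perfect fit, 0
#' matches a horizontal mean line, negative values are worse than it.
#'
#' @param predictions,truths Equal-length numeric vectors (length >= 2);
#'   the truths must not all be identical.
#' @return A single number, at most 1.
#' @export
r_squared <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) < 2L) {
    stop("predictions and truths must be equal-length vectors of length >= 2",
      call. = FALSE
    )
  }
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot == 0) stop("R^2 undefined: truths are all identical", call. = FALSE)
  1 - sum((truths - predictions)^2) / ss_tot
}

#' Forecasting performance on stage-2 samples
#'
#' Rolls each held-out window out to its own gap and scores the
#' regressor's predictions of the (normalized) last real observation.
#'
#' @param model A trained `glp_model`.
#' @param samples A [stage2_dataset()].
#' @return The R-squared of the forecasts.
#' @export
evaluate_forecast <- function(model, samples) {
  stopifnot(inherits(samples, "glp_stage2_set"))
  preds <- rollout(model, samples$X, samples$g)$progress_out
  r_squared(preds, samples$y)
}

# Seeded patient-level split: test ids and a fold assignment of the rest.
make_split <- function(ids, cfg, rep_seed) {
  set.seed(rep_seed)
  ids <- sort(unique(ids))
  n_test <- max(1L, round(length(ids) * cfg$test_fraction))
  test_ids <- sample(ids, n_test)
  train_ids <- setdiff(ids, test_ids)
  folds <- if (cfg$n_folds == 1L) {
    rep(1L, length(train_ids))
  } else {
    sample(rep_len(seq_len(cfg$n_folds), length(train_ids)))
  }
  list(test_ids = test_ids, train_ids = train_ids, folds = folds)
}

subset_frames <- function(d, keep) {
  idx <- which(d$patient_id %in% keep)
  d$X <- d$X[idx, , , drop = FALSE]
  d$y <- d$y[idx]
  d$patient_id <- d$patient_id[idx]
  if (!is.null(d$n_real)) d$n_real <- d$n_real[idx]
  if (!is.null(d$g)) d$g <- d$g[idx]
  d
}

eval_cell <- function(observations, patients, marker, cfg, splits, thresholds) {
  frames <- stage1_dataset(observations, patients, marker, cfg, thresholds)
  samples <- stage2_dataset(observations, patients, marker, cfg, thresholds)
  rows <- list()
  for (rep_i in seq_along(splits)) {
    sp <- splits[[rep_i]]
    test_s2 <- subset_frames(samples, sp$test_ids)
    for (f in seq_len(cfg$n_folds)) {
      keep <- if (cfg$n_folds == 1L) {
        sp$train_ids
      } else {
        sp$train_ids[sp$folds != f]
      }
      cfg_f <- cfg
      cfg_f$seed <- cfg$seed + 7919L * rep_i + 101L * f
      tr_fr <- subset_frames(frames, keep)
      tr_s2 <- subset_frames(samples, keep)
      m <- train_glp(tr_fr, tr_s2, cfg_f, thresholds)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = marker, regime = cfg$regime,
        interpolation = cfg$interpolation, certain = cfg$certain_min,
        rep = rep_i, fold = f,
        r2 = evaluate_forecast(m, test_s2)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Cross-validated evaluation of one training configuration
#'
#' For each of `n_repeats` repetitions: patients are split 80:20, the
#' training split is divided into `n_folds` folds, a model is trained on
#' each fold complement under the configured regime, and every fold model
#' forecasts the held-out patients' last real observations (gap at most
#' `g_max`, no interpolation support). All splits are at the patient
#' level, so no patient contributes to both training and testing.
#'
#' @param cohort A `pretext_cohort` (or a list with `observations` and
#'   `patients` tibbles).
#' @param cfg A [train_config()].
#' @param marker Marker to evaluate (default: first marker present).
#' @param thresholds Threshold table.
#' @return A tibble of class `glp_eval` with columns `marker`, `regime`,
#'   `interpolation`, `certain`, `rep`, `fold`, `r2`
#'   (`n_folds * n_repeats` rows) and attribute `mean_r2`.
#' @export
cross_validate <- function(cohort, cfg = train_config(),
                           marker = NULL, thresholds = default_thresholds()) {
  obs <- cohort$observations
  patients <- cohort$patients
  if (is.null(marker)) marker <- obs$marker[1L]
  ids <- unique(obs$patient_id)
  if (length(ids) < cfg$n_folds) stop("too few patients", call. = FALSE)
  splits <- lapply(
    seq_len(cfg$n_repeats),
    function(i) make_split(ids, cfg, cfg$seed + 104729L * i)
  )
  out <- eval_cell(obs, patients, marker, cfg, splits, thresholds)
  attr(out, "mean_r2") <- mean(out$r2)
  class(out) <- c("glp_eval", class(out))
  out
}

#' Factorial ablation over regimes, interpolation methods and certainty
#'
#' Runs every combination of the supplied training regimes,
#' interpolation methods and certainty-mask settings with identical
#' patient splits across cells (so cells are directly comparable), and
#' returns the per-fold results together with per-cell means.
#'
#' @inheritParams cross_validate
#' @param regimes Character vector of training regimes.
#' @param methods Character vector of interpolation methods.
#' @param certain_range Integer vector of `certain_min` values.
#' @return A list with `results` (per-fold tibble) and `summary`
#'   (per-cell mean R-squared).
#' @export
ablation_grid <- function(cohort, regimes = c("two_stage", "ssl"),
                          methods = "linear", certain_range = 0L,
                          cfg = train_config(), marker = NULL,
                          thresholds = default_thresholds()) {
  stopifnot(length(regimes) > 0L, length(methods) > 0L, length(certain_range) > 0L)
  obs <- cohort$observations
  if (is.null(marker)) marker <- obs$marker[1L]
  ids <- unique(obs$patient_id)
  splits <- lapply(
    seq_len(cfg$n_repeats),
    function(i) make_split(ids, cfg, cfg$seed + 104729L * i)
  )
  grid <- expand.grid(
    regime = regimes, method = methods, certain = certain_range,
    stringsAsFactors = FALSE
  )
  res <- purrr::pmap(grid, function(regime, method, certain) {
    cell_cfg <- cfg
    cell_cfg$regime <- regime
    cell_cfg$interpolation <- method
    cell_cfg$certain_min <- as.integer(certain)
    eval_cell(obs, cohort$patients, marker, cell_cfg, splits, thresholds)
  })
  results <- dplyr::bind_rows(res)
  summary <- results |>
    dplyr::group_by(.data$regime, .data$interpolation, .data$certain) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), .groups = "drop")
  list(results = results, summary = summary)
}

#' Per-regime configurations with matched optimization budgets
#'
#' The four regimes consume very different numbers of parameter updates
#' under a fixed epoch count: an epoch of stage 1 visits every frame
#' (many minibatches) while an epoch of stage 2 visits one window per
#' patient. For a fair comparison each regime is given the same total
#' number of Adam updates as the two-stage schedule
#' (`epochs x (stage-1 batches + stage-2 batches)`), by scaling the
#' epoch counts of the single-stage regimes.
#'
#' @param n_frames,n_samples Sizes of the stage-1 and stage-2 training
#'   sets.
#' @param cfg Base [train_config()].
#' @return A named list of `train_config`s, one per regime.
#' @export
matched_budget_configs <- function(n_frames, n_samples, cfg = train_config()) {
  nb1 <- max(1L, ceiling(n_frames / cfg$batch_size))
  nb2 <- max(1L, ceiling(n_samples / cfg$batch_size))
  budget <- cfg$epochs * (nb1 + nb2)
  cfgs <- list()
  for (rg in c("two_stage", "ssl", "supervised", "hybrid")) {
    ci <- cfg
    ci$regime <- rg
    if (rg == "supervised") {
      ci$epochs_stage1 <- as.integer(round(budget / nb1))
    } else if (rg == "ssl") {
      ci$epochs_stage2 <- as.integer(round(budget / nb2))
    }
    # two_stage and hybrid consume the full budget by construction
    cfgs[[rg]] <- ci
  }
  cfgs
}
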