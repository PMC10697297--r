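#' Balance an episodic cohort by downsampling the majority class
#'
#' Keeps every event-positive record and draws an equal number of
#' negatives without replacement.
#'
#' @param records Downstream records tibble (see
#'   [simulate_downstream_cohort()]) with an `event_label` column.
#' @param seed Integer seed for the draw.
#' @return The balanced tibble (positives first, then sampled negatives).
#' @export
balance_downsample <- function(records, seed = 1L) {
  pos <- records[records$event_label == "positive", ]
  neg <- records[records$event_label == "negative", ]
  if (nrow(pos) == 0L) stop("no positive records", call. = FALSE)
  if (nrow(pos) > nrow(neg)) {
    stop("positives must not outnumber negatives", call. = FALSE)
  }
  set.seed(seed)
  keep <- sample.int(nrow(neg), nrow(pos))
  dplyr::bind_rows(pos, neg[keep, ])
}

#' Expand an episodic record into a model window
#'
#' The paper's pipeline feeds single-visit records to forecasters trained
#' on `(r+1)`-month windows; the expansion is a design choice. The
#' default carries the observed value back across the whole window with
#' the certainty bit set only at the final month (the only real
#' observation); `fill = "zero"` instead zeroes the value column before
#' the final month.
#'
#' @param record One downstream record (a one-row tibble with `age`,
#'   `sex` and a column per marker).
#' @param marker Marker name.
#' @param table Threshold table.
#' @param r Window span in months.
#' @param fill `"carry"` (default) or `"zero"`.
#' @return A list with `features` (the `(r+1) x 5` matrix) and `g` (the
#'   record's gap in months).
#' @export
episodic_to_frame <- function(record, marker, table = default_thresholds(),
                              r = 12L, fill = c("carry", "zero")) {
  fill <- match.arg(fill)
  if (!marker %in% names(record) || is.na(record[[marker]][1L])) {
    stop("record has no value for marker '", marker, "'", call. = FALSE)
  }
  v <- record[[marker]][1L]
  vals <- rep(v, r + 1L)
  if (fill == "zero") vals[seq_len(r)] <- 0
  feats <- assemble_features(
    vals, c(rep(FALSE, r), TRUE), record$age[1L], record$sex[1L], marker, table
  )
  list(features = feats, g = as.integer(record$gap_months[1L]))
}

episodic_windows <- function(records, marker, table, r, fill) {
  n <- nrow(records)
  X <- array(0, c(n, r + 1L, N_FEAT))
  for (i in seq_len(n)) {
    X[i, , ] <- episodic_to_frame(records[i, ], marker, table, r, fill)$features
  }
  X
}

#' Extract frozen-model progress representations
#'
#' Each patient's single-visit record is expanded into a window per
#' marker and rolled out by that marker's frozen forecaster to the chosen
#' horizon (`"g"`: the patient's full gap; `"g_half"`: `floor(g/2)`, the
#' iteration before reaching the intended event; `"zero"`: a single
#' pass). The condensed embeddings are concatenated across markers (a
#' 30-vector for six markers) and so are the scalar regressor outputs (a
#' 6-vector). Extraction never updates model parameters.
#'
#' @param models Named list of trained `glp_model`s, one per marker.
#' @param records Downstream records tibble.
#' @param horizon `"g"`, `"g_half"` or `"zero"`.
#' @param table Threshold table.
#' @param fill Window fill strategy, see [episodic_to_frame()].
#' @return A tibble of class `glp_representations`: `patient_id`,
#'   `event_label`, `gap_months`, original features (`orig_<marker>`,
#'   `orig_age`, `orig_sex`, all normalized), embeddings
#'   (`emb_<marker>_1..5`) and outputs (`out_<marker>`).
#' @export
extract_representations <- function(models, records,
                                    horizon = c("g", "g_half", "zero"),
                                    table = default_thresholds(),
                                    fill = "carry") {
  horizon <- match.arg(horizon)
  markers <- names(models)
  if (is.null(markers) || !all(markers %in% names(records))) {
    stop("models must be a named list matching marker columns of `records`",
      call. = FALSE
    )
  }
  g <- as.integer(records$gap_months)
  h <- switch(horizon, g = g, g_half = g %/% 2L, zero = rep(0L, nrow(records)))
  out <- tibble::tibble(
    patient_id = records$patient_id,
    event_label = records$event_label,
    gap_months = g
  )
  for (m in markers) out[[paste0("orig_", m)]] <- normalize_value(records[[m]])
  out$orig_age <- normalize_value(records$age)
  out$orig_sex <- as.numeric(records$sex)
  for (m in markers) {
    model <- models[[m]]
    stopifnot(inherits(model, "glp_model"))
    X <- episodic_windows(records, m, table, model$r, fill)
    roll <- rollout(model, X, h)
    emb <- roll$progress_emb
    colnames(emb) <- paste0("emb_", m, "_", seq_len(N_FEAT))
    out <- dplyr::bind_cols(out, tibble::as_tibble(emb))
    out[[paste0("out_", m)]] <- roll$progress_out
  }
  class(out) <- c("glp_representations", class(out))
  out
}

confusion_metrics <- function(truth, pred, prob) {
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  auroc <- if (length(unique(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(truth, prob,
      levels = c(0, 1),
      direction = "<", quiet = TRUE
    )))
  } else {
    NA_real_
  }
  c(
    auroc = auroc, accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1
  )
}

fit_predict <- function(clf, Xtr, ytr, Xte, seed) {
  set.seed(seed)
  switch(clf,
    gbm = {
      fit <- xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = 3L, eta = 0.3,
          nthread = 1L
        ),
        data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L),
        nrounds = 50L, verbose = 0L
      )
      prob <- stats::predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1L))
      list(prob = prob, pred = as.integer(prob >= 0.5))
    },
    svm = {
      fit <- e1071::svm(Xtr, factor(ytr, levels = c(0, 1)),
        kernel = "radial", probability = TRUE, scale = apply(Xtr, 2, stats::sd) > 0
      )
      pr <- stats::predict(fit, Xte, probability = TRUE)
      prob <- attr(pr, "probabilities")[, "1"]
      list(prob = prob, pred = as.integer(as.character(pr)))
    },
    logistic = {
      df <- data.frame(y = ytr, Xtr)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      prob <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(Xte), type = "response")
      )
      list(prob = prob, pred = as.integer(prob >= 0.5))
    },
    knn = {
      ksize <- min(5L, nrow(Xtr))
      sc <- apply(Xtr, 2, stats::sd)
      sc[sc == 0] <- 1
      ctr <- colMeans(Xtr)
      pr <- class::knn(
        scale(Xtr, ctr, sc), scale(Xte, ctr, sc),
        factor(ytr, levels = c(0, 1)),
        k = ksize, prob = TRUE
      )
      win <- attr(pr, "prob")
      pred <- as.integer(as.character(pr))
      prob <- ifelse(pred == 1L, win, 1 - win)
      list(prob = prob, pred = pred)
    },
    stop("unknown classifier '", clf, "'", call. = FALSE)
  )
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Benchmark four classifier families on a representation table
#'
#' Repeated stratified cross-validation of gradient-boosted trees, an
#' RBF support vector machine, logistic regression and k-nearest
#' neighbours. Per repeat, held-out predictions are pooled across folds
#' to compute AUROC, accuracy, sensitivity, specificity, precision and
#' F1, plus the mean pairwise Cohen's kappa between the classifiers'
#' prediction vectors; reported values are means over repeats.
#'
#' @param X Numeric feature matrix (rows = patients).
#' @param y Binary labels (0/1 or a two-level factor/character vector;
#'   `"positive"` maps to 1).
#' @param n_repeats,n_folds Repetitions and folds (defaults 5 and 5).
#' @param seed Integer seed.
#' @param classifiers Subset of `c("gbm", "svm", "logistic", "knn")`.
#' @return A list of class `glp_classifier_report`: `metrics` (tibble,
#'   one row per classifier), `kappa` (mean pairwise), `per_repeat`
#'   (tibble of per-repeat metrics and kappas).
#' @export
run_classifiers <- function(X, y, n_repeats = 5L, n_folds = 5L, seed = 1L,
                            classifiers = c("gbm", "svm", "logistic", "knn")) {
  X <- as.matrix(X)
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "positive")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("need two classes", call. = FALSE)
  rows <- list()
  kap <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + 1009L * rep_i)
    fold <- stratified_folds(y, n_folds)
    pooled <- lapply(classifiers, function(...) {
      list(prob = numeric(length(y)), pred = integer(length(y)))
    })
    names(pooled) <- classifiers
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      for (clf in classifiers) {
        res <- fit_predict(
          clf, X[tr, , drop = FALSE], y[tr],
          X[te, , drop = FALSE], seed + 1009L * rep_i + 13L * f
        )
        pooled[[clf]]$prob[te] <- res$prob
        pooled[[clf]]$pred[te] <- res$pred
      }
    }
    for (clf in classifiers) {
      met <- confusion_metrics(y, pooled[[clf]]$pred, pooled[[clf]]$prob)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = rep_i, classifier = clf, metric = names(met), value = unname(met)
      )
    }
    kap[rep_i] <- mean_pairwise_kappa(lapply(pooled, `[[`, "pred"))
  }
  per_repeat <- dplyr::bind_rows(rows)
  metrics <- per_repeat |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  structure(
    list(metrics = metrics, kappa = mean(kap), per_repeat = per_repeat,
         kappa_per_repeat = kap),
    class = "glp_classifier_report"
  )
}

#' @export
print.glp_classifier_report <- function(x, ...) {
  cat("<glp_classifier_report> mean pairwise kappa:", round(x$kappa, 3), "\n")
  print(x$metrics)
  invisible(x)
}

cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  po <- mean(a == b)
  lv <- union(unique(a), unique(b))
  pe <- sum(vapply(lv, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (pe >= 1) {
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Mean pairwise Cohen's kappa between classifier predictions
#'
#' Computes Cohen's kappa for every unordered pair of prediction vectors
#' and returns the arithmetic mean — the overall agreement among the
#' classifier ensemble. Kappa of 1 is perfect agreement, 0 chance-level,
#' negative worse than chance.
#'
#' @param predictions A list (length >= 2) of equal-length label vectors.
#' @return A single number in `[-1, 1]`.
#' @export
mean_pairwise_kappa <- function(predictions) {
  stopifnot(length(predictions) >= 2L)
  n <- lengths(predictions)
  if (length(unique(n)) != 1L) stop("prediction length mismatch", call. = FALSE)
  pairs <- utils::combn(length(predictions), 2L)
  mean(apply(pairs, 2L, function(ij) {
    cohen_kappa(predictions[[ij[1L]]], predictions[[ij[2L]]])
  }))
}

#' Export denormalized progress snapshots
#'
#' For each patient, the frozen forecasters' scalar outputs are computed
#' at three horizons — a single pass (`0`), half the gap (`g/2`) and the
#' full gap (`g`) — and mapped back to the raw measurement scale, giving
#' the raw material of before/after distribution plots (stable patients
#' converge, diverging patients scatter).
#'
#' @inheritParams extract_representations
#' @return A tibble with `patient_id`, `event_label`, `horizon` (factor
#'   `"0"`, `"g/2"`, `"g"`) and one column per marker; `nrow = patients x
#'   3`.
#' @export
snapshot_export <- function(models, records, table = default_thresholds(),
                            fill = "carry") {
  horizons <- c(zero = "0", g_half = "g/2", g = "g")
  parts <- purrr::imap(horizons, function(lab, hz) {
    reps <- extract_representations(models, records,
      horizon = hz, table = table, fill = fill
    )
    out <- tibble::tibble(
      patient_id = reps$patient_id,
      event_label = reps$event_label,
      horizon = lab
    )
    for (m in names(models)) {
      out[[m]] <- denormalize_value(reps[[paste0("out_", m)]])
    }
    out
  })
  res <- dplyr::bind_rows(parts)
  res$horizon <- factor(res$horizon, levels = c("0", "g/2", "g"))
  res
}
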