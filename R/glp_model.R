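#' Construct a per-marker progress forecaster
#'
#' Builds the untrained network for one laboratory marker: a longitudinal
#' iterative block (bidirectional LSTM with 5 hidden nodes per direction
#' plus a condensing affine layer mapping the concatenated 10-dimensional
#' state back to the 5-dimensional input feature width, with ReLU after
#' each layer) and a regressor (two affine layers, widths 5 -> 2 -> 1,
#' with ReLU in between) that predicts the next-month normalized value.
#' Because the condensed output has the input width, the model's own
#' predictions can be appended to the window, closing the autoregressive
#' loop.
#'
#' @param marker Marker name; one model is trained per marker.
#' @param r Window span in months (the window holds `r + 1` monthly
#'   points); default 12.
#' @param thresholds Threshold table used to recompute the discrete value
#'   code of predicted months during rollout.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `glp_model`.
#' @export
glp_model <- function(marker, r = 12L, thresholds = default_thresholds(),
                      seed = 1L) {
  if (!marker %in% names(thresholds)) {
    stop("no thresholds defined for marker '", marker, "'", call. = FALSE)
  }
  set.seed(seed)
  structure(
    list(
      marker = marker, r = as.integer(r), params = init_params(),
      thresholds = thresholds, stage = "init", seed = as.integer(seed),
      loss = list()
    ),
    class = "glp_model"
  )
}

#' @export
print.glp_model <- function(x, ...) {
  cat(
    "<glp_model> marker:", x$marker, " stage:", x$stage,
    " r:", x$r, " params:", sum(lengths(x$params)), "\n"
  )
  invisible(x)
}

as_batch <- function(features, r) {
  if (is.matrix(features)) {
    features <- array(features, c(1L, nrow(features), ncol(features)))
  }
  if (length(dim(features)) != 3L || dim(features)[3L] != N_FEAT) {
    stop("features must be an (r+1) x 5 matrix or a batch array with 5 features",
      call. = FALSE
    )
  }
  if (dim(features)[2L] != r + 1L) {
    stop("window must hold r + 1 = ", r + 1L, " monthly points", call. = FALSE)
  }
  features
}

#' Run the longitudinal iterative block over a window
#'
#' Applies the bidirectional LSTM and the condensing layer to a feature
#' window, returning the per-step condensed vectors (all non-negative, by
#' the terminal ReLU) and the final-step condensed vector, interpreted as
#' the predicted feature vector for the month following the window.
#'
#' @param model A [glp_model()].
#' @param features An `(r+1) x 5` feature matrix (see
#'   [assemble_features()]) or a `B x (r+1) x 5` batch array.
#' @return A list with `condensed` (same leading shape as the input, last
#'   dimension 5) and `next_step` (the condensed vector at the final
#'   step; a length-5 vector, or a `B x 5` matrix for batches).
#' @export
libc_forward <- function(model, features) {
  stopifnot(inherits(model, "glp_model"))
  single <- is.matrix(features)
  X <- as_batch(features, model$r)
  fw <- libc_fwd(X, model$params)
  T <- dim(X)[2L]
  nxt <- matrix(fw$C[, T, ], nrow = dim(X)[1L])
  if (single) {
    list(condensed = matrix(fw$C[1L, , ], ncol = N_FEAT), next_step = drop(nxt))
  } else {
    list(condensed = fw$C, next_step = nxt)
  }
}

#' Run the regressor head on a condensed vector
#'
#' @param model A [glp_model()].
#' @param vec A length-5 vector or a `B x 5` matrix of condensed feature
#'   vectors.
#' @return Scalar (or length-B vector) prediction of the next-month
#'   normalized laboratory value.
#' @export
regressor_forward <- function(model, vec) {
  stopifnot(inherits(model, "glp_model"))
  V <- if (is.matrix(vec)) vec else matrix(vec, nrow = 1L)
  if (ncol(V) != N_FEAT) stop("input width must be 5", call. = FALSE)
  reg_fwd(V, model$params)$out
}

#' Autoregressive rollout of a window
#'
#' Iterates the longitudinal iterative block `g + 1` times: each pass
#' predicts the next month's feature vector, whose value is appended to
#' the window (certainty bit 0, discrete code recomputed from the
#' denormalized predicted value, age and sex carried forward) before the
#' window slides by one month. The progress embedding is the condensed
#' vector at pass `g + 1`; the progress output is the regressor applied
#' to it. With `g = 0` this reduces to a single forward pass.
#'
#' @inheritParams libc_forward
#' @param g Non-negative integer gap: number of months between the end of
#'   the window and the prediction target. Either a scalar (shared by the
#'   whole batch) or one value per batch row.
#' @return An object of class `glp_rollout`: `steps` (per-pass predicted
#'   feature vectors, `g + 1` of them), `progress_emb` (the condensed
#'   5-vector at the selected pass) and `progress_out` (scalar regressor
#'   output, normalized units).
#' @export
rollout <- function(model, features, g = 0L) {
  stopifnot(inherits(model, "glp_model"), all(g >= 0))
  single <- is.matrix(features)
  X <- as_batch(features, model$r)
  B <- dim(X)[1L]
  gvec <- if (length(g) == 1L) rep(as.integer(g), B) else as.integer(g)
  stopifnot(length(gvec) == B)
  roll <- rollout_fwd(X, gvec, model$params, model$marker, model$thresholds,
    keep_steps = TRUE
  )
  if (single) {
    structure(
      list(
        steps = matrix(roll$steps[1L, seq_len(gvec[1L] + 1L), ], ncol = N_FEAT),
        progress_emb = drop(roll$emb),
        progress_out = unname(roll$out)
      ),
      class = "glp_rollout"
    )
  } else {
    structure(
      list(
        steps = roll$steps, progress_emb = roll$emb,
        progress_out = unname(roll$out)
      ),
      class = "glp_rollout"
    )
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter blocks of a progress forecaster
#'
#' @param x A `glp_model`.
#' @param ... Unused.
#' @return A tibble with one row per parameter block: `block`, `n`,
#'   `mean`, `sd`.
#' @export
tidy.glp_model <- function(x, ...) {
  tibble::tibble(
    block = names(x$params),
    n = vapply(x$params, length, integer(1)),
    mean = vapply(x$params, function(p) mean(p), numeric(1)),
    sd = vapply(x$params, function(p) stats::sd(as.numeric(p)), numeric(1))
  )
}

#' One-row summary of a progress forecaster
#'
#' @param x A `glp_model`.
#' @param ... Unused.
#' @return A tibble with `marker`, `stage`, `n_params`, `seed` and the
#'   final recorded training loss (NA if untrained).
#' @export
glance.glp_model <- function(x, ...) {
  fl <- if (length(x$loss) > 0L) {
    tail(x$loss[[length(x$loss)]]$loss, 1L)
  } else {
    NA_real_
  }
  tibble::tibble(
    marker = x$marker, stage = x$stage,
    n_params = sum(lengths(x$params)), seed = x$seed, final_loss = fl
  )
}

#' Save / load a progress forecaster as plain text
#'
#' Checkpoints record the marker, window span, stage tag, seed, threshold
#' table and all parameter blocks in a single YAML file, so frozen models
#' can be reloaded for the transfer stage.
#'
#' @param model A `glp_model`.
#' @param path File path.
#' @return `write_glp_model()` returns the path invisibly;
#'   `read_glp_model()` returns the model.
#' @export
write_glp_model <- function(model, path) {
  stopifnot(inherits(model, "glp_model"))
  obj <- list(
    marker = model$marker, r = model$r, stage = model$stage,
    seed = model$seed, thresholds = model$thresholds,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) {
        list(dim = dim(p), data = as.numeric(p))
      } else {
        list(dim = NULL, data = as.numeric(p))
      }
    })
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_glp_model
#' @export
read_glp_model <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- lapply(obj$params, function(p) {
    if (is.null(p$dim)) as.numeric(p$data) else matrix(p$data, p$dim[1L], p$dim[2L])
  })
  structure(
    list(
      marker = obj$marker, r = as.integer(obj$r), params = params,
      thresholds = obj$thresholds, stage = obj$stage,
      seed = as.integer(obj$seed), loss = list()
    ),
    class = "glp_model"
  )
}
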