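#' Locate the anchor observations of a series
#'
#' The framing scheme distinguishes three anchors of an observation
#' sequence: the first observed month `t0`, the second-to-last observed
#' month `tm` (the end of the interpolated region and of the stage-2 input
#' window) and the last observed month `tn` (the stage-2 forecasting
#' target, never interpolated). With exactly two observations `tm`
#' degenerates to `t0`.
#'
#' @inheritParams interpolate_linear
#' @return A list of class `glp_anchors` with elements `t0`, `tm`, `tn`
#'   and the corresponding observed values `y0`, `ym`, `yn`.
#' @examples
#' locate_anchors(c(0, 3, 6, 9), c(1, 2, 3, 4)) # t0 = 0, tm = 6, tn = 9
#' @export
locate_anchors <- function(months, values) {
  obs <- check_obs(months, values)
  n <- length(obs$months)
  i_m <- if (n == 2L) 1L else n - 1L
  structure(
    list(
      t0 = obs$months[1L], tm = obs$months[i_m], tn = obs$months[n],
      y0 = obs$values[1L], ym = obs$values[i_m], yn = obs$values[n]
    ),
    class = "glp_anchors"
  )
}

#' Build stage-1 supervised frames from an interpolated timeline
#'
#' Slides an `(r+1)`-month window over the filled timeline one month at a
#' time. A frame starting at month `i` covers `i..i+r` and predicts the
#' value one month later, so frames exist while `i + r <= m - 1` where `m`
#' is the last month of the timeline; series whose filled span is at most
#' `r` yield no frames. Frames containing fewer than `certain_min` real
#' observations are discarded (the certainty-mask inclusion criterion).
#'
#' @param timeline A tibble as returned by [fill_timeline()], filled up to
#'   the second-to-last observed month.
#' @param r Window span in months (window holds `r + 1` monthly points);
#'   default 12.
#' @param certain_min Minimum number of real observations a frame must
#'   contain to be kept (default 0, i.e. keep all).
#' @return A tibble with one row per retained frame: `start_month`,
#'   `target_month`, `target_value`, `n_real`, and list-columns `values`
#'   and `is_real` holding the `r + 1` window points. Zero rows is a valid
#'   result.
#' @export
build_stage1_frames <- function(timeline, r = 12L, certain_min = 0L) {
  stopifnot(r >= 1L)
  m <- timeline$month[nrow(timeline)]
  t0 <- timeline$month[1L]
  starts <- seq_len(max(0L, (m - 1L - r) - t0 + 1L)) + t0 - 1L
  if (length(starts) == 0L) {
    return(tibble::tibble(
      start_month = integer(), target_month = integer(),
      target_value = numeric(), n_real = integer(),
      values = list(), is_real = list()
    ))
  }
  rows <- purrr::map(starts, function(i) {
    idx <- (i - t0 + 1L):(i - t0 + 1L + r)
    tibble::tibble(
      start_month = as.integer(i),
      target_month = as.integer(i + r + 1L),
      target_value = timeline$value[i - t0 + 2L + r],
      n_real = sum(timeline$is_real[idx]),
      values = list(timeline$value[idx]),
      is_real = list(timeline$is_real[idx])
    )
  })
  out <- dplyr::bind_rows(rows)
  out[out$n_real >= certain_min, ]
}

#' Isolate the stage-2 self-supervised sample of a series
#'
#' The final real-anchored window `tm - r .. tm` is paired with the last
#' real observation `y(tn)` as target, a gap of `g = tn - tm - 1` months
#' ahead of the window. Returns `NULL` when the filled span is shorter
#' than the window (`tm - t0 < r`) or when the gap exceeds `g_max`
#' (default `r/2`), mirroring the evaluation rule that forecasts receive
#' no interpolation support beyond half a window.
#'
#' @inheritParams build_stage1_frames
#' @param anchors Anchors of the *original* observation sequence, from
#'   [locate_anchors()].
#' @param g_max Maximum admissible gap in months (default `floor(r / 2)`).
#' @return A list of class `glp_stage2_sample` with `values`, `is_real`
#'   (the `r + 1` window points ending at `tm`), `g`, `target_value`,
#'   `target_month`; or `NULL` if the series is ineligible.
#' @export
build_stage2_sample <- function(timeline, anchors, r = 12L, g_max = floor(r / 2)) {
  stopifnot(inherits(anchors, "glp_anchors"))
  t0 <- timeline$month[1L]
  m <- anchors$tm
  if (timeline$month[nrow(timeline)] < m) {
    stop("timeline must be filled up to the second-to-last observation", call. = FALSE)
  }
  g <- anchors$tn - m - 1L
  if (m - t0 < r || g > g_max) {
    return(NULL)
  }
  idx <- (m - r - t0 + 1L):(m - t0 + 1L)
  structure(
    list(
      values = timeline$value[idx],
      is_real = timeline$is_real[idx],
      start_month = as.integer(m - r),
      g = as.integer(g),
      target_month = as.integer(anchors$tn),
      target_value = anchors$yn
    ),
    class = "glp_stage2_sample"
  )
}
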