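#' Validate an observation sequence
#'
#' Observation sequences are the raw (month, value) anchors of one patient
#' and one marker: at least two points, strictly increasing integer months,
#' finite values.
#'
#' @param months Integer vector of observation months.
#' @param values Numeric vector of observed values, same length as `months`.
#' @return Invisibly, a list with `months` and `values`.
#' @keywords internal
check_obs <- function(months, values) {
  if (length(months) < 2L) {
    stop("an observation sequence needs at least 2 points", call. = FALSE)
  }
  if (length(months) != length(values)) {
    stop("`months` and `values` must have the same length", call. = FALSE)
  }
  if (any(diff(months) <= 0)) {
    stop("`months` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  invisible(list(months = as.numeric(months), values = as.numeric(values)))
}

check_query <- function(months, query) {
  if (any(query < months[1L] | query > months[length(months)])) {
    stop("query months outside the observed span; no extrapolation", call. = FALSE)
  }
}

#' Linear interpolation between observed months
#'
#' Each query value is computed from the gradient of its bracketing observed
#' pair; values at observed months are reproduced exactly. Queries outside
#' the observed span are an error (the method never extrapolates).
#'
#' @param months Integer vector of observed months (strictly increasing).
#' @param values Numeric vector of observed values.
#' @param query Numeric vector of months at which to interpolate; must lie
#'   within `[min(months), max(months)]`.
#' @return Numeric vector of interpolated values, one per query month.
#' @examples
#' interpolate_linear(c(0, 2), c(2, 4), 1) # 3
#' @export
interpolate_linear <- function(months, values, query) {
  check_obs(months, values)
  check_query(months, query)
  stats::approx(months, values, xout = query, method = "linear", ties = "ordered")$y
}

# Shape-preserving node derivatives: weighted harmonic mean of the two
# adjacent secant slopes, zeroed when their signs differ or either is zero.
# Endpoints use the non-centred three-point rule with sign clipping
# (Moler), so the interpolant agrees with reference PCHIP implementations.
pchip_derivatives <- function(h, delta) {
  n <- length(h) + 1L
  d <- numeric(n)
  if (n == 2L) {
    d[] <- delta[1L] # degenerates to the straight line
    return(d)
  }
  for (j in 2L:(n - 1L)) {
    d1 <- delta[j - 1L]
    d2 <- delta[j]
    if (d1 * d2 > 0) {
      w1 <- 2 * h[j] + h[j - 1L]
      w2 <- h[j] + 2 * h[j - 1L]
      d[j] <- (w1 + w2) / (w1 / d1 + w2 / d2)
    } # else stays 0
  }
  ends <- function(h1, h2, del1, del2) {
    dd <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
    if (sign(dd) != sign(del1)) {
      dd <- 0
    } else if (sign(del1) != sign(del2) && abs(dd) > abs(3 * del1)) {
      dd <- 3 * del1
    }
    dd
  }
  d[1L] <- ends(h[1L], h[2L], delta[1L], delta[2L])
  d[n] <- ends(h[n - 1L], h[n - 2L], delta[n - 1L], delta[n - 2L])
  d
}

#' Shape-preserving piecewise cubic Hermite (PCHIP) interpolation
#'
#' Node derivatives are the weighted harmonic mean of the two adjacent
#' secant slopes, with weights `w1 = 2*h_next + h_prev` and
#' `w2 = h_next + 2*h_prev`; the derivative is set to zero where the secant
#' slopes change sign or either is zero, which prevents overshoot beyond
#' the neighbouring node values.
#'
#' @inheritParams interpolate_linear
#' @return Numeric vector of interpolated values.
#' @examples
#' interpolate_pchip(c(0, 1, 2), c(0, 1, 0), 0.5)
#' @export
interpolate_pchip <- function(months, values, query) {
  obs <- check_obs(months, values)
  check_query(obs$months, query)
  x <- obs$months
  y <- obs$values
  h <- diff(x)
  delta <- diff(y) / h
  d <- pchip_derivatives(h, delta)
  # locate interval of each query (queries at the right edge go to the last)
  k <- findInterval(query, x, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  s <- query - x[k]
  hk <- h[k]
  # Hermite basis on [x_k, x_k + h_k]
  t <- s / hk
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- s * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- s * t^2 - s * t
  h00 * y[k] + h10 * d[k] + h01 * y[k + 1L] + h11 * d[k + 1L]
}

#' Barycentric polynomial interpolation
#'
#' Evaluates the unique degree-n polynomial through all observation nodes
#' using the numerically stable barycentric form: weights
#' `w_i = 1 / prod_{j != i} (x_i - x_j)` and
#' `p(x) = sum(w_i y_i / (x - x_i)) / sum(w_i / (x - x_i))`, with exact
#' node values returned when a query coincides with a node. Unlike the
#' piecewise methods, the global polynomial may overshoot the data; node
#' counts are capped because high-degree polynomial interpolation on
#' near-equispaced months is numerically fragile.
#'
#' @inheritParams interpolate_linear
#' @param max_nodes Maximum number of nodes accepted before erroring
#'   (default 50).
#' @return Numeric vector of interpolated values.
#' @examples
#' interpolate_barycentric(c(0, 1, 2, 3), c(0, 1, 4, 9), 1.5) # 2.25
#' @export
interpolate_barycentric <- function(months, values, query, max_nodes = 50L) {
  obs <- check_obs(months, values)
  check_query(obs$months, query)
  x <- obs$months
  y <- obs$values
  if (anyDuplicated(x)) stop("duplicated nodes", call. = FALSE)
  n <- length(x)
  if (n > max_nodes) {
    stop("too many nodes for stable polynomial interpolation (", n, " > ",
      max_nodes, ")",
      call. = FALSE
    )
  }
  # O(n^2) product weights, rescaled by the span to avoid overflow
  xs <- x / (x[n] - x[1L])
  w <- vapply(seq_len(n), function(i) 1 / prod(xs[i] - xs[-i]), numeric(1))
  qs <- query / (x[n] - x[1L])
  vapply(qs, function(q) {
    dx <- q - xs
    hit <- which(abs(dx) < .Machine$double.eps * 8 * max(1, abs(q)))
    if (length(hit) > 0L) {
      return(y[hit[1L]])
    }
    r <- w / dx
    sum(r * y) / sum(r)
  }, numeric(1))
}

#' Fill a monthly timeline from irregular observations
#'
#' Produces the consecutive monthly grid from the first observation up to
#' `upto_month`, carrying observed values unchanged (flagged real) and
#' filling missing months with the chosen interpolation method. Months
#' after `upto_month` are never filled; in the two-stage pipeline
#' `upto_month` is the second-to-last observed month, so the last real
#' observation is left untouched as a forecasting target.
#'
#' @inheritParams interpolate_linear
#' @param method One of `"linear"`, `"pchip"`, `"barycentric"`.
#' @param upto_month Last month of the grid; must itself be observed.
#' @return A tibble with columns `month` (consecutive integers), `value`,
#'   and `is_real` (`TRUE` iff the month was observed).
#' @examples
#' fill_timeline(c(0, 3, 6), c(10, 13, 10), method = "linear", upto_month = 6)
#' @export
fill_timeline <- function(months, values, method = c("linear", "pchip", "barycentric"),
                          upto_month = max(months)) {
  method <- match.arg(method)
  obs <- check_obs(months, values)
  if (!upto_month %in% obs$months) {
    stop("`upto_month` must be an observed month", call. = FALSE)
  }
  keep <- obs$months <= upto_month
  mo <- obs$months[keep]
  va <- obs$values[keep]
  grid <- seq(mo[1L], upto_month)
  is_real <- grid %in% mo
  value <- numeric(length(grid))
  value[is_real] <- va[match(grid[is_real], mo)]
  if (any(!is_real)) {
    fun <- switch(method,
      linear = interpolate_linear,
      pchip = interpolate_pchip,
      barycentric = interpolate_barycentric
    )
    if (length(mo) >= 2L) {
      value[!is_real] <- fun(mo, va, grid[!is_real])
    }
  }
  tibble::tibble(month = as.integer(grid), value = value, is_real = is_real)
}
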