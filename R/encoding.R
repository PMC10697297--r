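#' Normalize a laboratory value
#'
#' Values are mapped through `log(1 + x)`, which keeps the feature space
#' non-negative, is accurate for small inputs, and (unlike min-max
#' scaling) requires no dataset-level statistics, so it cannot leak
#' information across train/test splits.
#'
#' @param x Non-negative numeric vector.
#' @return `log1p(x)`.
#' @export
normalize_value <- function(x) {
  if (any(x < 0)) stop("values must be non-negative", call. = FALSE)
  log1p(x)
}

#' Invert the value normalization
#'
#' @param z Numeric vector on the normalized (`log1p`) scale.
#' @return `expm1(z)`, the raw-scale value.
#' @export
denormalize_value <- function(z) expm1(z)

#' Default discretization thresholds
#'
#' Ships physiologically plausible cut-points for the six default markers,
#' defining two (low/high) or three (low/normal/high) groups. These are
#' configurable defaults for the discrete value encoding, not clinical
#' assertions; supply your own table (or a YAML file via
#' [read_thresholds()]) to change them.
#'
#' @return A named list; each element has `cuts` (strictly increasing
#'   numeric) and `labels` (length `length(cuts) + 1`).
#' @export
default_thresholds <- function() {
  list(
    chol_hdl   = list(cuts = c(3.5, 5.0), labels = c("low", "normal", "high")),
    ldl        = list(cuts = c(100, 160), labels = c("low", "normal", "high")),
    ldl_hdl    = list(cuts = c(2.0, 3.5), labels = c("low", "normal", "high")),
    glucose_ac = list(cuts = c(70, 126), labels = c("low", "normal", "high")),
    wbc        = list(cuts = c(4, 11), labels = c("low", "normal", "high")),
    ua         = list(cuts = 7, labels = c("low", "high"))
  )
}

#' Read a threshold table from YAML
#'
#' Expected layout: `marker: {cuts: [a, b], labels: [low, normal, high]}`.
#'
#' @param path Path to a YAML file.
#' @return A threshold table (named list), validated.
#' @export
read_thresholds <- function(path) {
  tab <- yaml::read_yaml(path)
  for (m in names(tab)) {
    cuts <- tab[[m]]$cuts
    if (is.null(cuts) || any(diff(as.numeric(cuts)) <= 0)) {
      stop("threshold cuts for '", m, "' must be strictly increasing", call. = FALSE)
    }
    ng <- length(cuts) + 1L
    if (!ng %in% c(2L, 3L)) {
      stop("marker '", m, "' must define 2 or 3 groups", call. = FALSE)
    }
  }
  tab
}

#' Discretize a laboratory value
#'
#' Returns the 0-based index of the half-open bin `[cut_k, cut_{k+1})`
#' containing `x`, counted from the lowest group; a value equal to a
#' cut-point falls in the upper bin.
#'
#' @param x Numeric vector of raw-scale values.
#' @param marker Marker name, a key of `table`.
#' @param table Threshold table, e.g. [default_thresholds()].
#' @return Integer vector of category indices (0-based).
#' @examples
#' discretize(c(60, 100, 126, 130), "glucose_ac", default_thresholds())
#' @export
discretize <- function(x, marker, table = default_thresholds()) {
  if (!marker %in% names(table)) {
    stop("unknown marker '", marker, "'", call. = FALSE)
  }
  cuts <- as.numeric(table[[marker]]$cuts)
  findInterval(x, cuts)
}

# Discrete code scaled to [0, 1]: index / (groups - 1).
discrete_code <- function(x, marker, table) {
  cuts <- as.numeric(table[[marker]]$cuts)
  discretize(x, marker, table) / length(cuts)
}

# Feature column order used throughout the model.
FEATURES <- c("value", "age", "sex", "certain", "discrete")

#' Assemble the per-timestep feature matrix of a window
#'
#' Each window month becomes a row with five features: the normalized
#' (`log1p`) laboratory value, normalized age, the sex bit (1 = male), the
#' certainty bit (1 iff the month's value is a real observation rather
#' than an interpolation), and the discrete value code (threshold category
#' scaled to `[0, 1]`). Age and sex are static across the window.
#'
#' @param values Raw-scale window values (length `r + 1`).
#' @param is_real Logical flags, same length.
#' @param age Age in years at the start of the record.
#' @param sex 0 (female) or 1 (male).
#' @param marker Marker name for the discrete encoding.
#' @param table Threshold table.
#' @return A numeric matrix with `length(values)` rows and columns
#'   `value`, `age`, `sex`, `certain`, `discrete`.
#' @export
assemble_features <- function(values, is_real, age, sex, marker,
                              table = default_thresholds()) {
  stopifnot(length(values) == length(is_real), sex %in% c(0, 1))
  m <- cbind(
    value = normalize_value(values),
    age = rep(normalize_value(age), length(values)),
    sex = rep(as.numeric(sex), length(values)),
    certain = as.numeric(is_real),
    discrete = discrete_code(values, marker, table)
  )
  rownames(m) <- NULL
  m
}
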