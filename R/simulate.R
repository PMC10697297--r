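#' Configuration for the synthetic cohort generator
#'
#' Describes the visit process and the latent trajectory model used to
#' emulate longitudinal laboratory cohorts: visits nominally every
#' `visit_interval_months` months with independent dropout and integer
#' jitter, record spans of at least a year, and per-marker log-scale
#' baselines with exponential trends perturbed by AR(1) noise (so lab
#' values stay strictly positive).
#'
#' @param n_patients Number of patients.
#' @param markers Character vector of marker names; defaults to the six
#'   cardiometabolic markers (Chol/HDL-c ratio, LDL-c, LDL-c/HDL-c ratio,
#'   fasting glucose, WBC, uric acid).
#' @param visit_interval_months Nominal months between scheduled visits
#'   (default 3, the insurance-mandated follow-up schedule).
#' @param visit_dropout_prob Probability an interior scheduled visit is
#'   missed (default 0.15).
#' @param jitter_months Maximum +/- integer shift of an interior visit
#'   (default 1).
#' @param span_months_range Inclusive (min, max) of per-patient record
#'   span in months; the minimum must be at least 12 (records spanning
#'   less than a year are excluded from the study design).
#' @param trend_slope_sd SD of the per-year log-scale trend slope; scalar
#'   or one value per marker.
#' @param noise_sd Stationary SD of the AR(1) log-scale noise; scalar or
#'   per marker.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-patient
#'   log baseline; scalars or per marker. Defaults are plausible values
#'   for the six default markers.
#' @param ar1_phi AR(1) autocorrelation of the monthly noise (default 0.7).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          markers = c(
                            "chol_hdl", "ldl", "ldl_hdl",
                            "glucose_ac", "wbc", "ua"
                          ),
                          visit_interval_months = 3L,
                          visit_dropout_prob = 0.15,
                          jitter_months = 1L,
                          span_months_range = c(18L, 48L),
                          trend_slope_sd = 0.10,
                          noise_sd = 0.05,
                          baseline_log_mean = NULL,
                          baseline_log_sd = 0.20,
                          ar1_phi = 0.7,
                          seed = 1L) {
  default_blm <- c(
    chol_hdl = log(4.0), ldl = log(115), ldl_hdl = log(2.4),
    glucose_ac = log(105), wbc = log(6.8), ua = log(6.0)
  )
  if (is.null(baseline_log_mean)) {
    baseline_log_mean <- unname(default_blm[markers])
    baseline_log_mean[is.na(baseline_log_mean)] <- log(100)
  }
  per_marker <- function(x) {
    if (length(x) == 1L) rep(as.numeric(x), length(markers)) else as.numeric(x)
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    markers = markers,
    visit_interval_months = as.integer(visit_interval_months),
    visit_dropout_prob = visit_dropout_prob,
    jitter_months = as.integer(jitter_months),
    span_months_range = as.integer(span_months_range),
    trend_slope_sd = per_marker(trend_slope_sd),
    noise_sd = per_marker(noise_sd),
    baseline_log_mean = per_marker(baseline_log_mean),
    baseline_log_sd = per_marker(baseline_log_sd),
    ar1_phi = ar1_phi,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_patients >= 1L,
    length(cfg$span_months_range) == 2L,
    cfg$span_months_range[1L] <= cfg$span_months_range[2L],
    cfg$visit_dropout_prob >= 0, cfg$visit_dropout_prob < 1,
    cfg$jitter_months >= 0L, cfg$visit_interval_months >= 1L,
    all(cfg$trend_slope_sd >= 0), all(cfg$noise_sd >= 0),
    all(cfg$baseline_log_sd >= 0)
  )
  if (cfg$span_months_range[1L] < 12L) {
    stop("span minimum must be at least 12 months (sub-year records are excluded)",
      call. = FALSE
    )
  }
  structure(cfg, class = "cohort_config")
}

# AR(1) log-noise with stationary sd `sd` on months 0..T.
ar1_noise <- function(T, phi, sd) {
  e <- numeric(T + 1L)
  if (sd == 0) {
    return(e)
  }
  e[1L] <- stats::rnorm(1L, 0, sd)
  if (T >= 1L) {
    innov <- stats::rnorm(T, 0, sd * sqrt(1 - phi^2))
    for (t in seq_len(T)) e[t + 1L] <- phi * e[t] + innov[t]
  }
  e
}

# Visit months for one patient: {0, k*interval +/- jitter, T} with
# independent dropout of interior visits; first and last always kept.
visit_months <- function(T, interval, dropout, jitter) {
  sched <- seq(interval, T - 1L, by = interval)
  sched <- sched[sched > 0L]
  if (length(sched) > 0L) {
    if (jitter > 0L) {
      sched <- sched + sample(seq(-jitter, jitter), length(sched), replace = TRUE)
    }
    if (dropout > 0) sched <- sched[stats::runif(length(sched)) >= dropout]
    sched <- sched[sched > 0L & sched < T]
  }
  sort(unique(c(0L, sched, T)))
}

#' Simulate a longitudinal pretext cohort
#'
#' For every patient and marker, a latent monthly trajectory
#' `baseline * exp(slope * t / 12)` (log-scale AR(1)-perturbed) is drawn
#' on months `0..T`, and observations are sampled at the jittered,
#' dropout-thinned visit schedule. The noise-free latent curve is retained
#' as ground truth for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pretext_cohort` with tibbles:
#'   * `observations`: `patient_id`, `marker`, `month`, `value`;
#'   * `patients`: `patient_id`, `age`, `sex`, `span`;
#'   * `latent`: monthly AR(1)-perturbed latent values;
#'   * `trajectories`: one row per patient x marker with `baseline`,
#'     `slope` (per year, log scale) and `span`.
#' @export
simulate_pretext_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  K <- length(config$markers)
  obs <- vector("list", config$n_patients)
  lat <- vector("list", config$n_patients)
  trj <- vector("list", config$n_patients)
  age <- pmin(pmax(stats::rnorm(config$n_patients, 57, 12), 30), 95)
  sex <- stats::rbinom(config$n_patients, 1L, 0.65)
  span_choices <- seq(config$span_months_range[1L], config$span_months_range[2L])
  spans <- span_choices[sample.int(length(span_choices), config$n_patients,
    replace = TRUE
  )]
  for (p in seq_len(config$n_patients)) {
    T <- spans[p]
    vm <- visit_months(
      T, config$visit_interval_months,
      config$visit_dropout_prob, config$jitter_months
    )
    lb <- stats::rnorm(K, config$baseline_log_mean, config$baseline_log_sd)
    sl <- stats::rnorm(K, 0, config$trend_slope_sd)
    o_k <- l_k <- vector("list", K)
    for (k in seq_len(K)) {
      e <- ar1_noise(T, config$ar1_phi, config$noise_sd[k])
      latent <- exp(lb[k] + sl[k] * (0:T) / 12 + e)
      l_k[[k]] <- tibble::tibble(
        patient_id = p, marker = config$markers[k],
        month = 0:T, latent = latent
      )
      o_k[[k]] <- tibble::tibble(
        patient_id = p, marker = config$markers[k],
        month = vm, value = latent[vm + 1L]
      )
    }
    obs[[p]] <- dplyr::bind_rows(o_k)
    lat[[p]] <- dplyr::bind_rows(l_k)
    trj[[p]] <- tibble::tibble(
      patient_id = p, marker = config$markers,
      baseline = exp(lb), slope = sl, span = T
    )
  }
  structure(
    list(
      observations = dplyr::bind_rows(obs),
      patients = tibble::tibble(
        patient_id = seq_len(config$n_patients),
        age = age, sex = sex, span = spans
      ),
      latent = dplyr::bind_rows(lat),
      trajectories = dplyr::bind_rows(trj),
      config = config
    ),
    class = "pretext_cohort"
  )
}

#' Noise-free latent value of a trajectory at a month
#'
#' Evaluates the generator's closed-form latent curve
#' `baseline * exp(slope * month / 12)`; used as the oracle in recovery
#' tests.
#'
#' @param trajectory A one-row slice of a cohort's `trajectories` tibble
#'   (columns `baseline`, `slope`, `span`).
#' @param month Integer month in `0..span`.
#' @return The noise-free latent value.
#' @export
ground_truth_at <- function(trajectory, month) {
  stopifnot(nrow(trajectory) == 1L)
  if (month < 0 || month > trajectory$span) {
    stop("month outside the trajectory span", call. = FALSE)
  }
  trajectory$baseline * exp(trajectory$slope * month / 12)
}

#' Simulate an episodic downstream cohort
#'
#' One observation per marker per patient, collected at an index
#' procedure, with a binary event label and a gap `g` in months between
#' the index procedure and the event (positives) or censoring
#' (negatives). Negative patients' log-scale marker values are drawn from
#' the stable baseline regime; positives have their log-scale dispersion
#' inflated by `1 + effect_size` (mean unchanged), emulating the
#' scattered single-visit distribution of cases whose latent trajectories
#' diverge. Positives draw their time-to-event gap `g` from a
#' geometric-like law with mean about 28 months; negatives draw a
#' censoring gap whose mean is longer by the factor `1 + effect_size`
#' (censored patients are observed until study end, so their gaps run
#' longer than times-to-event). At `effect_size = 0` the two classes are
#' identical in law — values and gaps — so nothing leaks the label.
#'
#' @param config A [cohort_config()]; supplies marker set, baselines and
#'   the seed.
#' @param n_pos,n_neg Number of event-positive / negative patients
#'   (defaults 42 and 441).
#' @param effect_size Non-negative dispersion shift of the positive class
#'   (0 means the classes are identical in law).
#' @return A tibble with one row per patient: `patient_id`, `age`, `sex`,
#'   `event_label` (`"positive"`/`"negative"`), `gap_months`, and one
#'   column per marker.
#' @export
simulate_downstream_cohort <- function(config, n_pos = 42L, n_neg = 441L,
                                       effect_size = 0) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_pos <= 0L || n_neg <= 0L) {
    stop("n_pos and n_neg must be positive", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- n_pos + n_neg
  is_pos <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  K <- length(config$markers)
  disp <- ifelse(is_pos, 1 + effect_size, 1)
  vals <- sapply(seq_len(K), function(k) {
    exp(stats::rnorm(n, config$baseline_log_mean[k], config$baseline_log_sd[k] * disp))
  })
  colnames(vals) <- config$markers
  out <- tibble::tibble(
    patient_id = seq_len(n),
    age = pmin(pmax(stats::rnorm(n, 57, 12), 30), 95),
    sex = stats::rbinom(n, 1L, 0.65),
    event_label = ifelse(is_pos, "positive", "negative"),
    gap_months = pmin(
      stats::rgeom(n, 1 / ifelse(is_pos, 28, 28 * (1 + effect_size))) + 1L,
      120L
    )
  )
  dplyr::bind_cols(out, tibble::as_tibble(vals))
}

#' Write a cohort to plain-text files
#'
#' Long-format observations go to `observations.csv`
#' (`patient_id,marker,month,value`), static covariates to
#' `patients.csv`; a downstream tibble goes to `downstream.csv`.
#'
#' @param cohort A `pretext_cohort` or a downstream records tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(cohort, "pretext_cohort")) {
    paths <- file.path(dir, c("observations.csv", "patients.csv"))
    utils::write.csv(cohort$observations, paths[1L], row.names = FALSE)
    utils::write.csv(cohort$patients, paths[2L], row.names = FALSE)
  } else {
    paths <- file.path(dir, "downstream.csv")
    utils::write.csv(cohort, paths, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file whose keys match [cohort_config()] arguments.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
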