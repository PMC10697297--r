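# Independent oracles and small fixtures shared across tests. Everything
# here is deliberately naive (brute force, closed forms) and never calls
# the code paths it is used to check.

# Eq.-style two-point linear interpolation at a single query.
linear_oracle <- function(months, values, q) {
  k <- max(which(months <= q))
  if (months[k] == q) {
    return(values[k])
  }
  i <- k
  values[i] + (q - months[i]) * (values[i + 1] - values[i]) /
    (months[i + 1] - months[i])
}

# Direct Lagrange-form polynomial evaluation.
lagrange_oracle <- function(x, y, q) {
  n <- length(x)
  sum(vapply(seq_len(n), function(i) {
    y[i] * prod((q - x[-i]) / (x[i] - x[-i]))
  }, numeric(1)))
}

# Exhaustive stage-1 frame enumeration from first principles: observed
# months define t0 and m (second-to-last); every start i with
# i + r <= m - 1 yields a frame targeting i + r + 1.
brute_frames <- function(obs_months, r) {
  obs_months <- sort(obs_months)
  n <- length(obs_months)
  t0 <- obs_months[1]
  m <- obs_months[n - 1]
  starts <- integer(0)
  i <- t0
  while (i + r <= m - 1) {
    starts <- c(starts, i)
    i <- i + 1
  }
  list(starts = starts, targets = starts + r + 1, count = length(starts))
}

# Brute-force stage-2 eligibility and gap.
brute_stage2 <- function(obs_months, r, g_max = floor(r / 2)) {
  obs_months <- sort(obs_months)
  n <- length(obs_months)
  m <- obs_months[n - 1]
  tn <- obs_months[n]
  g <- tn - m - 1
  t0 <- obs_months[1]
  if (m - t0 < r || g > g_max) {
    return(NULL)
  }
  list(window = (m - r):m, g = g)
}

# Random irregular observation series on an integer month grid.
random_series <- function(n_obs = NULL, span = NULL) {
  if (is.null(span)) span <- sample(13:40, 1)
  if (is.null(n_obs)) n_obs <- sample(3:min(10, span), 1)
  months <- sort(sample(1:(span - 1), n_obs - 2))
  months <- c(0, months, span)
  values <- exp(rnorm(length(months), log(100), 0.2))
  list(months = months, values = values)
}

# Small pretext cohort used by several training tests.
tiny_cohort <- function(n = 12, seed = 42, noise_sd = 0.05, span = c(18, 36)) {
  simulate_pretext_cohort(cohort_config(
    n_patients = n, seed = seed, noise_sd = noise_sd,
    span_months_range = span
  ))
}

# Patient-level subset of a glp_frames / glp_stage2_set.
take_patients <- function(d, keep) {
  idx <- which(d$patient_id %in% keep)
  d$X <- d$X[idx, , , drop = FALSE]
  d$y <- d$y[idx]
  d$patient_id <- d$patient_id[idx]
  if (!is.null(d$n_real)) d$n_real <- d$n_real[idx]
  if (!is.null(d$g)) d$g <- d$g[idx]
  d
}
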