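# Independent oracles and fixture builders shared across the suite.

# Naive double-loop KDE: the reference the vectorized implementation must
# match to 1e-12 relative.
naive_kde <- function(points, h, x) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  d <- ncol(points)
  total <- 0
  for (i in seq_len(n)) {
    u <- (x - points[i, ]) / h
    total <- total + (2 * pi)^(-d / 2) * exp(-sum(u^2) / 2)
  }
  total / (n * h^d)
}

# Minimal cohort-shaped records carrying one or two feature columns.
# Values land in `age_at_surgery` (plain standardization) and optionally
# `annual_wear` (log-standardized) so classifier tests control the
# geometry directly.
toy_records <- function(age, label, wear = NULL, sex = NULL) {
  df <- data.frame(age_at_surgery = age, label = label,
                   stringsAsFactors = FALSE)
  if (!is.null(wear)) df$annual_wear <- wear
  if (!is.null(sex)) df$sex <- sex
  df
}

# A kernel_bayes model with identity standardization, so training points
# are used exactly as given (hand-computable posteriors).
std_model <- function(points_by_class, priors, h) {
  classes <- names(points_by_class)
  params <- structure(
    list(features = "age_at_surgery",
         transforms = c(age_at_surgery = "standardize"),
         center = c(age_at_surgery = 0), scale = c(age_at_surgery = 1)),
    class = "standardization_params")
  densities <- lapply(points_by_class, kde_model, h = h)
  structure(list(classes = classes,
                 priors = stats::setNames(priors, classes),
                 densities = densities,
                 feature_spec = feature_spec("age_at_surgery"),
                 standardization = params, h = h,
                 n = sum(lengths(points_by_class)), d = 1L),
            class = "kernel_bayes")
}

# Down-scaled default cohort for fast CV tests: class sizes shrunk by
# `scale` with the same per-class moments and sex ratios.
small_cohort_config <- function(seed = 1, scale = 0.25) {
  d <- cohort_config(seed = seed)
  shrink <- function(g) {
    g$n <- max(8L, as.integer(round(g$n * scale)))
    g$n_male <- as.integer(round(g$n * 0.5))
    do.call(group_spec, unclass(g))
  }
  cohort_config(control = shrink(d$control),
                osteolysis = shrink(d$osteolysis), seed = seed)
}
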