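#' @title Kernel Bayes classifier
#' @description Bayes' theorem with class-conditional kernel density
#'   estimates: \eqn{P(C_i | x) = p(x | C_i) P(C_i) / \sum_j p(x | C_j)
#'   P(C_j)}, with priors taken as relative class frequencies and each
#'   \eqn{p(x | C_i)} a fixed-bandwidth Gaussian KDE on standardized
#'   features. Annual wear rate is log-transformed before standardization to
#'   tame its long right tail; decisions use the MAP rule with ties going to
#'   the control class.
#' @name classifier
NULL

ALLOWED_FEATURES <- c("annual_wear", "age_at_surgery", "bmi", "height")
CLASS_LEVELS <- c("control", "osteolysis")

#' Feature specification
#'
#' Names the model features and the per-feature transform. `annual_wear`
#' always uses `log_then_standardize`; all other features use `standardize`
#' (zero mean, unit variance on the training set).
#'
#' @param features character vector drawn from
#'   `annual_wear, age_at_surgery, bmi, height`; non-empty, no duplicates.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(features = c("annual_wear", "age_at_surgery")) {
  features <- as.character(features)
  if (length(features) == 0) stop_invalid("feature list must be non-empty")
  if (anyDuplicated(features)) stop_invalid("duplicate feature names")
  unknown <- setdiff(features, ALLOWED_FEATURES)
  if (length(unknown))
    stop_invalid("unknown feature(s) %s; allowed: %s",
                 paste(unknown, collapse = ", "),
                 paste(ALLOWED_FEATURES, collapse = ", "))
  transforms <- ifelse(features == "annual_wear",
                       "log_then_standardize", "standardize")
  names(transforms) <- features
  structure(list(names = features, transforms = transforms),
            class = "feature_spec")
}

# Raw feature matrix from a cohort data.frame (or compatible newdata),
# with domain checks (wear must be positive before the log).
raw_feature_matrix <- function(records, spec) {
  miss <- setdiff(spec$names, names(records))
  if (length(miss))
    stop_invalid("missing feature column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(records)[spec$names])
  storage.mode(X) <- "double"
  if ("annual_wear" %in% spec$names) {
    w <- X[, "annual_wear"]
    if (any(!is.finite(w)) || any(w <= 0))
      stop_invalid("annual_wear must be positive to apply the log transform")
  }
  if (!all(is.finite(X))) stop_invalid("non-finite feature values")
  X
}

#' Fit the preprocessing transform and return the design matrix
#'
#' Applies the per-feature transform (log for wear), then standardizes each
#' column to zero mean and unit variance using moments estimated on the
#' fitting set. The returned parameters are applied verbatim to held-out
#' data (a held-out point is standardized by the *training* moments).
#'
#' @param records cohort rows used for fitting.
#' @param spec a [feature_spec()].
#' @return list with `x` (standardized n x d matrix) and `params` (an object
#'   of class `standardization_params`: per-feature transform, center, scale).
#' @export
fit_transform <- function(records, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  X <- raw_feature_matrix(records, spec)
  if (nrow(X) < 2) stop_invalid("need at least 2 rows to fit a transform")
  for (f in spec$names)
    if (spec$transforms[[f]] == "log_then_standardize") X[, f] <- log(X[, f])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  zero <- which(!is.finite(scale) | scale <= 0)
  if (length(zero))
    stop_invalid("zero-variance feature(s): %s",
                 paste(spec$names[zero], collapse = ", "))
  params <- structure(
    list(features = spec$names, transforms = spec$transforms,
         center = center, scale = scale),
    class = "standardization_params")
  list(x = apply_transform(params, records), params = params)
}

#' Apply fitted standardization parameters to new data
#'
#' @param params a `standardization_params` object from [fit_transform()].
#' @param records new cohort rows (or a data.frame with the feature columns).
#' @return standardized numeric matrix.
#' @export
apply_transform <- function(params, records) {
  stopifnot(inherits(params, "standardization_params"))
  spec <- structure(list(names = params$features,
                         transforms = params$transforms),
                    class = "feature_spec")
  X <- raw_feature_matrix(records, spec)
  for (f in params$features)
    if (params$transforms[[f]] == "log_then_standardize") X[, f] <- log(X[, f])
  sweep(sweep(X, 2, params$center, "-"), 2, params$scale, "/")
}

# Back-transform standardized coordinates of one feature to raw units.
back_transform <- function(params, feature, z) {
  i <- match(feature, params$features)
  raw <- params$center[i] + params$scale[i] * z
  if (params$transforms[[feature]] == "log_then_standardize") raw <- exp(raw)
  raw
}

#' Empirical prior class probabilities
#'
#' Relative frequency of each class: `prior_i = n_i / n`.
#'
#' @param labels vector (or factor) of class labels; every class level must
#'   be represented.
#' @return named numeric vector of priors summing to 1.
#' @export
estimate_priors <- function(labels) {
  f <- as_class_factor(labels)
  counts <- table(f)
  if (any(counts == 0))
    stop_invalid("empty class: %s",
                 paste(names(counts)[counts == 0], collapse = ", "))
  p <- as.numeric(counts) / length(f)
  names(p) <- names(counts)
  p
}

as_class_factor <- function(labels) {
  if (is.factor(labels)) return(labels)
  u <- unique(as.character(labels))
  if (all(u %in% CLASS_LEVELS)) return(factor(labels, levels = CLASS_LEVELS))
  factor(labels, levels = sort(u)) # general M-class support
}

#' Fit the kernel Bayes classifier
#'
#' Standardization is fitted on the pooled training data (both classes
#' together) so that the shared bandwidth h is meaningful on one common
#' scale; one KDE is then built per class from that class's standardized
#' rows. With cohort labels, the class order is (control, osteolysis).
#'
#' @param records training cohort: a data.frame with the feature columns and
#'   a `label` column.
#' @param spec a [feature_spec()].
#' @param h bandwidth (default 0.7, the headline smoothing choice; the
#'   MAD-robust rule on log wear gives about 0.3, which is visibly rough).
#' @param priors `"empirical"` for relative class frequencies, or a numeric
#'   vector of fixed priors (one per class, summing to 1).
#' @return an object of class `kernel_bayes`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' model <- fit_classifier(cohort, feature_spec(c("annual_wear", "age_at_surgery")))
#' posterior(model, data.frame(annual_wear = 0.2, age_at_surgery = 60))
#' @export
fit_classifier <- function(records, spec = feature_spec(), h = 0.7,
                           priors = "empirical") {
  stopifnot(inherits(spec, "feature_spec"))
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop_invalid("bandwidth h must be a single positive number")
  labels <- as_class_factor(records$label)
  classes <- levels(labels)
  if (length(classes) < 2) stop_invalid("need at least two classes to fit")
  counts <- table(labels)
  if (any(counts < 2))
    stop_invalid("every class needs >= 2 training rows")
  ft <- fit_transform(records, spec)
  if (identical(priors, "empirical")) {
    pr <- estimate_priors(labels)
  } else {
    if (!is.numeric(priors) || length(priors) != length(classes))
      stop_invalid("fixed priors must be numeric, one per class")
    if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-8)
      stop_invalid("fixed priors must be positive and sum to 1")
    pr <- priors
    names(pr) <- classes
  }
  densities <- lapply(classes, function(cl)
    kde_model(ft$x[labels == cl, , drop = FALSE], h))
  names(densities) <- classes
  structure(list(classes = classes, priors = pr, densities = densities,
                 feature_spec = spec, standardization = ft$params,
                 h = h, n = nrow(ft$x), d = length(spec$names)),
            class = "kernel_bayes")
}

#' @export
print.kernel_bayes <- function(x, ...) {
  cat("Kernel Bayes classifier\n")
  cat(sprintf("  features: %s (h = %g)\n",
              paste(x$feature_spec$names, collapse = ", "), x$h))
  for (cl in x$classes)
    cat(sprintf("  %s: n = %d, prior = %.4f\n",
                cl, x$densities[[cl]]$n, x$priors[[cl]]))
  invisible(x)
}

# Density values below this are exact zeros in double precision; when every
# class-conditional density underflows, the query is outside the supported
# region and the posterior falls back to the priors.
LOG_UNDERFLOW <- log(.Machine$double.xmin)

# Posterior matrix from already-standardized query rows.
posterior_from_standardized <- function(model, Z) {
  M <- length(model$classes)
  logd <- matrix(NA_real_, nrow(Z), M, dimnames = list(NULL, model$classes))
  for (j in seq_len(M)) {
    dm <- model$densities[[model$classes[j]]]
    logd[, j] <- kde_logdensity(dm$points, dm$h, Z)
  }
  logp <- sweep(logd, 2, log(as.numeric(model$priors)), "+")
  lse <- row_logsumexp(logp)
  post <- exp(logp - lse)
  no_support <- apply(logd < LOG_UNDERFLOW, 1L, all)
  if (any(no_support))
    post[no_support, ] <- matrix(as.numeric(model$priors),
                                 sum(no_support), M, byrow = TRUE)
  attr(post, "no_support") <- no_support
  post
}

#' Posterior class probabilities
#'
#' Queries are given in raw clinical units (mm/yr, years, kg/m^2, m); the
#' training transform is applied internally. Where every class density
#' underflows to zero (query far outside the sampled region) the posterior
#' falls back to the priors and the row is flagged in the `no_support`
#' attribute — the model is only informative where data are densely sampled.
#'
#' @param model a fitted [fit_classifier()] model.
#' @param newdata a data.frame with the feature columns, or a single named
#'   numeric vector.
#' @return numeric matrix (rows = queries, columns = classes) of posterior
#'   probabilities summing to 1 per row, with attribute `no_support`.
#' @export
posterior <- function(model, newdata) {
  stopifnot(inherits(model, "kernel_bayes"))
  if (!is.data.frame(newdata)) {
    if (is.null(names(newdata)))
      stop_invalid("newdata must be a data.frame or a named vector")
    newdata <- as.data.frame(as.list(newdata))
  }
  Z <- apply_transform(model$standardization, newdata)
  posterior_from_standardized(model, Z)
}

#' MAP classification
#'
#' Assigns the class with maximal posterior probability; exact ties go to
#' the first class (control).
#'
#' @inheritParams posterior
#' @return factor of predicted class labels.
#' @export
classify <- function(model, newdata) {
  post <- posterior(model, newdata)
  factor(model$classes[max.col(post, ties.method = "first")],
         levels = model$classes)
}

#' @export
predict.kernel_bayes <- function(object, newdata,
                                 type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "posterior") posterior(object, newdata)
  else classify(object, newdata)
}

#' Posterior probability curve for a univariate model
#'
#' Evaluates the posterior on a regular grid in transformed (standardized)
#' space spanning the training data range plus padding, reporting the axis
#' back-transformed to raw units (wear is exponentiated so the axis reads in
#' mm/yr). The pooled (whole-dataset) density on the same grid locates the
#' densely sampled region.
#'
#' @param model a 1-feature [fit_classifier()] model.
#' @param n_points grid resolution (default 200).
#' @param padding grid extension beyond the data range, in standardized
#'   units (default 1).
#' @return data.frame with the raw feature value, its standardized
#'   coordinate, one posterior column per class, and the pooled `density`
#'   (on the standardized scale).
#' @export
posterior_curve <- function(model, n_points = 200, padding = 1) {
  stopifnot(inherits(model, "kernel_bayes"))
  if (model$d != 1)
    stop_invalid("posterior_curve needs a 1-feature model (d = %d)", model$d)
  feat <- model$feature_spec$names[1]
  pts <- do.call(rbind, lapply(model$densities, function(m) m$points))
  z <- seq(min(pts) - padding, max(pts) + padding, length.out = n_points)
  raw <- back_transform(model$standardization, feat, z)
  df <- data.frame(raw, check.names = FALSE)
  names(df) <- feat
  post <- posterior(model, df)
  dens <- exp(kde_logdensity(pts, model$h, matrix(z, ncol = 1)))
  out <- data.frame(value = raw, value_std = z, check.names = FALSE)
  names(out)[1] <- feat
  for (cl in model$classes) out[[paste0("posterior_", cl)]] <- post[, cl]
  out$density <- dens
  out$no_support <- attr(post, "no_support")
  out
}

#' Posterior probability surface for a bivariate model
#'
#' As [posterior_curve()], on a `resolution` x `resolution` grid over both
#' features, accompanied by the pooled joint training density on the same
#' grid (identifying where the model is supported by data).
#'
#' @param model a 2-feature [fit_classifier()] model.
#' @param resolution grid points per axis (default 50).
#' @param padding grid extension in standardized units (default 1).
#' @return long-format data.frame: raw feature values, standardized
#'   coordinates (`*_std`), posterior columns, pooled `density`.
#' @export
posterior_surface <- function(model, resolution = 50, padding = 1) {
  stopifnot(inherits(model, "kernel_bayes"))
  if (model$d != 2)
    stop_invalid("posterior_surface needs a 2-feature model (d = %d)", model$d)
  feats <- model$feature_spec$names
  pts <- do.call(rbind, lapply(model$densities, function(m) m$points))
  z1 <- seq(min(pts[, 1]) - padding, max(pts[, 1]) + padding,
            length.out = resolution)
  z2 <- seq(min(pts[, 2]) - padding, max(pts[, 2]) + padding,
            length.out = resolution)
  grid <- expand.grid(z1 = z1, z2 = z2, KEEP.OUT.ATTRS = FALSE)
  Z <- as.matrix(grid)
  post <- posterior_from_standardized(model, Z)
  dens <- exp(kde_logdensity(pts, model$h, Z))
  out <- data.frame(
    back_transform(model$standardization, feats[1], grid$z1),
    back_transform(model$standardization, feats[2], grid$z2),
    grid$z1, grid$z2, check.names = FALSE)
  names(out) <- c(feats, paste0(feats, "_std"))
  for (cl in model$classes) out[[paste0("posterior_", cl)]] <- post[, cl]
  out$density <- dens
  out$no_support <- attr(post, "no_support")
  out
}

#' Serialize / restore a fitted classifier as JSON
#'
#' The document stores classes, priors, bandwidth, feature spec,
#' standardization parameters and the standardized training points, so a
#' restored model reproduces posteriors exactly.
#'
#' @param model a [fit_classifier()] model.
#' @param path JSON file path.
#' @return `read_model` returns the restored `kernel_bayes` object;
#'   `write_model` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kernel_bayes"))
  doc <- list(
    format = "osteoKDE/kernel_bayes/v1",
    classes = model$classes,
    priors = as.numeric(model$priors),
    h = model$h,
    features = model$feature_spec$names,
    transforms = as.character(model$feature_spec$transforms),
    center = as.numeric(model$standardization$center),
    scale = as.numeric(model$standardization$scale),
    points = lapply(model$classes, function(cl)
      unname(as.data.frame(model$densities[[cl]]$points)))
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "osteoKDE/kernel_bayes/v1"))
    stop_invalid("%s is not an osteoKDE model file", path)
  spec <- structure(list(names = doc$features,
                         transforms = stats::setNames(doc$transforms,
                                                      doc$features)),
                    class = "feature_spec")
  params <- structure(
    list(features = doc$features, transforms = spec$transforms,
         center = stats::setNames(doc$center, doc$features),
         scale = stats::setNames(doc$scale, doc$features)),
    class = "standardization_params")
  densities <- lapply(doc$points, function(p)
    kde_model(as.matrix(as.data.frame(p)), doc$h))
  names(densities) <- doc$classes
  structure(list(classes = doc$classes,
                 priors = stats::setNames(doc$priors, doc$classes),
                 densities = densities, feature_spec = spec,
                 standardization = params, h = doc$h,
                 n = sum(vapply(densities, `[[`, 0, "n")),
                 d = length(doc$features)),
            class = "kernel_bayes")
}
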