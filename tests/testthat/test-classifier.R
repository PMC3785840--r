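# classifier module: transforms, priors, posteriors, decision rule, grids.

test_that("fit_transform log-standardizes wear and retains training moments", {
  rec <- toy_records(age = c(50, 60, 70), label = rep("control", 3),
                     wear = exp(0:2))
  ft <- fit_transform(rec, feature_spec(c("annual_wear")))
  expect_equal(as.numeric(ft$x), c(-1, 0, 1)) # log -> {0,1,2} -> z-scores

  # fitted columns have mean 0, sd 1
  set.seed(8)
  rec2 <- toy_records(age = rnorm(40, 60, 8), label = rep("control", 40),
                      wear = rlnorm(40))
  ft2 <- fit_transform(rec2, feature_spec(c("annual_wear", "age_at_surgery")))
  expect_equal(unname(colMeans(ft2$x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(ft2$x, 2, sd)), c(1, 1), tolerance = 1e-9)

  # idempotence: params applied to the fitting set reproduce the matrix
  expect_equal(apply_transform(ft2$params, rec2), ft2$x)

  # held-out points use the *training* center/scale, not their own
  hold <- toy_records(age = 90, label = "control", wear = 5)
  z <- apply_transform(ft2$params, hold)
  expect_false(any(z == 0))
  expect_equal(unname(z[1, "age_at_surgery"]),
               (90 - mean(rec2$age_at_surgery)) / sd(rec2$age_at_surgery))

  expect_error(fit_transform(toy_records(1:3, rep("control", 3), wear = c(1, -1, 2)),
                             feature_spec("annual_wear")), "positive")
  expect_error(fit_transform(toy_records(rep(60, 5), rep("control", 5)),
                             feature_spec("age_at_surgery")), "zero-variance")
})

test_that("feature_spec validates its inputs", {
  fs <- feature_spec(c("annual_wear", "bmi"))
  expect_equal(unname(fs$transforms),
               c("log_then_standardize", "standardize"))
  expect_error(feature_spec(character(0)), "non-empty")
  expect_error(feature_spec(c("bmi", "bmi")), "duplicate")
  expect_error(feature_spec("weight"), "allowed")
})

test_that("priors are exact relative frequencies", {
  labs <- c(rep("control", 283), rep("osteolysis", 180))
  p <- estimate_priors(labs)
  expect_equal(unname(p), c(283, 180) / 463, tolerance = 1e-15)
  expect_equal(sum(p), 1)
  expect_equal(unname(estimate_priors(rep(c("control", "osteolysis"), 10))),
               c(0.5, 0.5))
  expect_equal(unname(estimate_priors(c("control", rep("osteolysis", 3)))),
               c(0.25, 0.75))
  expect_error(estimate_priors(factor(rep("control", 5),
                                      levels = c("control", "osteolysis"))),
               "empty class")
})

test_that("fit_classifier builds per-class KDEs on a pooled standard scale", {
  co <- generate_cohort(cohort_config(seed = 2))
  m <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")),
                      h = 0.7)
  expect_equal(m$d, 2)
  expect_equal(m$densities$control$n, 283)
  expect_equal(m$densities$osteolysis$n, 180)
  expect_equal(unname(m$priors), c(283, 180) / 463)
  expect_equal(m$densities$control$h, 0.7)

  # pooled standardization: class point sets stack to mean 0 / sd 1
  pooled <- rbind(m$densities$control$points, m$densities$osteolysis$points)
  expect_equal(unname(colMeans(pooled)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(pooled, 2, sd)), c(1, 1), tolerance = 1e-9)

  # fixed priors override the counts
  m2 <- fit_classifier(co, feature_spec(), h = 0.7, priors = c(0.5, 0.5))
  expect_equal(unname(m2$priors), c(0.5, 0.5))

  # no hidden randomness: refit is identical
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(m, f1)
  write_model(fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")),
                             h = 0.7), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(fit_classifier(co, feature_spec(), h = -1), "positive")
  expect_error(fit_classifier(co, feature_spec(), priors = c(0.7, 0.7)),
               "sum to 1")
})

test_that("posterior matches hand computation and Bayes algebra", {
  # classes at {0} and {2}, h = 1, equal priors, query 0:
  # P(A|0) = phi(0) / (phi(0) + phi(2))
  m <- std_model(list(control = 0, osteolysis = 2), c(0.5, 0.5), h = 1)
  p <- posterior(m, data.frame(age_at_surgery = 0))
  expect_equal(unname(p[1, "control"]), dnorm(0) / (dnorm(0) + dnorm(2)),
               tolerance = 1e-12)
  expect_equal(unname(p[1, "control"]), 0.8808, tolerance = 1e-4)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # mirror symmetry: equal priors, query at the symmetry point
  ms <- std_model(list(control = c(-2, -1), osteolysis = c(1, 2)),
                  c(0.5, 0.5), h = 0.8)
  ps <- posterior(ms, data.frame(age_at_surgery = 0))
  expect_equal(unname(ps[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # ... and the tie goes to control
  expect_equal(as.character(classify(ms, data.frame(age_at_surgery = 0))),
               "control")

  # huge h: posterior collapses to the priors everywhere in the data range
  mh <- std_model(list(control = c(-2, 0, 1), osteolysis = c(-1, 2)),
                  c(0.7, 0.3), h = 1e6)
  for (x in c(-2, 0, 2)) {
    ph <- posterior(mh, data.frame(age_at_surgery = x))
    expect_equal(unname(ph[1, ]), c(0.7, 0.3), tolerance = 1e-3)
  }
})

test_that("posterior flags no-support queries and rejects bad input", {
  co <- generate_cohort(small_cohort_config(seed = 4))
  m <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")))
  far <- data.frame(annual_wear = 0.1, age_at_surgery = 1e6)
  p <- posterior(m, far)
  expect_true(attr(p, "no_support")[1])
  expect_equal(unname(p[1, ]), unname(as.numeric(m$priors)))
  expect_equal(as.character(classify(m, far)), "control") # majority prior

  expect_error(posterior(m, data.frame(annual_wear = -0.2, age_at_surgery = 60)),
               "positive")
})

test_that("posterior properties hold over random models", {
  set.seed(99)
  for (rep in 1:50) {
    n0 <- sample(3:20, 1); n1 <- sample(3:20, 1)
    pr <- runif(1, 0.05, 0.95)
    m <- std_model(list(control = rnorm(n0, -1), osteolysis = rnorm(n1, 1)),
                   c(pr, 1 - pr), h = runif(1, 0.2, 2))
    x <- data.frame(age_at_surgery = rnorm(1, 0, 2))
    p <- posterior(m, x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))

    # prior limit as h -> infinity
    m_inf <- m; m_inf$densities <- lapply(m$densities, function(d)
      kde_model(d$points, 1e6))
    expect_equal(unname(posterior(m_inf, x)[1, ]), c(pr, 1 - pr),
                 tolerance = 1e-3)

    # raising the osteolysis prior never lowers its posterior
    m_up <- m; m_up$priors <- stats::setNames(c(pr * 0.5, 1 - pr * 0.5),
                                              m$classes)
    expect_gte(posterior(m_up, x)[1, "osteolysis"], p[1, "osteolysis"] - 1e-12)
  }
})

test_that("swapping class labels swaps posterior components exactly", {
  set.seed(17)
  rec <- toy_records(age = rnorm(60, 60, 8),
                     label = rep(c("control", "osteolysis"), 30),
                     wear = rlnorm(60, -1.5, 0.8))
  swapped <- rec
  swapped$label <- ifelse(rec$label == "control", "osteolysis", "control")
  spec <- feature_spec(c("annual_wear", "age_at_surgery"))
  m1 <- fit_classifier(rec, spec, 0.7)
  m2 <- fit_classifier(swapped, spec, 0.7)
  q <- data.frame(annual_wear = c(0.1, 0.3), age_at_surgery = c(55, 70))
  p1 <- posterior(m1, q)
  p2 <- posterior(m2, q)
  expect_equal(p1[, "control"], p2[, "osteolysis"], tolerance = 1e-14)
  expect_equal(p1[, "osteolysis"], p2[, "control"], tolerance = 1e-14)
})

test_that("MAP error approaches the analytic Bayes error on N(0,1) vs N(2,1)", {
  # two unit-variance normals 2 apart, equal priors: Bayes error = pnorm(-1)
  n <- 2000
  train <- with_seed(1234, toy_records(
    age = c(rnorm(n, 0), rnorm(n, 2)),
    label = rep(c("control", "osteolysis"), each = n)))
  spec <- feature_spec("age_at_surgery")
  ft <- fit_transform(train, spec)
  h_std <- bandwidth_normal_reference(as.numeric(ft$x))
  m <- fit_classifier(train, spec, h = h_std, priors = c(0.5, 0.5))
  test <- with_seed(4321, toy_records(
    age = c(rnorm(n, 0), rnorm(n, 2)),
    label = rep(c("control", "osteolysis"), each = n)))
  err <- mean(as.character(classify(m, test)) != test$label)
  expect_lt(abs(err - pnorm(-1)), 0.02)
})

test_that("posterior_curve matches pointwise posteriors and back-transforms wear", {
  co <- generate_cohort(small_cohort_config(seed = 9))
  m <- fit_classifier(co, feature_spec("annual_wear"), 0.7)
  cur <- posterior_curve(m, n_points = 41, padding = 1)
  expect_true(all(cur$annual_wear > 0)) # back-transformed axis
  expect_equal(cur$posterior_control + cur$posterior_osteolysis,
               rep(1, 41), tolerance = 1e-12)
  # pointwise oracle: re-evaluate posterior() at a few grid rows
  for (i in c(1, 20, 41)) {
    p <- posterior(m, data.frame(annual_wear = cur$annual_wear[i]))
    expect_equal(cur$posterior_osteolysis[i], unname(p[1, "osteolysis"]),
                 tolerance = 1e-10)
  }
  m2 <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")))
  expect_error(posterior_curve(m2), "1-feature")
})

test_that("posterior_surface matches pointwise posteriors; density integrates to 1", {
  co <- generate_cohort(small_cohort_config(seed = 10))
  m <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")), 0.7)
  surf <- posterior_surface(m, resolution = 61, padding = 4)
  i <- c(1, 1500, 3721)
  p <- posterior(m, surf[i, c("annual_wear", "age_at_surgery")])
  expect_equal(surf$posterior_osteolysis[i], unname(p[, "osteolysis"]),
               tolerance = 1e-10)

  # pooled joint density integrates to ~1 over the padded standardized grid
  z1 <- sort(unique(surf$annual_wear_std))
  z2 <- sort(unique(surf$age_at_surgery_std))
  M <- matrix(surf$density, length(z1), length(z2))
  w1 <- rep(diff(z1)[1], length(z1)); w1[c(1, length(z1))] <- w1[1] / 2
  w2 <- rep(diff(z2)[1], length(z2)); w2[c(1, length(z2))] <- w2[1] / 2
  integral <- as.numeric(t(w1) %*% M %*% w2)
  expect_lt(abs(integral - 1), 0.01)

  m1 <- fit_classifier(co, feature_spec("annual_wear"))
  expect_error(posterior_surface(m1), "2-feature")
})

test_that("osteolysis risk declines with age at fixed wear in the dense region", {
  co <- generate_cohort(cohort_config(seed = 1))
  m <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")), 0.7)
  ages <- seq(55, 70, by = 1)
  for (wear in c(0.08, 0.12, 0.2)) {
    p <- posterior(m, data.frame(annual_wear = wear, age_at_surgery = ages))
    expect_true(all(diff(p[, "osteolysis"]) <= 1e-10),
                label = sprintf("monotone decline at wear %g", wear))
  }
})

test_that("model JSON round-trips to identical posteriors", {
  co <- generate_cohort(small_cohort_config(seed = 12))
  m <- fit_classifier(co, feature_spec(c("annual_wear", "age_at_surgery")), 0.7)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  q <- data.frame(annual_wear = c(0.05, 0.1, 0.4),
                  age_at_surgery = c(50, 62, 75))
  expect_equal(posterior(m2, q), posterior(m, q), tolerance = 1e-14)
  expect_equal(m2$priors, m$priors)
  expect_error(read_model(withr::local_tempfile(lines = "{}")), "model file")
})
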