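test_that("Harrell's C matches brute-force pair enumeration", {
  # 3 comparable pairs, 2 concordant
  expect_equal(harrell_c(c(3, 1, 2), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  # constant scores: all ties
  expect_equal(harrell_c(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    sc <- sample(1:6, n, TRUE)          # force score ties
    tm <- sample(1:10, n, TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    if (all(tm == tm[1])) tm[1] <- tm[1] + 1
    got <- harrell_c(sc, tm, ev)
    want <- oracle_harrell_c(sc, tm, ev)
    expect_equal(got, want)
    # antisymmetry under score negation
    expect_equal(harrell_c(-sc, tm, ev), 1 - got)
  }
  expect_error(harrell_c(1:3, c(1, 1, 1), c(0, 0, 1)), "comparable")
})

test_that("log-rank statistic matches explicit risk-table computation", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    tm <- sample(1:12, n, TRUE)
    ev <- rbinom(n, 1, 0.7)
    g <- factor(c("a", "b"))[c(1, 2, sample(1:2, n - 2, TRUE))]
    if (sum(ev) == 0) ev[1] <- 1
    lr <- km_logrank(tm, ev, g)
    expect_equal(lr$chisq, oracle_logrank(tm, ev, g), tolerance = 1e-9)
    expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE))
  }
  # identical groups: statistic 0, p 1
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 0, 1, 1, 0, 1)
  g <- factor(rep(c("a", "b"), each = 3))
  lr0 <- km_logrank(tm, ev, g)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(km_logrank(tm, ev, factor(rep("a", 6))), "2 non-empty")
  expect_warning(km_logrank(tm, rep(0, 6), g), "no events")
})

test_that("KM estimator equals hand product-limit and 1-ECDF", {
  # times {1,2}, events {1,0}: S = 1 on [0,1), 0.5 from t = 1
  lr <- km_logrank(c(1, 2, 1, 2), c(1, 0, 1, 0),
                   factor(rep(c("a", "b"), each = 2)))
  a <- lr$curves[lr$curves$group == "a", ]
  expect_equal(a$surv[a$time == 1], 0.5)
  # no censoring: KM = 1 - ECDF at every event time
  set.seed(16)
  tm <- sample(1:20, 30, TRUE); ev <- rep(1, 30)
  g <- factor(rep(c("a", "b"), 15))
  cv <- km_logrank(tm, ev, g)$curves
  for (grp in c("a", "b")) {
    cc <- cv[cv$group == grp, ]
    ec <- stats::ecdf(tm[g == grp])
    expect_equal(cc$surv, 1 - ec(cc$time), tolerance = 1e-12)
  }
})

test_that("Cox fit recovers a known hazard ratio and flags nulls", {
  set.seed(17)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.01 * 2^x)
  cens <- runif(n, 0, 200)
  d <- survival_data(pmin(tm, cens), as.integer(tm <= cens),
                     matrix(x, dimnames = list(NULL, "grp")))
  fit <- fit_cox(d)
  expect_gte(fit$hr[["grp"]], 1.7)
  expect_lte(fit$hr[["grp"]], 2.3)
  expect_true(fit$ci_lower[["grp"]] < fit$hr[["grp"]],
              fit$ci_upper[["grp"]] > fit$hr[["grp"]])
  expect_lt(fit$wald_p[["grp"]], 0.001)

  # permuted covariate: small coefficient
  d0 <- survival_data(pmin(tm, cens), as.integer(tm <= cens),
                      matrix(sample(x), dimnames = list(NULL, "grp")))
  fit0 <- fit_cox(d0)
  expect_lt(abs(fit0$beta[["grp"]]), 0.2)

  # perfect concordance: all events, risk ordering exact
  dp <- survival_data(1:20, rep(1, 20),
                      matrix(20:1, dimnames = list(NULL, "z")))
  expect_equal(harrell_c(as.vector(20:1), 1:20, rep(1, 20)), 1)
  expect_equal(unname(suppressWarnings(fit_cox(dp))$cindex), 1,
               tolerance = 1e-9)
})

test_that("PRS scoring and dichotomization follow the frozen conventions", {
  model <- structure(list(selected = c("f1", "f2"), beta = c(f1 = 1, f2 = -1),
                          lambda = 0.1, threshold = 0,
                          center = c(f1 = 0, f2 = 0),
                          scale = c(f1 = 1, f2 = 1)),
                     class = "prs_model")
  X <- cbind(f1 = c(2, 0), f2 = c(0.5, 0))
  expect_equal(prs_score(model, X), c(1.5, 0))
  expect_error(prs_score(model, cbind(f1 = 1)), "missing feature")

  # zero-coefficient model scores zero
  m0 <- model; m0$beta[] <- 0
  expect_equal(prs_score(m0, X), c(0, 0))

  expect_equal(as.character(dichotomize(c(-1, 0, 1), 0)),
               c("low", "high", "high"))
  expect_true(all(dichotomize(c(-3, -2), 0) == "low"))
})

test_that("LASSO-Cox selects causal features and keeps thresholds on train", {
  p <- sim_params(n_patients = 150, beta_texture = 1.2, seed = 19)
  co <- simulate_cohort(p, mode = "features")
  X <- as.matrix(co$features[, patient_feature_names()])
  d <- survival_data(co$patients$rfs_days, co$patients$event, X)
  m <- suppressWarnings(lasso_cox_select(d, n_folds = 5, seed = 20))
  expect_gte(length(m$selected), 1)
  expect_true("har_contrast_sd" %in% m$selected)
  # threshold is the mean training PRS by definition
  prs <- prs_score(m, X)
  expect_equal(m$threshold, mean(prs), tolerance = 1e-12)
  # duplicating every patient leaves the standardized coefficient path
  # unchanged at matched lambda (CV fold noise may move lambda itself)
  d2 <- survival_data(rep(d$times, 2), rep(d$events, 2), X[rep(1:150, 2), ])
  grid <- m$path$lambda
  m1 <- suppressWarnings(lasso_cox_select(d, n_folds = 5, seed = 20,
                                          lambda = grid, thresh = 1e-12))
  m2 <- suppressWarnings(lasso_cox_select(d2, n_folds = 5, seed = 20,
                                          lambda = grid, thresh = 1e-12))
  # invariance is exact in exact arithmetic (population-SD standardization
  # and a 1/n-scaled partial likelihood); coordinate-descent convergence
  # limits the observed agreement to ~1e-5
  expect_equal(as.matrix(m1$path$beta), as.matrix(m2$path$beta),
               tolerance = 1e-4)
  # constant features are dropped with a warning
  Xc <- cbind(X[, 1:20], const = 1)
  expect_warning(
    lasso_cox_select(survival_data(d$times, d$events, Xc), 5, 20),
    "constant")
})

test_that("multivariable Cox keeps the PRS effect with null covariates", {
  p <- sim_params(n_patients = 250, beta_texture = 1.2, seed = 23)
  co <- simulate_cohort(p, mode = "features")
  pt <- co$patients
  X <- cbind(h = pt$h, age = pt$age, sex = pt$sex,
             comorbidity = pt$comorbidity_index)
  fit <- fit_cox(survival_data(pt$rfs_days, pt$event, X))
  expect_gt(fit$beta[["h"]], 0)
  expect_lt(fit$wald_p[["h"]], 0.01)
  # independent covariates: hazard ratios near 1
  expect_true(all(abs(log(fit$hr[c("age", "sex", "comorbidity")])) < 0.35))
})
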