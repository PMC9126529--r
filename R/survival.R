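#' Survival data container
#'
#' @param times positive follow-up times (days).
#' @param events binary event indicators (1 = relapse/death observed).
#' @param X numeric patients x features matrix.
#' @return list of class `survival_data`.
#' @export
survival_data <- function(times, events, X) {
  X <- as.matrix(X)
  stopifnot(length(times) == nrow(X), length(events) == nrow(X),
            all(times > 0), all(events %in% c(0, 1)))
  if (anyNA(X) || anyNA(times) || anyNA(events))
    stop("survival_data: missing values (exclude and log upstream)")
  structure(list(times = as.numeric(times), events = as.integer(events),
                 X = X), class = "survival_data")
}

#' LASSO-penalized Cox feature selection
#'
#' Standardizes each feature to zero mean / unit variance on the supplied
#' (training) data, fits the L1-penalized Cox partial likelihood over a
#' 100-point lambda path (glmnet), and picks lambda by `n_folds`-fold
#' cross-validated partial-likelihood deviance under the minimum rule.
#' When the minimum-rule solution is empty, steps to the largest lambda on
#' the path selecting at least one feature. Constant features are dropped
#' with a warning. The returned model carries the dichotomization
#' threshold — the mean training PRS — and the standardization transform;
#' nothing is ever recomputed on validation data.
#'
#' @param data a [survival_data()] with at least 10 events.
#' @param n_folds cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param ... passed to [glmnet::cv.glmnet()] (e.g. `lambda`, `thresh`).
#' @return list of class `prs_model`: `selected`, `beta` (per-SD log
#'   hazards), `lambda`, `threshold`, `center`, `scale`.
#' @export
lasso_cox_select <- function(data, n_folds = 10, seed = 1L, ...) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$events) < 1) stop("lasso_cox_select: no events")
  if (sum(data$events) < 10)
    warning("lasso_cox_select: fewer than 10 events; ",
            "selection will be unstable")
  X <- data$X
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  ctr <- colMeans(X)
  # population (1/n) standard deviation: the glmnet standardization
  # convention, and exactly invariant under sample duplication
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Xs <- scale(X, center = ctr, scale = scl)
  y <- survival::Surv(data$times, data$events)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(Xs)))
  cv <- glmnet::cv.glmnet(Xs, y, family = "cox", foldid = foldid,
                          nlambda = 100, standardize = FALSE, ...)
  beta_at <- function(lam) {
    b <- as.matrix(coef(cv$glmnet.fit, s = lam))[, 1]
    b[b != 0]
  }
  lambda <- cv$lambda.min
  beta <- beta_at(lambda)
  if (!length(beta)) {
    df <- cv$glmnet.fit$df
    ok <- which(df >= 1)
    if (!length(ok)) stop("lasso_cox_select: no feature ever selected")
    lambda <- cv$glmnet.fit$lambda[ok[1]]   # largest lambda with >= 1
    beta <- beta_at(lambda)
  }
  sel <- names(beta)
  prs_train <- as.vector(Xs[, sel, drop = FALSE] %*% beta)
  structure(list(selected = sel, beta = beta, lambda = lambda,
                 threshold = mean(prs_train),
                 center = ctr[sel], scale = scl[sel],
                 path = cv$glmnet.fit, cv = cv),
            class = "prs_model")
}

#' Pathological risk score
#'
#' PRS = sum over selected features of beta_j * standardized feature_j,
#' with the standardization frozen at training time.
#'
#' @param model a `prs_model`.
#' @param X_new matrix/data.frame containing the model's selected columns.
#' @return numeric vector of scores.
#' @export
prs_score <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  missing <- setdiff(model$selected, colnames(X_new))
  if (length(missing))
    stop("prs_score: missing feature column(s): ",
         paste(missing, collapse = ", "))
  Xs <- scale(X_new[, model$selected, drop = FALSE],
              center = model$center, scale = model$scale)
  as.vector(Xs %*% model$beta)
}

#' Dichotomize risk scores at a fixed threshold
#'
#' High-risk iff PRS >= threshold (ties go to high-risk). The threshold is
#' the training-set mean PRS and is never recomputed on validation data.
#'
#' @param prs numeric scores.
#' @param threshold finite scalar.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(prs, threshold) {
  stopifnot(is.finite(threshold))
  factor(ifelse(prs >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Efron-corrected partial likelihood (survival::coxph); reports hazard
#' ratios with Wald 95% CIs, per-coefficient Wald p-values and Harrell's C
#' of the linear predictor.
#'
#' @param data a [survival_data()]; every column of `X` enters the model.
#' @return list of class `cox_fit`: beta, se, hr, ci_lower, ci_upper,
#'   wald_p, cindex, n, n_events.
#' @export
fit_cox <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$events) < 1) stop("fit_cox: no events")
  df <- data.frame(data$X, check.names = FALSE)
  df$.time <- data$times; df$.event <- data$events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(data$X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-10))
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    warning("fit_cox: possible monotone likelihood (separation)")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 cindex = unname(summary(fit)$concordance["C"]),
                 n = fit$n, n_events = fit$nevent),
            class = "cox_fit")
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group and the two-sample log-rank
#' chi-square (sum over distinct event times of O - E in group 1, squared,
#' over the summed hypergeometric variance), with p from the chi-square
#' distribution on 1 df.
#'
#' @param times,events survival outcome.
#' @param groups factor with exactly two non-empty levels.
#' @return list of class `km_logrank`: `curves` (data.frame group, time,
#'   n_risk, n_event, surv), `chisq`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stop("km_logrank: exactly 2 non-empty groups required")
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  grp <- rep(sub("^groups=", "", names(sf$strata)),
             times = sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  if (sum(events) == 0) {
    warning("km_logrank: no events; p = 1")
    return(structure(list(curves = curves, chisq = 0, p = 1),
                     class = "km_logrank"))
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  structure(list(curves = curves, chisq = sd_$chisq,
                 p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)),
            class = "km_logrank")
}

#' Harrell's concordance index
#'
#' Over pairs (i, j) with times_i < times_j and events_i = 1, a pair is
#' concordant when the shorter-lived patient has the higher score; score
#' ties earn half credit.
#'
#' @param scores risk scores (higher = worse).
#' @param times,events survival outcome.
#' @return concordance in [0, 1].
#' @export
harrell_c <- function(scores, times, events) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  conc <- ties <- comp <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    comp <- comp + sum(later)
    conc <- conc + sum(scores[i] > scores[later])
    ties <- ties + sum(scores[i] == scores[later])
  }
  if (comp == 0) stop("harrell_c: no comparable pairs")
  (conc + 0.5 * ties) / comp
}
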