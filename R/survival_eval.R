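#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function; with `censoring = TRUE`
#' the event indicator is flipped so the returned curve estimates the
#' censoring distribution G (used as IPCW weights in the Brier score).
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @param censoring estimate the censoring distribution instead.
#' @return A function of class `km_fit` evaluating S(t) (right-continuous);
#'   `km_eval(km, t, left = TRUE)` gives the left limit S(t-).
#' @export
km_estimator <- function(times, events, censoring = FALSE) {
  if (length(times) == 0L) stop("empty input")
  if (censoring) events <- 1 - events
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  f <- function(t) km_eval_at(sf$time, sf$surv, t, left = FALSE)
  attr(f, "time") <- sf$time
  attr(f, "surv") <- sf$surv
  class(f) <- c("km_fit", "function")
  f
}

km_eval_at <- function(tt, ss, t, left = FALSE) {
  idx <- if (left) findInterval(t, tt, left.open = TRUE)
         else findInterval(t, tt)
  c(1, ss)[idx + 1L]
}

#' @rdname km_estimator
#' @param km a `km_fit`.
#' @param t evaluation times.
#' @param left evaluate the left limit S(t-).
#' @export
km_eval <- function(km, t, left = FALSE)
  km_eval_at(attr(km, "time"), attr(km, "surv"), t, left = left)

#' Extreme-quantile patient grouping
#'
#' Labels patients in the bottom `low_q` and top `high_q` quantiles of a
#' score as `"low"` and `"high"`; the middle is `"excluded"`. Quantiles use
#' the nearest-rank convention: with `k = ceiling(q * n)`, the low group is
#' all scores `<=` the k-th smallest and the high group all scores `>=` the
#' k-th largest, so boundary ties fall into the extreme group.
#'
#' @param scores numeric scores, length >= 7.
#' @param low_q,high_q tail fractions (default 0.15 each).
#' @return Character vector of labels `"low"`, `"high"`, `"excluded"`.
#' @export
quantile_groups <- function(scores, low_q = 0.15, high_q = 0.15) {
  n <- length(scores)
  if (n < 7L) stop("need at least 7 patients")
  if (max(scores) == min(scores)) stop("constant scores: groups undefined")
  s <- sort(scores)
  lo_cut <- s[ceiling(low_q * n)]
  hi_cut <- s[n - ceiling(high_q * n) + 1L]
  out <- rep("excluded", n)
  out[scores <= lo_cut] <- "low"
  out[scores >= hi_cut] <- "high"
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of survival between the `"low"` and
#' `"high"` groups of [quantile_groups()]; other labels are dropped.
#'
#' @param times,events survival data.
#' @param labels group labels; only `"low"`/`"high"` rows are used.
#' @return A list with `chisq` and `p`.
#' @export
logrank_test <- function(times, events, labels) {
  keep <- labels %in% c("low", "high")
  g <- factor(labels[keep], levels = c("low", "high"))
  if (any(table(g) == 0)) stop("both groups must be nonempty")
  sd <- survival::survdiff(survival::Surv(times[keep], events[keep]) ~ g)
  list(chisq = sd$chisq, p = 1 - stats::pchisq(sd$chisq, length(sd$n) - 1))
}

#' Survival model specifications
#'
#' Named covariate sets for the prediction-error comparison. `Reference` is
#' the intercept-only model (its predicted survival is the training-set
#' Kaplan-Meier curve); every other model additionally includes ordinal
#' tumor stage. `TMB` adds tumor mutation burden, `TMB_I` mutation burden
#' plus immunogenicity, `CYT_TMB` cytolytic activity plus mutation burden.
#'
#' @param name model label.
#' @param covariates character vector of `patient_profiles` column names
#'   (not counting stage).
#' @param include_stage include ordinal stage (forced off for Reference).
#' @return A list of class `survival_model_spec`.
#' @export
survival_model_spec <- function(name, covariates = character(0),
                                include_stage = !identical(name, "Reference")) {
  if (identical(name, "Reference") &&
      (length(covariates) || include_stage))
    stop("Reference is intercept-only")
  structure(list(name = name, covariates = covariates,
                 include_stage = include_stage),
            class = "survival_model_spec")
}

#' @rdname survival_model_spec
#' @export
standard_model_specs <- function() {
  list(Reference = survival_model_spec("Reference"),
       TMB = survival_model_spec("TMB", "tmb"),
       TMB_I = survival_model_spec("TMB_I", c("tmb", "immunogenicity")),
       CYT_TMB = survival_model_spec("CYT_TMB", c("cyt", "tmb")))
}

# Design matrix shared by the Cox fit and the synthetic generator: skewed
# positive covariates enter on the log scale, stage as ordinal codes, all
# columns z-scored (training centers/scales reused for new data).
covariate_transform <- function(profiles, covariates, include_stage) {
  cols <- list()
  tr <- list(tmb = function(x) log1p(x), cyt = function(x) log(x),
             immunogenicity = function(x) log1p(x),
             til_burden = function(x) log1p(x))
  for (cv in covariates) {
    f <- tr[[cv]]
    cols[[cv]] <- if (is.null(f)) as.numeric(profiles[[cv]]) else f(profiles[[cv]])
  }
  if (include_stage) cols$stage <- as.numeric(as.integer(factor(profiles$stage)))
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

build_design <- function(profiles, covariates, include_stage,
                         center = NULL, scale = NULL) {
  x <- covariate_transform(profiles, covariates, include_stage)
  if (is.null(x)) return(NULL)
  if (is.null(center)) {
    center <- colMeans(x)
    # population sd keeps the design invariant under patient replication
    scale <- sqrt(colMeans(sweep(x, 2, center, "-")^2))
    scale[scale == 0] <- 1
  }
  x <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(x, "center") <- center
  attr(x, "scale") <- scale
  x
}

#' Fit a Cox proportional-hazards model from a specification
#'
#' Fits the partial-likelihood Cox model for one [survival_model_spec()] on
#' a patient table, with covariates standardized on a log scale where
#' appropriate (see the package vignette). The Reference specification is
#' the intercept-only model whose predicted survival is the training
#' Kaplan-Meier curve. A proportional-hazards check (correlation of scaled
#' Schoenfeld residuals with time, plus the score-test p-value) is attached.
#'
#' @param profiles a [patient_profiles()] table.
#' @param spec a [survival_model_spec()].
#' @return An object of class `cox_fit` exposing `coef`, `ph_check`, and
#'   predicted survival via [predict_surv()].
#' @export
fit_cox <- function(profiles, spec) {
  y <- survival::Surv(profiles$time, profiles$event)
  x <- build_design(profiles, spec$covariates, spec$include_stage)
  if (is.null(x)) {
    sf <- survival::survfit(y ~ 1)
    obj <- list(spec = spec, fit = NULL, center = NULL, scale = NULL,
                km_time = sf$time, km_surv = sf$surv, ph_check = NULL)
    class(obj) <- "cox_fit"
    return(obj)
  }
  if (sum(profiles$event) < ncol(x))
    stop("fewer events than covariates")
  df <- as.data.frame(x)
  df$.time <- profiles$time
  df$.event <- profiles$event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(x), collapse = " + ")))
  # Breslow ties keep the partial likelihood exactly invariant under
  # patient duplication (replication-weight consistency)
  fit <- survival::coxph(fml, data = df, ties = "breslow", model = TRUE)
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 20)) {
    bad <- colnames(x)[which(!is.finite(coef(fit)) | abs(coef(fit)) > 20)[1]]
    stop("non-convergence: unbounded estimate for covariate '", bad, "'")
  }
  ph <- tryCatch({
    zp <- survival::cox.zph(fit)
    data.frame(covariate = colnames(x),
               cor_time = apply(as.matrix(zp$y), 2,
                                function(r) suppressWarnings(cor(zp$x, r))),
               p = zp$table[seq_len(ncol(x)), "p"], row.names = NULL)
  }, error = function(e) NULL)
  obj <- list(spec = spec, fit = fit, center = attr(x, "center"),
              scale = attr(x, "scale"), profiles = profiles, ph_check = ph)
  class(obj) <- "cox_fit"
  obj
}

#' @export
coef.cox_fit <- function(object, ...) {
  if (is.null(object$fit)) return(numeric(0))
  coef(object$fit)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model:", x$spec$name, "\n")
  if (is.null(x$fit)) cat("  intercept-only (Kaplan-Meier reference)\n")
  else print(coef(x))
  invisible(x)
}

#' Predicted survival probabilities
#'
#' Evaluates the fitted model's survival function S(t | x) for each row of
#' `newdata` at the requested times, via the Breslow-type baseline from
#' [survival::survfit.coxph()].
#'
#' @param object a [fit_cox()] result.
#' @param newdata a `patient_profiles` table.
#' @param times evaluation times (days).
#' @return Matrix with `nrow(newdata)` rows and `length(times)` columns.
#' @export
predict_surv <- function(object, newdata, times) {
  n <- nrow(newdata)
  if (is.null(object$fit)) {
    s <- km_eval_at(object$km_time, object$km_surv, times)
    return(matrix(rep(s, each = n), nrow = n))
  }
  x <- build_design(newdata, object$spec$covariates, object$spec$include_stage,
                    center = object$center, scale = object$scale)
  sf <- survival::survfit(object$fit, newdata = as.data.frame(x),
                          se.fit = FALSE)
  # step-evaluate each curve at the requested times
  surv <- as.matrix(sf$surv)
  out <- matrix(NA_real_, n, length(times))
  idx <- findInterval(times, sf$time)
  for (j in seq_along(times))
    out[, j] <- if (idx[j] == 0L) 1 else surv[idx[j], ]
  out
}

#' IPCW Brier prediction-error curve
#'
#' Time-dependent Brier score: the weighted average squared distance between
#' each patient's observed survival status at t and the model's predicted
#' survival probability, reweighted for right censoring by the inverse of
#' the Kaplan-Meier censoring estimate G:
#' `BS(t) = n^-1 sum_i [ S(t|x_i)^2 1(t_i <= t, d_i = 1) / G(t_i-) +
#' (1 - S(t|x_i))^2 1(t_i > t) / G(t) ]`.
#' With no censoring G is identically 1 and the curve reduces to the plain
#' mean squared error. Grid times where G = 0 are dropped with a warning.
#'
#' @param object a `cox_fit`, a prediction matrix (`nrow(profiles)` x
#'   `length(times)`), or a function `(newdata, times)` returning one.
#' @param profiles evaluation [patient_profiles()].
#' @param times evaluation grid; default all distinct event times.
#' @param cens_km optional pre-fit censoring `km_fit` (defaults to the
#'   Kaplan-Meier censoring estimate on `profiles`).
#' @return A data frame of class `prediction_error_curve` with columns
#'   `time`, `brier`; observed exit times are kept in
#'   `attr(, "observed_times")` for horizon selection.
#' @export
brier_curve <- function(object, profiles, times = NULL, cens_km = NULL) {
  if (is.null(times))
    times <- sort(unique(profiles$time[profiles$event == 1]))
  if (is.null(cens_km))
    cens_km <- km_estimator(profiles$time, profiles$event, censoring = TRUE)
  g_t <- km_eval(cens_km, times)
  ok <- g_t > 0
  if (!all(ok)) {
    warning("censoring survival G(t) = 0 at late grid times; grid truncated")
    times <- times[ok]; g_t <- g_t[ok]
  }
  pred <- if (is.matrix(object)) object
          else if (is.function(object)) object(profiles, times)
          else predict_surv(object, profiles, times)
  stopifnot(nrow(pred) == nrow(profiles), ncol(pred) == length(times))
  ti <- profiles$time; di <- profiles$event
  g_ti <- km_eval(cens_km, ti, left = TRUE)
  bs <- vapply(seq_along(times), function(j) {
    t <- times[j]; s <- pred[, j]
    w1 <- as.numeric(ti <= t & di == 1) / ifelse(g_ti > 0, g_ti, Inf)
    w0 <- as.numeric(ti > t) / g_t[j]
    mean(s^2 * w1 + (1 - s)^2 * w0)
  }, numeric(1))
  structure(data.frame(time = times, brier = bs),
            observed_times = profiles$time,
            model = if (inherits(object, "cox_fit")) object$spec$name else "model",
            class = c("prediction_error_curve", "data.frame"))
}

#' Integrated Brier score
#'
#' Time-normalized integral of a prediction-error curve over `[0, tmax]`
#' (trapezoidal rule, constant extension beyond the grid ends). By default
#' `tmax` is the time by which `horizon_fraction` (80%) of the patients
#' have exited the risk set.
#'
#' @param curve a [brier_curve()] result.
#' @param tmax integration horizon; overrides `horizon_fraction`.
#' @param horizon_fraction fraction of patients exited by the horizon.
#' @return The IBS (scalar).
#' @export
integrated_brier <- function(curve, tmax = NULL, horizon_fraction = 0.8) {
  if (nrow(curve) < 2L) stop("need >= 2 grid points")
  if (is.null(tmax)) {
    obs <- attr(curve, "observed_times")
    if (is.null(obs)) stop("no observed times stored; supply tmax")
    tmax <- as.numeric(quantile(obs, horizon_fraction, type = 1))
  }
  f <- stats::approxfun(curve$time, curve$brier, rule = 2)
  knots <- sort(unique(c(0, curve$time[curve$time < tmax], tmax)))
  v <- f(knots)
  sum(diff(knots) * (head(v, -1) + v[-1]) / 2) / tmax
}

# 0.632+ combination at each grid time: relative overfitting rate
# R = (min(oob, gamma) - app) / (gamma - app) clipped to [0, 1], weight
# w = .632 / (1 - .368 R); R = 0 (no overfitting) gives w = 0.632 exactly.
combine_632plus <- function(app, oob, gamma) {
  b1 <- pmin(oob, gamma)
  denom <- gamma - app
  r <- ifelse(denom > 0 & b1 > app, (b1 - app) / denom, 0)
  r <- pmin(pmax(r, 0), 1)
  w <- 0.632 / (1 - 0.368 * r)
  list(err = (1 - w) * app + w * b1, w = w, r = r)
}

noinf_error <- function(pred, profiles, times, cens_km) {
  ti <- profiles$time; di <- profiles$event
  g_ti <- km_eval(cens_km, ti, left = TRUE)
  g_t <- km_eval(cens_km, times)
  vapply(seq_along(times), function(j) {
    t <- times[j]; s <- pred[, j]
    m1 <- mean(as.numeric(ti <= t & di == 1) / ifelse(g_ti > 0, g_ti, Inf))
    m0 <- mean(as.numeric(ti > t)) / g_t[j]
    mean(s^2) * m1 + mean((1 - s)^2) * m0
  }, numeric(1))
}

#' 0.632+ bootstrap prediction-error estimation and model comparison
#'
#' For each model specification, combines the apparent error (fit and
#' evaluated on the full cohort) with the average out-of-bag bootstrap error
#' using the 0.632+ rule: at each grid time,
#' `w = 0.632 / (1 - 0.368 * R)` where the relative overfitting rate
#' `R = (err_oob - err_app) / (gamma - err_app)` (clipped to \[0, 1\], with
#' `gamma` the no-information error) and
#' `err632plus = (1 - w) * err_app + w * min(err_oob, gamma)`.
#' Bootstrap samples with too few events or an empty out-of-bag set are
#' redrawn. Error curves are compared pairwise by one-sided Wilcoxon tests:
#' by default the paired signed-rank test over the per-timepoint 0.632+
#' curve values; `comparison = "ibs"` instead pairs per-bootstrap
#' out-of-bag IBS values across replicates.
#'
#' @param specs list of [survival_model_spec()]s.
#' @param profiles a [patient_profiles()] table.
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @param times evaluation grid; default all distinct event times up to the
#'   80% exit horizon.
#' @param horizon_fraction IBS horizon (fraction of patients exited).
#' @param comparison `"pointwise"` (default) or `"ibs"`.
#' @return A list of class `prediction_error_curves`: `curves` (long data
#'   frame: model, time, apparent, oob, brier = 0.632+ estimate), `ibs`
#'   (named vector), `pairwise_p` (matrix; `p[i, j]` is the one-sided p for
#'   "model i has lower error than model j"), `tmax`, `B`.
#' @export
bootstrap_632plus <- function(specs, profiles, B = 100, seed = NULL,
                              times = NULL, horizon_fraction = 0.8,
                              comparison = c("pointwise", "ibs")) {
  comparison <- match.arg(comparison)
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  n <- nrow(profiles)
  tmax <- as.numeric(quantile(profiles$time, horizon_fraction, type = 1))
  if (is.null(times)) {
    times <- sort(unique(profiles$time[profiles$event == 1]))
    times <- times[times <= tmax]
  }
  cens_full <- km_estimator(profiles$time, profiles$event, censoring = TRUE)
  nmod <- length(specs)

  app <- matrix(NA_real_, nmod, length(times), dimnames = list(names(specs)))
  gam <- app
  full_fits <- lapply(specs, fit_cox, profiles = profiles)
  for (k in seq_len(nmod)) {
    pred <- predict_surv(full_fits[[k]], profiles, times)
    app[k, ] <- brier_curve(pred, profiles, times, cens_full)$brier
    gam[k, ] <- noinf_error(pred, profiles, times, cens_full)
  }

  oob_sum <- matrix(0, nmod, length(times))
  oob_cnt <- matrix(0, nmod, length(times))
  oob_ibs <- matrix(NA_real_, B, nmod, dimnames = list(NULL, names(specs)))
  min_events <- max(4L, max(vapply(specs, function(s)
    length(s$covariates) + s$include_stage, integer(1))) + 1L)
  b <- 0L
  while (b < B) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    train <- profiles[idx, , drop = FALSE]
    test <- profiles[oob, , drop = FALSE]
    if (length(oob) < 5L || sum(train$event) < min_events ||
        sum(test$event) < 2L) {
      message("degenerate bootstrap sample; redrawing")
      next
    }
    fits <- tryCatch(lapply(specs, fit_cox, profiles = train),
                     error = function(e) NULL)
    if (is.null(fits)) { message("bootstrap fit failed; redrawing"); next }
    b <- b + 1L
    cens_oob <- km_estimator(test$time, test$event, censoring = TRUE)
    keep <- km_eval(cens_oob, times) > 0
    for (k in seq_len(nmod)) {
      pred <- predict_surv(fits[[k]], test, times[keep])
      cv <- brier_curve(pred, test, times[keep], cens_oob)
      oob_sum[k, keep] <- oob_sum[k, keep] + cv$brier
      oob_cnt[k, keep] <- oob_cnt[k, keep] + 1
      if (sum(keep) >= 2)
        oob_ibs[b, k] <- integrated_brier(cv, tmax = min(tmax, max(times[keep])))
    }
  }
  oob <- oob_sum / pmax(oob_cnt, 1)

  err632 <- app
  for (k in seq_len(nmod))
    err632[k, ] <- combine_632plus(app[k, ], oob[k, ], gam[k, ])$err

  curves <- do.call(rbind, lapply(seq_len(nmod), function(k) {
    data.frame(model = names(specs)[k], time = times, apparent = app[k, ],
               oob = oob[k, ], brier = err632[k, ])
  }))
  ibs <- vapply(seq_len(nmod), function(k) {
    cv <- structure(data.frame(time = times, brier = err632[k, ]),
                    observed_times = profiles$time,
                    class = c("prediction_error_curve", "data.frame"))
    integrated_brier(cv, tmax = tmax)
  }, numeric(1))
  names(ibs) <- names(specs)

  pw <- matrix(NA_real_, nmod, nmod, dimnames = list(names(specs), names(specs)))
  for (i in seq_len(nmod)) for (j in seq_len(nmod)) {
    if (i == j) next
    pw[i, j] <- if (comparison == "pointwise") {
      if (isTRUE(all.equal(err632[i, ], err632[j, ]))) 1
      else suppressWarnings(wilcox.test(err632[i, ], err632[j, ], paired = TRUE,
                                        alternative = "less")$p.value)
    } else {
      if (isTRUE(all.equal(oob_ibs[, i], oob_ibs[, j]))) 1
      else suppressWarnings(wilcox.test(oob_ibs[, i], oob_ibs[, j],
                                        paired = TRUE,
                                        alternative = "less")$p.value)
    }
  }

  structure(list(curves = curves, ibs = ibs, pairwise_p = pw,
                 oob_ibs = oob_ibs, tmax = tmax, B = B,
                 comparison = comparison),
            class = "prediction_error_curves")
}

#' @export
print.prediction_error_curves <- function(x, ...) {
  cat("0.632+ bootstrap prediction error (B =", x$B, ", horizon", x$tmax, ")\n")
  cat("Integrated Brier scores:\n")
  print(round(x$ibs, 4))
  cat("One-sided Wilcoxon p (row model error < column model error):\n")
  print(round(x$pairwise_p, 4))
  invisible(x)
}

#' @export
plot.prediction_error_curves <- function(x, ...) {
  models <- unique(x$curves$model)
  cols <- seq_along(models)
  plot(NA, xlim = range(x$curves$time), ylim = range(x$curves$brier),
       xlab = "time (days)", ylab = "Brier score (0.632+)", ...)
  for (k in seq_along(models)) {
    sub <- x$curves[x$curves$model == models[k], ]
    lines(sub$time, sub$brier, col = cols[k], lwd = 2)
  }
  graphics::legend("topleft", legend = models, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Cross-validated one-sided KS comparison of two models
#'
#' Repeatedly splits the cohort at random, fits both model specifications
#' on the training part, and records each model's integrated Brier score on
#' the held-out part; the two IBS samples are then compared by a one-sided
#' KS test with the alternative that the first specification's errors are
#' stochastically smaller.
#'
#' @param spec_a,spec_b [survival_model_spec()]s; the alternative is
#'   "`spec_a` has lower error".
#' @param profiles a [patient_profiles()] table.
#' @param iterations number of random splits (>= 10).
#' @param seed integer seed.
#' @param train_fraction fraction of patients in the training split.
#' @return A list with `statistic`, `p.value`, and the per-iteration IBS
#'   vectors `ibs_a`, `ibs_b`.
#' @export
crossval_ks <- function(spec_a, spec_b, profiles, iterations = 100,
                        seed = NULL, train_fraction = 0.5) {
  if (iterations < 10) stop("iterations must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  ibs_a <- ibs_b <- numeric(0)
  it <- 0L
  while (it < iterations) {
    tr <- sample.int(n, round(train_fraction * n))
    train <- profiles[tr, , drop = FALSE]
    test <- profiles[-tr, , drop = FALSE]
    if (sum(train$event) < 5L || sum(test$event) < 5L) next
    fits <- tryCatch(list(fit_cox(train, spec_a), fit_cox(train, spec_b)),
                     error = function(e) NULL)
    if (is.null(fits)) next
    it <- it + 1L
    ib <- vapply(fits, function(f) {
      cv <- brier_curve(f, test)
      integrated_brier(cv)
    }, numeric(1))
    ibs_a <- c(ibs_a, ib[1]); ibs_b <- c(ibs_b, ib[2])
  }
  if (isTRUE(all.equal(ibs_a, ibs_b)))
    return(list(statistic = 0, p.value = 1, ibs_a = ibs_a, ibs_b = ibs_b))
  ks <- ks_one_sided(ibs_a, ibs_b)
  list(statistic = ks$statistic, p.value = ks$p.value,
       ibs_a = ibs_a, ibs_b = ibs_b)
}
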