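test_that("Kaplan-Meier estimator matches empirical survival closed forms", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km(1.5), 2 / 3)
  expect_equal(km(0), 1)
  expect_equal(km(3), 0)
  # all censored: survival never drops
  kmc <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_equal(kmc(10), 1)
  # single event among five
  km5 <- km_estimator(c(5, 6, 7, 8, 9), c(1, 0, 0, 0, 0))
  expect_equal(km5(5), 0.8)
  # left limits sit strictly above the step at an event time
  expect_equal(km_eval(km, 2, left = TRUE), 2 / 3)
  expect_equal(km_eval(km, 2), 1 / 3)
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")
})

test_that("quantile grouping uses inclusive nearest-rank percentiles", {
  g <- quantile_groups(1:100)
  expect_equal(which(g == "low"), 1:15)
  expect_equal(which(g == "high"), 86:100)
  # minimum size keeps both extremes nonempty
  g7 <- quantile_groups(c(3, 9, 1, 7, 5, 8, 2))
  expect_gte(sum(g7 == "low"), 1)
  expect_gte(sum(g7 == "high"), 1)
  # permutation equivariance
  set.seed(71)
  x <- rnorm(50)
  p <- sample(50)
  expect_identical(quantile_groups(x)[p], quantile_groups(x[p]))
  # boundary ties all land in the extreme group
  g_tie <- quantile_groups(c(rep(1, 20), 2:81))
  expect_equal(sum(g_tie == "low"), 20)
  expect_error(quantile_groups(rep(1, 10)), "constant")
  expect_error(quantile_groups(1:5), "at least 7")
})

test_that("log-rank test behaves at the null and under label swap", {
  set.seed(72)
  t0 <- rexp(80, 0.01)
  # two copies of the same data: no separation
  res <- logrank_test(c(t0, t0), rep(1, 160),
                      rep(c("low", "high"), each = 80))
  expect_gt(res$p, 0.99)
  # label swap leaves the statistic unchanged
  t1 <- rexp(80, 0.03)
  lab <- rep(c("low", "high"), each = 80)
  a <- logrank_test(c(t0, t1), rep(1, 160), lab)
  b <- logrank_test(c(t0, t1), rep(1, 160), rev(lab))
  expect_equal(a$chisq, b$chisq)
  expect_error(logrank_test(t0, rep(1, 80), rep("low", 80)), "nonempty")
})

test_that("log-rank detects a hazard ratio of three with high power", {
  set.seed(73)
  pvals <- vapply(1:15, function(i) {
    times <- c(rexp(200, 0.01), rexp(200, 0.03))
    cens <- runif(400, 0, 250)
    logrank_test(pmin(times, cens), as.numeric(times <= cens),
                 rep(c("low", "high"), each = 200))$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.95)
})

test_that("Cox fits recover planted effects and stay calibrated at the null", {
  betas <- ses <- numeric(6)
  for (i in 1:6) {
    co <- generate_cohort(cohort_config(n_patients = 500, seed = 700 + i))
    f <- fit_cox(co$patients, survival_model_spec("CYT_TMB", c("cyt", "tmb")))
    betas[i] <- coef(f)["cyt"]
  }
  expect_lt(abs(mean(betas) - (-0.8)), 0.15)

  # pure-noise covariate: |beta| < 2 SE in at least 90% of replicates
  ok <- vapply(1:10, function(i) {
    co <- generate_cohort(cohort_config(
      n_patients = 500, seed = 800 + i,
      hazard = list(baseline = 1 / 1095, beta_cyt = -0.8, beta_tmb = -0.3,
                    beta_imm = 0, beta_stage = 0.3)))
    f <- fit_cox(co$patients,
                 survival_model_spec("TMB_I", c("tmb", "immunogenicity")))
    s <- sqrt(diag(f$fit$var))[which(names(coef(f)) == "immunogenicity")]
    abs(coef(f)["immunogenicity"]) < 2 * s
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("Cox estimates are invariant to duplicating every patient", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 75))
  spec <- survival_model_spec("CYT_TMB", c("cyt", "tmb"))
  f1 <- fit_cox(co$patients, spec)
  dup <- patient_profiles(rbind(as.data.frame(co$patients),
                                as.data.frame(co$patients)))
  f2 <- fit_cox(dup, spec)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
  # the PH check reports a time-correlation per covariate
  expect_equal(f1$ph_check$covariate, c("cyt", "tmb", "stage"))
  expect_true(all(abs(f1$ph_check$cor_time) <= 1))
})

test_that("the Brier curve equals plain MSE without censoring", {
  set.seed(76)
  n <- 60
  prof <- patient_profiles(data.frame(
    patient_id = sprintf("s%02d", 1:n), time = rexp(n, 0.01),
    event = 1, stage = sample(1:3, n, TRUE), tmb = rpois(n, 50),
    cyt = rlnorm(n, 2, 1), til_burden = 1, til_clonality = 0.5,
    immunogenicity = rlnorm(n, 0, 1)))
  times <- sort(unique(prof$time))[seq(5, 50, by = 5)]
  # constant prediction p reduces the curve to a binomial MSE
  p <- 0.7
  pred <- matrix(p, n, length(times))
  bc <- brier_curve(pred, prof, times)
  manual <- vapply(times, function(t) mean(((prof$time > t) - p)^2), numeric(1))
  expect_equal(bc$brier, manual)
  # a perfect oracle prediction gives zero error everywhere
  oracle <- outer(prof$time, times, function(ti, t) as.numeric(ti > t))
  expect_equal(brier_curve(oracle, prof, times)$brier, rep(0, length(times)))
  # model-based curve equals the unweighted MSE of its own predictions
  fit <- fit_cox(prof, survival_model_spec("CYT_TMB", c("cyt", "tmb")))
  pr <- predict_surv(fit, prof, times)
  bc2 <- brier_curve(fit, prof, times)
  manual2 <- vapply(seq_along(times), function(j) {
    s <- pr[, j]; t <- times[j]
    mean(ifelse(prof$time > t, (1 - s)^2, s^2))
  }, numeric(1))
  expect_equal(bc2$brier, manual2)
})

test_that("IPCW corrects censoring-induced bias toward the latent truth", {
  set.seed(77)
  n <- 4000
  latent <- rexp(n, 0.01)
  cens <- runif(n, 0, 250)
  obs_time <- pmin(latent, cens)
  event <- as.numeric(latent <= cens)
  prof <- patient_profiles(data.frame(
    patient_id = sprintf("s%04d", 1:n), time = obs_time, event = event,
    stage = 1, tmb = 1, cyt = 1, til_burden = 1, til_clonality = 0.5,
    immunogenicity = 1))
  times <- c(25, 50, 100, 150)
  p <- 0.6
  pred <- matrix(p, n, length(times))
  ipcw <- brier_curve(pred, prof, times)$brier
  truth <- vapply(times, function(t) mean(((latent > t) - p)^2), numeric(1))
  expect_equal(ipcw, truth, tolerance = 0.03)
})

test_that("integrated Brier score is a normalized trapezoid", {
  mk <- function(time, brier, obs) structure(
    data.frame(time = time, brier = brier), observed_times = obs,
    class = c("prediction_error_curve", "data.frame"))
  obs <- 0:100
  # constant curves integrate to the constant
  expect_equal(integrated_brier(mk(c(0, 40, 80), rep(0.2, 3), obs)), 0.2)
  # linear 0 -> c over the horizon integrates to c/2
  expect_equal(integrated_brier(mk(c(0, 40, 80), c(0, 0.15, 0.3), obs)), 0.15)
  # explicit horizon overrides the 80% rule
  expect_equal(integrated_brier(mk(c(0, 50, 100), c(0, 0.1, 0.2), obs),
                                tmax = 50), 0.05)
  expect_error(integrated_brier(mk(0, 0.1, obs)), "grid")
})

test_that("the 0.632+ combiner has the textbook limits", {
  # no overfitting: weight exactly 0.632
  cmb <- neofit:::combine_632plus(app = 0.1, oob = 0.1, gamma = 0.3)
  expect_equal(cmb$w, 0.632)
  expect_equal(cmb$err, 0.1)
  # complete overfitting (oob at the no-information level): R = 1, w = 1
  cmb2 <- neofit:::combine_632plus(app = 0.1, oob = 0.5, gamma = 0.3)
  expect_equal(cmb2$r, 1)
  expect_equal(cmb2$err, 0.3)
  # oob below apparent never increases the estimate beyond oob
  cmb3 <- neofit:::combine_632plus(app = 0.2, oob = 0.15, gamma = 0.3)
  expect_equal(cmb3$w, 0.632)
  expect_lt(cmb3$err, 0.2)
})

test_that("bootstrap error estimation is reproducible and self-consistent", {
  co <- generate_cohort(cohort_config(n_patients = 120, seed = 78))
  specs <- standard_model_specs()[c("Reference", "CYT_TMB")]
  r1 <- bootstrap_632plus(specs, co$patients, B = 10, seed = 79)
  r2 <- bootstrap_632plus(specs, co$patients, B = 10, seed = 79)
  expect_identical(r1$curves, r2$curves)
  expect_identical(r1$ibs, r2$ibs)
  # identical model specifications cannot separate
  twin <- list(A = survival_model_spec("A", "tmb"),
               B = survival_model_spec("B", "tmb"))
  rt <- bootstrap_632plus(twin, co$patients, B = 10, seed = 80)
  expect_gt(rt$pairwise_p["A", "B"], 0.95)
  # per-bootstrap IBS comparison mode is also available
  ri <- bootstrap_632plus(specs, co$patients, B = 10, seed = 81,
                          comparison = "ibs")
  expect_true(is.finite(ri$pairwise_p["CYT_TMB", "Reference"]))
})

test_that("cross-validated KS separates planted signal from noise", {
  co <- generate_cohort(cohort_config(n_patients = 250, seed = 82))
  sig <- survival_model_spec("CYT_TMB", c("cyt", "tmb"))
  noise <- survival_model_spec("I_only", "immunogenicity")
  res <- crossval_ks(sig, noise, co$patients, iterations = 30, seed = 83)
  expect_lt(res$p.value, 0.05)
  # identical specifications: no separation
  res2 <- crossval_ks(sig, sig, co$patients, iterations = 10, seed = 84)
  expect_equal(res2$p.value, 1)
  # seed determinism
  res3 <- crossval_ks(sig, noise, co$patients, iterations = 10, seed = 85)
  res4 <- crossval_ks(sig, noise, co$patients, iterations = 10, seed = 85)
  expect_identical(res3$ibs_a, res4$ibs_a)
})
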