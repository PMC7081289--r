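#' Empirical CDF curve of binding affinities
#'
#' Sorted values with cumulative fractions, for plotting the
#' neoepitope-versus-viral affinity comparison.
#'
#' @param values numeric vector (ic50, nM).
#' @return A data frame of class `ecdf_curve` with columns `value` and
#'   `fraction` (nondecreasing, ending at 1).
#' @export
ecdf_curve <- function(values) {
  v <- sort(values)
  structure(data.frame(value = v, fraction = seq_along(v) / length(v)),
            class = c("ecdf_curve", "data.frame"))
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the first sample's distribution "falls above" the second's:
#' the statistic is `D+ = sup_x [F_1(x) - F_2(x)]` over the pooled values.
#' On ic50 scales, smaller values mean stronger binding, so the first
#' ECDF lying above the second means the first population binds more
#' strongly. The asymptotic one-sided p-value `exp(-2 m n D+^2 / (m + n))`
#' (capped at 1) is used by default; for small samples an exact permutation
#' p-value can be requested instead.
#'
#' @param x,y nonempty numeric samples; the alternative is that `x`'s
#'   distribution lies above `y`'s (x stochastically smaller).
#' @param exact `"asymptotic"` (default), or `"permutation"` for a
#'   resampling p-value (recommended below ~50 observations).
#' @param nperm permutation count when `exact = "permutation"`.
#' @return A list of class `ks_one_sided` with `statistic` (D+) and
#'   `p.value`.
#' @export
ks_one_sided <- function(x, y, exact = c("asymptotic", "permutation"),
                         nperm = 2000) {
  exact <- match.arg(exact)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  d <- ks_dplus(x, y)
  m <- length(x); n <- length(y)
  p <- if (exact == "asymptotic") {
    min(1, exp(-2 * m * n * d^2 / (m + n)))
  } else {
    pool <- c(x, y)
    reps <- vapply(seq_len(nperm), function(i) {
      idx <- sample.int(m + n, m)
      ks_dplus(pool[idx], pool[-idx])
    }, numeric(1))
    (1 + sum(reps >= d)) / (nperm + 1)
  }
  structure(list(statistic = d, p.value = p, alternative = "first above second",
                 method = exact), class = "ks_one_sided")
}

ks_dplus <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- ecdf(x)(grid)
  fy <- ecdf(y)(grid)
  max(0, max(fx - fy))
}

#' @export
print.ks_one_sided <- function(x, ...) {
  cat(sprintf("One-sided two-sample KS: D+ = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p.value, x$method))
  invisible(x)
}

#' Subsampled KS robustness analysis
#'
#' Guards the affinity comparison against unequal population sizes:
#' subsamples `m` epitopes from each population and applies the one-sided
#' KS test, repeated `reps` times; reports the fraction of replicates
#' rejecting at `alpha`. Populations smaller than `m` are sampled with
#' replacement (with a warning).
#'
#' @param neo,viral affinity populations (ic50, nM).
#' @param m subsample size per population (the full-scale analysis uses
#'   10,000).
#' @param reps number of replicates (the full-scale analysis uses 1,000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param alpha rejection level.
#' @return A list of class `subsampled_ks`: `rejection_fraction`,
#'   `statistics`, `pvalues`, and the parameters used.
#' @export
subsampled_ks <- function(neo, viral, m = 10000, reps = 1000, seed = NULL,
                          alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  replace_neo <- length(neo) < m
  replace_vir <- length(viral) < m
  if (replace_neo || replace_vir)
    warning("population smaller than m; subsampling with replacement")
  d <- p <- numeric(reps)
  for (r in seq_len(reps)) {
    ks <- ks_one_sided(sample(neo, m, replace = replace_neo),
                       sample(viral, m, replace = replace_vir))
    d[r] <- ks$statistic; p[r] <- ks$p.value
  }
  structure(list(rejection_fraction = mean(p < alpha), statistics = d,
                 pvalues = p, m = m, reps = reps, alpha = alpha),
            class = "subsampled_ks")
}

#' @export
print.subsampled_ks <- function(x, ...) {
  cat(sprintf(
    "Subsampled one-sided KS: %d reps of m = %d; rejection fraction %.3f at alpha = %g\n",
    x$reps, x$m, x$rejection_fraction, x$alpha))
  invisible(x)
}

#' Strong-binder burden versus TIL burden correlation
#'
#' Counts each patient's strong-binding epitopes (ic50 strictly below
#' `strong_binder_max`, default 200 nM) separately for neoepitopes and viral
#' epitopes, and correlates each burden with TIL burden by Spearman rank
#' correlation.
#'
#' @param patients a [patient_profiles()] table with `til_burden`.
#' @param records cohort [epitope_records()] (both sources pooled).
#' @param strong_binder_max strict ic50 cutoff defining a strong binder.
#' @return A data frame with one row per source (`neoepitope`, `viral`):
#'   `rho`, `p`, and `n` patients used.
#' @export
burden_til_correlation <- function(patients, records, strong_binder_max = 200) {
  if (nrow(patients) < 3L) stop("need >= 3 patients")
  strong <- records[records$ic50_mt < strong_binder_max, , drop = FALSE]
  out <- lapply(c("neoepitope", "viral"), function(src) {
    sub <- strong[strong$source == src, , drop = FALSE]
    burden <- vapply(patients$patient_id,
                     function(p) sum(sub$patient_id == p), numeric(1))
    ct <- suppressWarnings(cor.test(burden, patients$til_burden,
                                    method = "spearman", exact = FALSE))
    data.frame(source = src, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(patients))
  })
  do.call(rbind, out)
}
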