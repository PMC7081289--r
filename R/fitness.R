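#' Fitness model parameters
#'
#' Constants of the neoantigen fitness model. `alpha` is the horizontal
#' displacement of the logistic binding curve mapping alignment scores to
#' TCR recognition probability and `k` its steepness; the defaults are the
#' melanoma values fitted by the original fitness model (alpha = 26,
#' k = 4.87), since the model is normally applied with those constants
#' carried over. `affinity_threshold` (nM) is the strict ic50 cutoff a
#' neoepitope must pass to enter the immunogenicity maximum (default 500).
#' `amplitude_normalization` selects the dissociation-constant bias
#' correction of the amplitude (see [amplitude()]).
#'
#' @param alpha binding-curve displacement, in raw alignment-score units.
#' @param k binding-curve steepness (> 0).
#' @param affinity_threshold strict ic50 admission cutoff, nM.
#' @param amplitude_normalization `"reciprocal_max_wt"` (default) or
#'   `"none"`.
#' @return A list of class `fitness_params`.
#' @export
fitness_params <- function(alpha = 26, k = 4.87, affinity_threshold = 500,
                           amplitude_normalization = c("reciprocal_max_wt",
                                                       "none")) {
  if (k <= 0) stop("k must be > 0")
  if (affinity_threshold <= 0) stop("affinity_threshold must be > 0")
  structure(list(alpha = alpha, k = k,
                 affinity_threshold = affinity_threshold,
                 amplitude_normalization = match.arg(amplitude_normalization)),
            class = "fitness_params")
}

#' TCR recognition potential
#'
#' The probability that a neoepitope is recognized via similarity to known
#' reactive (viral) epitopes, modeled as a saturating logistic over the
#' local alignment scores |s,e| of the neoepitope against the database:
#' `R = Z / (1 + Z)` with `Z = sum_e exp(-k * (alpha - |s,e|))`. An empty
#' hit list gives `R = 0`; a single hit scoring exactly `alpha` gives 0.5;
#' R approaches but never reaches 1.
#'
#' @param hit_scores numeric vector of alignment scores |s,e| for the hits
#'   retained for this neoepitope.
#' @param params a [fitness_params()].
#' @return `R` in \[0, 1).
#' @export
recognition_potential <- function(hit_scores, params = fitness_params()) {
  if (length(hit_scores) == 0L) return(0)
  stopifnot(all(is.finite(hit_scores)))
  z <- sum(exp(-params$k * (params$alpha - hit_scores)))
  # R < 1 always; cap at the largest double below 1 once the logistic
  # saturates past floating-point resolution
  cap <- 1 - .Machine$double.eps / 2
  if (!is.finite(z)) cap else min(z / (1 + z), cap)
}

#' MHC-I binding-affinity amplitude
#'
#' The amplitude `A` measures how much better the mutant peptide binds
#' MHC-I than its wild-type counterpart: the base ratio is
#' `ic50_wt / ic50_mt` (lower ic50 = stronger binding, so mutant-stronger
#' gives A > 1). With `amplitude_normalization = "reciprocal_max_wt"` the
#' ratio is corrected for dissociation-constant bias by multiplying by the
#' wild-type affinity relative to the largest wild-type affinity among the
#' patient's epitopes, i.e. `A = (ic50_wt / ic50_mt) * (ic50_wt /
#' max_ic50_wt)`; epitopes whose wild type is already near the patient's
#' weakest binder keep their full ratio, strong wild-type binders are
#' shrunk. `A` is strictly decreasing in `ic50_mt` in both modes.
#'
#' @param ic50_wt,ic50_mt positive affinities (nM); vectorized.
#' @param max_ic50_wt patient-level maximum wild-type ic50 used by the
#'   normalization; defaults to `max(ic50_wt)`.
#' @param params a [fitness_params()].
#' @return Numeric vector of amplitudes, `A >= 0`.
#' @export
amplitude <- function(ic50_wt, ic50_mt, max_ic50_wt = max(ic50_wt),
                      params = fitness_params()) {
  if (any(ic50_wt <= 0, na.rm = TRUE) || any(ic50_mt <= 0, na.rm = TRUE))
    stop("ic50 values must be positive")
  a <- ic50_wt / ic50_mt
  if (params$amplitude_normalization == "reciprocal_max_wt") {
    if (any(max_ic50_wt <= 0)) stop("max_ic50_wt must be positive")
    a <- a * ic50_wt / max_ic50_wt
  }
  a
}

#' Score one patient: immunogenicity and tumor fitness
#'
#' Combines recognition potential and amplitude per neoepitope and takes the
#' maximal clonal immunogenicity `I = max_j (R_j * A_j)` over the patient's
#' qualifying neoepitopes; tumor fitness is `1 / I`. Records must have a
#' wild-type affinity (viral records carry no amplitude); epitopes at or
#' above the strict `affinity_threshold` (default 500 nM) are excluded
#' before the maximum. Patients with no qualifying epitope are flagged and
#' get `I = 0` with undefined (`NA`) tumor fitness.
#'
#' @param records the patient's [epitope_records()].
#' @param hits hit table from [search_all()] for these records (the `record`
#'   column indexes rows of `records`), or a list of per-record score
#'   vectors.
#' @param params a [fitness_params()].
#' @return A list of class `fitness_result`: `patient_id`, `per_epitope`
#'   data frame (`peptide_mt`, `R`, `A`, `product`), `immunogenicity`,
#'   `argmax_epitope`, `tumor_fitness`, `n_epitopes`, `flagged`.
#' @export
score_patient <- function(records, hits, params = fitness_params()) {
  pid <- if (nrow(records)) records$patient_id[1] else NA_character_
  keep <- which(records$source == "neoepitope" & !is.na(records$ic50_wt) &
                records$ic50_mt < params$affinity_threshold)
  scores_of <- function(i) {
    if (is.data.frame(hits)) hits$score[hits$record == i]
    else if (is.list(hits)) hits[[i]]
    else stop("'hits' must be a hit table or a list of score vectors")
  }
  if (length(keep) == 0L) {
    return(structure(list(patient_id = pid,
                          per_epitope = data.frame(peptide_mt = character(0),
                                                   R = numeric(0), A = numeric(0),
                                                   product = numeric(0)),
                          immunogenicity = 0, argmax_epitope = NA_character_,
                          tumor_fitness = NA_real_, n_epitopes = 0L,
                          flagged = TRUE),
                     class = "fitness_result"))
  }
  sub <- records[keep, , drop = FALSE]
  r <- vapply(keep, function(i) recognition_potential(scores_of(i), params),
              numeric(1))
  a <- amplitude(sub$ic50_wt, sub$ic50_mt, max(sub$ic50_wt), params)
  prod <- r * a
  imax <- which.max(prod)
  imm <- prod[imax]
  structure(list(patient_id = pid,
                 per_epitope = data.frame(peptide_mt = sub$peptide_mt,
                                          R = r, A = a, product = prod),
                 immunogenicity = imm,
                 argmax_epitope = sub$peptide_mt[imax],
                 tumor_fitness = if (imm > 0) 1 / imm else NA_real_,
                 n_epitopes = length(keep), flagged = FALSE),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("Patient", x$patient_id, "-", x$n_epitopes, "qualifying neoepitope(s)\n")
  if (x$flagged) {
    cat("  no epitope below the affinity threshold; immunogenicity 0,",
        "tumor fitness undefined\n")
  } else {
    cat(sprintf("  immunogenicity %.4g (argmax %s), tumor fitness %.4g\n",
                x$immunogenicity, x$argmax_epitope, x$tumor_fitness))
  }
  invisible(x)
}

#' Tumor-fitness scoring across a cohort
#'
#' End-to-end fitness fit: filters neoepitopes to the strict affinity
#' threshold, aligns each against the viral epitope database, applies the
#' e-value homology filter, and computes per-patient recognition potential,
#' amplitude, maximal clonal immunogenicity and tumor fitness.
#'
#' @param records cohort [epitope_records()].
#' @param db viral [epitope_db()].
#' @param params a [fitness_params()].
#' @param align an [align_params()].
#' @param evalue_max homology e-value cutoff for retained hits (default 10).
#' @param best_only use only the top database hit per neoepitope instead of
#'   all hits passing the e-value filter.
#' @return An object of class `neofit`: a per-patient data frame
#'   (`patient_id`, `immunogenicity`, `tumor_fitness`, `argmax_peptide`,
#'   `n_epitopes`, `flagged`) with the per-patient `fitness_result` objects
#'   in `attr(, "results")` and the hit table in `attr(, "hits")`.
#' @export
tumor_fitness <- function(records, db, params = fitness_params(),
                          align = align_params(), evalue_max = 10,
                          best_only = FALSE) {
  stopifnot(inherits(db, "epitope_db"))
  cand <- records[records$source == "neoepitope" &
                  records$ic50_mt < params$affinity_threshold, , drop = FALSE]
  hits <- search_all(cand, db, align, evalue_max, best_only)
  patients <- unique(records$patient_id)
  results <- lapply(patients, function(p) {
    rows <- which(cand$patient_id == p)
    sub <- cand[rows, , drop = FALSE]
    h <- hits[hits$patient_id == p, , drop = FALSE]
    h$record <- match(h$record, rows)
    res <- score_patient(sub, h, params)
    res$patient_id <- p
    res
  })
  tab <- data.frame(
    patient_id = patients,
    immunogenicity = vapply(results, `[[`, numeric(1), "immunogenicity"),
    tumor_fitness = vapply(results, `[[`, numeric(1), "tumor_fitness"),
    argmax_peptide = vapply(results, `[[`, character(1), "argmax_epitope"),
    n_epitopes = vapply(results, `[[`, integer(1), "n_epitopes"),
    flagged = vapply(results, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)
  structure(tab, results = results, hits = hits, params = params,
            class = c("neofit", "data.frame"))
}

#' @export
print.neofit <- function(x, ...) {
  cat("Tumor-fitness scores:", nrow(x), "patient(s),",
      sum(x$flagged), "without qualifying neoepitopes\n")
  p <- attr(x, "params")
  cat(sprintf("  model constants: alpha = %g, k = %g, affinity threshold < %g nM\n",
              p$alpha, p$k, p$affinity_threshold))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' @export
summary.neofit <- function(object, ...) {
  ok <- !object$flagged
  cat("Immunogenicity over", sum(ok), "scored patient(s):\n")
  print(summary(object$immunogenicity[ok]))
  invisible(object)
}
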