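#' Epitope admission thresholds
#'
#' The binding-affinity and homology cutoffs applied before scoring or
#' comparison: a noise filter at ic50 < 10,000 nM for raw predictor output,
#' the strict 500 nM threshold for epitopes entering the fitness model, a
#' 200 nM strong-binder definition for burden counts, the anchor-residue
#' exclusion rule, and the e-value < 10 homology cutoff. All affinity
#' thresholds are strict (`<`).
#'
#' @param noise_ic50_max,fitness_ic50_max,strong_binder_ic50_max nM cutoffs;
#'   must satisfy strong <= fitness <= noise.
#' @param anchor_positions anchor positions within a peptide; `NULL` means
#'   position 2 plus the C-terminal residue whatever the length (the 9-mer
#'   "2,9" anchors generalized), otherwise an explicit integer set.
#' @param homology_evalue_max e-value cutoff for viral homology.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(noise_ic50_max = 10000, fitness_ic50_max = 500,
                          strong_binder_ic50_max = 200,
                          anchor_positions = NULL,
                          homology_evalue_max = 10) {
  if (!(strong_binder_ic50_max <= fitness_ic50_max &&
        fitness_ic50_max <= noise_ic50_max))
    stop("thresholds must satisfy strong_binder <= fitness <= noise")
  structure(list(noise_ic50_max = noise_ic50_max,
                 fitness_ic50_max = fitness_ic50_max,
                 strong_binder_ic50_max = strong_binder_ic50_max,
                 anchor_positions = anchor_positions,
                 homology_evalue_max = homology_evalue_max),
            class = "filter_config")
}

#' Filter epitopes by binding affinity
#'
#' Keeps records with `ic50_mt` strictly below the threshold (boundary
#' values are excluded), preserving input order.
#'
#' @param records an [epitope_records()] data frame.
#' @param threshold_nM strict upper ic50 bound, nM.
#' @return The surviving records.
#' @export
filter_by_affinity <- function(records, threshold_nM) {
  records[records$ic50_mt < threshold_nM, , drop = FALSE]
}

anchor_set <- function(len, anchor_positions = NULL) {
  if (is.null(anchor_positions)) c(2L, len) else as.integer(anchor_positions)
}

#' Exclude anchor-only mutants
#'
#' Mutations at MHC anchor residues (position 2 and the C-terminus, the
#' canonical 9-mer "2,9" anchors generalized to lengths 8-11) are buried in
#' the binding groove and invisible to the TCR. Records whose mutated
#' positions lie entirely within the anchor set are dropped; records with at
#' least one non-anchor mutation are kept. Viral records (no wild type) pass
#' through untouched.
#'
#' @param records an [epitope_records()] data frame.
#' @param anchor_positions explicit anchor position set, or `NULL` for the
#'   default rule (2 and C-terminal).
#' @return The surviving records.
#' @export
exclude_anchor_mutants <- function(records, anchor_positions = NULL) {
  if (nrow(records) == 0L) return(records)
  drop <- vapply(seq_len(nrow(records)), function(i) {
    mp <- records$mutated_positions[[i]]
    if (is.na(records$peptide_wt[i]) || length(mp) == 0L) return(FALSE)
    anchors <- anchor_set(nchar(records$peptide_mt[i]), anchor_positions)
    all(mp %in% anchors)
  }, logical(1))
  records[!drop, , drop = FALSE]
}

#' Call viral-like patients
#'
#' A patient is "viral-like" when at least one neoepitope passes the strict
#' affinity threshold (ic50 < 500 nM) and has at least one database hit with
#' significant viral homology (e-value < 10).
#'
#' @param records cohort [epitope_records()].
#' @param hits hit table from [search_all()] over the same records.
#' @param config a [filter_config()].
#' @return Named logical vector, one element per patient in `records`.
#' @export
call_viral_like <- function(records, hits, config = filter_config()) {
  patients <- unique(records$patient_id)
  ok_aff <- records$source == "neoepitope" &
    records$ic50_mt < config$fitness_ic50_max
  ok_hit <- hits$evalue < config$homology_evalue_max
  hit_records <- unique(hits$record[ok_hit])
  vapply(setNames(patients, patients), function(p) {
    idx <- which(records$patient_id == p & ok_aff)
    any(idx %in% hit_records)
  }, logical(1))
}
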