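AA_STANDARD <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# BLOSUM62 (NCBI), restricted to the 20 standard amino acids.
BLOSUM62_20 <- local({
  v <- c(
    4, -1, -2, -2, 0, -1, -1, 0, -2, -1, -1, -1, -1, -2, -1, 1, 0, -3, -2, 0,
    -1, 5, 0, -2, -3, 1, 0, -2, 0, -3, -2, 2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2, 0, 6, 1, -3, 0, 0, 0, 1, -3, -3, 0, -2, -3, -2, 1, 0, -4, -2, -3,
    -2, -2, 1, 6, -3, 0, 2, -1, -1, -3, -4, -1, -3, -3, -1, 0, -1, -4, -3, -3,
    0, -3, -3, -3, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1, 1, 0, 0, -3, 5, 2, -2, 0, -3, -2, 1, 0, -3, -1, 0, -1, -2, -1, -2,
    -1, 0, 0, 2, -4, 2, 5, -2, 0, -3, -3, 1, -2, -3, -1, 0, -1, -3, -2, -2,
    0, -2, 0, -1, -3, -2, -2, 6, -2, -4, -4, -2, -3, -3, -2, 0, -2, -2, -3, -3,
    -2, 0, 1, -1, -3, 0, 0, -2, 8, -3, -3, -1, -2, -1, -2, -1, -2, -2, 2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3, 4, 2, -3, 1, 0, -3, -2, -1, -3, -1, 3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1,
    -1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 5, 0, -2, -1, -1, -1, -1, 1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1, 0, 0, -3, 0, 6, -4, -2, -2, 1, 3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4, 7, -1, -1, -4, -3, -2,
    1, -1, 1, 0, -1, 0, 0, 0, -1, -2, -2, 0, -1, -2, -1, 4, 1, -3, -2, -2,
    0, -1, 0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1, 1, 5, -2, -2, 0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1, 1, -4, -3, -2, 11, 2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3, 2, -1, -1, -2, -1, 3, -3, -2, -2, 2, 7, -1,
    0, -3, -3, -3, -1, -2, -2, -3, -3, 3, 1, -2, 1, -1, -2, -2, 0, -3, -1, 4)
  m <- matrix(as.integer(v), 20, 20, byrow = TRUE,
              dimnames = list(AA_STANDARD, AA_STANDARD))
  m
})

#' BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 matrix restricted to the 20 standard amino
#' acids; the default scoring matrix for peptide alignment.
#'
#' @return A named 20 x 20 integer matrix.
#' @export
blosum62 <- function() BLOSUM62_20

#' Alignment parameters
#'
#' Scoring scheme for local peptide alignment and its Karlin-Altschul
#' statistics. Defaults follow protein BLAST: BLOSUM62 with gap
#' existence 11 and extension 1 (a gap of length L costs `gap_open +
#' L * gap_extend`), and gapped-BLOSUM62 constants `lambda = 0.267`,
#' `K = 0.041` for converting raw scores to bitscores and e-values.
#'
#' @param substitution_matrix named symmetric integer matrix over the 20
#'   standard amino acids.
#' @param gap_open,gap_extend nonnegative gap penalties, `gap_open >=
#'   gap_extend`.
#' @param karlin_lambda,karlin_K Karlin-Altschul constants for the scheme.
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = blosum62(), gap_open = 11L,
                         gap_extend = 1L, karlin_lambda = 0.267,
                         karlin_K = 0.041) {
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))))
    stop("substitution_matrix must be a symmetric square matrix")
  if (is.null(rownames(m)) || !all(AA_STANDARD %in% rownames(m)))
    stop("substitution_matrix must be named over the 20 standard amino acids")
  if (gap_open < gap_extend || gap_extend < 0)
    stop("require gap_open >= gap_extend >= 0")
  structure(list(substitution_matrix = m[AA_STANDARD, AA_STANDARD],
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K),
            class = "align_params")
}

encode_peptide <- function(p) {
  idx <- match(strsplit(p, "")[[1]], AA_STANDARD) - 1L
  if (anyNA(idx)) stop("non-standard residue in peptide: ", p)
  idx
}

#' Smith-Waterman local alignment of two peptides
#'
#' Computes the optimal local alignment score |s,e| between two peptides
#' under affine gap penalties, by exact dynamic programming over the full
#' score matrix. The score is 0 when no positive-scoring local alignment
#' exists, in which case the spans are empty (`NA`).
#'
#' @param query,target peptides over the 20 standard amino acids.
#' @param params an [align_params()].
#' @return A list of class `alignment_hit` with elements `score`,
#'   `query_span`, `target_span` (1-based inclusive, `NA` when score 0).
#' @examples
#' smith_waterman("SIINFEKL", "SIINFEKL")$score
#' @export
smith_waterman <- function(query, target, params = align_params()) {
  q <- if (nzchar(query)) encode_peptide(query) else integer(0)
  t <- if (nzchar(target)) encode_peptide(target) else integer(0)
  r <- sw_align_cpp(q, t, params$substitution_matrix, params$gap_open,
                    params$gap_extend)
  span <- function(a, b) if (r[1] > 0) c(a, b) else c(NA_integer_, NA_integer_)
  structure(list(score = r[1], query_span = span(r[2], r[3]),
                 target_span = span(r[4], r[5])),
            class = "alignment_hit")
}

karlin_bitscore <- function(score, params)
  (params$karlin_lambda * score - log(params$karlin_K)) / log(2)

#' Search an epitope database by exhaustive local alignment
#'
#' Aligns a query peptide against every database entry with
#' [smith_waterman()] and attaches Karlin-Altschul statistics: `bitscore =
#' (lambda * score - ln K) / ln 2` and `evalue = m * n * 2^(-bitscore)` with
#' `m` the query length and `n` the total residue count of the database.
#' At short-peptide database scale the exhaustive scan is exact, playing the
#' role of the usual heuristic search plus rescoring. Hits with `evalue <=
#' evalue_max` are returned sorted by descending score, ties broken by
#' ascending `db_id`.
#'
#' @param query a peptide string.
#' @param db an [epitope_db()].
#' @param params an [align_params()].
#' @param evalue_max e-value cutoff (the homology filter uses 10).
#' @param best_only keep only the top-ranked hit.
#' @return A data frame with columns `db_id`, `score`, `bitscore`, `evalue`,
#'   `query_start`, `query_end`, `target_start`, `target_end`.
#' @export
search_db <- function(query, db, params = align_params(), evalue_max = 10,
                      best_only = FALSE) {
  stopifnot(inherits(db, "epitope_db"))
  empty <- data.frame(db_id = character(0), score = integer(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      query_start = integer(0), query_end = integer(0),
                      target_start = integer(0), target_end = integer(0))
  if (nrow(db) == 0L) return(empty)
  q <- encode_peptide(query)
  targets <- lapply(db$peptide, encode_peptide)
  res <- sw_batch_cpp(q, targets, params$substitution_matrix, params$gap_open,
                      params$gap_extend)
  bits <- karlin_bitscore(res[, 1], params)
  ev <- length(q) * total_residues(db) * 2^(-bits)
  keep <- which(ev <= evalue_max)
  if (length(keep) == 0L) return(empty)
  out <- data.frame(db_id = db$id[keep], score = res[keep, 1],
                    bitscore = bits[keep], evalue = ev[keep],
                    query_start = res[keep, 2], query_end = res[keep, 3],
                    target_start = res[keep, 4], target_end = res[keep, 5])
  out[out$score == 0, c("query_start", "query_end", "target_start",
                        "target_end")] <- NA_integer_
  out <- out[order(-out$score, out$db_id), , drop = FALSE]
  rownames(out) <- NULL
  if (best_only && nrow(out) > 1L) out <- out[1L, , drop = FALSE]
  out
}

#' Align all epitope records against a database
#'
#' Convenience wrapper running [search_db()] for each record; returns one
#' long table of hits keyed by record row.
#'
#' @param records an [epitope_records()] data frame.
#' @inheritParams search_db
#' @return A data frame with columns `record`, `patient_id`, `peptide_mt`,
#'   `db_id`, `score`, `bitscore`, `evalue`.
#' @export
search_all <- function(records, db, params = align_params(), evalue_max = 10,
                       best_only = FALSE) {
  hits <- lapply(seq_len(nrow(records)), function(i) {
    h <- search_db(records$peptide_mt[i], db, params, evalue_max, best_only)
    if (nrow(h) == 0L) return(NULL)
    cbind(record = i, patient_id = records$patient_id[i],
          peptide_mt = records$peptide_mt[i],
          h[, c("db_id", "score", "bitscore", "evalue")])
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(record = integer(0), patient_id = character(0),
                       peptide_mt = character(0), db_id = character(0),
                       score = integer(0), bitscore = numeric(0),
                       evalue = numeric(0))
  rownames(hits) <- NULL
  hits
}

#' Shuffle residues within each peptide (negative control)
#'
#' Produces the randomized control set: each mutant peptide has its residues
#' permuted in place, preserving per-peptide amino-acid composition. The
#' wild-type pairing is dropped (a shuffled peptide no longer has a
#' meaningful wild type), so control records pass through downstream steps
#' as unmatched peptides.
#'
#' @param records an [epitope_records()] data frame.
#' @param seed integer seed for reproducibility.
#' @return An `epitope_records` data frame with shuffled `peptide_mt`.
#' @export
randomize_peptides <- function(records, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shuf <- vapply(records$peptide_mt, function(p) {
    paste(sample(strsplit(p, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  epitope_records(records$patient_id, shuf, NA, records$hla_allele,
                  records$ic50_mt, NA)
}
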