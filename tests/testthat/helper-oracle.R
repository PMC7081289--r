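# Independent brute-force Smith-Waterman oracle: full-matrix affine-gap DP
# in plain R, with the substitution matrix taken from Biostrings rather than
# the package's embedded copy.
sw_oracle_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  e$BLOSUM62[aa, aa]
})

sw_oracle <- function(q, t, sub = sw_oracle_matrix, open = 11, ext = 1) {
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  m <- length(qa); n <- length(ta)
  if (m == 0 || n == 0) return(0)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + sub[qa[i - 1], ta[j - 1]],
                   E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

rand_peptide <- function(len) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Tiny deterministic epitope-record fixture used across filter/fitness tests
toy_records <- function() {
  epitope_records(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    peptide_mt = c("KLLEIFTEL", "SIINFEKL", "GILGFVFTL", "NLVPMVATV",
                   "RAKFKQLLQ"),
    peptide_wt = c("KLLEIFSEL", "SIINFEKL", "GILGFVFTL", "NLVPMVATV",
                   "RAKFKQLLQ"),
    ic50_mt = c(50, 400, 9999, 10000, 20000),
    ic50_wt = c(500, 800, 12000, 15000, 25000))
}
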