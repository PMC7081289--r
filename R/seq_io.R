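#' @useDynLib neofit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test coef ecdf ks.test median pnorm qnorm quantile
#'   rbeta rbinom rexp rlnorm rnbinom rnorm rpois runif sd setNames uniroot
#'   wilcox.test
#' @importFrom graphics lines legend
#' @importFrom utils read.delim write.table head
NULL

#' Construct an epitope database
#'
#' An epitope database is the set of short peptides (typically IEDB-derived
#' viral epitopes) that neoepitopes are searched against. It is stored as a
#' data frame with columns `id` and `peptide`; the total residue count, used
#' as the database size `n` in Karlin-Altschul e-values, is available via
#' [total_residues()].
#'
#' @param id character vector of unique record identifiers.
#' @param peptide character vector of peptides over the 20 standard amino
#'   acids.
#' @return A data frame of class `epitope_db`.
#' @examples
#' db <- epitope_db(c("a", "b"), c("SIINFEKL", "GILGFVFTL"))
#' total_residues(db)
#' @export
epitope_db <- function(id, peptide) {
  id <- as.character(id)
  peptide <- toupper(as.character(peptide))
  if (length(id) != length(peptide))
    stop("'id' and 'peptide' must have equal length")
  if (anyDuplicated(id))
    stop("duplicate epitope ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(peptide)))
    stop("empty peptide for record(s): ", paste(id[!nzchar(peptide)], collapse = ", "))
  bad <- !vapply(strsplit(peptide, ""), function(x) all(x %in% AA_STANDARD), logical(1))
  if (any(bad))
    stop("non-standard amino-acid residue in record(s): ",
         paste(id[bad], collapse = ", "))
  structure(data.frame(id = id, peptide = peptide, stringsAsFactors = FALSE),
            class = c("epitope_db", "data.frame"))
}

#' @rdname epitope_db
#' @param db an `epitope_db`.
#' @export
total_residues <- function(db) sum(nchar(db$peptide))

#' Read an epitope database from FASTA
#'
#' Peptide FASTA reader for the viral epitope database. Records must contain
#' only the 20 standard amino acids; anything else is rejected with an error
#' naming the offending record.
#'
#' @param path path to a FASTA file of peptides.
#' @return An [epitope_db()].
#' @export
read_epitope_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA at line ", nonempty[1], ": expected '>' header")
  aas <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA (", conditionMessage(e), ")"))
  ids <- sub("\\s.*$", "", names(aas))
  epitope_db(ids, as.character(aas))
}

#' @rdname read_epitope_fasta
#' @param db an `epitope_db` to serialize.
#' @export
write_epitope_fasta <- function(db, path) {
  stopifnot(inherits(db, "epitope_db"))
  writeLines(paste0(">", db$id, "\n", db$peptide), path)
  invisible(path)
}

mutated_positions_of <- function(mt, wt) {
  if (is.na(wt)) return(integer(0))
  which(strsplit(mt, "")[[1]] != strsplit(wt, "")[[1]])
}

#' Construct epitope records
#'
#' One record per candidate epitope: the mutant (or viral) peptide, its
#' wild-type counterpart when one exists, the restricting HLA allele, and
#' predicted MHC-I binding affinities (ic50, nM; lower = stronger binding).
#' Peptides must be HLA-I processed lengths (8-11 residues). For records with
#' a wild-type peptide, `mutated_positions` (a list column of 1-based indices)
#' is derived by per-position comparison.
#'
#' @param patient_id,peptide_mt,hla_allele,ic50_mt required per-record fields.
#' @param peptide_wt wild-type peptides; `NA` marks viral (non-mutant) records.
#' @param ic50_wt wild-type affinities; `NA` where no wild type exists.
#' @return A data frame of class `epitope_records` with a `source` column
#'   (`"neoepitope"` or `"viral"`) and a `mutated_positions` list column.
#' @export
epitope_records <- function(patient_id, peptide_mt, peptide_wt = NA,
                            hla_allele = "HLA-A*02:01", ic50_mt,
                            ic50_wt = NA) {
  n <- max(length(patient_id), length(peptide_mt), length(peptide_wt),
           length(hla_allele), length(ic50_mt), length(ic50_wt))
  peptide_mt <- rep_len(toupper(as.character(peptide_mt)), n)
  peptide_wt <- toupper(as.character(rep_len(peptide_wt, n)))
  patient_id <- as.character(rep_len(patient_id, n))
  hla_allele <- as.character(rep_len(hla_allele, n))
  ic50_mt <- as.numeric(rep_len(ic50_mt, n))
  ic50_wt <- as.numeric(rep_len(ic50_wt, n))

  len <- nchar(peptide_mt)
  bad_len <- len < 8L | len > 11L
  if (any(bad_len))
    stop("peptide length outside 8-11 residues in row(s): ",
         paste(which(bad_len), collapse = ", "))
  check_aa <- function(p) is.na(p) || all(strsplit(p, "")[[1]] %in% AA_STANDARD)
  if (!all(vapply(peptide_mt, check_aa, logical(1))) ||
      !all(vapply(peptide_wt, check_aa, logical(1))))
    stop("non-standard amino-acid residue in peptide")
  has_wt <- !is.na(peptide_wt)
  if (any(has_wt & nchar(peptide_wt) != len))
    stop("MT/WT length mismatch in row(s): ",
         paste(which(has_wt & nchar(peptide_wt) != len), collapse = ", "))
  if (any(!is.na(ic50_mt) & ic50_mt <= 0) || any(!is.na(ic50_wt) & ic50_wt <= 0))
    stop("ic50 values must be positive (nM)")
  if (any(is.na(ic50_mt)))
    stop("missing ic50_mt in row(s): ", paste(which(is.na(ic50_mt)), collapse = ", "))

  res <- data.frame(patient_id = patient_id, peptide_mt = peptide_mt,
                    peptide_wt = peptide_wt, hla_allele = hla_allele,
                    ic50_mt = ic50_mt, ic50_wt = ic50_wt,
                    source = ifelse(has_wt, "neoepitope", "viral"),
                    stringsAsFactors = FALSE)
  res$mutated_positions <- mapply(mutated_positions_of, peptide_mt, peptide_wt,
                                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(res, class = c("epitope_records", "data.frame"))
}

#' Read a neoepitope table
#'
#' Reads the tab-separated interface format produced by external MHC-binding
#' predictors: columns `patient_id`, `peptide_mt`, `peptide_wt`, `hla_allele`,
#' `ic50_mt`, `ic50_wt`. Empty or `NA` wild-type fields mark viral epitopes.
#'
#' @param path path to a TSV file with the header above.
#' @return An [epitope_records()] data frame.
#' @export
read_neoepitope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "peptide_mt", "peptide_wt", "hla_allele",
            "ic50_mt", "ic50_wt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  tab$peptide_wt[blank(tab$peptide_wt)] <- NA
  tab$ic50_wt[blank(tab$ic50_wt)] <- NA
  epitope_records(tab$patient_id, tab$peptide_mt, tab$peptide_wt,
                  tab$hla_allele, as.numeric(tab$ic50_mt),
                  as.numeric(tab$ic50_wt))
}

#' @rdname read_neoepitope_table
#' @param records an `epitope_records` data frame to serialize.
#' @export
write_neoepitope_table <- function(records, path) {
  out <- records[, c("patient_id", "peptide_mt", "peptide_wt", "hla_allele",
                     "ic50_mt", "ic50_wt")]
  out$ic50_mt <- format_num(out$ic50_mt)
  out$ic50_wt <- format_num(out$ic50_wt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# numeric formatting shared by all table writers so that round-trips and
# golden-output comparisons are byte-stable
format_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, trimws(formatC(x, digits = digits, format = "g")))
}

#' Read a patient clinical/immune table
#'
#' Per-patient covariates for the survival stage: follow-up `time` (days),
#' `event` (1 = death, 0 = censored), ordinal `stage`, `tmb`, `cyt`,
#' `til_burden`, `til_clonality`, and optional `immunogenicity`.
#'
#' @param path path to a TSV file with the columns above.
#' @return A data frame of class `patient_profiles`.
#' @export
read_patient_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event", "stage", "tmb", "cyt",
            "til_burden", "til_clonality")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$immunogenicity)) tab$immunogenicity <- NA_real_
  patient_profiles(tab)
}

#' @rdname read_patient_table
#' @param profiles a data frame of per-patient covariates to validate.
#' @export
patient_profiles <- function(profiles) {
  profiles <- as.data.frame(profiles)
  if (!all(profiles$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(!is.finite(profiles$time)) || any(profiles$time < 0))
    stop("time must be finite and nonnegative")
  if (any(profiles$cyt <= 0, na.rm = TRUE)) stop("cyt must be positive")
  structure(profiles, class = c("patient_profiles", "data.frame"))
}

#' @rdname read_patient_table
#' @export
write_patient_table <- function(profiles, path) {
  out <- as.data.frame(profiles)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a MAF-like somatic mutation table
#'
#' Accepts any tab-separated table containing the columns `patient_id`,
#' `chrom`, `pos`, `ref`, `alt` (a `variant_class` column is kept when
#' present); extra columns are ignored. Coordinates are 1-based.
#'
#' @param path path to the mutation TSV.
#' @return A data frame of class `mutation_records`.
#' @export
read_mutation_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$variant_class)) tab$variant_class <- NA_character_
  if (any(tab$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
  structure(tab[, c(need, "variant_class")],
            class = c("mutation_records", "data.frame"))
}

#' Tumor mutation burden from a mutation table
#'
#' Counts the somatic DNA mutations recorded for one patient. Identical
#' variant rows (same chrom, pos, ref, alt — e.g. one MAF line per affected
#' transcript) are de-duplicated so the count is variant-level. Silent
#' variants are included by default; set `include_silent = FALSE` to drop
#' rows whose `variant_class` matches `silent_classes`.
#'
#' @param records a mutation table (see [read_mutation_table()]).
#' @param patient_id patient to count; `NULL` counts all records.
#' @param include_silent logical; include silent/synonymous variants.
#' @param silent_classes variant classes treated as silent.
#' @return Integer mutation count (0 for an absent patient).
#' @export
tmb_from_maf <- function(records, patient_id = NULL, include_silent = TRUE,
                         silent_classes = c("Silent", "synonymous_variant")) {
  rec <- as.data.frame(records)
  if (!is.null(patient_id)) rec <- rec[rec$patient_id %in% patient_id, , drop = FALSE]
  if (!include_silent && !is.null(rec$variant_class))
    rec <- rec[!(rec$variant_class %in% silent_classes), , drop = FALSE]
  if (nrow(rec) == 0L) return(0L)
  key <- paste(rec$patient_id, rec$chrom, rec$pos, rec$ref, rec$alt, sep = "\r")
  length(unique(key))
}
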