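# Amino-acid background composition (Robinson & Robinson-style frequencies)
# used when sampling random peptides.
AA_BACKGROUND <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                   Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
                   L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                   S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.065)

random_peptides <- function(n, length_range = c(8, 11)) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(names(AA_BACKGROUND), L, replace = TRUE,
                 prob = AA_BACKGROUND), collapse = ""), character(1))
}

#' Generate a synthetic epitope database
#'
#' Random peptide database standing in for the IEDB-derived viral epitope
#' set: i.i.d. residues from a fixed background amino-acid composition,
#' lengths uniform over `length_range`.
#'
#' @param db_size number of entries (>= 1).
#' @param length_range inclusive peptide length range.
#' @param seed integer seed.
#' @return An [epitope_db()] with ids `VE0001`, `VE0002`, ...
#' @export
generate_epitope_db <- function(db_size, length_range = c(8, 11), seed = NULL) {
  stopifnot(db_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  epitope_db(sprintf("VE%04d", seq_len(db_size)),
             random_peptides(db_size, length_range))
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator, chosen to emulate the
#' statistical structure of matched somatic-mutation / expression / survival
#' cohorts at desk scale. ic50 values are log-normal on ln(nM), with the
#' neoepitope location below the viral location by default so neoepitopes
#' bind more strongly on average; survival times follow an exponential
#' proportional-hazards model on z-scored covariates with independent
#' uniform censoring calibrated to the target rate; CYT and TIL burden share
#' a Gaussian copula achieving a planted Spearman correlation.
#'
#' @param n_patients cohort size.
#' @param epitopes_per_patient Poisson mean of neoepitope counts.
#' @param viral_per_patient Poisson mean of viral epitope counts.
#' @param ic50_neo_lognormal,ic50_viral_lognormal `(meanlog, sdlog)` on
#'   ln(nM).
#' @param db_size viral database size.
#' @param planted_neighbor_fraction fraction of neoepitopes copied from a
#'   database entry with one substitution (drives viral homology).
#' @param anchor_mutant_fraction fraction of neoepitopes mutated only at an
#'   anchor position.
#' @param hazard list: `baseline` (per-day rate) and coefficients
#'   `beta_cyt`, `beta_tmb`, `beta_imm`, `beta_stage` on the z-scored
#'   design of [fit_cox()].
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param planted_rho target Spearman correlation between CYT and TIL
#'   burden.
#' @param tmb_mean,tmb_size negative-binomial mutation-count parameters.
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300, epitopes_per_patient = 30,
                          viral_per_patient = 20,
                          ic50_neo_lognormal = c(6.0, 1.5),
                          ic50_viral_lognormal = c(7.0, 1.5),
                          db_size = 200, planted_neighbor_fraction = 0.3,
                          anchor_mutant_fraction = 0.2,
                          hazard = list(baseline = 1 / 1095, beta_cyt = -0.8,
                                        beta_tmb = -0.3, beta_imm = 0,
                                        beta_stage = 0.3),
                          censor_rate = 0.35, planted_rho = 0.6,
                          tmb_mean = 100, tmb_size = 2, seed = 1L) {
  stopifnot(planted_neighbor_fraction >= 0, planted_neighbor_fraction <= 1,
            anchor_mutant_fraction >= 0, anchor_mutant_fraction <= 1,
            censor_rate >= 0, censor_rate < 1,
            ic50_neo_lognormal[2] > 0, ic50_viral_lognormal[2] > 0)
  if (abs(planted_rho) > 0.999)
    stop("infeasible copula correlation")
  structure(as.list(environment()), class = "cohort_config")
}

# Bivariate Gaussian copula hitting a target Spearman correlation exactly:
# Pearson parameter r = 2 sin(pi * rho_s / 6).
copula_pair <- function(n, rho_s) {
  r <- 2 * sin(pi * rho_s / 6)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  cbind(z1, z2)
}

# Uniform-censoring horizon tau achieving the target expected censor rate
# for exponential event times with per-patient rates r.
censor_horizon <- function(rates, target) {
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  uniroot(f, c(1e-6, 1e9), tol = 1e-8)$root
}

substitute_one <- function(peptide, pos = NULL) {
  ch <- strsplit(peptide, "")[[1]]
  if (is.null(pos)) pos <- sample.int(length(ch), 1)
  ch[pos] <- sample(setdiff(names(AA_BACKGROUND), ch[pos]), 1)
  paste(ch, collapse = "")
}

#' Generate a full synthetic cohort
#'
#' Produces every input the pipeline consumes: per-patient clinical/immune
#' profiles with proportional-hazards survival, neoepitope and viral epitope
#' tables with log-normal affinities, a mutation table realizing TMB,
#' HBV-like contigs with planted ORFs plus homopolymer and low-support
#' decoys, and the viral epitope database. Deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `patients`,
#'   `neoepitopes`, `viral`, `mutations`, `contigs`, `db`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))
  db <- epitope_db(sprintf("VE%04d", seq_len(config$db_size)),
                   random_peptides(config$db_size))

  # --- immune covariates (CYT, TIL burden share the planted copula) ---
  z <- copula_pair(n, config$planted_rho)
  cyt <- exp(3 + 1.0 * z[, 1])
  til_burden <- exp(2 + 0.8 * z[, 2])
  spread <- exp(rnorm(n, 0, 0.3))
  gzma <- cyt * spread
  prf1 <- cyt / spread          # geometric mean recovers cyt exactly
  til_clonality <- stats::rbeta(n, 2, 5)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15))
  imm <- rlnorm(n, 0, 1)

  # --- mutations and TMB ---
  nmut <- rnbinom(n, mu = config$tmb_mean, size = config$tmb_size) + 1L
  mutations <- data.frame(
    patient_id = rep(pid, nmut),
    chrom = paste0("chr", sample(1:22, sum(nmut), replace = TRUE)),
    pos = sample.int(1e8, sum(nmut), replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), sum(nmut), replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), sum(nmut), replace = TRUE),
    variant_class = sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation"),
                           sum(nmut), replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE)
  tmb <- as.integer(nmut)

  # --- survival from the PH model on the fitted design scale ---
  prof0 <- data.frame(patient_id = pid, time = 1, event = 1, stage = stage,
                      tmb = tmb, cyt = cyt, til_burden = til_burden,
                      til_clonality = til_clonality, immunogenicity = imm)
  X <- build_design(prof0, c("cyt", "tmb", "immunogenicity"), TRUE)
  beta <- c(cyt = config$hazard$beta_cyt, tmb = config$hazard$beta_tmb,
            immunogenicity = config$hazard$beta_imm,
            stage = config$hazard$beta_stage)
  rates <- config$hazard$baseline * exp(drop(X %*% beta[colnames(X)]))
  t_event <- rexp(n, rates)
  if (config$censor_rate > 0) {
    tau <- censor_horizon(rates, config$censor_rate)
    cens <- runif(n, 0, tau)
  } else cens <- rep(Inf, n)
  time <- round(pmin(t_event, cens), 2)
  time[time <= 0] <- 0.01
  event <- as.integer(t_event <= cens)
  patients <- patient_profiles(
    data.frame(patient_id = pid, time = time, event = event, stage = stage,
               tmb = tmb, cyt = cyt, gzma_rpkm = gzma, prf1_rpkm = prf1,
               til_burden = til_burden, til_clonality = til_clonality,
               immunogenicity = imm, stringsAsFactors = FALSE))

  # --- neoepitope table ---
  nepi <- rpois(n, config$epitopes_per_patient)
  tot <- sum(nepi)
  planted <- runif(tot) < config$planted_neighbor_fraction
  mt <- character(tot)
  mt[planted] <- vapply(sample.int(nrow(db), sum(planted), replace = TRUE),
                        function(k) substitute_one(db$peptide[k]), character(1))
  mt[!planted] <- random_peptides(sum(!planted))
  anchor_only <- runif(tot) < config$anchor_mutant_fraction
  wt <- vapply(seq_len(tot), function(i) {
    len <- nchar(mt[i])
    pos <- if (anchor_only[i]) sample(c(2L, len), 1)
           else sample(setdiff(seq_len(len), c(2L, len)), 1)
    substitute_one(mt[i], pos)
  }, character(1))
  neo <- epitope_records(
    patient_id = rep(pid, nepi), peptide_mt = mt, peptide_wt = wt,
    hla_allele = sample(c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02"),
                        tot, replace = TRUE),
    ic50_mt = rlnorm(tot, config$ic50_neo_lognormal[1],
                     config$ic50_neo_lognormal[2]),
    ic50_wt = rlnorm(tot, config$ic50_neo_lognormal[1] + 1,
                     config$ic50_neo_lognormal[2]))

  # --- viral epitope table ---
  nvir <- rpois(n, config$viral_per_patient)
  viral <- epitope_records(
    patient_id = rep(pid, nvir),
    peptide_mt = db$peptide[sample.int(nrow(db), sum(nvir), replace = TRUE)],
    peptide_wt = NA,
    hla_allele = sample(c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02"),
                        sum(nvir), replace = TRUE),
    ic50_mt = rlnorm(sum(nvir), config$ic50_viral_lognormal[1],
                     config$ic50_viral_lognormal[2]),
    ic50_wt = NA)

  contigs <- generate_contigs()
  structure(list(patients = patients, neoepitopes = neo, viral = viral,
                 mutations = structure(mutations,
                                       class = c("mutation_records", "data.frame")),
                 contigs = contigs, db = db, config = config),
            class = "synthetic_cohort")
}

# HBV-like contigs: planted-ORF contigs that pass every filter, plus decoys
# failing exactly one rule each (uses the current RNG stream).
generate_contigs <- function(n_good = 3, orf_aa = 150) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")
  good <- vapply(seq_len(n_good), function(i) {
    orf <- paste0("ATG", paste(sample(non_stop, orf_aa - 1, replace = TRUE),
                               collapse = ""), "TAA")
    paste0(rand_dna(60), orf, rand_dna(60))
  }, character(1))
  ids <- c(sprintf("contig_orf%d", seq_len(n_good)),
           "contig_homopolymer", "contig_short", "contig_lowsupport")
  seqs <- c(good, strrep("A", 500), rand_dna(80), rand_dna(400))
  support <- c(rep(50L, n_good), 100L, 60L, 5L)
  contig_set(ids, seqs, support)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$patients), "patients,",
      nrow(x$neoepitopes), "neoepitopes,", nrow(x$viral), "viral epitopes,",
      nrow(x$contigs), "contigs (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Serializes all generated tables in the pipeline's external formats
#' (TSV tables, FASTA for database and contigs) plus a `metadata.json`
#' recording the generator parameters and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_table(cohort$patients, file.path(dir, "patients.tsv"))
  write_neoepitope_table(cohort$neoepitopes, file.path(dir, "neo.tsv"))
  write_neoepitope_table(cohort$viral, file.path(dir, "viral.tsv"))
  write.table(cohort$mutations, file.path(dir, "mutations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_contig_fasta(cohort$contigs, file.path(dir, "contigs.fasta"))
  write_epitope_fasta(cohort$db, file.path(dir, "db.fasta"))
  cfg <- cohort$config
  cfg$hazard <- unlist(cfg$hazard)
  meta <- vapply(cfg[setdiff(names(cfg), "hazard")], function(v)
    paste(format(v), collapse = ","), character(1))
  writeLines(c("{",
               paste0('  "', names(meta), '": "', meta, '",'),
               paste0('  "hazard": "', paste(names(cfg$hazard), cfg$hazard,
                                             sep = "=", collapse = ","), '"'),
               "}"), file.path(dir, "metadata.json"))
  invisible(dir)
}

#' Hand-checkable worked example
#'
#' A fixed six-patient cohort (twelve epitopes, five-entry database) whose
#' fitness arithmetic can be verified by hand. Patient WE01 carries a
#' neoepitope containing the database entry `GAAAAA` as an exact substring;
#' its only meaningful alignment scores exactly 26 = alpha, so its
#' recognition potential is exactly 0.5. Patient WE02 has no neoepitope
#' below the 500 nM threshold and is flagged with immunogenicity 0.
#'
#' @return A list with `db` ([epitope_db()]), `neoepitopes`
#'   ([epitope_records()]), and `patients` ([patient_profiles()]).
#' @export
worked_example <- function() {
  db <- epitope_db(
    c("IEDB_GA", "IEDB_NEF", "IEDB_FLU", "IEDB_CMV", "IEDB_EBV"),
    c("GAAAAA", "SIINFEKL", "GILGFVFTL", "NLVPMVATV", "RAKFKQLL"))
  neo <- epitope_records(
    patient_id = rep(sprintf("WE%02d", 1:6), each = 2),
    peptide_mt = c("WGAAAAAW", "KLYEIFTEL",   # WE01: planted alpha-score hit
                   "MPYERWLTC", "HDWKNPRTC",  # WE02: all ic50 >= 500
                   "SIINFEKL", "QPRGHEDKW",   # WE03: exact database match
                   "GILGFVFTM", "DERWQNKHY",  # WE04: near match to IEDB_FLU
                   "WWCHMDPGK", "YFNREQDHS",  # WE05
                   "NLVPMVATM", "TKGDERWHN"), # WE06: near match to IEDB_CMV
    peptide_wt = c("WGAAATAW", "KLYEIFSEL",
                   "MPYERWLSC", "HDWKNPRSC",
                   "SIINFEKV", "QPRGHEDKW",
                   "GILGFVFSM", "DERWQNKHY",
                   "WWCHMDPGK", "YFNREQDHS",
                   "NLVPMVASM", "TKGDERWHN"),
    hla_allele = "HLA-A*02:01",
    ic50_mt = c(100, 250, 800, 5000, 50, 400, 150, 300, 600, 450, 80, 9000),
    ic50_wt = c(1000, 500, 1600, 8000, 500, 800, 1500, 600, 1200, 900, 640, 9000))
  patients <- patient_profiles(data.frame(
    patient_id = sprintf("WE%02d", 1:6),
    time = c(400, 150, 900, 620, 310, 75),
    event = c(1, 1, 0, 1, 0, 1),
    stage = c(2, 3, 1, 2, 4, 3),
    tmb = c(120, 40, 260, 90, 150, 30),
    cyt = c(12, 3, 45, 8, 20, 2.5),
    til_burden = c(5.2, 1.1, 9.8, 3.3, 6.4, 0.9),
    til_clonality = c(0.31, 0.12, 0.52, 0.27, 0.4, 0.08),
    immunogenicity = NA_real_))
  list(db = db, neoepitopes = neo, patients = patients)
}
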