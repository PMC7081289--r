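test_that("affinity filtering is strict at the boundary", {
  rec <- toy_records()   # ic50_mt: 50, 400, 9999, 10000, 20000
  expect_equal(nrow(filter_by_affinity(rec, 10000)), 3L)
  expect_equal(nrow(filter_by_affinity(rec, 500)), 2L)
  expect_equal(nrow(filter_by_affinity(rec[0, ], 500)), 0L)
  # order preserved
  expect_equal(filter_by_affinity(rec, 10000)$ic50_mt, c(50, 400, 9999))
})

test_that("anchor exclusion drops only fully anchor-buried mutations", {
  mk <- function(wt_pos) {
    mt <- "KLLEIFTEL"
    ch <- strsplit(mt, "")[[1]]
    wt <- ch
    for (p in wt_pos) wt[p] <- "A"
    epitope_records("p", mt, paste(wt, collapse = ""), ic50_mt = 100,
                    ic50_wt = 200)
  }
  expect_equal(nrow(exclude_anchor_mutants(mk(2))), 0L)     # position 2
  expect_equal(nrow(exclude_anchor_mutants(mk(9))), 0L)     # C-terminus
  expect_equal(nrow(exclude_anchor_mutants(mk(5))), 1L)     # non-anchor
  expect_equal(nrow(exclude_anchor_mutants(mk(c(2, 5)))), 1L)  # mixed kept
  expect_equal(nrow(exclude_anchor_mutants(mk(c(2, 9)))), 0L)
  # viral records (no wild type) pass through untouched
  viral <- epitope_records("p", "SIINFEKL", NA, ic50_mt = 100)
  expect_equal(nrow(exclude_anchor_mutants(viral)), 1L)
  # explicit anchor sets override the default rule
  expect_equal(nrow(exclude_anchor_mutants(mk(5), anchor_positions = 5)), 0L)
})

test_that("anchor rule uses the C-terminal position for every length", {
  for (len in 8:11) {
    mt <- rand_peptide(len)
    ch <- strsplit(mt, "")[[1]]
    wt <- ch; wt[len] <- if (ch[len] == "A") "R" else "A"
    rec <- epitope_records("p", mt, paste(wt, collapse = ""), ic50_mt = 10,
                           ic50_wt = 10)
    expect_equal(nrow(exclude_anchor_mutants(rec)), 0L, info = len)
  }
})

test_that("affinity and anchor filters commute", {
  set.seed(21)
  n <- 40
  mt <- vapply(sample(8:11, n, TRUE), rand_peptide, character(1))
  wt <- vapply(mt, function(p) {
    ch <- strsplit(p, "")[[1]]
    i <- sample(length(ch), 1)
    ch[i] <- sample(setdiff(c("A", "R", "N", "D", "C"), ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  rec <- epitope_records("p", mt, wt, ic50_mt = runif(n, 1, 20000),
                         ic50_wt = runif(n, 1, 20000))
  a_then_b <- exclude_anchor_mutants(filter_by_affinity(rec, 500))
  b_then_a <- filter_by_affinity(exclude_anchor_mutants(rec), 500)
  expect_equal(a_then_b$peptide_mt, b_then_a$peptide_mt)
})

test_that("survivor counts are monotone in the threshold", {
  rec <- toy_records()
  counts <- vapply(c(100, 500, 10000, 30000),
                   function(th) nrow(filter_by_affinity(rec, th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("viral-like calls require both affinity and homology", {
  rec <- epitope_records(c("pA", "pB", "pC"),
                         c("SIINFEKL", "SIINFEKL", "SIINFEKL"),
                         c("SIINFEKV", "SIINFEKV", "SIINFEKV"),
                         ic50_mt = c(300, 300, 800), ic50_wt = 1000)
  hits <- data.frame(record = c(1L, 2L, 3L), patient_id = c("pA", "pB", "pC"),
                     peptide_mt = "SIINFEKL", db_id = "v1",
                     score = c(40, 12, 40), bitscore = 1,
                     evalue = c(5, 50, 5))
  calls <- call_viral_like(rec, hits)
  expect_identical(calls, c(pA = TRUE, pB = FALSE, pC = FALSE))
})

test_that("viral-like call rate recovers a planted patient proportion", {
  set.seed(22)
  db <- generate_epitope_db(60, seed = 23)
  n_pat <- 80
  planted <- rbinom(n_pat, 1, 0.6) == 1
  mt <- character(n_pat); ic50 <- numeric(n_pat)
  for (i in seq_len(n_pat)) {
    if (planted[i]) {
      # strong binder with a one-substitution database neighbor
      p <- db$peptide[sample(nrow(db), 1)]
      ch <- strsplit(p, "")[[1]]
      j <- sample(length(ch), 1)
      ch[j] <- sample(setdiff(c("A", "R", "N", "D"), ch[j]), 1)
      mt[i] <- paste(ch, collapse = ""); ic50[i] <- runif(1, 10, 499)
    } else {
      # weak binder: fails the 500 nM arm of the conjunction
      mt[i] <- rand_peptide(9); ic50[i] <- runif(1, 600, 9000)
    }
  }
  rec <- epitope_records(sprintf("p%03d", seq_len(n_pat)), mt,
                         vapply(mt, function(p) {
                           ch <- strsplit(p, "")[[1]]
                           k <- max(3, length(ch) - 2)
                           ch[k] <- if (ch[k] == "G") "T" else "G"
                           paste(ch, collapse = "")
                         }, character(1), USE.NAMES = FALSE),
                         ic50_mt = ic50, ic50_wt = 1000)
  hits <- search_all(rec, db, evalue_max = 10)
  calls <- call_viral_like(rec, hits)
  rate <- mean(calls)
  expect_lt(abs(rate - mean(planted)), 3 * sqrt(0.6 * 0.4 / n_pat))
})

test_that("filter configuration enforces threshold ordering", {
  expect_error(filter_config(noise_ic50_max = 100), "strong_binder")
  cfg <- filter_config()
  expect_equal(cfg$noise_ic50_max, 10000)
  expect_equal(cfg$fitness_ic50_max, 500)
  expect_equal(cfg$strong_binder_ic50_max, 200)
})
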