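test_that("recognition potential matches its logistic closed forms", {
  p <- fitness_params()
  expect_identical(recognition_potential(numeric(0), p), 0)
  expect_equal(recognition_potential(p$alpha, p), 0.5)
  expect_equal(recognition_potential(c(p$alpha, p$alpha), p), 2 / 3)
})

test_that("recognition potential is monotone, saturating, and bounded", {
  p <- fitness_params()
  set.seed(3)
  scores <- sort(runif(20, 0, 32))  # below floating-point saturation
  r <- vapply(scores, recognition_potential, numeric(1), params = p)
  expect_true(all(diff(r) > 0))          # increasing in the score
  expect_true(all(r < 1 & r >= 0))
  # adding a hit never decreases R
  base <- c(20, 25)
  expect_gte(recognition_potential(c(base, 10), p),
             recognition_potential(base, p))
  # saturation guard for overflow-scale scores
  expect_lt(recognition_potential(1e6, p), 1)
})

test_that("amplitude implements both normalization modes", {
  none <- fitness_params(amplitude_normalization = "none")
  norm <- fitness_params(amplitude_normalization = "reciprocal_max_wt")
  expect_equal(amplitude(100, 100, params = none), 1)
  expect_equal(amplitude(500, 50, params = none), 10)
  # halving the mutant affinity doubles A in both modes
  expect_equal(amplitude(500, 25, params = none),
               2 * amplitude(500, 50, params = none))
  expect_equal(amplitude(500, 25, 1000, norm), 2 * amplitude(500, 50, 1000, norm))
  # dissociation-constant correction: ratio shrunk by ic50_wt / max_wt
  expect_equal(amplitude(500, 50, 1000, norm), 10 * 500 / 1000)
  expect_error(amplitude(0, 10), "positive")
})

test_that("patient scoring takes the maximal product over qualifying epitopes", {
  p <- fitness_params(amplitude_normalization = "none")
  rec <- epitope_records("p1", c("SIINFEKL", "KLLEIFTEL", "GILGFVFTL"),
                         c("SIINFEKV", "KLLEIFSEL", "GILGFVFSL"),
                         ic50_mt = c(100, 200, 900),
                         ic50_wt = c(200, 2000, 1800))
  hits <- list(c(26), c(26, 26), c(40))   # scores at alpha give known R
  res <- score_patient(rec, hits, p)
  # epitope 3 fails the 500 nM threshold; products: 0.5*2 = 1, (2/3)*10
  expect_equal(res$n_epitopes, 2L)
  expect_equal(res$immunogenicity, (2 / 3) * 10)
  expect_equal(res$argmax_epitope, "KLLEIFTEL")
  expect_equal(res$tumor_fitness * res$immunogenicity, 1)
  # permuting epitope order changes nothing
  perm <- c(3, 1, 2)
  res2 <- score_patient(rec[perm, ], hits[perm], p)
  expect_equal(res2$immunogenicity, res$immunogenicity)
  expect_equal(res2$argmax_epitope, res$argmax_epitope)
})

test_that("patients with no qualifying epitope are flagged with zero score", {
  rec <- epitope_records("p1", "SIINFEKL", "SIINFEKV",
                         ic50_mt = 800, ic50_wt = 1000)
  res <- score_patient(rec, list(c(30)), fitness_params())
  expect_true(res$flagged)
  expect_identical(res$immunogenicity, 0)
  expect_true(is.na(res$tumor_fitness))
})

test_that("scoring matches an exhaustive product recomputation", {
  set.seed(12)
  p <- fitness_params()
  for (rep in 1:10) {
    k <- sample(1:10, 1)
    rec <- epitope_records("px",
                           vapply(rep(9, k), rand_peptide, character(1)),
                           vapply(rep(9, k), rand_peptide, character(1)),
                           ic50_mt = runif(k, 10, 499),
                           ic50_wt = runif(k, 10, 5000))
    hits <- lapply(seq_len(k), function(i) runif(sample(0:5, 1), 0, 33))
    res <- score_patient(rec, hits, p)
    # independent recomputation from raw ingredients
    z <- vapply(hits, function(s) sum(exp(-p$k * (p$alpha - s))), numeric(1))
    r <- ifelse(lengths(hits) == 0, 0, z / (1 + z))
    a <- (rec$ic50_wt / rec$ic50_mt) * rec$ic50_wt / max(rec$ic50_wt)
    expect_equal(res$immunogenicity, max(r * a))
    expect_equal(res$argmax_epitope, rec$peptide_mt[which.max(r * a)])
  }
})

test_that("immunogenicity is invariant to duplicating non-maximal epitopes", {
  p <- fitness_params(amplitude_normalization = "none")
  rec <- epitope_records("p1", c("SIINFEKL", "KLLEIFTEL"),
                         c("SIINFEKV", "KLLEIFSEL"),
                         ic50_mt = c(100, 200), ic50_wt = c(2000, 400))
  hits <- list(c(26), c(20))
  base <- score_patient(rec, hits, p)
  dup <- score_patient(rec[c(1, 2, 2), ], hits[c(1, 2, 2)], p)
  expect_equal(dup$immunogenicity, base$immunogenicity)
  # scaling every amplitude by c scales the maximum by c (via wild-type ic50)
  rec2 <- rec; rec2$ic50_wt <- rec$ic50_wt * 3
  expect_equal(score_patient(rec2, hits, p)$immunogenicity,
               3 * base$immunogenicity)
})

test_that("cohort-level fitness reproduces the worked example by hand", {
  ex <- worked_example()
  fit <- tumor_fitness(ex$neoepitopes, ex$db)
  res <- attr(fit, "results")
  names(res) <- fit$patient_id
  # WE01: planted hit scores exactly alpha = 26, so R is exactly 0.5;
  # A = (1000/100) * (1000/1000) = 10 under the reciprocal-max correction
  pe <- res$WE01$per_epitope
  expect_equal(pe$R[pe$peptide_mt == "WGAAAAAW"], 0.5)
  expect_equal(fit$immunogenicity[fit$patient_id == "WE01"], 5)
  expect_equal(fit$tumor_fitness[fit$patient_id == "WE01"], 0.2)
  # WE02 has no neoepitope under 500 nM
  expect_true(fit$flagged[fit$patient_id == "WE02"])
  expect_equal(fit$immunogenicity[fit$patient_id == "WE02"], 0)
})
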