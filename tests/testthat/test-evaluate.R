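test_that("recovery rate counts exact positional matches", {
  expect_equal(recovery_rate("ACGU", "ACGU"), 100)
  expect_equal(recovery_rate("ACGU", "AGGU"), 75)
  expect_equal(recovery_rate("AAAA", "UUUU"), 0)
  expect_error(recovery_rate("ACG", "ACGU"), "length mismatch")
})

test_that("macro-F1 matches worked examples and excludes absent classes", {
  expect_equal(macro_f1("ACGU", "ACGU"), 100)
  expect_equal(macro_f1("AUAU", "AAUU"), 50)
  expect_equal(macro_f1("UUUU", "AAAA"), 0)
  # pooling across pairs
  expect_equal(macro_f1(c("AA", "UU"), c("AA", "UU")), 100)
  expect_error(macro_f1(character(0), character(0)), "empty")
  expect_error(macro_f1("AC", "ACG"), "length mismatch")
})

test_that("sequence metrics agree with confusion-matrix oracles on random pairs", {
  withr::with_seed(55, {
    for (rep in 1:200) {
      n <- sample(2:60, 1)
      a <- sample(c("A", "U", "C", "G"), n, TRUE)
      b <- sample(c("A", "U", "C", "G"), n, TRUE)
      expect_equal(recovery_rate(paste(a, collapse = ""),
                                 paste(b, collapse = "")),
                   oracle_recovery(a, b), tolerance = 1e-9)
      expect_equal(macro_f1(paste(a, collapse = ""), paste(b, collapse = "")),
                   oracle_macro_f1(a, b), tolerance = 1e-9)
    }
  })
})

test_that("macro-F1 is bounded by 100 with equality only at identity, and per-sample mode averages", {
  withr::with_seed(56, {
    for (rep in 1:50) {
      n <- sample(4:30, 1)
      a <- sample(c("A", "U", "C", "G"), n, TRUE)
      b <- sample(c("A", "U", "C", "G"), n, TRUE)
      s <- macro_f1(paste(a, collapse = ""), paste(b, collapse = ""))
      expect_lte(s, 100)
      if (s == 100) expect_identical(a, b)
    }
  })
  expect_equal(macro_f1(c("AAAA", "UUUU"), c("AAAA", "AAAA"),
                        per_sample = TRUE), 50)
})

test_that("uniform random designs recover about 25 percent", {
  withr::with_seed(60, {
    a <- sample(c("A", "U", "C", "G"), 1e4, TRUE)
    b <- sample(c("A", "U", "C", "G"), 1e4, TRUE)
  })
  rec <- oracle_recovery(a, b)
  ci <- 100 * (0.25 + c(-1, 1) * qnorm(0.995) * sqrt(0.25 * 0.75 / 1e4))
  expect_gt(rec, ci[1])
  expect_lt(rec, ci[2])
})

test_that("secondary-structure accuracy counts symbol matches", {
  expect_equal(ss_accuracy("(((...)))", "(((...)))"), 100)
  expect_equal(ss_accuracy("(((...)))", "((.....))"), 100 * 7 / 9,
               tolerance = 1e-9)
  expect_equal(ss_accuracy("((.))", ".(.)."), 60)  # matches at positions 2-4
  expect_error(ss_accuracy("...", "...."), "length mismatch")
})

test_that("recovered sequence rate is the fraction of foldable designs", {
  expect_equal(recovered_sequence_rate(c(TRUE, TRUE, TRUE, FALSE)), 75)
  expect_equal(recovered_sequence_rate(rep(TRUE, 5)), 100)
  expect_error(recovered_sequence_rate(logical(0)), "empty")
})

test_that("rmsd handles identity, rigid motion, and raw comparisons", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-12)
  shift <- sweep(a, 2, c(3, -1, 2), `+`)
  expect_equal(rmsd(a, shift), 0, tolerance = 1e-9)
  tr <- withr::with_seed(3, random_rigid_transform())
  moved <- a %*% t(tr$R) + rep(tr$t, each = 10)
  expect_equal(rmsd(a, moved), 0, tolerance = 1e-9)
  # raw RMSD hand example
  expect_equal(rmsd(rbind(c(0, 0, 0), c(0, 0, 2)),
                    rbind(c(0, 0, 0), c(0, 0, 0)), superpose = FALSE),
               sqrt(2), tolerance = 1e-12)
  expect_error(rmsd(a, a[1:5, ]), "count mismatch")
  expect_error(rmsd(a[1:2, ], a[1:2, ], superpose = TRUE), "at least 3")
})

test_that("rmsd is symmetric, superposition never increases it, and matches bio3d", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      a <- matrix(rnorm(36, sd = 4), 12, 3)
      b <- a + matrix(rnorm(36, sd = 1), 12, 3)
      expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-9)
      expect_lte(rmsd(a, b, superpose = TRUE),
                 rmsd(a, b, superpose = FALSE) + 1e-12)
      # independent route: bio3d least-squares fit
      ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
      expect_equal(rmsd(a, b), ref, tolerance = 1e-3)
    }
  })
})

test_that("fold backends honor the backend contract", {
  stub <- stub_fold_backend()
  db <- stub$fold("ACGUACGUA")
  expect_equal(nchar(db), 9L)
  expect_true(oracle_balanced(db))
  expect_true(is.na(stub_fold_backend("fail")$fold("ACGU")))
  expect_equal(stub_fold_backend("dots")$fold("ACGU"), "....")
})

test_that("the vienna backend folds a GC hairpin via RNAfold", {
  skip_if(!nzchar(Sys.which("RNAfold")), "RNAfold not on PATH")
  be <- vienna_fold_backend()
  seq <- "GGGGGAAAACCCCC"
  db <- be$fold(seq)
  expect_equal(nchar(db), nchar(seq))
  expect_true(oracle_balanced(db))
  expect_true(grepl("\\(", db))  # a strong GC hairpin pairs
})

test_that("evaluate_design aggregates, stratifies by length bins, and uses backends", {
  refs <- list(list(sequence = "ACGUACGUA", secondary = new_rna_ss("(((...)))")),
               list(sequence = "AAAACCCC", secondary = new_rna_ss("((....))")))
  rep1 <- evaluate_design(list("ACGUACGUA", "AAAAGGGG"), refs)
  expect_s3_class(rep1, "design_report")
  expect_equal(rep1$aggregate$recovery_pct, mean(c(100, 50)))
  expect_null(rep1$aggregate$recovered_sequence_rate_pct)
  # failing backend: rate 0, accuracy absent
  rep2 <- evaluate_design(list("ACGUACGUA", "AAAAGGGG"), refs,
                          backend = stub_fold_backend("fail"))
  expect_equal(rep2$aggregate$recovered_sequence_rate_pct, 0)
  expect_null(rep2$aggregate$ss_accuracy_pct)
  # hairpin stub folds everything; accuracy computed against truths
  rep3 <- evaluate_design(list("ACGUACGUA", "AAAAGGGG"), refs,
                          backend = stub_fold_backend())
  expect_equal(rep3$aggregate$recovered_sequence_rate_pct, 100)
  expect_true(rep3$aggregate$ss_accuracy_pct > 0)
  # length bins: one item in each of Short/Medium/Long
  seqs <- vapply(c(30, 70, 150), function(n) strrep("A", n), "")
  refs2 <- lapply(seqs, function(s) list(sequence = s, secondary = NULL))
  rep4 <- evaluate_design(as.list(seqs), refs2)
  expect_equal(rep4$per_item$bin, c("Short", "Medium", "Long"))
  expect_equal(rep4$by_bin$n, c(1L, 1L, 1L))
  # boundary membership: 50 is Medium, 100 is Long
  expect_equal(as.character(rnadesign:::length_bin(c(49, 50, 99, 100))),
               c("Short", "Medium", "Medium", "Long"))
  expect_error(evaluate_design(list("A"), refs), "misaligned")
})
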