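test_that("charge and hydropathy features match hand values", {
  f <- compositional_features(protein_record("p", "DEDE"))
  expect_equal(f[["FCR"]], 1)
  expect_equal(f[["NCPR"]], -1)
  f <- compositional_features(protein_record("p", "KRDE"))
  expect_equal(f[["FCR"]], 1)
  expect_equal(f[["NCPR"]], 0)
  f <- compositional_features(protein_record("p", "GGGG"))
  expect_equal(f[["mean_hydropathy"]], -0.4)
})

test_that("residue fractions sum to 1 with X excluded", {
  f <- compositional_features(protein_record("p", "AXAXG"))
  expect_equal(sum(f[paste0("frac_", AA)]), 1)
  expect_equal(f[["frac_A"]], 2 / 3)
  expect_error(compositional_features(protein_record("p", "XXX")), "all-X")
})

test_that("|NCPR| <= FCR and both are reversal-invariant", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_sequence(sample(20:200, 1))
    f <- compositional_features(protein_record("p", s))
    expect_lte(abs(f[["NCPR"]]), f[["FCR"]] + 1e-12)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    fr <- compositional_features(protein_record("p", rev_s))
    expect_equal(f[["NCPR"]], fr[["NCPR"]])
    expect_equal(f[["FCR"]], fr[["FCR"]])
  }
})

test_that("molecular weight is residue-additive with one water", {
  expect_equal(molecular_weight(protein_record("p", "G")), 75.07,
               tolerance = 1e-4)
  mw_g <- molecular_weight(protein_record("p", "G"))
  mw_gg <- molecular_weight(protein_record("p", "GG"))
  expect_equal(mw_gg - mw_g, 57.052, tolerance = 1e-3)
  expect_error(protein_record("p", ""))
  # permutation invariance
  set.seed(5)
  s <- random_sequence(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(molecular_weight(protein_record("a", s)),
               molecular_weight(protein_record("b", perm)))
})

test_that("isoelectric point is the bisection root of the charge curve", {
  for (s in c("DDDDDDDD", "KKKKKKKK", "ACDEFGHIKLMNPQRSTVWY")) {
    rec <- protein_record("p", s)
    pi_hat <- isoelectric_point(rec)
    chars <- strsplit(s, "")[[1]]
    expect_lt(abs(proxitome:::protein_net_charge(chars, pi_hat)), 1e-4)
    expect_gt(pi_hat, 0); expect_lt(pi_hat, 14)
  }
  expect_lt(isoelectric_point(protein_record("d", "DDDDDDDD")), 4)
  expect_gt(isoelectric_point(protein_record("k", "KKKKKKKK")), 9.5)
})

test_that("annotation coverage merges overlaps and defaults to zero", {
  r <- protein_record("p", random_sequence(100),
                      annotations = data.frame(category = "RRM",
                                               start = 1, end = 50))
  expect_equal(unname(annotation_coverage(r, "RRM")), 0.5)
  expect_equal(unname(annotation_coverage(r, "disorder")), 0)
  r2 <- protein_record("p", random_sequence(100),
                       annotations = data.frame(category = c("dom", "dom"),
                                                start = c(1, 41),
                                                end = c(60, 100)))
  expect_equal(unname(annotation_coverage(r2, "dom")), 1)
  expect_error(protein_record("p", "AAA",
                              annotations = data.frame(category = "x",
                                                       start = 1, end = 9)),
               "outside")
})

test_that("MinMax normalization maps ranges to [0,1] and is idempotent", {
  m <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  n1 <- minmax_normalize(m)
  expect_equal(unname(n1[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(n1[, "b"]), c(0, 0, 0))
  expect_equal(minmax_normalize(n1), n1)
})

test_that("feature matrix assembly validates ids and normalizes", {
  set.seed(3)
  recs <- list(protein_record("a", random_sequence(50)),
               protein_record("b", random_sequence(60)))
  fm <- assemble_feature_matrix(recs)
  expect_true(all(fm >= 0 & fm <= 1))
  expect_equal(rownames(fm), c("a", "b"))
  recs_dup <- list(protein_record("a", "AAA"), protein_record("a", "CCC"))
  expect_error(assemble_feature_matrix(recs_dup), "duplicate")
})
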