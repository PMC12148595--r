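test_that("factor model RDMs match the hand-coded attribute oracle", {
  for (f in c("modality", "experience", "type")) {
    expect_equal(unclass(factor_rdm(f)), oracle_factor_matrix(f),
                 ignore_attr = TRUE)
  }
  # spot checks on specific condition pairs
  M <- factor_rdm("modality")
  expect_identical(M["HPA", "HIA"], 1)
  expect_identical(M["HPA", "LPF"], 0)
  E <- factor_rdm("experience")
  expect_identical(E["HPA", "LPA"], 1)
  expect_identical(E["HPA", "HIF"], 0)
  Tt <- factor_rdm("type")
  expect_identical(Tt["HPA", "HPF"], 1)
  expect_identical(Tt["HPA", "LIA"], 0)
  expect_error(factor_rdm("colour"))
})

test_that("independent model is all-ones off the diagonal", {
  I8 <- independent_rdm()
  expect_equal(diag(unclass(I8)), rep(0, 8), ignore_attr = TRUE)
  v <- rdm_vector(I8)
  expect_length(v, 28)
  expect_true(all(v == 1))
})

test_that("weighted combinations reproduce the graded-model arithmetic", {
  m2 <- combine_weighted(1, 1 / 2, 1 / 2)
  expect_equal(m2["HPA", "LIF"], 1)        # (1 + 1/2 + 1/2) / 2
  expect_equal(m2["HPA", "HIA"], 0.5)      # 1 / 2
  met <- combine_weighted(1, 1, 1)
  expect_equal(met["HPA", "LPA"], 1 / 3)
  expect_equal(unclass(combine_weighted(1, 0, 0)),
               unclass(factor_rdm("modality")), ignore_attr = TRUE)
  # linear before normalization: scaling all weights changes nothing
  expect_equal(unclass(combine_weighted(2, 2 / 3, 2 / 3)),
               unclass(combine_weighted(1, 1 / 3, 1 / 3)),
               ignore_attr = TRUE)
  expect_error(combine_weighted(0, 0, 0))
  expect_error(combine_weighted(-1, 0, 0))
})

test_that("candidate family has exactly the expected members", {
  fam <- candidate_family()
  expect_length(fam, 9)
  fam10 <- candidate_family(include_partial = TRUE)
  expect_length(fam10, 10)
  expect_true("Exp|Type" %in% names(fam10))
  oracle <- list(
    Independent = matrix(1, 8, 8) - diag(8),
    Modality = oracle_factor_matrix("modality"),
    Experience = oracle_factor_matrix("experience"),
    Type = oracle_factor_matrix("type"),
    `Mod|Exp|Type` = oracle_weighted_matrix(1, 1, 1),
    `Mod|(Exp|Type)/2` = oracle_weighted_matrix(1, 1 / 2, 1 / 2),
    `Mod|(Exp|Type)/3` = oracle_weighted_matrix(1, 1 / 3, 1 / 3),
    `Exp|(Mod|Type)/2` = oracle_weighted_matrix(1 / 2, 1, 1 / 2),
    `Exp|(Mod|Type)/3` = oracle_weighted_matrix(1 / 3, 1, 1 / 3),
    `Exp|Type` = oracle_weighted_matrix(0, 1, 1)
  )
  for (nm in names(fam10)) {
    expect_equal(unclass(fam10[[nm]]), oracle[[nm]], ignore_attr = TRUE,
                 label = nm)
  }
  # every member satisfies the RDM invariants and vector round-trips
  for (nm in names(fam10)) {
    m <- fam10[[nm]]
    expect_true(isSymmetric(unclass(m)))
    expect_true(all(diag(unclass(m)) == 0))
    expect_true(all(m >= 0))
    expect_equal(unclass(rdm_from_vector(rdm_vector(m))), unclass(m),
                 ignore_attr = TRUE)
  }
})

test_that("factor RDMs are invariant to relabeling within non-focal factors", {
  # swapping art/face stimuli (a non-focal factor) permutes conditions
  # HPA<->HPF, LPA<->LPF, HIA<->HIF, LIA<->LIF but leaves the modality
  # model unchanged
  p <- c(3, 4, 1, 2, 7, 8, 5, 6)
  M <- unclass(factor_rdm("modality"))
  expect_equal(M[p, p], M, ignore_attr = TRUE)
  E <- unclass(factor_rdm("experience"))
  expect_equal(E[p, p], E, ignore_attr = TRUE)
  # swapping high/low leaves modality and type models unchanged
  q <- c(2, 1, 4, 3, 6, 5, 8, 7)
  expect_equal(M[q, q], M, ignore_attr = TRUE)
  Tt <- unclass(factor_rdm("type"))
  expect_equal(Tt[q, q], Tt, ignore_attr = TRUE)
})

test_that("average_rdm averages entrywise and checks labels", {
  a <- independent_rdm()
  expect_equal(unclass(average_rdm(list(a))), unclass(a),
               ignore_attr = TRUE)
  b <- rdm(2 * (matrix(1, 8, 8) - diag(8)))
  z <- rdm(matrix(0, 8, 8))
  avg <- average_rdm(list(z, b))
  expect_true(all(rdm_vector(avg) == 1))
  c2 <- rdm(matrix(0, 8, 8), labels = rev(condition_labels()))
  expect_error(average_rdm(list(a, c2)), "label order")
})

test_that("rdm constructor enforces the invariants", {
  expect_error(rdm(matrix(1:9, 3, 3)), "symmetric")
  m <- matrix(1, 3, 3)
  expect_error(rdm(m), "zero diagonal")
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- -1
  expect_error(rdm(m), "nonnegative")
})
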