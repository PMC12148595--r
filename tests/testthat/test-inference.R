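test_that("whitening matrix construction matches the contrast oracle", {
  V <- whitening_matrix(8)
  C <- attr(V, "C")
  expect_equal(dim(C), c(28L, 8L))
  # every squared distance involves exactly 2 conditions
  expect_true(all(diag(C %*% t(C)) == 2))
  # unit trace normalization
  expect_equal(sum(diag(V)), 1)
  # symmetric positive definite across condition counts
  for (k in 4:8) {
    Vk <- whitening_matrix(k)
    expect_true(isSymmetric(unclass(Vk)))
    expect_gt(min(eigen(Vk, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  expect_error(whitening_matrix(2), "at least 3")
})

test_that("identity whitening reduces to the plain cosine", {
  Vi <- whitening_matrix(8, mode = "identity")
  vecs <- random_rdm_vectors(20, seed = 8)
  for (j in seq_len(ncol(vecs))) {
    a <- vecs[, j]
    b <- vecs[, (j %% ncol(vecs)) + 1]
    expect_lt(abs(whitened_cosine(a, b, Vi) - plain_cosine(a, b)), 1e-12)
  }
})

test_that("whitened cosine: self-similarity, orthogonality, scale invariance", {
  V <- whitening_matrix(8)
  Vi <- whitening_matrix(8, mode = "identity")
  v <- random_rdm_vectors(1, seed = 3)[, 1]
  expect_equal(whitened_cosine(v, v, V), 1, tolerance = 1e-12)
  a <- c(1, rep(0, 27)); b <- c(0, 1, rep(0, 26))
  expect_equal(whitened_cosine(a, b, Vi), 0)
  w <- random_rdm_vectors(1, seed = 4)[, 1]
  expect_lt(abs(whitened_cosine(3.7 * v, w, V) - whitened_cosine(v, w, V)),
            1e-12)
  expect_error(whitened_cosine(rep(0, 28), v, V), "zero-norm")
})

test_that("noise ceiling brackets behave as specified", {
  V <- whitening_matrix(8)
  one <- rdm_from_vector(runif(28, 0.5, 1.5))
  same <- list(one, one, one)
  nc <- noise_ceiling(same, V)
  expect_equal(nc$lower, 1, tolerance = 1e-12)
  expect_equal(nc$upper, 1, tolerance = 1e-12)
  # lower <= upper over random datasets
  set.seed(12)
  for (i in 1:100) {
    rdms <- lapply(1:5, function(s) runif(28, 0.1, 2))
    nc <- noise_ceiling(rdms, V)
    expect_lte(nc$lower, nc$upper + 1e-12)
  }
  expect_error(noise_ceiling(list(one), V), "at least 2")
})

test_that("toy noise ceiling matches a brute-force plain-cosine oracle", {
  Vi <- whitening_matrix(8, mode = "identity")
  vecs <- random_rdm_vectors(3, seed = 99)
  nc <- noise_ceiling(lapply(1:3, function(s) vecs[, s]), Vi)
  up <- mean(sapply(1:3, function(s) {
    plain_cosine(vecs[, s], rowMeans(vecs))
  }))
  lo <- mean(sapply(1:3, function(s) {
    plain_cosine(vecs[, s], rowMeans(vecs[, -s]))
  }))
  expect_equal(nc$upper, up, tolerance = 1e-12)
  expect_equal(nc$lower, lo, tolerance = 1e-12)
})

test_that("bootstrap evaluation is seeded, honest about degeneracy", {
  V <- whitening_matrix(8)
  models <- candidate_family()
  one <- rdm_from_vector(runif(28, 0.5, 1.5))
  same <- list(S1 = one, S2 = one, S3 = one)
  ev <- bootstrap_evaluate(same, models, V, n_boot = 50, seed = 1)
  expect_true(all(ev$table$ci_hi - ev$table$ci_lo < 1e-12))
  g <- geometry_spec(n_channels = 30)
  rdms <- subject_rdms(generate_patterns(6, g, seed = 2))
  e1 <- bootstrap_evaluate(rdms, models, V, n_boot = 100, seed = 7)
  e2 <- bootstrap_evaluate(rdms, models, V, n_boot = 100, seed = 7)
  expect_identical(e1$table, e2$table)
  e3 <- bootstrap_evaluate(rdms, models, V, n_boot = 100, seed = 8)
  expect_false(identical(e1$table, e3$table))
  expect_error(bootstrap_evaluate(rdms, models, V, n_boot = 0), "n_boot")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  V <- whitening_matrix(8, mode = "identity")
  models <- candidate_family()["Modality"]
  set.seed(50)
  width <- vapply(c(10, 40, 160), function(n) {
    # iid subject RDMs around the modality geometry
    rdms <- lapply(seq_len(n), function(s) {
      rdm_vector(factor_rdm("modality")) + runif(28, 0, 0.6)
    })
    ev <- bootstrap_evaluate(rdms, models, V, n_boot = 400, seed = 5)
    ev$table$ci_hi - ev$table$ci_lo
  }, numeric(1))
  expect_gt(width[1] / width[2], 1.3)
  expect_gt(width[2] / width[3], 1.3)
})

test_that("score matrix is invariant to subject order and consistent relabeling", {
  models <- candidate_family()
  V <- whitening_matrix(8)
  g <- recovery_geometry("Mod|(Exp|Type)/2")
  rdms <- subject_rdms(generate_patterns(8, g, seed = 21))
  sc <- model_scores(rdms, models, V)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  sc_perm <- model_scores(rdms[perm], models, V)
  expect_equal(sc[perm, ], sc_perm, ignore_attr = TRUE)
  expect_equal(colMeans(sc), colMeans(sc_perm))
})

test_that("compare_models runs the three test families correctly", {
  V <- whitening_matrix(8, mode = "identity")
  models <- candidate_family()
  models$ModalityCopy <- models$Modality
  g <- recovery_geometry("Modality")
  rdms <- subject_rdms(generate_patterns(12, g, seed = 33))
  ev <- bootstrap_evaluate(rdms, models, V, n_boot = 100, seed = 3)
  nc <- noise_ceiling(rdms, V)
  cmp <- compare_models(ev, nc)
  # identical models are exact ties
  tie <- cmp$pairwise[cmp$pairwise$model_a == "Modality" &
                        cmp$pairwise$model_b == "ModalityCopy", ]
  expect_equal(tie$t, 0)
  expect_equal(tie$p, 1)
  expect_false(tie$significant)
  # BH adjustment matches a hand-coded step-up oracle
  expect_equal(cmp$pairwise$q, hand_bh(cmp$pairwise$p))
  expect_true(all(cmp$pairwise$q >= cmp$pairwise$p - 1e-15))
  expect_true(all(cmp$vs_ceiling$p_bonferroni <= 1))
  # planted modality data: modality beats experience and type, is above 0,
  # and is not below the ceiling
  pw <- cmp$pairwise
  for (other in c("Experience", "Type")) {
    row <- pw[pw$model_a == "Modality" & pw$model_b == other, ]
    expect_true(row$significant)
    expect_gt(row$t, 0)
  }
  vz <- cmp$vs_zero
  expect_true(vz$significant[vz$model == "Modality"])
  vc <- cmp$vs_ceiling
  expect_false(vc$below_ceiling[vc$model == "Modality"])
})

test_that("the hand BH oracle reproduces the two-p worked example", {
  # p = (0.001, 0.5): q = (0.002, 0.5); only the first survives q < 0.01
  q <- hand_bh(c(0.001, 0.5))
  expect_equal(q, c(0.002, 0.5))
  expect_equal(q < 0.01, c(TRUE, FALSE))
})
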