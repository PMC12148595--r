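# deterministic geometry (no between-subject variability) for exactness
exact_geom <- function(...) {
  geometry_spec(..., subject_tau = 0, spike_prob = 0)
}

test_that("noiseless generated means reproduce the planted RDM exactly", {
  g <- exact_geom(w_mod = 1, w_exp = 1 / 3, w_type = 1 / 3, noise_sd = 0)
  ps <- generate_patterns(2, g, seed = 4)
  planted <- rdm_vector(combine_weighted(1, 1 / 3, 1 / 3))
  for (s in 1:2) {
    m <- ps$data[s, , ]
    rownames(m) <- ps$labels
    v <- rdm_vector(compute_neural_rdm(m, zscore = FALSE))
    expect_lt(max(abs(v / max(v) - planted)), 1e-10)
  }
})

test_that("pure modality geometry gives equidistant cross-modality pairs", {
  g <- exact_geom(w_mod = 1, noise_sd = 0)
  ps <- generate_patterns(1, g, seed = 9)
  m <- ps$data[1, , ]
  rownames(m) <- ps$labels
  d <- unclass(compute_neural_rdm(m, zscore = FALSE))
  M <- unclass(factor_rdm("modality"))
  cross <- d[M == 1]
  within <- d[M == 0 & row(d) != col(d)]
  expect_lt(diff(range(cross)) / mean(cross), 1e-10)
  expect_lt(max(abs(within)), 1e-8 * mean(cross))
})

test_that("equal-weights geometry is recovered by rank correlation", {
  g <- exact_geom(w_mod = 1, w_exp = 1, w_type = 1, noise_sd = 0.2,
                  snr = 400)
  ps <- generate_patterns(30, g, seed = 11)
  avg <- average_rdm(subject_rdms(ps))
  model <- combine_weighted(1, 1, 1)
  expect_gt(cor(rdm_vector(avg), rdm_vector(model)), 0.99)
  # the model's tied entries cap Spearman at ~0.917; require near-cap
  expect_gt(cor(rdm_vector(avg), rdm_vector(model), method = "spearman"),
            0.9)
})

test_that("pattern generation is reproducible and honors the seed", {
  g <- geometry_spec()
  a <- generate_patterns(3, g, seed = 5)
  b <- generate_patterns(3, g, seed = 5)
  expect_identical(a$data, b$data)
  c2 <- generate_patterns(3, g, seed = 6)
  expect_false(identical(a$data, c2$data))
})

test_that("z-scoring standardizes with the population-SD convention", {
  expect_equal(as.numeric(zscore_patterns(matrix(c(1, 2, 3), 1))),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # idempotence
  x <- matrix(rnorm(40), 4, 10)
  z1 <- zscore_patterns(x)
  expect_equal(zscore_patterns(z1), z1, tolerance = 1e-12)
  # degenerate constant pattern names the culprit
  expect_error(zscore_patterns(matrix(1, 1, 5)), "zero-variance")
  g <- geometry_spec(n_channels = 20)
  ps <- generate_patterns(2, g, seed = 2)
  ps$data[2, 3, ] <- 7
  expect_error(zscore_patterns(ps), "S02.*HPF")
})

test_that("neural RDM equals a brute-force double loop on toy patterns", {
  set.seed(31)
  X <- matrix(rnorm(8 * 5), 8, 5)
  rownames(X) <- condition_labels()
  fast <- unclass(compute_neural_rdm(X, zscore = TRUE))
  brute <- brute_sq_dist(zscore_patterns(X))
  expect_lt(max(abs(fast - brute)), 1e-12)
  # raw mode worked example: (0,0) vs (3,4) -> 25
  Y <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  d <- as.matrix(compute_neural_rdm(Y, zscore = FALSE))
  expect_equal(d[1, 2], 25)
  # identical patterns give an all-zero RDM
  Z <- matrix(rep(rnorm(5), each = 8), 8, 5)
  rownames(Z) <- condition_labels()
  expect_true(all(compute_neural_rdm(Z, zscore = FALSE) == 0))
})

test_that("masking and missing-condition errors behave as specified", {
  g <- geometry_spec(n_channels = 20)
  ps <- generate_patterns(2, g, seed = 3)
  m <- ps$data[1, , ]
  rownames(m) <- ps$labels
  mask <- rep(c(TRUE, FALSE), 10)
  rd <- compute_neural_rdm(m, mask = mask, zscore = FALSE)
  expect_equal(unclass(rd), brute_sq_dist(m[, mask]), ignore_attr = TRUE)
  expect_error(compute_neural_rdm(m, mask = c(TRUE, rep(FALSE, 19))),
               "at least 2")
  m["LIF", ] <- NA
  expect_error(compute_neural_rdm(m), "LIF")
})

test_that("embedding dimension below the geometry rank errors", {
  g <- exact_geom(w_mod = 1, w_exp = 1, w_type = 1, embed_dim = 2)
  expect_error(generate_patterns(1, g, seed = 1), "embed_dim")
  g2 <- exact_geom(w_mod = 1, embed_dim = 5, noise_sd = 0)
  ps <- generate_patterns(1, g2, seed = 1) # padding with zero directions is fine
  expect_equal(dim(ps$data), c(1L, 8L, 200L))
})

test_that("geometry_spec validates its inputs", {
  expect_error(geometry_spec(w_mod = -1), "nonnegative")
  expect_error(geometry_spec(w_mod = 0), "at least one weight")
  expect_error(geometry_spec(n_channels = 4), "at least 8")
  expect_error(geometry_spec(noise_sd = -1))
  g <- geometry_spec(independent = TRUE)
  expect_true(g$independent)
})
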