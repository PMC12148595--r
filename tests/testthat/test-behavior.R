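test_that("complete-case filter counts and removes missing rows", {
  r <- do.call(rbind, lapply(1:20, function(i) {
    pair_ratings(c(5, 5, 5), c(4, 4, 4), stimulus = sprintf("A%02d", i))
  }))
  expect_equal(complete_case_filter(r, quiet = TRUE), r,
               ignore_attr = TRUE)
  r2 <- r
  r2$beauty[7] <- NA
  expect_message(out <- complete_case_filter(r2), "2.5%")
  expect_equal(nrow(out), 39)
  expect_equal(unname(attr(out, "missingness")["beauty"]), 1 / 40)
  r3 <- r
  r3$moving <- NA
  expect_error(complete_case_filter(r3, quiet = TRUE), "all rows")
})

test_that("dissimilarity score reproduces the worked examples", {
  expect_equal(dissimilarity_score(pair_ratings(c(5, 5, 5), c(5, 5, 5)))$S, 0)
  expect_equal(dissimilarity_score(pair_ratings(c(6, 2, 4), c(4, 5, 4)))$S, 13)
  expect_equal(dissimilarity_score(pair_ratings(c(7, 7, 7), c(1, 1, 1)))$S, 108)
})

test_that("the score is symmetric and dimension-order invariant", {
  a <- pair_ratings(c(6, 2, 4), c(4, 5, 4))
  # modality swap: exchange the rating triples
  b <- pair_ratings(c(4, 5, 4), c(6, 2, 4))
  expect_equal(dissimilarity_score(a)$S, dissimilarity_score(b)$S)
  # permuting the dimension columns leaves S unchanged
  a2 <- a
  a2[, c("pleasure", "beauty", "moving")] <-
    a[, c("moving", "pleasure", "beauty")]
  expect_equal(dissimilarity_score(a2)$S, dissimilarity_score(a)$S)
})

test_that("unpaired trials are skipped and duplicates rejected", {
  a <- rbind(pair_ratings(c(5, 5, 5), c(4, 4, 4)),
             pair_ratings(c(3, 3, 3), c(3, 3, 3), stimulus = "A02")[1, ])
  expect_message(s <- dissimilarity_score(a), "skipped 1")
  expect_equal(nrow(s), 1)
  dup <- rbind(pair_ratings(c(5, 5, 5), c(4, 4, 4)),
               pair_ratings(c(5, 5, 5), c(4, 4, 4)))
  expect_error(dissimilarity_score(dup), "duplicated")
  # vividness of the paired imagery trial is carried along
  s2 <- dissimilarity_score(pair_ratings(c(5, 5, 5), c(4, 4, 4),
                                         vividness = 3))
  expect_equal(s2$vividness, 3)
})

test_that("experience labeling excludes the midpoint and splits 1-3/5-7", {
  r <- do.call(rbind, lapply(1:7, function(v) {
    pair_ratings(c(v, 4, 4), c(v, 4, 4), stimulus = sprintf("A%02d", v))
  }))
  r$moving <- rep(1:7, each = 2)
  lab <- label_experience(r, dimension = "moving")
  expect_false(any(lab$moving == 4))
  expect_equal(nrow(lab), 12)
  expect_true(all(lab$experience[lab$moving <= 3] == "low"))
  expect_true(all(lab$experience[lab$moving >= 5] == "high"))
  expect_true(!is.null(attr(lab, "cell_counts")))
  expect_error(label_experience(r, dimension = "awe"), "not present")
})

test_that("high-vividness subset keeps 6-7 trials with their pairs", {
  r7 <- pair_ratings(c(5, 5, 5), c(4, 4, 4), vividness = 7)
  expect_equal(nrow(suppressMessages(subset_high_vividness(r7))), 2)
  r5 <- pair_ratings(c(5, 5, 5), c(4, 4, 4), vividness = 5)
  out <- suppressMessages(suppressWarnings(subset_high_vividness(r5)))
  expect_equal(nrow(out), 0)  # the perception pair goes too
  mixed <- rbind(
    pair_ratings(c(5, 5, 5), c(4, 4, 4), vividness = 7, stimulus = "A01"),
    pair_ratings(c(5, 5, 5), c(4, 4, 4), vividness = 2, stimulus = "A02"),
    pair_ratings(c(5, 5, 5), c(4, 4, 4), vividness = 6, stimulus = "A03",
                 subject = "S02"))
  out <- suppressMessages(subset_high_vividness(mixed))
  expect_equal(nrow(out), 4)
  ret <- attr(out, "retention")
  expect_equal(as.integer(ret[c("S01", "S02")]), c(1L, 1L))
})
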