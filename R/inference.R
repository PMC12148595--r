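#' Whitening matrix for vectorized RDM comparison
#'
#' Squared-Euclidean distance estimates of condition pairs are correlated
#' because pairs share conditions. Under isotropic pattern noise, the
#' covariance of the vectorized distances is proportional to
#' `(C C') * (C C')` (elementwise square), where `C` is the
#' pairs x conditions contrast matrix whose row for pair (i, j) is
#' `e_i - e_j`. The whitened cosine similarity measures angles in the
#' metric of the inverse of this matrix; `mode = "identity"` falls back to
#' the plain cosine.
#'
#' @param n_conditions Number of conditions (>= 3; default 8).
#' @param mode `"distance-covariance"` (default) or `"identity"`.
#' @return A `whitening_matrix`: the pairs x pairs matrix, normalized to
#'   unit trace, with attributes `mode` and `C`.
#' @export
whitening_matrix <- function(n_conditions = 8,
                             mode = c("distance-covariance", "identity")) {
  mode <- match.arg(mode)
  if (n_conditions < 3) stop("n_conditions must be at least 3")
  k <- n_conditions
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  C <- matrix(0, np, k)
  C[cbind(seq_len(np), pairs[, 1])] <- 1
  C[cbind(seq_len(np), pairs[, 2])] <- -1
  V <- if (mode == "identity") diag(np) else (C %*% t(C))^2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("whitening matrix is singular")
  V <- V / sum(diag(V))
  structure(V, mode = mode, C = C, class = c("whitening_matrix",
                                             "matrix", "array"))
}

#' Whitened cosine similarity between two RDMs
#'
#' `s = d1' V^-1 d2 / sqrt((d1' V^-1 d1)(d2' V^-1 d2))` on the vectorized
#' upper triangles. Invariant to positive rescaling of either RDM; equals
#' the plain cosine when `V` is the identity.
#'
#' @param d_model,d_data `rdm` objects or vectorized RDMs (same length and
#'   label order).
#' @param V A [whitening_matrix()] (defaults to distance-covariance mode).
#' @return Similarity in \[-1, 1\].
#' @export
whitened_cosine <- function(d_model, d_data, V = whitening_matrix()) {
  v1 <- if (inherits(d_model, "rdm")) rdm_vector(d_model) else
    as.numeric(d_model)
  v2 <- if (inherits(d_data, "rdm")) rdm_vector(d_data) else
    as.numeric(d_data)
  if (length(v1) != length(v2)) stop("vectorized RDM lengths differ")
  if (length(v1) != nrow(V)) stop("whitening matrix size mismatch")
  Vi1 <- solve(V, v1)
  Vi2 <- solve(V, v2)
  n1 <- sum(v1 * Vi1)
  n2 <- sum(v2 * Vi2)
  if (n1 <= 0 || n2 <= 0) stop("zero-norm RDM vector")
  sum(v1 * Vi2) / sqrt(n1 * n2)
}

#' Per-subject model score matrix
#'
#' Whitened-cosine similarity of every subject RDM to every candidate
#' model, the raw material of [bootstrap_evaluate()] and
#' [compare_models()].
#'
#' @param subject_rdms List of per-subject `rdm`s (or vectorized RDMs).
#' @param models Named list of model `rdm`s.
#' @param V A [whitening_matrix()].
#' @return subjects x models numeric matrix.
#' @export
model_scores <- function(subject_rdms, models = candidate_family(),
                         V = whitening_matrix()) {
  score_matrix(subject_rdms, models, V)
}

# internal: per-subject x per-model whitened-cosine score matrix
score_matrix <- function(subject_rdms, models, V) {
  mv <- lapply(models, function(m) if (inherits(m, "rdm")) rdm_vector(m)
               else as.numeric(m))
  Vinv_m <- lapply(mv, function(v) solve(V, v))
  nm <- vapply(seq_along(mv), function(j) sum(mv[[j]] * Vinv_m[[j]]),
               numeric(1))
  out <- matrix(NA_real_, length(subject_rdms), length(models),
                dimnames = list(names(subject_rdms), names(models)))
  for (s in seq_along(subject_rdms)) {
    d <- if (inherits(subject_rdms[[s]], "rdm")) {
      rdm_vector(subject_rdms[[s]])
    } else {
      as.numeric(subject_rdms[[s]])
    }
    Vd <- solve(V, d)
    nd <- sum(d * Vd)
    if (nd <= 0) stop("zero-norm subject RDM")
    for (j in seq_along(mv)) {
      out[s, j] <- sum(mv[[j]] * Vd) / sqrt(nm[j] * nd)
    }
  }
  out
}

#' Noise ceiling for RDM model performance
#'
#' Brackets the performance that the (unknown) true data-generating model
#' could achieve given between-subject variability: the upper bound is the
#' mean similarity of each subject's RDM to the all-subject mean RDM
#' (optimistic, the target includes the subject itself); the lower bound
#' is the mean similarity to the leave-one-out mean of the other subjects
#' (pessimistic).
#'
#' @param subject_rdms List of per-subject `rdm`s (>= 2).
#' @param V A [whitening_matrix()].
#' @return A `noise_ceiling`: list with `lower`, `upper` and the
#'   per-subject similarity vectors `lower_by_subject`,
#'   `upper_by_subject`.
#' @export
noise_ceiling <- function(subject_rdms, V = whitening_matrix()) {
  n <- length(subject_rdms)
  if (n < 2) stop("need at least 2 subjects for a noise ceiling")
  vecs <- vapply(subject_rdms, function(r) {
    if (inherits(r, "rdm")) rdm_vector(r) else as.numeric(r)
  }, numeric(nrow(V)))
  tot <- rowSums(vecs)
  up <- lo <- numeric(n)
  for (s in seq_len(n)) {
    up[s] <- whitened_cosine(vecs[, s], tot / n, V)
    lo[s] <- whitened_cosine(vecs[, s], (tot - vecs[, s]) / (n - 1), V)
  }
  structure(list(lower = mean(lo), upper = mean(up),
                 lower_by_subject = lo, upper_by_subject = up),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Noise ceiling: lower = %.4f, upper = %.4f (n = %d)\n",
              x$lower, x$upper, length(x$lower_by_subject)))
  invisible(x)
}

#' Evaluate candidate models with subject-level bootstrap
#'
#' Computes the per-subject whitened-cosine score of every candidate
#' model, then resamples subjects with replacement `n_boot` times to
#' obtain the bootstrap SEM and percentile 95% CI of each model's mean
#' score.
#'
#' @param subject_rdms List of per-subject `rdm`s.
#' @param models Named list of model `rdm`s (default [candidate_family()]).
#' @param V A [whitening_matrix()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling.
#' @return A `model_evaluation`: list with `scores` (subjects x models),
#'   `table` (model, mean, sem, ci_lo, ci_hi), `n_boot`, `seed`, and the
#'   whitening `mode`.
#' @export
bootstrap_evaluate <- function(subject_rdms, models = candidate_family(),
                               V = whitening_matrix(), n_boot = 2000,
                               seed = 1) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (length(subject_rdms) < 2) stop("need at least 2 subjects")
  sc <- score_matrix(subject_rdms, models, V)
  set.seed(seed)
  n <- nrow(sc)
  boot_means <- matrix(NA_real_, n_boot, ncol(sc),
                       dimnames = list(NULL, colnames(sc)))
  for (b in seq_len(n_boot)) {
    boot_means[b, ] <- colMeans(sc[sample.int(n, n, replace = TRUE), ,
                                   drop = FALSE])
  }
  tab <- data.frame(
    model = colnames(sc),
    mean = colMeans(sc),
    sem = apply(boot_means, 2, sd),
    ci_lo = apply(boot_means, 2, quantile, 0.025, names = FALSE),
    ci_hi = apply(boot_means, 2, quantile, 0.975, names = FALSE),
    row.names = NULL
  )
  structure(list(scores = sc, table = tab, n_boot = n_boot, seed = seed,
                 mode = attr(V, "mode")),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, digits = 4, ...) {
  cat(sprintf("Model evaluation (%s whitening, %d bootstrap resamples)\n",
              x$mode, x$n_boot))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.model_evaluation <- function(x, ceiling = NULL, las = 2, ...) {
  tab <- x$table
  ylim <- range(0, tab$ci_hi, if (!is.null(ceiling)) ceiling$upper)
  bp <- barplot(tab$mean, names.arg = tab$model, las = las,
                ylim = ylim * 1.05, ylab = "whitened cosine similarity",
                ...)
  segments(bp, tab$ci_lo, bp, tab$ci_hi)
  if (!is.null(ceiling)) {
    rect(min(bp) - 0.5, ceiling$lower, max(bp) + 0.5, ceiling$upper,
         col = grDevices::adjustcolor("grey", 0.4), border = NA)
  }
  invisible(x)
}

#' Model comparison tests
#'
#' Runs the three statistical comparisons of the RSA stage on the
#' per-subject score matrix of a [bootstrap_evaluate()] result:
#'
#' * all pairwise model comparisons with paired two-tailed t-tests,
#'   Benjamini-Hochberg FDR adjusted (significant at `q < fdr_q`);
#' * each model against zero (one-sample two-tailed t-test);
#' * each model against the per-subject lower noise-ceiling values
#'   (paired t-test of the deficiency, one-sided: is the model
#'   significantly *below* the ceiling?), Bonferroni adjusted for the
#'   number of models.
#'
#' Zero-variance differences (e.g. two identical models) are reported as
#' exact ties with `t = 0`, `p = 1`.
#'
#' @param evaluation A `model_evaluation`.
#' @param ceiling A [noise_ceiling()] computed from the same subjects.
#' @param fdr_q FDR threshold for pairwise significance (default 0.01).
#' @param alpha Significance level for the vs-zero and vs-ceiling tests.
#' @return A `comparison_table`: list of data.frames `pairwise`,
#'   `vs_zero`, `vs_ceiling`.
#' @export
compare_models <- function(evaluation, ceiling, fdr_q = 0.01,
                           alpha = 0.05) {
  sc <- evaluation$scores
  mods <- colnames(sc)
  nm <- length(mods)

  paired_t <- function(a, b, alternative = "two.sided") {
    d <- a - b
    if (all(d == 0) || sd(d) == 0) {
      return(list(t = 0, p = if (alternative == "two.sided") 1 else 1))
    }
    tt <- t.test(a, b, paired = TRUE, alternative = alternative)
    list(t = unname(tt$statistic), p = tt$p.value)
  }

  pw <- do.call(rbind, lapply(seq_len(nm - 1), function(i) {
    do.call(rbind, lapply((i + 1):nm, function(j) {
      r <- paired_t(sc[, i], sc[, j])
      data.frame(model_a = mods[i], model_b = mods[j], t = r$t, p = r$p)
    }))
  }))
  pw$q <- p.adjust(pw$p, method = "BH")
  pw$significant <- pw$q < fdr_q

  vz <- do.call(rbind, lapply(seq_len(nm), function(j) {
    x <- sc[, j]
    if (sd(x) == 0) {
      data.frame(model = mods[j], t = if (all(x == 0)) 0 else Inf,
                 p = if (all(x == 0)) 1 else 0)
    } else {
      tt <- t.test(x, mu = 0)
      data.frame(model = mods[j], t = unname(tt$statistic), p = tt$p.value)
    }
  }))
  vz$significant <- vz$p < alpha

  lo <- ceiling$lower_by_subject
  vc <- do.call(rbind, lapply(seq_len(nm), function(j) {
    r <- paired_t(sc[, j], lo, alternative = "less")
    data.frame(model = mods[j], t = r$t, p = r$p)
  }))
  vc$p_bonferroni <- pmin(vc$p * nm, 1)
  vc$below_ceiling <- vc$p_bonferroni < alpha

  structure(list(pairwise = pw, vs_zero = vz, vs_ceiling = vc,
                 fdr_q = fdr_q, alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Pairwise comparisons (paired t, BH-FDR q < %g): %d of %d significant\n",
              x$fdr_q, sum(x$pairwise$significant), nrow(x$pairwise)))
  cat(sprintf("Models above zero: %d of %d\n",
              sum(x$vs_zero$significant), nrow(x$vs_zero)))
  cat(sprintf("Models below the lower noise ceiling (Bonferroni): %d of %d\n",
              sum(x$vs_ceiling$below_ceiling), nrow(x$vs_ceiling)))
  invisible(x)
}
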