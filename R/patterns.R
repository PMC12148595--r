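#' Planted representational geometry
#'
#' Describes the ground-truth geometry used by [generate_patterns()]: a
#' target squared-distance matrix over the 8 conditions,
#' `D* = w_mod*Modality + w_exp*Experience + w_type*Type` (normalized to
#' maximum entry 1), the number of measurement channels (voxels), the
#' channel noise SD, and the between-subject variability of the planted
#' weights.
#'
#' The overall signal level is parametrized by `snr`, the ratio of the
#' maximum planted squared distance to the expected noise-induced squared
#' distance `2 * n_channels * noise_sd^2` that plain (non-cross-validated)
#' distance estimates accumulate. Between-subject variability has two
#' parts, both acting on the planted weights per subject: a multiplicative
#' lognormal spread (`subject_tau`, preserving the population geometry)
#' and sparse heavy-tailed "idiosyncrasy spikes" (`spike_prob`,
#' `spike_sd`, truncated below at 0) through which a minority of subjects
#' express additional attribute dimensions. See the package vignette for
#' why variability around a pure single-factor geometry must be sparse.
#'
#' @param w_mod,w_exp,w_type Nonnegative planted weights.
#' @param independent If `TRUE`, plant the Independent geometry (all
#'   conditions equidistant) instead of a weighted combination; mutually
#'   exclusive with nonzero weights.
#' @param n_channels Number of measurement channels P (>= 8).
#' @param noise_sd Channel noise SD sigma (>= 0).
#' @param snr Max planted squared distance divided by `2*P*sigma^2`.
#' @param embed_dim Embedding rank; defaults to the rank of the
#'   double-centered planted matrix. Must be at least that rank.
#' @param subject_tau SD of the lognormal weight spread across subjects.
#' @param spike_prob,spike_sd Probability and SD of sparse additive weight
#'   spikes per subject and factor (truncated at zero).
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(w_mod = 1, w_exp = 0, w_type = 0,
                          independent = FALSE,
                          n_channels = 200, noise_sd = 1, snr = 400,
                          embed_dim = NULL,
                          subject_tau = 0.25, spike_prob = 0.1,
                          spike_sd = 0.35) {
  w <- c(w_mod = w_mod, w_exp = w_exp, w_type = w_type)
  if (any(w < 0)) stop("geometry weights must be nonnegative")
  if (independent && any(w != c(1, 0, 0)) && any(w > 0)) {
    stop("'independent' is mutually exclusive with explicit weights")
  }
  if (!independent && all(w == 0)) {
    stop("at least one weight must be positive (or set independent = TRUE)")
  }
  if (n_channels < 8) stop("n_channels must be at least 8")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (snr <= 0) stop("snr must be positive")
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0,1]")
  structure(list(
    w = if (independent) NULL else unname(w) / max(w),
    independent = independent,
    n_channels = as.integer(n_channels), noise_sd = noise_sd, snr = snr,
    embed_dim = embed_dim,
    subject_tau = subject_tau, spike_prob = spike_prob, spike_sd = spike_sd
  ), class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  geo <- if (x$independent) "Independent" else
    sprintf("weights (%.3g, %.3g, %.3g)", x$w[1], x$w[2], x$w[3])
  cat(sprintf(
    "Planted geometry: %s, P = %d channels, noise sd = %.3g, snr = %.3g\n",
    geo, x$n_channels, x$noise_sd, x$snr))
  cat(sprintf(
    "Subject variability: lognormal tau = %.3g, spikes p = %.3g sd = %.3g\n",
    x$subject_tau, x$spike_prob, x$spike_sd))
  invisible(x)
}

# planted squared-distance matrix for a weight vector (max entry 1)
planted_dstar <- function(w = NULL, independent = is.null(w)) {
  if (independent) unclass(independent_rdm())
  else unclass(combine_weighted(w[1], w[2], w[3]))
}

# per-subject weight draw under the geometry's variability model
draw_subject_weights <- function(geom) {
  if (geom$independent) return(NULL)
  w <- geom$w * exp(rnorm(3, 0, geom$subject_tau))
  spike <- rbinom(3, 1, geom$spike_prob) * rnorm(3, 0, geom$spike_sd)
  out <- pmax(w + spike, 0)
  if (max(out) <= 0) out <- geom$w
  out
}

# Embed a squared-distance matrix as k condition means in P channels.
# Classical MDS: B = -1/2 H D H; means Y = V L^{1/2} mapped into channel
# directions orthogonal to the constant vector so that per-pattern mean
# centering never touches the signal. `basis` may be supplied to reuse a
# subject-specific orthonormal basis.
embed_conditions <- function(dsq, n_channels, embed_dim = NULL,
                             basis = NULL, what = "geometry") {
  k <- nrow(dsq)
  H <- diag(k) - 1 / k
  B <- -0.5 * H %*% dsq %*% H
  e <- eigen(B, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol * 10) {
    stop(sprintf("%s is not embeddable (negative eigenvalue %.3g)",
                 what, min(e$values)))
  }
  r <- sum(e$values > tol)
  if (!is.null(embed_dim)) {
    if (embed_dim < r) {
      stop(sprintf("embed_dim = %d below rank %d of the planted geometry",
                   embed_dim, r))
    }
  }
  Y <- e$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(r)]), r)
  if (is.null(basis)) {
    X <- matrix(rnorm(n_channels * r), n_channels, r)
    X <- X - rep(colMeans(X), each = n_channels)
    basis <- qr.Q(qr(X))
  }
  Y %*% t(basis[, seq_len(r), drop = FALSE])
}

#' Generate multivoxel condition patterns with a planted geometry
#'
#' For each subject, draws 8 condition-mean patterns whose pairwise
#' squared Euclidean distances are exactly proportional to the (subject's)
#' planted matrix `D*`, then adds independent Gaussian channel noise. The
#' means are obtained by double-centering `-D*/2` and embedding its
#' eigendecomposition; each subject receives their own random orthonormal
#' channel basis (orthogonal to the constant channel direction), mirroring
#' the fact that different brains express the same geometry in different
#' voxel patterns.
#'
#' @param design A [design_spec()] (supplies the number of subjects).
#' @param geom A [geometry_spec()].
#' @param seed Integer seed; defaults to the design seed.
#' @return A `pattern_set`: list with `data` (subjects x 8 conditions x P
#'   channels array), `labels`, `subject_ids`, `geometry`,
#'   `subject_weights` (ground truth per subject) and `seed`.
#' @export
generate_patterns <- function(design, geom, seed = design$seed) {
  stopifnot(inherits(geom, "geometry_spec"))
  n_sub <- if (inherits(design, "design_spec")) design$n_subjects
           else as.integer(design)
  if (n_sub < 1) stop("need at least one subject")
  set.seed(seed)
  P <- geom$n_channels
  sigma <- geom$noise_sd
  scale_sq <- if (sigma > 0) geom$snr * 2 * P * sigma^2 else 1
  labs <- condition_labels()
  dat <- array(NA_real_, dim = c(n_sub, 8, P),
               dimnames = list(sprintf("S%02d", seq_len(n_sub)), labs, NULL))
  wmat <- if (geom$independent) NULL else
    matrix(NA_real_, n_sub, 3, dimnames = list(NULL, c("w_mod", "w_exp", "w_type")))
  for (s in seq_len(n_sub)) {
    ws <- draw_subject_weights(geom)
    if (!is.null(wmat)) wmat[s, ] <- ws
    dsq <- planted_dstar(ws, independent = geom$independent) * scale_sq
    mu <- embed_conditions(dsq, P, geom$embed_dim,
                           what = weight_label(ws, geom$independent))
    dat[s, , ] <- mu + matrix(rnorm(8 * P, 0, sigma), 8, P)
  }
  structure(list(data = dat, labels = labs,
                 subject_ids = dimnames(dat)[[1]],
                 geometry = geom, subject_weights = wmat, seed = seed),
            class = "pattern_set")
}

weight_label <- function(w, independent) {
  if (independent) "independent geometry"
  else sprintf("weight set (%.3g, %.3g, %.3g)", w[1], w[2], w[3])
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Pattern set: %d subjects x %d conditions x %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Standardize condition patterns
#'
#' Z-scores every subject-condition pattern across channels to mean 0 and
#' (population) SD 1, the preprocessing applied before neural RDMs are
#' computed.
#'
#' @param patterns A `pattern_set`, or a conditions x channels matrix.
#' @return Object of the same shape with standardized patterns.
#' @export
zscore_patterns <- function(patterns) {
  zrow <- function(p, who) {
    mu <- mean(p)
    s <- sqrt(mean((p - mu)^2))
    if (s == 0) stop(sprintf("zero-variance pattern for %s", who))
    (p - mu) / s
  }
  if (inherits(patterns, "pattern_set")) {
    d <- dim(patterns$data)
    for (s in seq_len(d[1])) {
      for (cc in seq_len(d[2])) {
        patterns$data[s, cc, ] <- zrow(
          patterns$data[s, cc, ],
          sprintf("subject %s condition %s", patterns$subject_ids[s],
                  patterns$labels[cc]))
      }
    }
    patterns
  } else {
    m <- as.matrix(patterns)
    for (cc in seq_len(nrow(m))) {
      m[cc, ] <- zrow(m[cc, ], sprintf("condition %d", cc))
    }
    m
  }
}

#' Neural RDM from condition patterns
#'
#' Entry (i, j) is the squared Euclidean distance between the (optionally
#' masked and z-scored) patterns of conditions i and j.
#'
#' @param patterns A conditions x channels matrix with rownames, or a
#'   `pattern_set` (then a list of per-subject RDMs is returned).
#' @param mask Optional logical/0-1 channel mask (>= 2 channels selected).
#' @param zscore Standardize each pattern first (default TRUE; the
#'   raw-distance mode exists for tests and diagnostics).
#' @return An `rdm`, or a named list of `rdm`s for a `pattern_set`.
#' @export
compute_neural_rdm <- function(patterns, mask = NULL, zscore = TRUE) {
  if (inherits(patterns, "pattern_set")) {
    out <- lapply(seq_along(patterns$subject_ids), function(s) {
      m <- patterns$data[s, , ]
      rownames(m) <- patterns$labels
      compute_neural_rdm(m, mask = mask, zscore = zscore)
    })
    names(out) <- patterns$subject_ids
    return(out)
  }
  m <- as.matrix(patterns)
  if (is.null(rownames(m)) && nrow(m) == 8) rownames(m) <- condition_labels()
  bad <- rownames(m)[!stats::complete.cases(m)]
  if (length(bad)) {
    stop(sprintf("missing pattern for condition(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(m)) stop("mask length must match channels")
    if (sum(mask) < 2) stop("mask must select at least 2 channels")
    m <- m[, mask, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 channels")
  if (zscore) m <- zscore_patterns(m)
  d2 <- as.matrix(dist(m))^2
  rdm(d2, labels = rownames(m))
}

#' Per-subject neural RDMs for a pattern set
#'
#' Convenience wrapper around [compute_neural_rdm()] returning the list of
#' per-subject RDMs.
#'
#' @inheritParams compute_neural_rdm
#' @return Named list of `rdm`s.
#' @export
subject_rdms <- function(patterns, mask = NULL, zscore = TRUE) {
  stopifnot(inherits(patterns, "pattern_set"))
  compute_neural_rdm(patterns, mask = mask, zscore = zscore)
}
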