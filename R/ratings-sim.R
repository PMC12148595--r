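#' Behavioral study design
#'
#' Describes the rating-study layout: subjects, stimuli (half artworks,
#' half faces), runs, rating dimensions and the ordinal scale. Defaults
#' mirror the study design the package emulates: 34 subjects rating 20
#' artworks and 20 faces on 7-point scales across 4 runs, in both a
#' perception and an imagery condition.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_stimuli_per_type Stimuli per type (art, face).
#' @param n_runs Number of runs; every stimulus appears in exactly one run
#'   per subject.
#' @param rating_dims Rating dimensions.
#' @param scale_K Number of ordinal categories (>= 3).
#' @param seed Default seed for data generation.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 34, n_stimuli_per_type = 20,
                        n_runs = 4,
                        rating_dims = c("pleasure", "beauty", "moving"),
                        scale_K = 7, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (n_stimuli_per_type < 1) stop("n_stimuli_per_type must be positive")
  if (scale_K < 3) stop("scale_K must be at least 3")
  if (n_runs < 1) stop("n_runs must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_stimuli_per_type = as.integer(n_stimuli_per_type),
                 n_runs = as.integer(n_runs),
                 rating_dims = rating_dims,
                 scale_K = as.integer(scale_K),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Design: %d subjects, %d art + %d face stimuli, %d runs, K = %d (%s)\n",
    x$n_subjects, x$n_stimuli_per_type, x$n_stimuli_per_type, x$n_runs,
    x$scale_K, paste(x$rating_dims, collapse = ", ")))
  invisible(x)
}

#' Planted behavioral effects
#'
#' Parameters of the generative ordinal model behind
#' [generate_ratings()]. The latent scale has unit residual SD (probit
#' convention), so the regression effects are directly comparable to
#' standardized cumulative-probit coefficients. Default effect sizes match
#' the modality and stimulus-type effects reported for the "moving"
#' dimension of the study the package emulates (-0.29 and -0.56 on the
#' latent scale).
#'
#' @param beta_modality Latent-scale effect of imagery vs. perception.
#' @param beta_type Latent-scale effect of face vs. art.
#' @param thresholds Strictly increasing vector of K-1 thresholds, or
#'   `NULL` to place them at latent quantiles giving (approximately)
#'   uniform category usage at baseline.
#' @param sd_subject,sd_stimulus Random-intercept SDs (>= 0).
#' @param vividness_probs Probabilities of vividness ratings 1..7 on
#'   imagery trials (sums to 1). The default is skewed toward high
#'   vividness, matching a sample screened for average-to-high imagery
#'   ability.
#' @param kappa Vividness coupling strength (>= 0): imagery latents get
#'   additional noise `kappa * (7 - v)/6 * epsilon`, so low-vividness
#'   trials diverge more from their perception counterpart. `kappa = 0`
#'   removes the coupling. The default is calibrated so the standardized
#'   slope of the dissimilarity score on vividness is about -0.27.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(beta_modality = -0.29, beta_type = -0.56,
                        thresholds = NULL,
                        sd_subject = 0.5, sd_stimulus = 0.5,
                        vividness_probs = c(0.02, 0.04, 0.08, 0.12,
                                            0.20, 0.28, 0.26),
                        kappa = 4.2) {
  if (sd_subject < 0 || sd_stimulus < 0) stop("random-intercept SDs must be >= 0")
  if (kappa < 0) stop("kappa must be nonnegative")
  if (any(vividness_probs < 0) || abs(sum(vividness_probs) - 1) > 1e-8) {
    stop("vividness_probs must be nonnegative and sum to 1")
  }
  if (!is.null(thresholds) && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  structure(list(beta_modality = beta_modality, beta_type = beta_type,
                 thresholds = thresholds,
                 sd_subject = sd_subject, sd_stimulus = sd_stimulus,
                 vividness_probs = vividness_probs, kappa = kappa),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat(sprintf(
    "Effects: beta_modality = %.3g, beta_type = %.3g, kappa = %.3g, sd_subj = %.3g, sd_stim = %.3g\n",
    x$beta_modality, x$beta_type, x$kappa, x$sd_subject, x$sd_stimulus))
  invisible(x)
}

# default thresholds: uniform category usage for the marginal latent
# (residual + random intercepts) at baseline
default_thresholds <- function(K, sd_subject, sd_stimulus) {
  qnorm(seq_len(K - 1) / K) * sqrt(1 + sd_subject^2 + sd_stimulus^2)
}

#' Generate a synthetic ratings table
#'
#' Simulates the full behavioral dataset under a cumulative-probit
#' generative model with subject and stimulus random intercepts. For each
#' subject, stimulus and rating dimension, the perception latent is
#' `u_subj + u_stim + beta_type * [face]`; the imagery latent adds
#' `beta_modality` plus vividness-coupled divergence noise
#' `kappa * (7 - v)/6 * epsilon` (one vividness draw per imagery trial,
#' shared by the three dimensions). Ratings are obtained by adding unit
#' normal noise and cutting at the thresholds.
#'
#' @param design A [design_spec()].
#' @param effects An [effect_spec()].
#' @param missing_rate Optional MCAR missingness rate applied to rating
#'   cells (not vividness); default 0.
#' @param seed Integer seed; defaults to the design seed.
#' @return A data.frame with columns `subject_id`, `stimulus_id`,
#'   `stimulus_type`, `modality`, `run`, one column per rating dimension,
#'   and `vividness` (NA on perception rows).
#' @export
generate_ratings <- function(design, effects, missing_rate = 0,
                             seed = design$seed) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  K <- design$scale_K
  if (length(effects$vividness_probs) != K) {
    stop("vividness_probs length must equal scale_K")
  }
  tau <- effects$thresholds
  if (is.null(tau)) {
    tau <- default_thresholds(K, effects$sd_subject, effects$sd_stimulus)
  }
  if (length(tau) != K - 1) {
    stop(sprintf("thresholds length %d inconsistent with K = %d",
                 length(tau), K))
  }
  if (any(diff(tau) <= 0)) stop("thresholds must be strictly increasing")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  set.seed(seed)

  nS <- design$n_subjects
  nI <- 2L * design$n_stimuli_per_type
  dims <- design$rating_dims
  stim_ids <- c(sprintf("A%02d", seq_len(design$n_stimuli_per_type)),
                sprintf("F%02d", seq_len(design$n_stimuli_per_type)))
  stim_face <- rep(c(0, 1), each = design$n_stimuli_per_type)
  subj_ids <- sprintf("S%02d", seq_len(nS))

  # per-dimension random intercepts
  u_subj <- matrix(rnorm(nS * length(dims), 0, effects$sd_subject),
                   nS, length(dims), dimnames = list(NULL, dims))
  u_stim <- matrix(rnorm(nI * length(dims), 0, effects$sd_stimulus),
                   nI, length(dims), dimnames = list(NULL, dims))

  subj <- rep(seq_len(nS), each = nI)
  stim <- rep(seq_len(nI), times = nS)
  # every stimulus appears in exactly one (random) run per subject
  run <- unlist(lapply(seq_len(nS), function(s) {
    sample(rep_len(seq_len(design$n_runs), nI))
  }))
  v <- sample.int(K, nS * nI, replace = TRUE,
                  prob = effects$vividness_probs)

  cut_rating <- function(latent) {
    findInterval(latent + rnorm(length(latent)), tau) + 1L
  }
  per_mat <- ima_mat <- matrix(NA_integer_, nS * nI, length(dims),
                               dimnames = list(NULL, dims))
  for (d in seq_along(dims)) {
    mu_per <- u_subj[subj, d] + u_stim[stim, d] +
      effects$beta_type * stim_face[stim]
    mu_ima <- mu_per + effects$beta_modality +
      effects$kappa * (K - v) / (K - 1) * rnorm(length(mu_per))
    per_mat[, d] <- cut_rating(mu_per)
    ima_mat[, d] <- cut_rating(mu_ima)
  }

  base <- data.frame(
    subject_id = subj_ids[subj],
    stimulus_id = stim_ids[stim],
    stimulus_type = ifelse(stim_face[stim] == 1, "face", "art"),
    run = run, stringsAsFactors = FALSE)
  per <- cbind(base, modality = "perception",
               as.data.frame(per_mat), vividness = NA_integer_)
  ima <- cbind(base, modality = "imagery",
               as.data.frame(ima_mat), vividness = v)
  out <- rbind(per, ima)
  out <- out[order(out$subject_id, out$stimulus_id,
                   out$modality == "imagery"), ]
  out <- out[, c("subject_id", "stimulus_id", "stimulus_type", "modality",
                 "run", dims, "vividness")]
  rownames(out) <- NULL
  if (missing_rate > 0) {
    for (d in dims) {
      out[[d]][runif(nrow(out)) < missing_rate] <- NA_integer_
    }
  }
  attr(out, "thresholds") <- tau
  out
}
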