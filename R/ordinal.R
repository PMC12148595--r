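#' Hierarchical Bayesian cumulative probit regression
#'
#' Fits the winning behavioral model: an ordinal (cumulative) regression
#' with probit link and flexible thresholds for one rating dimension, with
#' fixed effects for stimulation modality (imagery vs. perception) and
#' stimulus type (face vs. art) and random intercepts for subjects and
#' stimuli. Because the latent residual SD is fixed at 1 (probit
#' convention), the regression coefficients are standardized latent-scale
#' effects and are reported directly as `beta_modality` / `beta_type`.
#'
#' Priors: `normal(0, 1)` on the two regression coefficients (weakly
#' informative on the latent probit scale), `student_t(3, 0, 2.5)` on each
#' threshold (subject to ordering) and half-`student_t(3, 0, 2.5)` on the
#' random-intercept SDs.
#'
#' Sampling uses an adaptive random-walk Metropolis-within-Gibbs scheme on
#' the marginal ordinal likelihood: scalar blocks for the coefficients and
#' each threshold, vectorized simultaneous updates of the conditionally
#' independent subject and stimulus intercepts, log-scale updates of the
#' SDs, and interweaving "shift" moves along the weakly identified
#' directions (thresholds vs. intercept means; type coefficient vs.
#' stimulus intercepts) that would otherwise mix slowly. Proposal scales
#' adapt during warmup only.
#'
#' @param ratings A ratings table (complete cases are used; rows with a
#'   missing response on `dimension` are dropped).
#' @param dimension Which rating dimension to model.
#' @param chains,iter,warmup Number of chains, kept iterations per chain,
#'   and warmup iterations (discarded).
#' @param seed Integer seed.
#' @param init Optional named list of initial values (`beta_modality`,
#'   `beta_type`, `tau`, `sd_subject`, `sd_stimulus`). Threshold inits are
#'   sorted, so unordered values are accepted.
#' @param rhat_threshold Convergence flag threshold for split-R-hat.
#' @param quiet Suppress progress messages.
#' @return A `cumprobit_fit` (see [summary.aesthsim_fit()]): contains the
#'   draws array `[iter, chain, parameter]`, split-R-hat and effective
#'   sample sizes, and a `converged` flag. Non-convergence warns but still
#'   returns the (flagged) fit.
#' @export
fit_cumulative_probit <- function(ratings, dimension = "moving",
                                  chains = 4, iter = 2000, warmup = 2000,
                                  seed = 1, init = NULL,
                                  rhat_threshold = 1.05, quiet = TRUE) {
  if (!dimension %in% names(ratings)) {
    stop(sprintf("dimension '%s' not present in ratings", dimension))
  }
  ok <- !is.na(ratings[[dimension]])
  ratings <- ratings[ok, , drop = FALSE]
  y <- as.integer(ratings[[dimension]])
  K <- max(7L, max(y))
  if (length(unique(y)) < 2) {
    stop("degenerate data: only one response category observed")
  }
  subj <- as.integer(factor(ratings$subject_id))
  stim <- as.integer(factor(ratings$stimulus_id))
  nS <- max(subj)
  nI <- max(stim)
  if (nS < 2) stop("need at least 2 subjects")
  x_mod <- as.numeric(ratings$modality == "imagery")
  x_face <- as.numeric(ratings$stimulus_type == "face")
  has_mod <- var(x_mod) > 0
  has_type <- var(x_face) > 0
  N <- length(y)

  # face/art membership of each stimulus (constant within stimulus)
  stim_face <- vapply(seq_len(nI), function(j) x_face[match(j, stim)][1],
                      numeric(1))

  tau_init <- if (!is.null(init$tau)) {
    sort(as.numeric(init$tau))
  } else {
    p <- cumsum(tabulate(y, K) / N)[seq_len(K - 1)]
    qnorm(pmin(pmax(p, 0.01), 0.99))
  }
  tau_init <- fix_ties(tau_init)

  n_tau <- K - 1
  par_names <- c("beta_modality", "beta_type",
                 paste0("tau", seq_len(n_tau)),
                 "sd_subject", "sd_stimulus")
  draws <- array(NA_real_,
                 dim = c(iter, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  # per-row ordinal log likelihood given latent means and thresholds
  llfun <- function(eta, tau_ext, yy) {
    p <- pnorm(tau_ext[yy + 1L] - eta) - pnorm(tau_ext[yy] - eta)
    log(pmax(p, 1e-300))
  }
  rows_mod <- which(x_mod == 1)
  rows_face <- which(x_face == 1)
  idx_tau <- lapply(seq_len(n_tau), function(k) which(y == k | y == k + 1L))
  face_stims <- which(stim_face == 1)

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    b_mod <- init$beta_modality %||% 0
    b_type <- init$beta_type %||% 0
    tau <- tau_init + rnorm(n_tau, 0, 0.02 * (ch > 1))
    tau <- fix_ties(sort(tau))
    u <- rnorm(nS, 0, 0.1)
    w <- rnorm(nI, 0, 0.1)
    lsd_u <- log(init$sd_subject %||% 0.5)
    lsd_w <- log(init$sd_stimulus %||% 0.5)

    eta <- b_mod * x_mod + b_type * x_face + u[subj] + w[stim]
    tau_ext <- c(-Inf, tau, Inf)
    llr <- llfun(eta, tau_ext, y)

    # adaptive log proposal scales
    ls_b <- c(-2.5, -2)           # beta_modality, beta_type
    ls_tau <- rep(-2.5, n_tau)
    ls_u <- rep(-1.5, nS)
    ls_w <- rep(-1.5, nI)
    ls_sd <- c(-1, -1)
    ls_shift <- c(-2, -2, -2)     # tau+u, tau+w, b_type+w

    total <- warmup + iter
    for (it in seq_len(total)) {
      adapting <- it <= warmup

      ## regression coefficients
      if (has_mod) {
        d <- rnorm(1, 0, exp(ls_b[1]))
        lln <- llfun(eta[rows_mod] + d, tau_ext, y[rows_mod])
        logr <- sum(lln - llr[rows_mod]) +
          dnorm(b_mod + d, 0, 1, log = TRUE) - dnorm(b_mod, 0, 1, log = TRUE)
        acc <- log(runif(1)) < logr
        if (acc) {
          b_mod <- b_mod + d
          eta[rows_mod] <- eta[rows_mod] + d
          llr[rows_mod] <- lln
        }
        if (adapting) ls_b[1] <- adapt_scale(ls_b[1], acc, it, 0.44)
      }
      if (has_type) {
        d <- rnorm(1, 0, exp(ls_b[2]))
        lln <- llfun(eta[rows_face] + d, tau_ext, y[rows_face])
        logr <- sum(lln - llr[rows_face]) +
          dnorm(b_type + d, 0, 1, log = TRUE) -
          dnorm(b_type, 0, 1, log = TRUE)
        acc <- log(runif(1)) < logr
        if (acc) {
          b_type <- b_type + d
          eta[rows_face] <- eta[rows_face] + d
          llr[rows_face] <- lln
        }
        if (adapting) ls_b[2] <- adapt_scale(ls_b[2], acc, it, 0.44)
      }

      ## thresholds (ordered; out-of-order proposals rejected)
      for (k in seq_len(n_tau)) {
        d <- rnorm(1, 0, exp(ls_tau[k]))
        tk <- tau[k] + d
        lo_ok <- k == 1 || tk > tau[k - 1]
        hi_ok <- k == n_tau || tk < tau[k + 1]
        acc <- FALSE
        if (lo_ok && hi_ok) {
          tau_new <- tau
          tau_new[k] <- tk
          te_new <- c(-Inf, tau_new, Inf)
          rows <- idx_tau[[k]]
          lln <- llfun(eta[rows], te_new, y[rows])
          logr <- sum(lln - llr[rows]) +
            log_t_prior(tk) - log_t_prior(tau[k])
          acc <- log(runif(1)) < logr
          if (acc) {
            tau <- tau_new
            tau_ext <- te_new
            llr[rows] <- lln
          }
        }
        if (adapting) ls_tau[k] <- adapt_scale(ls_tau[k], acc, it, 0.44)
      }

      ## subject intercepts: simultaneous independent RW
      sd_u <- exp(lsd_u)
      du <- rnorm(nS, 0, exp(ls_u))
      lln <- llfun(eta + du[subj], tau_ext, y)
      dll <- rowsum(lln - llr, subj, reorder = TRUE)[, 1]
      logr <- dll + dnorm(u + du, 0, sd_u, log = TRUE) -
        dnorm(u, 0, sd_u, log = TRUE)
      acc <- log(runif(nS)) < logr
      if (any(acc)) {
        du_eff <- du * acc
        eta <- eta + du_eff[subj]
        rows <- which(acc[subj])
        llr[rows] <- lln[rows]
        u <- u + du_eff
      }
      if (adapting) ls_u <- adapt_scale(ls_u, as.numeric(acc), it, 0.44)

      ## stimulus intercepts
      sd_w <- exp(lsd_w)
      dw <- rnorm(nI, 0, exp(ls_w))
      lln <- llfun(eta + dw[stim], tau_ext, y)
      dll <- rowsum(lln - llr, stim, reorder = TRUE)[, 1]
      logr <- dll + dnorm(w + dw, 0, sd_w, log = TRUE) -
        dnorm(w, 0, sd_w, log = TRUE)
      acc <- log(runif(nI)) < logr
      if (any(acc)) {
        dw_eff <- dw * acc
        eta <- eta + dw_eff[stim]
        rows <- which(acc[stim])
        llr[rows] <- lln[rows]
        w <- w + dw_eff
      }
      if (adapting) ls_w <- adapt_scale(ls_w, as.numeric(acc), it, 0.44)

      ## random-intercept SDs (log scale)
      d <- rnorm(1, 0, exp(ls_sd[1]))
      lsd_new <- lsd_u + d
      logr <- sum(dnorm(u, 0, exp(lsd_new), log = TRUE)) -
        sum(dnorm(u, 0, exp(lsd_u), log = TRUE)) +
        log_half_t(exp(lsd_new)) - log_half_t(exp(lsd_u)) + d
      acc <- log(runif(1)) < logr
      if (acc) lsd_u <- lsd_new
      if (adapting) ls_sd[1] <- adapt_scale(ls_sd[1], acc, it, 0.44)

      d <- rnorm(1, 0, exp(ls_sd[2]))
      lsd_new <- lsd_w + d
      logr <- sum(dnorm(w, 0, exp(lsd_new), log = TRUE)) -
        sum(dnorm(w, 0, exp(lsd_w), log = TRUE)) +
        log_half_t(exp(lsd_new)) - log_half_t(exp(lsd_w)) + d
      acc <- log(runif(1)) < logr
      if (acc) lsd_w <- lsd_new
      if (adapting) ls_sd[2] <- adapt_scale(ls_sd[2], acc, it, 0.44)

      ## interweaving shift moves (likelihood-invariant directions)
      # thresholds and subject intercepts shift together
      cshift <- rnorm(1, 0, exp(ls_shift[1]))
      logr <- sum(log_t_prior(tau + cshift)) - sum(log_t_prior(tau)) +
        sum(dnorm(u + cshift, 0, exp(lsd_u), log = TRUE)) -
        sum(dnorm(u, 0, exp(lsd_u), log = TRUE))
      acc <- log(runif(1)) < logr
      if (acc) {
        tau <- tau + cshift
        tau_ext <- c(-Inf, tau, Inf)
        u <- u + cshift
        eta <- eta + cshift
      }
      if (adapting) ls_shift[1] <- adapt_scale(ls_shift[1], acc, it, 0.44)

      # thresholds and stimulus intercepts shift together
      cshift <- rnorm(1, 0, exp(ls_shift[2]))
      logr <- sum(log_t_prior(tau + cshift)) - sum(log_t_prior(tau)) +
        sum(dnorm(w + cshift, 0, exp(lsd_w), log = TRUE)) -
        sum(dnorm(w, 0, exp(lsd_w), log = TRUE))
      acc <- log(runif(1)) < logr
      if (acc) {
        tau <- tau + cshift
        tau_ext <- c(-Inf, tau, Inf)
        w <- w + cshift
        eta <- eta + cshift
      }
      if (adapting) ls_shift[2] <- adapt_scale(ls_shift[2], acc, it, 0.44)

      # type coefficient trades against face-stimulus intercepts
      if (has_type && length(face_stims)) {
        cshift <- rnorm(1, 0, exp(ls_shift[3]))
        logr <- dnorm(b_type + cshift, 0, 1, log = TRUE) -
          dnorm(b_type, 0, 1, log = TRUE) +
          sum(dnorm(w[face_stims] - cshift, 0, exp(lsd_w), log = TRUE)) -
          sum(dnorm(w[face_stims], 0, exp(lsd_w), log = TRUE))
        acc <- log(runif(1)) < logr
        if (acc) {
          b_type <- b_type + cshift
          w[face_stims] <- w[face_stims] - cshift
        }
        if (adapting) ls_shift[3] <- adapt_scale(ls_shift[3], acc, it, 0.44)
      }

      if (!adapting) {
        draws[it - warmup, ch, ] <- c(b_mod, b_type, tau,
                                      exp(lsd_u), exp(lsd_w))
      }
    }
    if (!quiet) message(sprintf("chain %d/%d done", ch, chains))
  }

  keep_pars <- par_names
  if (!has_type) keep_pars <- setdiff(keep_pars, "beta_type")
  if (!has_mod) keep_pars <- setdiff(keep_pars, "beta_modality")
  draws <- draws[, , keep_pars, drop = FALSE]

  diag <- mcmc_diagnostics(draws)
  converged <- all(diag$rhat < rhat_threshold)
  if (!converged) {
    warning(sprintf("sampler not converged: max split-R-hat = %.3f",
                    max(diag$rhat)))
  }
  structure(list(
    draws = draws, parameters = keep_pars,
    rhat = diag$rhat, ess = diag$ess, converged = converged,
    rhat_threshold = rhat_threshold,
    model_label = sprintf("Cumulative probit fit of '%s' (N = %d, %d subjects, %d stimuli)",
                          dimension, N, nS, nI),
    dimension = dimension, n = N, n_subjects = nS, n_stimuli = nI,
    prior = list(beta = c(0, 1), tau = c(3, 0, 2.5), sd = c(3, 0, 2.5)),
    seed = seed, chains = chains, iter = iter, warmup = warmup
  ), class = c("cumprobit_fit", "aesthsim_fit"))
}

fix_ties <- function(tau) {
  for (k in seq_along(tau)[-1]) {
    if (tau[k] <= tau[k - 1]) tau[k] <- tau[k - 1] + 1e-3
  }
  tau
}

`%||%` <- function(a, b) if (is.null(a)) b else a
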