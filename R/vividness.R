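#' Hierarchical Bayesian Student-t regression of dissimilarity on vividness
#'
#' Models the cross-modality dissimilarity score as a linear function of
#' imagery vividness with a subject random intercept and Student-t
#' residuals (robust to the long right tail of the score). Outcome and
#' predictor are z-scored before fitting, so the slope `beta_vividness` is
#' a standardized coefficient.
#'
#' Priors: `normal(0, 1)` on intercept and slope (weakly informative on
#' the standardized scale), half-`student_t(3, 0, 2.5)` on the residual
#' and random-intercept SDs, `gamma(2, 0.1)` on the residual degrees of
#' freedom (truncated below at 1).
#'
#' Sampling uses the same adaptive Metropolis-within-Gibbs engine as
#' [fit_cumulative_probit()]: scalar blocks for intercept, slope and the
#' three transformed scale/df parameters, a vectorized update of the
#' subject intercepts, and an interweaving shift move between the
#' intercept and the subject effects.
#'
#' @param scores Output of [dissimilarity_score()] (columns `subject_id`,
#'   `S`, `vividness`).
#' @inheritParams fit_cumulative_probit
#' @return A `studentt_fit` with parameters `beta_vividness`,
#'   `intercept`, `sigma`, `nu`, `sd_subject`.
#' @export
fit_vividness_regression <- function(scores, chains = 4, iter = 2000,
                                     warmup = 2000, seed = 1,
                                     rhat_threshold = 1.05, quiet = TRUE) {
  req <- c("subject_id", "S", "vividness")
  if (!all(req %in% names(scores))) {
    stop("scores must have columns subject_id, S, vividness")
  }
  scores <- scores[!is.na(scores$S) & !is.na(scores$vividness), ,
                   drop = FALSE]
  if (var(scores$vividness) == 0) {
    stop("zero-variance vividness: slope not identifiable")
  }
  subj <- as.integer(factor(scores$subject_id))
  nS <- max(subj)
  if (nS < 2) stop("need at least 2 subjects")
  zscore <- function(x) {
    s <- sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  }
  yv <- zscore(scores$S)
  xv <- zscore(scores$vividness)
  N <- length(yv)

  par_names <- c("beta_vividness", "intercept", "sigma", "nu", "sd_subject")
  draws <- array(NA_real_, dim = c(iter, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  llfun <- function(mu, sigma, nu) {
    dt((yv - mu) / sigma, nu, log = TRUE) - log(sigma)
  }

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    b0 <- rnorm(1, 0, 0.1 * (ch > 1))
    b1 <- rnorm(1, 0, 0.1 * (ch > 1))
    u <- rnorm(nS, 0, 0.1)
    lsig <- log(0.8)
    lnu <- log(10)   # nu = 1 + exp(lnu)
    lsd_u <- log(0.5)

    mu <- b0 + b1 * xv + u[subj]
    sigma <- exp(lsig)
    nu <- 1 + exp(lnu)
    llr <- llfun(mu, sigma, nu)

    ls <- c(b0 = -2, b1 = -2, sig = -2, nu = -1, sdu = -1, shift = -2,
            resc = -1)
    ls_u <- rep(-1.5, nS)
    total <- warmup + iter

    for (it in seq_len(total)) {
      adapting <- it <= warmup

      # intercept and slope
      d <- rnorm(1, 0, exp(ls["b0"]))
      lln <- llfun(mu + d, sigma, nu)
      logr <- sum(lln - llr) + dnorm(b0 + d, 0, 1, log = TRUE) -
        dnorm(b0, 0, 1, log = TRUE)
      if ((acc <- log(runif(1)) < logr)) {
        b0 <- b0 + d; mu <- mu + d; llr <- lln
      }
      if (adapting) ls["b0"] <- adapt_scale(ls["b0"], acc, it, 0.44)

      d <- rnorm(1, 0, exp(ls["b1"]))
      lln <- llfun(mu + d * xv, sigma, nu)
      logr <- sum(lln - llr) + dnorm(b1 + d, 0, 1, log = TRUE) -
        dnorm(b1, 0, 1, log = TRUE)
      if ((acc <- log(runif(1)) < logr)) {
        b1 <- b1 + d; mu <- mu + d * xv; llr <- lln
      }
      if (adapting) ls["b1"] <- adapt_scale(ls["b1"], acc, it, 0.44)

      # subject intercepts (vectorized independent RW)
      sd_u <- exp(lsd_u)
      du <- rnorm(nS, 0, exp(ls_u))
      lln <- llfun(mu + du[subj], sigma, nu)
      dll <- rowsum(lln - llr, subj, reorder = TRUE)[, 1]
      logr <- dll + dnorm(u + du, 0, sd_u, log = TRUE) -
        dnorm(u, 0, sd_u, log = TRUE)
      accv <- log(runif(nS)) < logr
      if (any(accv)) {
        du_eff <- du * accv
        mu <- mu + du_eff[subj]
        rows <- which(accv[subj])
        llr[rows] <- lln[rows]
        u <- u + du_eff
      }
      if (adapting) ls_u <- adapt_scale(ls_u, as.numeric(accv), it, 0.44)

      # residual scale
      d <- rnorm(1, 0, exp(ls["sig"]))
      sig_new <- exp(lsig + d)
      lln <- llfun(mu, sig_new, nu)
      logr <- sum(lln - llr) + log_half_t(sig_new) - log_half_t(sigma) + d
      if ((acc <- log(runif(1)) < logr)) {
        lsig <- lsig + d; sigma <- sig_new; llr <- lln
      }
      if (adapting) ls["sig"] <- adapt_scale(ls["sig"], acc, it, 0.44)

      # residual degrees of freedom, nu = 1 + exp(lnu)
      d <- rnorm(1, 0, exp(ls["nu"]))
      lnu_new <- lnu + d
      nu_new <- 1 + exp(lnu_new)
      lln <- llfun(mu, sigma, nu_new)
      logr <- sum(lln - llr) +
        stats::dgamma(nu_new, 2, rate = 0.1, log = TRUE) -
        stats::dgamma(nu, 2, rate = 0.1, log = TRUE) +
        lnu_new - lnu   # Jacobian of nu = 1 + exp(lnu)
      if ((acc <- log(runif(1)) < logr)) {
        lnu <- lnu_new; nu <- nu_new; llr <- lln
      }
      if (adapting) ls["nu"] <- adapt_scale(ls["nu"], acc, it, 0.44)

      # random-intercept SD
      d <- rnorm(1, 0, exp(ls["sdu"]))
      lsd_new <- lsd_u + d
      logr <- sum(dnorm(u, 0, exp(lsd_new), log = TRUE)) -
        sum(dnorm(u, 0, exp(lsd_u), log = TRUE)) +
        log_half_t(exp(lsd_new)) - log_half_t(exp(lsd_u)) + d
      if ((acc <- log(runif(1)) < logr)) lsd_u <- lsd_new
      if (adapting) ls["sdu"] <- adapt_scale(ls["sdu"], acc, it, 0.44)

      # joint rescale of subject effects and their SD: cures the slow
      # boundary mixing of sd_subject when the effects are near zero
      cresc <- rnorm(1, 0, exp(ls["resc"]))
      u_new <- u * exp(cresc)
      mu_new <- mu + (exp(cresc) - 1) * u[subj]
      lln <- llfun(mu_new, sigma, nu)
      logr <- sum(lln - llr) +
        log_half_t(exp(lsd_u + cresc)) - log_half_t(exp(lsd_u)) + cresc
      if ((acc <- log(runif(1)) < logr)) {
        u <- u_new; mu <- mu_new; llr <- lln; lsd_u <- lsd_u + cresc
      }
      if (adapting) ls["resc"] <- adapt_scale(ls["resc"], acc, it, 0.44)

      # shift move: intercept vs subject-effect mean (likelihood-invariant)
      cshift <- rnorm(1, 0, exp(ls["shift"]))
      logr <- dnorm(b0 + cshift, 0, 1, log = TRUE) -
        dnorm(b0, 0, 1, log = TRUE) +
        sum(dnorm(u - cshift, 0, exp(lsd_u), log = TRUE)) -
        sum(dnorm(u, 0, exp(lsd_u), log = TRUE))
      if ((acc <- log(runif(1)) < logr)) {
        b0 <- b0 + cshift
        u <- u - cshift
      }
      if (adapting) ls["shift"] <- adapt_scale(ls["shift"], acc, it, 0.44)

      if (!adapting) {
        draws[it - warmup, ch, ] <- c(b1, b0, sigma, nu, exp(lsd_u))
      }
    }
    if (!quiet) message(sprintf("chain %d/%d done", ch, chains))
  }

  diag <- mcmc_diagnostics(draws)
  converged <- all(diag$rhat < rhat_threshold)
  if (!converged) {
    warning(sprintf("sampler not converged: max split-R-hat = %.3f",
                    max(diag$rhat)))
  }
  structure(list(
    draws = draws, parameters = par_names,
    rhat = diag$rhat, ess = diag$ess, converged = converged,
    rhat_threshold = rhat_threshold,
    model_label = sprintf("Student-t vividness regression (N = %d, %d subjects)",
                          N, nS),
    n = N, n_subjects = nS,
    prior = list(beta = c(0, 1), sd = c(3, 0, 2.5), nu = c(2, 0.1)),
    seed = seed, chains = chains, iter = iter, warmup = warmup
  ), class = c("studentt_fit", "aesthsim_fit"))
}
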