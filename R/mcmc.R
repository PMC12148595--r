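# Internal MCMC machinery shared by the Bayesian fitting functions:
# adaptive random-walk Metropolis-within-Gibbs with vectorized
# conditionally-independent blocks, plus split-R-hat / ESS diagnostics.

# log density of the half-t(3, 0, 2.5) scale prior (unnormalized)
log_half_t <- function(x, df = 3, scale = 2.5) {
  ifelse(x > 0, dt(x / scale, df, log = TRUE), -Inf)
}

# log density of the t(3, 0, 2.5) threshold/intercept prior (unnormalized)
log_t_prior <- function(x, df = 3, scale = 2.5) {
  dt(x / scale, df, log = TRUE)
}

# Robbins-Monro step for log proposal scales (target acceptance `target`)
adapt_scale <- function(log_scale, accepted, iter, target) {
  gamma <- min(0.25, 2 / sqrt(iter))
  log_scale + gamma * (accepted - target)
}

#' Split-half R-hat
#'
#' Potential scale reduction factor computed on chains split in half, the
#' standard convergence diagnostic reported for every sampled parameter.
#'
#' @param draws iterations x chains matrix of draws for one parameter.
#' @return The split-R-hat value.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size using Geyer's initial
#' positive sequence truncation, summed over chains.
#'
#' @param draws iterations x chains matrix of draws for one parameter.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  per_chain <- apply(draws, 2, function(x) {
    v <- var(x)
    if (v == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                     demean = TRUE)$acf[-1]
    s <- 0
    k <- 1
    while (k <= length(ac) - 1) {
      pair <- ac[k] + ac[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    n / (1 + 2 * s)
  })
  sum(per_chain)
}

# assemble diagnostics for a draws array [iter, chain, par]
mcmc_diagnostics <- function(draws_arr) {
  pars <- dimnames(draws_arr)[[3]]
  rhat <- vapply(pars, function(p) split_rhat(draws_arr[, , p]), numeric(1))
  ess <- vapply(pars, function(p) ess_basic(draws_arr[, , p]), numeric(1))
  list(rhat = rhat, ess = ess)
}

# flatten [iter, chain, par] to (iter*chain) x par
flatten_draws <- function(draws_arr) {
  d <- dim(draws_arr)
  m <- matrix(aperm(draws_arr, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(draws_arr)[[3]]
  m
}

#' Extract posterior draws for a parameter
#'
#' @param object A fitted model object (`cumprobit_fit` or
#'   `studentt_fit`).
#' @param parameter Parameter name (see `object$parameters`).
#' @return Numeric vector of pooled posterior draws.
#' @export
posterior_draws <- function(object, parameter) {
  stopifnot(inherits(object, "aesthsim_fit"))
  if (!parameter %in% dimnames(object$draws)[[3]]) {
    stop(sprintf("unknown parameter '%s' (available: %s)", parameter,
                 paste(dimnames(object$draws)[[3]], collapse = ", ")))
  }
  as.numeric(object$draws[, , parameter])
}

#' @export
print.aesthsim_fit <- function(x, ...) {
  cat(sprintf("%s (%d chains x %d kept draws)\n", x$model_label,
              dim(x$draws)[2], dim(x$draws)[1]))
  print(summary(x), ...)
  if (!x$converged) {
    cat(sprintf("WARNING: max split-R-hat %.3f exceeds %.2f\n",
                max(x$rhat), x$rhat_threshold))
  }
  invisible(x)
}

#' @export
summary.aesthsim_fit <- function(object, ...) {
  m <- flatten_draws(object$draws)
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, sd),
    q2.5 = apply(m, 2, quantile, 0.025),
    q50 = apply(m, 2, quantile, 0.5),
    q97.5 = apply(m, 2, quantile, 0.975),
    rhat = object$rhat[colnames(m)],
    ess = object$ess[colnames(m)],
    row.names = NULL
  )
}

#' @export
coef.aesthsim_fit <- function(object, ...) {
  m <- flatten_draws(object$draws)
  keep <- grep("^beta", colnames(m), value = TRUE)
  colMeans(m[, keep, drop = FALSE])
}
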