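#' ROPE equivalence Bayes factor
#'
#' Quantifies whether the posterior of an effect has moved into or out of
#' a region of practical equivalence (ROPE), the interval of effect sizes
#' conventionally considered negligible (default \[-0.1, 0.1\]). The
#' Bayes factor is the ratio of posterior to prior odds of the parameter
#' lying inside the ROPE:
#' `BF01 = [P_post(in)/P_post(out)] / [P_prior(in)/P_prior(out)]`.
#' `BF01 > 1` is evidence for a negligible effect. Posterior mass is
#' estimated from the MCMC draws; prior mass is computed analytically from
#' the stated normal prior.
#'
#' @param posterior A fitted model (`aesthsim_fit`) or a numeric vector of
#'   posterior draws.
#' @param parameter Parameter name when `posterior` is a fit (default
#'   `"beta_modality"`).
#' @param prior_mean,prior_sd Normal prior of the parameter (defaults to
#'   the `normal(0, 1)` coefficient prior used by the fitting functions).
#' @param rope Lower and upper ROPE bounds.
#' @return A `rope_result`: list with the ROPE bounds, posterior and prior
#'   mass inside, `bf01`, and a `note` flag for degenerate cases. If no
#'   posterior mass lies outside the ROPE, `bf01 = Inf` with a flag.
#' @export
#' @examples
#' rope_bayes_factor(rnorm(4000, 0, 0.02))
rope_bayes_factor <- function(posterior, parameter = "beta_modality",
                              prior_mean = 0, prior_sd = 1,
                              rope = c(-0.1, 0.1)) {
  if (inherits(posterior, "aesthsim_fit")) {
    draws <- posterior_draws(posterior, parameter)
  } else {
    draws <- as.numeric(posterior)
    parameter <- "draws"
  }
  if (length(rope) != 2 || rope[1] >= rope[2]) {
    stop("rope must be (lower, upper) with lower < upper")
  }
  prior_in <- pnorm(rope[2], prior_mean, prior_sd) -
    pnorm(rope[1], prior_mean, prior_sd)
  if (prior_in <= 0) stop("prior has zero mass inside the ROPE")
  prior_out <- 1 - prior_in
  if (prior_out <= 0) stop("prior has zero mass outside the ROPE")
  post_in <- mean(draws >= rope[1] & draws <= rope[2])
  post_out <- 1 - post_in
  note <- NULL
  if (post_out == 0) {
    bf01 <- Inf
    note <- "all posterior draws inside the ROPE; BF01 reported as Inf"
  } else {
    bf01 <- (post_in / post_out) / (prior_in / prior_out)
  }
  structure(list(parameter = parameter, rope = rope,
                 posterior_inside = post_in, prior_inside = prior_in,
                 bf01 = bf01, n_draws = length(draws), note = note),
            class = "rope_result")
}

#' @export
print.rope_result <- function(x, ...) {
  cat(sprintf(
    "ROPE [%.3g, %.3g] for %s: P(in|post) = %.3f, P(in|prior) = %.3f, BF01 = %.3g\n",
    x$rope[1], x$rope[2], x$parameter, x$posterior_inside,
    x$prior_inside, x$bf01))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
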