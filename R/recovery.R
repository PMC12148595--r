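#' Generating geometries for the model-recovery study
#'
#' The nine planted geometries matching the candidate model family: each
#' candidate model's weight set used as ground truth of the pattern
#' generator (the Independent model plants the all-equidistant geometry).
#'
#' @return Named list: each element is `NULL` (Independent) or a
#'   `c(w_mod, w_exp, w_type)` weight vector.
#' @export
recovery_weights <- function() {
  list(
    Independent = NULL,
    Modality = c(1, 0, 0),
    Experience = c(0, 1, 0),
    Type = c(0, 0, 1),
    `Mod|Exp|Type` = c(1, 1, 1),
    `Mod|(Exp|Type)/2` = c(1, 1 / 2, 1 / 2),
    `Mod|(Exp|Type)/3` = c(1, 1 / 3, 1 / 3),
    `Exp|(Mod|Type)/2` = c(1 / 2, 1, 1 / 2),
    `Exp|(Mod|Type)/3` = c(1 / 3, 1, 1 / 3)
  )
}

#' Geometry spec for one generating model
#'
#' Builds the [geometry_spec()] (at the package's default study
#' conditions: 200 channels, unit noise, snr 400, default between-subject
#' variability) that plants the geometry of a named candidate model.
#'
#' @param model Name from [recovery_weights()], or a weight vector.
#' @param ... Overrides passed to [geometry_spec()].
#' @return A `geometry_spec`.
#' @export
recovery_geometry <- function(model, ...) {
  if (is.character(model)) {
    w <- recovery_weights()[[model]]
    if (is.null(w) && model != "Independent") {
      stop(sprintf("unknown generating model '%s'", model))
    }
  } else {
    w <- model
  }
  if (is.null(w)) {
    geometry_spec(independent = TRUE, ...)
  } else {
    geometry_spec(w_mod = w[1], w_exp = w[2], w_type = w[3], ...)
  }
}

#' Model-recovery simulation
#'
#' Repeatedly simulates a group study under one planted geometry and
#' scores the full candidate family against the subject RDMs under both
#' whitening modes. For each replicate the function records which model
#' attains the highest mean score and the one-sided p-value of the
#' generating model against the lower noise ceiling (paired t; a small p
#' means the generating model scores significantly below its own
#' ceiling).
#'
#' @param model Generating model name (see [recovery_weights()]).
#' @param n_reps Number of replicates.
#' @param n_subjects Subjects per replicate (default 30).
#' @param seed Integer seed.
#' @param geometry Optional [geometry_spec()] override; defaults to
#'   `recovery_geometry(model)`.
#' @param modes Whitening modes to evaluate.
#' @return A data.frame with one row per replicate and mode: `rep`,
#'   `mode`, `winner`, `win` (generating model won), `p_ceiling`,
#'   `score`, `ceiling_lower`.
#' @export
simulate_model_recovery <- function(model, n_reps = 10, n_subjects = 30,
                                    seed = 1,
                                    geometry = recovery_geometry(model),
                                    modes = c("distance-covariance",
                                              "identity")) {
  models <- candidate_family()
  if (!model %in% names(models)) {
    stop(sprintf("'%s' is not in the candidate family", model))
  }
  Vs <- lapply(modes, function(m) whitening_matrix(8, mode = m))
  names(Vs) <- modes
  out <- list()
  for (r in seq_len(n_reps)) {
    ps <- generate_patterns(n_subjects, geometry,
                            seed = seed + 7919L * (r - 1L))
    rdms <- subject_rdms(ps)
    for (m in modes) {
      sc <- score_matrix(rdms, models, Vs[[m]])
      nc <- noise_ceiling(rdms, V = Vs[[m]])
      mean_sc <- colMeans(sc)
      winner <- names(models)[which.max(mean_sc)]
      d <- sc[, model] - nc$lower_by_subject
      p <- if (sd(d) == 0) 1 else
        t.test(sc[, model], nc$lower_by_subject, paired = TRUE,
               alternative = "less")$p.value
      out[[length(out) + 1L]] <- data.frame(
        rep = r, mode = m, winner = winner, win = winner == model,
        p_ceiling = p, score = mean_sc[model],
        ceiling_lower = nc$lower, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
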