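#' Complete-case filter
#'
#' Removes every row with a missing rating on any dimension present in the
#' table, the missing-data strategy of the analysis (missingness in the
#' emulated study was below the conventional 5% threshold and judged
#' completely at random, so list-wise deletion leaves estimates unbiased).
#' Per-dimension missingness rates are reported via `message()` and
#' attached as attribute `missingness`.
#'
#' @param ratings A ratings table (see [generate_ratings()]).
#' @param quiet Suppress the missingness message.
#' @return The filtered table.
#' @export
complete_case_filter <- function(ratings, quiet = FALSE) {
  dims <- rating_dims_present(ratings)
  rates <- vapply(dims, function(d) mean(is.na(ratings[[d]])), numeric(1))
  keep <- stats::complete.cases(ratings[, dims, drop = FALSE])
  out <- ratings[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("complete-case filter removed all rows (all-missing data)")
  }
  if (!quiet && any(rates > 0)) {
    message(sprintf("complete-case filter: dropped %d/%d rows (%s)",
                    sum(!keep), length(keep),
                    paste(sprintf("%s %.1f%%", dims, 100 * rates),
                          collapse = ", ")))
  }
  rownames(out) <- NULL
  attr(out, "missingness") <- rates
  out
}

rating_dims_present <- function(ratings) {
  intersect(c("pleasure", "beauty", "moving"), names(ratings))
}

#' Cross-modality dissimilarity score
#'
#' For every (subject, stimulus) pair with both a perception and an
#' imagery trial, computes
#' `S = sum over rating dimensions of (perception - imagery)^2`, ranging
#' from 0 (identical experiences) to `3 * (K-1)^2 = 108` on three 7-point
#' scales. The vividness of the paired imagery trial is carried along.
#' Pairs lacking one modality (e.g. after complete-case filtering) are
#' skipped with a message rather than imputed.
#'
#' @param ratings A complete-case ratings table.
#' @param quiet Suppress the skipped-pair message.
#' @return A data.frame with `subject_id`, `stimulus_id`, `S`,
#'   `vividness`.
#' @export
#' @examples
#' r <- generate_ratings(design_spec(n_subjects = 2), effect_spec())
#' head(dissimilarity_score(r))
dissimilarity_score <- function(ratings, quiet = FALSE) {
  dims <- rating_dims_present(ratings)
  if (!length(dims)) stop("no rating dimension columns found")
  key <- paste(ratings$subject_id, ratings$stimulus_id, ratings$modality)
  if (anyDuplicated(key)) {
    stop("duplicated (subject, stimulus, modality) rows")
  }
  per <- ratings[ratings$modality == "perception", , drop = FALSE]
  ima <- ratings[ratings$modality == "imagery", , drop = FALSE]
  pk <- paste(per$subject_id, per$stimulus_id)
  ik <- paste(ima$subject_id, ima$stimulus_id)
  common <- intersect(pk, ik)
  skipped <- length(unique(c(pk, ik))) - length(common)
  if (skipped > 0 && !quiet) {
    message(sprintf("dissimilarity_score: skipped %d unpaired trial(s)",
                    skipped))
  }
  per <- per[match(common, pk), , drop = FALSE]
  ima <- ima[match(common, ik), , drop = FALSE]
  S <- rowSums((as.matrix(per[, dims, drop = FALSE]) -
                  as.matrix(ima[, dims, drop = FALSE]))^2)
  data.frame(subject_id = per$subject_id, stimulus_id = per$stimulus_id,
             S = as.numeric(S), vividness = ima$vividness,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label trials as high or low aesthetic experience
#'
#' Splits a rating dimension (by default "moving", the focal facet of the
#' profound aesthetic state) into low (1-3) and high (5-7) experiences,
#' excluding midpoint ratings (4). This is the split defining the
#' experience factor of the 8 neural conditions.
#'
#' @param ratings A ratings table.
#' @param dimension Dimension used for the split.
#' @return The table without midpoint trials, with an added `experience`
#'   column ("low"/"high") and attribute `cell_counts` (experience x
#'   modality x type counts).
#' @export
label_experience <- function(ratings, dimension = "moving") {
  if (!dimension %in% names(ratings)) {
    stop(sprintf("dimension '%s' not present", dimension))
  }
  r <- ratings[[dimension]]
  keep <- !is.na(r) & r != 4
  out <- ratings[keep, , drop = FALSE]
  out$experience <- ifelse(out[[dimension]] >= 5, "high", "low")
  attr(out, "cell_counts") <-
    table(experience = out$experience, modality = out$modality,
          type = out$stimulus_type)
  rownames(out) <- NULL
  out
}

#' Subset to highly vivid imagery trials
#'
#' Keeps imagery trials with vividness 6 or 7 together with their paired
#' perception trials, the subgroup in which perception and imagery are
#' compared free of vividness limitations.
#'
#' @param ratings A ratings table.
#' @param quiet Suppress the per-subject retention message.
#' @return The subset table with attribute `retention` (kept imagery
#'   trials per subject).
#' @export
subset_high_vividness <- function(ratings, quiet = FALSE) {
  ima <- ratings$modality == "imagery"
  if (!any(ima)) stop("no imagery rows present")
  keep_ima <- ima & !is.na(ratings$vividness) & ratings$vividness >= 6
  vivid_key <- unique(paste(ratings$subject_id[keep_ima],
                            ratings$stimulus_id[keep_ima]))
  key <- paste(ratings$subject_id, ratings$stimulus_id)
  out <- ratings[key %in% vivid_key, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no trials with vividness >= 6; empty subset")
  }
  retention <- table(factor(ratings$subject_id[keep_ima],
                            levels = unique(ratings$subject_id)))
  if (!quiet) {
    message(sprintf(
      "high-vividness subset: kept %d of %d imagery trials (%d subjects with >= 1 trial)",
      sum(keep_ima), sum(ima), sum(retention > 0)))
  }
  rownames(out) <- NULL
  attr(out, "retention") <- retention
  out
}
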