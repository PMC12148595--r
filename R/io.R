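#' Read and validate a ratings table
#'
#' Reads the tab-delimited ratings format (columns `subject_id`,
#' `stimulus_id`, `stimulus_type`, `modality`, `run`, the rating
#' dimensions, `vividness`) and validates the schema: ratings must be
#' integers in 1..K or missing, vividness must be present exactly on
#' imagery rows, and (subject, stimulus, modality) must be unique.
#' Violations are reported with row numbers.
#'
#' @param path Path to a TSV file.
#' @param scale_K Ordinal scale size (default 7).
#' @return A validated ratings data.frame.
#' @export
read_ratings <- function(path, scale_K = 7) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_ratings(tab, scale_K = scale_K)
}

#' @rdname read_ratings
#' @param ratings A ratings table to validate or write.
#' @export
validate_ratings <- function(ratings, scale_K = 7) {
  req <- c("subject_id", "stimulus_id", "stimulus_type", "modality", "run")
  miss <- setdiff(req, names(ratings))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  dims <- rating_dims_present(ratings)
  if (!length(dims)) stop("no rating dimension columns found")
  problems <- character(0)
  for (d in dims) {
    v <- ratings[[d]]
    bad <- which(!is.na(v) & (v < 1 | v > scale_K | v != round(v)))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "%s outside 1..%d at row(s) %s", d, scale_K,
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (!all(ratings$modality %in% c("perception", "imagery"))) {
    bad <- which(!ratings$modality %in% c("perception", "imagery"))
    problems <- c(problems, sprintf("invalid modality at row(s) %s",
                                    paste(head(bad, 5), collapse = ", ")))
  }
  if ("vividness" %in% names(ratings)) {
    bad <- which(ratings$modality == "perception" &
                   !is.na(ratings$vividness))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "vividness present on perception row(s) %s",
        paste(head(bad, 5), collapse = ", ")))
    }
    bad <- which(ratings$modality == "imagery" & is.na(ratings$vividness))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "vividness missing on imagery row(s) %s",
        paste(head(bad, 5), collapse = ", ")))
    }
    v <- ratings$vividness
    bad <- which(!is.na(v) & (v < 1 | v > scale_K))
    if (length(bad)) {
      problems <- c(problems, sprintf("vividness outside 1..%d at row(s) %s",
                                      scale_K,
                                      paste(head(bad, 5), collapse = ", ")))
    }
  }
  key <- paste(ratings$subject_id, ratings$stimulus_id, ratings$modality)
  if (anyDuplicated(key)) {
    problems <- c(problems, sprintf(
      "duplicated (subject, stimulus, modality) at row(s) %s",
      paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  if (length(problems)) {
    stop(paste(c("invalid ratings table:", problems), collapse = "\n  "))
  }
  ratings
}

#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# pack a channel vector into the 3D volume layout used on disk
pattern_volume <- function(v) array(v, dim = c(length(v), 1, 1))

#' Write a pattern set as NIfTI volumes
#'
#' One gzipped NIfTI volume per subject and condition
#' (`<subject>_<condition>.nii.gz`), a `mask.nii.gz` marking the valid
#' voxels, and a `conditions.json` sidecar listing the condition order of
#' the stored volumes.
#'
#' @param patterns A `pattern_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_patterns <- function(patterns, dir) {
  stopifnot(inherits(patterns, "pattern_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- dim(patterns$data)[3]
  RNifti::writeNifti(pattern_volume(rep(1, P)),
                     file.path(dir, "mask.nii.gz"))
  for (s in seq_along(patterns$subject_ids)) {
    for (cc in seq_along(patterns$labels)) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz",
                                  patterns$subject_ids[s],
                                  patterns$labels[cc]))
      RNifti::writeNifti(pattern_volume(patterns$data[s, cc, ]), f)
    }
  }
  jsonlite::write_json(
    list(conditions = patterns$labels, subjects = patterns$subject_ids),
    file.path(dir, "conditions.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Read a pattern set from NIfTI volumes
#'
#' Loads `<subject>_<condition>.nii.gz` volumes according to the
#' `conditions.json` sidecar, restricts to the voxels selected by the mask
#' and reorders conditions to the canonical order regardless of the order
#' stored in the sidecar.
#'
#' @param dir Directory written by [write_patterns()].
#' @param mask Path to a mask volume (default `mask.nii.gz` in `dir`); the
#'   mask grid must match the pattern volumes.
#' @return A `pattern_set`.
#' @export
read_patterns <- function(dir, mask = file.path(dir, "mask.nii.gz")) {
  sidecar <- jsonlite::read_json(file.path(dir, "conditions.json"),
                                 simplifyVector = TRUE)
  conds <- sidecar$conditions
  unknown <- setdiff(conds, condition_labels())
  if (length(unknown)) {
    stop(sprintf("unknown condition label(s) in sidecar: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (!setequal(conds, condition_labels())) {
    stop("sidecar must list exactly the 8 canonical conditions")
  }
  subjects <- sidecar$subjects
  mvol <- RNifti::readNifti(mask)
  msk <- as.vector(mvol) > 0
  if (sum(msk) < 2) stop("mask selects fewer than 2 voxels")
  P <- sum(msk)
  dat <- array(NA_real_, dim = c(length(subjects), 8, P),
               dimnames = list(subjects, condition_labels(), NULL))
  for (s in seq_along(subjects)) {
    for (cc in conds) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", subjects[s], cc))
      if (!file.exists(f)) {
        stop(sprintf("missing pattern file for subject %s condition %s",
                     subjects[s], cc))
      }
      vol <- RNifti::readNifti(f)
      if (!identical(dim(vol), dim(mvol))) {
        stop(sprintf("grid mismatch between %s and mask", basename(f)))
      }
      dat[s, cc, ] <- as.vector(vol)[msk]
    }
  }
  structure(list(data = dat, labels = condition_labels(),
                 subject_ids = subjects, geometry = NULL,
                 subject_weights = NULL, seed = NULL),
            class = "pattern_set")
}

#' Write a complete synthetic dataset
#'
#' Writes the ratings TSV, the pattern NIfTI volumes with their sidecar,
#' and a JSON manifest recording the generator parameters and seeds, so
#' the dataset can be regenerated byte-identically.
#'
#' @param ratings A ratings table.
#' @param patterns A `pattern_set`.
#' @param path Output directory.
#' @param design,effects The [design_spec()] / [effect_spec()] used (for
#'   the manifest; optional).
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
write_dataset <- function(ratings, patterns, path, design = NULL,
                          effects = NULL) {
  rs <- unique(ratings$subject_id)
  ps <- patterns$subject_ids
  if (!setequal(rs, ps)) {
    stop("subject mismatch between ratings and patterns")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_ratings(ratings, file.path(path, "ratings.tsv"))
  write_patterns(patterns, file.path(path, "patterns"))
  manifest <- list(
    package = "aesthsim",
    version = as.character(packageVersion("aesthsim")),
    created = format(Sys.time(), tz = "UTC"),
    seeds = list(patterns = patterns$seed,
                 design = if (!is.null(design)) design$seed),
    design = if (!is.null(design)) unclass(design),
    effects = if (!is.null(effects)) unclass(effects),
    geometry = if (!is.null(patterns$geometry)) {
      unclass(patterns$geometry)
    },
    files = list(ratings = "ratings.tsv", patterns = "patterns")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param path Dataset directory.
#' @return List with `ratings`, `patterns`, `manifest`.
#' @export
read_dataset <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  list(ratings = read_ratings(file.path(path, "ratings.tsv")),
       patterns = read_patterns(file.path(path, "patterns")),
       manifest = manifest)
}
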