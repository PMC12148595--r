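#' Representational dissimilarity matrix (RDM)
#'
#' An `rdm` is an 8x8 (more generally k x k) symmetric nonnegative matrix
#' with zero diagonal, carrying its condition labels in dimnames. The
#' 28-entry vectorized form used throughout the similarity computations is
#' the upper triangle in row-major order, i.e. pairs (1,2), (1,3), ...,
#' (1,8), (2,3), ..., (7,8).
#'
#' @param m Square numeric matrix, symmetric with zero diagonal.
#' @param labels Character vector of condition labels; defaults to
#'   [condition_labels()] for 8x8 matrices.
#' @return An object of class `rdm`.
#' @seealso [rdm_vector()], [rdm_from_vector()], [factor_rdm()]
#' @export
rdm <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RDM must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("RDM must be symmetric")
  if (any(diag(m) != 0)) stop("RDM must have a zero diagonal")
  if (any(m < 0)) stop("RDM entries must be nonnegative")
  m <- (m + t(m)) / 2
  if (is.null(labels)) {
    labels <- if (nrow(m) == 8L) condition_labels() else
      paste0("C", seq_len(nrow(m)))
  }
  if (length(labels) != nrow(m)) stop("labels length must match dimension")
  dimnames(m) <- list(labels, labels)
  class(m) <- c("rdm", "matrix", "array")
  m
}

#' @export
print.rdm <- function(x, digits = 3, ...) {
  cat(sprintf("RDM over %d conditions (%s)\n", nrow(x),
              paste(rdm_labels(x), collapse = " ")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = NULL, ...) {
  k <- nrow(x)
  image(seq_len(k), seq_len(k), t(unclass(x))[, k:1],
        col = hcl.colors(64, "viridis"), axes = FALSE,
        xlab = "", ylab = "", main = main, ...)
  axis(1, at = seq_len(k), labels = rdm_labels(x), las = 2, cex.axis = 0.8)
  axis(2, at = seq_len(k), labels = rev(rdm_labels(x)), las = 2,
       cex.axis = 0.8)
  invisible(x)
}

#' Condition labels of an RDM
#' @param x An `rdm`.
#' @return Character vector of labels.
#' @export
rdm_labels <- function(x) rownames(x)

#' Vectorize an RDM
#'
#' Extracts the upper triangle in row-major pair order (1,2), (1,3), ...,
#' (7,8), the layout assumed by [whitening_matrix()].
#'
#' @param x An `rdm` (or plain symmetric matrix).
#' @return Numeric vector of length k(k-1)/2 named "A:B" by pair.
#' @export
rdm_vector <- function(x) {
  k <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  v <- unclass(x)[idx]
  names(v) <- paste(rownames(x)[idx[, 1]], rownames(x)[idx[, 2]], sep = ":")
  v
}

#' Rebuild an RDM from its vectorized form
#'
#' @param v Numeric vector of length k(k-1)/2 (row-major upper triangle).
#' @param labels Condition labels; defaults to [condition_labels()] when
#'   the implied dimension is 8.
#' @return An `rdm`.
#' @export
rdm_from_vector <- function(v, labels = NULL) {
  k <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (k != round(k)) stop("vector length is not k(k-1)/2 for integer k")
  k <- as.integer(k)
  m <- matrix(0, k, k)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- v
  m <- m + t(m)
  rdm(m, labels = labels)
}

#' Single-factor model RDMs
#'
#' Binary candidate models predicting that two conditions are maximally
#' dissimilar if and only if they differ on one stimulus attribute:
#' modality (perception vs. imagery), experience (high vs. low) or type
#' (art vs. face).
#'
#' @param factor One of "modality", "experience", "type".
#' @return A binary `rdm`.
#' @export
#' @examples
#' factor_rdm("modality")["HPA", "HIA"] # 1: differs in modality
#' factor_rdm("modality")["HPA", "LPF"] # 0: same modality
factor_rdm <- function(factor = c("modality", "experience", "type")) {
  factor <- match.arg(factor)
  f <- condition_table()[[factor]]
  rdm(outer(f, f, FUN = "!=") + 0)
}

#' Independent model RDM
#'
#' Predicts that all 8 conditions are maximally (and equally) dissimilar
#' to each other: all off-diagonal entries 1.
#'
#' @return A binary `rdm`.
#' @export
independent_rdm <- function() {
  k <- 8L
  rdm(matrix(1, k, k) - diag(k))
}

#' Weighted combination of the factor models
#'
#' Builds `w_mod * Modality + w_exp * Experience + w_type * Type` and
#' rescales the result so its maximum entry equals 1. The rescaling is
#' cosmetic (for display comparability): the cosine-based similarity
#' metrics are invariant to positive scaling.
#'
#' @param w_mod,w_exp,w_type Nonnegative weights; at least one positive.
#' @param name Optional model name stored as attribute.
#' @return An `rdm` with attribute `weights`.
#' @export
#' @examples
#' combine_weighted(1, 0.5, 0.5)["HPA", "LIF"] # all three differ -> 1
combine_weighted <- function(w_mod, w_exp, w_type, name = NULL) {
  w <- c(w_mod, w_exp, w_type)
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be nonnegative")
  if (all(w == 0)) stop("at least one weight must be positive")
  m <- w[1] * unclass(factor_rdm("modality")) +
    w[2] * unclass(factor_rdm("experience")) +
    w[3] * unclass(factor_rdm("type"))
  out <- rdm(m / max(m))
  attr(out, "weights") <- c(w_mod = w[1], w_exp = w[2], w_type = w[3])
  attr(out, "name") <- name
  out
}

#' The candidate model family
#'
#' The nine theory-derived candidate models over modality (Mod),
#' experience (Exp) and stimulus type (Type): the Independent model, the
#' three single-factor models, the equal combination Mod|Exp|Type, and the
#' four graded combinations that down-weight either experience and type or
#' modality and type by a factor of 2 or 3. Optionally the supplementary
#' partial model Exp|Type (weights 0, 1, 1).
#'
#' @param include_partial Add the Exp|Type partial model (10 models).
#' @return Named list of `rdm` objects, each carrying `weights`
#'   (NULL for the Independent model).
#' @export
#' @examples
#' length(candidate_family())       # 9
#' length(candidate_family(TRUE))   # 10
candidate_family <- function(include_partial = FALSE) {
  fam <- list(
    Independent = independent_rdm(),
    Modality = combine_weighted(1, 0, 0),
    Experience = combine_weighted(0, 1, 0),
    Type = combine_weighted(0, 0, 1),
    `Mod|Exp|Type` = combine_weighted(1, 1, 1),
    `Mod|(Exp|Type)/2` = combine_weighted(1, 1 / 2, 1 / 2),
    `Mod|(Exp|Type)/3` = combine_weighted(1, 1 / 3, 1 / 3),
    `Exp|(Mod|Type)/2` = combine_weighted(1 / 2, 1, 1 / 2),
    `Exp|(Mod|Type)/3` = combine_weighted(1 / 3, 1, 1 / 3)
  )
  if (include_partial) {
    fam$`Exp|Type` <- combine_weighted(0, 1, 1)
  }
  for (nm in names(fam)) attr(fam[[nm]], "name") <- nm
  fam
}

#' Entrywise average of RDMs
#'
#' @param rdms List of `rdm` objects with identical label order.
#' @return The mean `rdm`.
#' @export
average_rdm <- function(rdms) {
  if (!length(rdms)) stop("empty RDM list")
  labs <- rdm_labels(rdms[[1]])
  for (r in rdms) {
    if (!identical(rdm_labels(r), labs)) {
      stop("label order mismatch between RDMs")
    }
  }
  m <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  rdm(m, labels = labs)
}
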