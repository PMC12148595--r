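# Independent oracles and small fixture builders used across tests.

# Hand-coded condition attribute table (independent of condition_table()):
# label, experience, modality, type, written out literally.
oracle_conditions <- data.frame(
  label = c("HPA", "LPA", "HPF", "LPF", "HIA", "LIA", "HIF", "LIF"),
  experience = c("high", "low", "high", "low", "high", "low", "high", "low"),
  modality = c("perception", "perception", "perception", "perception",
               "imagery", "imagery", "imagery", "imagery"),
  type = c("art", "art", "face", "face", "art", "art", "face", "face"),
  stringsAsFactors = FALSE
)

# brute-force binary model RDM from the oracle table
oracle_factor_matrix <- function(factor) {
  f <- oracle_conditions[[factor]]
  m <- matrix(0, 8, 8, dimnames = list(oracle_conditions$label,
                                       oracle_conditions$label))
  for (i in 1:8) for (j in 1:8) m[i, j] <- as.numeric(f[i] != f[j])
  m
}

# brute-force weighted model (normalized to max 1)
oracle_weighted_matrix <- function(w_mod, w_exp, w_type) {
  m <- w_mod * oracle_factor_matrix("modality") +
    w_exp * oracle_factor_matrix("experience") +
    w_type * oracle_factor_matrix("type")
  m / max(m)
}

# hand-coded Benjamini-Hochberg step-up adjustment
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# independently coded plain cosine
plain_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# brute-force squared Euclidean distance RDM (double loop)
brute_sq_dist <- function(X) {
  n <- nrow(X)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum((X[i, ] - X[j, ])^2)
    }
  }
  out
}

# tiny ratings table built by hand: one subject, one stimulus, both
# modalities, with explicit rating triples
pair_ratings <- function(per, ima, vividness = 7,
                         subject = "S01", stimulus = "A01",
                         type = "art") {
  data.frame(
    subject_id = subject, stimulus_id = stimulus, stimulus_type = type,
    modality = c("perception", "imagery"), run = 1L,
    pleasure = c(per[1], ima[1]), beauty = c(per[2], ima[2]),
    moving = c(per[3], ima[3]),
    vividness = c(NA_integer_, vividness),
    stringsAsFactors = FALSE
  )
}

# random valid 28-vectors (positive, as squared distances are)
random_rdm_vectors <- function(n, seed) {
  set.seed(seed)
  replicate(n, runif(28, 0.1, 2))
}

# small study ratings for fast Bayesian fits
small_study <- function(seed, n_subjects = 8, n_stimuli_per_type = 5,
                        effects = effect_spec(kappa = 0)) {
  d <- design_spec(n_subjects = n_subjects,
                   n_stimuli_per_type = n_stimuli_per_type,
                   n_runs = 2, seed = seed)
  generate_ratings(d, effects, seed = seed)
}
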