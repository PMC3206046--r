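#' Construct an additive binding-energy model
#'
#' The generative energy model (GEM) writes a ligand's binding energy
#' (RT units, relative to the optimal sequence) as a sum of position-specific
#' terms: `E(s) = e0 + sum_k terms[k, s_k]`.  The optimal nucleotide's entry
#' at each position is structurally 0 (the anchor), all other terms are
#' non-negative, and a binary indicator matrix `delta` records which terms
#' are currently included in the model (excluded terms are exactly 0).  A
#' per-sequence Gaussian error `epsilon ~ N(0, sigma^2)` absorbs deviations
#' of the observed energies from the additive prediction, so the model
#' automatically defers to count-based estimates when the additive picture
#' is poor or the counts are deep.
#'
#' `interactions` is a scaffold hook for pairwise/higher-order terms; the
#' sampler constrains all interactive terms to zero and the slot is kept
#' empty in this implementation.
#'
#' @param optimal_sequence The consensus/optimal DNA sequence (length L).
#' @param terms L x 4 numeric matrix of non-negative energies (columns
#'   A, C, G, T); defaults to all zero.
#' @param indicators L x 4 binary inclusion matrix `delta`; defaults to
#'   `terms > 0`.
#' @param sigma Error scale of the per-sequence Gaussian residual, > 0.
#' @param testable_mask L x 4 logical matrix marking which
#'   (position, nucleotide) combinations are observed in the data; terms
#'   outside the mask carry no information and are never sampled.  Defaults
#'   to everything testable.
#' @param e0 Energy offset of the optimal sequence (RT units; 0 when
#'   energies are expressed relative to the optimal Kd).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(optimal_sequence, terms = NULL, indicators = NULL,
                         sigma = 0.5, testable_mask = NULL, e0 = 0) {
  optimal_sequence <- toupper(optimal_sequence)
  check_dna(optimal_sequence)
  L <- nchar(optimal_sequence)
  opt <- seq_matrix(optimal_sequence)[, 1]
  if (is.null(terms)) terms <- matrix(0, L, 4)
  if (!is.matrix(terms) || !identical(dim(terms), c(L, 4L)))
    stop("terms must be an L x 4 matrix")
  if (any(terms < 0)) stop("energy terms must be non-negative")
  if (is.null(indicators)) indicators <- (terms > 0) * 1
  if (!identical(dim(indicators), dim(terms)))
    stop("indicators must match terms in shape")
  if (is.null(testable_mask)) testable_mask <- matrix(TRUE, L, 4)
  anchor <- matrix(FALSE, L, 4)
  anchor[cbind(seq_len(L), opt)] <- TRUE
  terms[anchor] <- 0
  indicators[anchor] <- 0
  terms[indicators == 0] <- 0
  dimnames(terms) <- dimnames(indicators) <- dimnames(testable_mask) <-
    dimnames(anchor) <- list(seq_len(L), NUCS)
  if (sigma <= 0) stop("sigma must be strictly positive")
  structure(list(optimal_sequence = optimal_sequence, e0 = e0,
                 terms = terms, indicators = indicators, sigma = sigma,
                 testable_mask = testable_mask, anchor = anchor,
                 interactions = list()),
            class = "energy_model")
}

#' Testable (position, nucleotide) combinations in a sequence set
#'
#' A term is testable only if some sequence in the data actually carries
#' that nucleotide at that position; untested variants are reported as
#' "no information", never as zero-energy.
#'
#' @param sequences Character vector of same-length DNA sequences.
#' @return L x 4 logical matrix (columns A, C, G, T).
#' @export
testable_mask <- function(sequences) {
  sm <- seq_matrix(sequences)
  L <- nrow(sm)
  m <- matrix(FALSE, L, 4, dimnames = list(seq_len(L), NUCS))
  for (k in seq_len(L)) m[k, sort(unique(sm[k, ]))] <- TRUE
  m
}

#' Additive energy of sequences under an energy model
#'
#' `e0` plus the sum of the included position-specific terms of the
#' nucleotides the sequence carries; the optimal sequence scores exactly
#' `e0`, and each substitution adds exactly its term.
#'
#' @param sequences Character vector of DNA sequences of the model's length.
#' @param model An [energy_model()].
#' @return Named numeric vector of energies (RT units).
#' @export
additive_energy <- function(sequences, model) {
  sequences <- toupper(sequences)
  check_dna(sequences)
  if (any(nchar(sequences) != nchar(model$optimal_sequence)))
    stop("sequence length does not match the energy model")
  sm <- seq_matrix(sequences)
  L <- nrow(sm)
  e <- vapply(seq_along(sequences), function(i)
    sum(model$terms[cbind(seq_len(L), sm[, i])]), numeric(1))
  stats::setNames(model$e0 + e, sequences)
}

#' Energy-model residuals
#'
#' The residual of ligand i is its observed relative energy (from its Kd
#' against the optimal Kd) minus the additive prediction:
#' `epsilon_i = ln(kd_i / kd_opt) - (additive_energy(s_i) - e0)`.
#' Residuals are zero when the Kds sit exactly on the additive model, and
#' reference ligands contribute residuals like any other (their Kds are
#' data-like constants).
#'
#' @param kd Named vector of dissociation constants (nM).
#' @param kd_opt Dissociation constant of the optimal sequence (nM).
#' @param model An [energy_model()].
#' @return Named residual vector (RT units).
#' @export
gem_residuals <- function(kd, kd_opt, model) {
  pred <- additive_energy(names(kd), model) - model$e0
  kd_to_energy(kd, kd_opt) - unname(pred)
}

#' Log-likelihood of the generative energy model
#'
#' The BBM multinomial log-likelihood plus the Gaussian penalty on the
#' energy-model residuals: `bbm_log_likelihood + sum_i log N(eps_i; 0,
#' sigma^2)`.  As sigma grows the penalty flattens and the GEM ranking of
#' states approaches the BBM ranking.  Non-positive sigma scores `-Inf`.
#'
#' @param state A [binding_state()].
#' @param os An [oligo_set()].
#' @param model An [energy_model()].
#' @param kd_opt Dissociation constant assigned to the optimal sequence;
#'   defaults to its entry in `state$kd` (the optimal sequence must then be
#'   a member of the set).
#' @return Scalar log-likelihood, possibly `-Inf`.
#' @export
gem_log_likelihood <- function(state, os, model, kd_opt = NULL) {
  if (model$sigma <= 0) return(-Inf)
  if (is.null(kd_opt)) {
    if (!model$optimal_sequence %in% names(state$kd))
      stop("optimal sequence absent from the state; supply kd_opt")
    kd_opt <- state$kd[[model$optimal_sequence]]
  }
  eps <- gem_residuals(state$kd, kd_opt, model)
  bbm_log_likelihood(state, os) +
    sum(stats::dnorm(eps, 0, model$sigma, log = TRUE))
}

#' Posterior inclusion probabilities of energy terms
#'
#' Fraction of post-burn-in samples in which each (position, nucleotide)
#' term was included in the model.  Cells outside the testable mask are
#' `NA` ("no information"), not 0.
#'
#' @param delta_samples Matrix of 0/1 indicator draws, one row per sample
#'   and one column per term, with columns ordered position-major
#'   (position 1 A..T, position 2 A..T, ...), as produced by [fit_gem()].
#' @param model The [energy_model()] supplying the mask and anchors.
#' @return L x 4 matrix of inclusion probabilities with `NA` for untested
#'   variants; anchored (optimal-nucleotide) entries are 0.
#' @export
inclusion_probability <- function(delta_samples, model) {
  if (nrow(delta_samples) < 1) stop("need at least one posterior sample")
  L <- nchar(model$optimal_sequence)
  pr <- matrix(colMeans(delta_samples), L, 4, byrow = TRUE,
               dimnames = list(seq_len(L), NUCS))
  pr[!model$testable_mask] <- NA_real_
  pr[model$anchor] <- 0
  pr
}
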