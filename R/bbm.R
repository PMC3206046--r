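#' Construct a binding-model parameter state
#'
#' The free parameters of the basic binding model (BBM) are the pre-bound
#' frequency vector `P`, the dissociation constants of the non-reference
#' ligands, and the free TF concentration; binding probabilities `theta` and
#' bound frequencies `B` are derived.  Reference ligands keep their known
#' Kds, which are treated as fixed constants without uncertainty.
#'
#' @param p Named pre-bound frequency vector (simplex, strictly positive).
#' @param kd Named vector of dissociation constants in nM for *all* ligands;
#'   entries named in `ref_kds` are overwritten by the known values.
#' @param tf_free Free TF concentration, nM.
#' @param ref_kds Named numeric vector of known reference Kds (may be empty).
#' @param tf_total Optional total TF concentration (nM); a hard upper bound
#'   on `tf_free`.
#' @return An object of class `binding_state`.
#' @export
binding_state <- function(p, kd, tf_free, ref_kds = numeric(),
                          tf_total = NULL) {
  if (is.null(names(p)) || is.null(names(kd)))
    stop("p and kd must be named by sequence")
  if (!identical(names(p), names(kd)))
    stop("p and kd must be named identically and in the same order")
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be strictly positive and sum to 1")
  if (length(ref_kds)) kd[names(ref_kds)] <- ref_kds
  if (any(kd <= 0)) stop("kd entries must be strictly positive")
  if (tf_free <= 0) stop("tf_free must be strictly positive")
  if (!is.null(tf_total) && tf_free >= tf_total)
    stop("tf_free must be less than tf_total")
  structure(list(p = p, kd = kd, tf_free = tf_free,
                 ref_kds = ref_kds, tf_total = tf_total),
            class = "binding_state")
}

#' Derived parameters of a binding state
#'
#' Computes the quantities that are deterministic functions of the free
#' parameters: per-ligand binding probabilities `theta` (reference ligands
#' use their fixed known Kds), bound frequencies `b`, and binding energies
#' relative to the minimum-Kd ligand.
#'
#' @param state A [binding_state()].
#' @return List with `theta`, `b`, `energies` (all named by sequence).
#' @export
derived_parameters <- function(state) {
  theta <- fraction_bound(state$tf_free, state$kd)
  b <- bound_freqs(state$p, theta)
  energies <- kd_to_energy(state$kd, min(state$kd))
  list(theta = theta, b = b, energies = energies)
}

#' Log-likelihood of the basic binding model
#'
#' The observed counts in each fraction are multinomial draws from the
#' parametric frequencies: `sum_i C_i ln P_i + sum_i D_i ln B_i`, with `B`
#' derived from `(P, Kd, tf_free)`.  The multinomial normalization constants
#' are dropped (they do not depend on the parameters), so only differences
#' between two evaluations are meaningful.  A state whose `tf_free` exceeds
#' `tf_total`, or that puts non-positive frequency on a ligand with a
#' non-zero count, scores `-Inf` (a rejected state, not an exception).
#'
#' @param state A [binding_state()].
#' @param os An [oligo_set()] with the observed counts.
#' @return Scalar log-likelihood (constant-free), possibly `-Inf`.
#' @export
bbm_log_likelihood <- function(state, os) {
  if (!identical(names(state$p), os$sequences))
    stop("state and oligo_set cover different sequences")
  if (!is.null(state$tf_total) && state$tf_free >= state$tf_total)
    return(-Inf)
  if (any(state$p <= 0) || any(state$kd <= 0) || state$tf_free <= 0)
    return(-Inf)
  theta <- state$tf_free / (state$tf_free + state$kd)
  ptheta <- state$p * theta
  s <- sum(ptheta)
  C <- os$pre_counts
  D <- os$bound_counts
  # observed zeros contribute 0 to each sum
  sum(C * log(state$p)) + sum(D * log(ptheta)) - os$n_bound * log(s)
}

#' Initialize a binding state from observed counts
#'
#' Plumbing for starting an MCMC run: `P` is initialized from
#' pseudocount-smoothed pre-bound frequencies, `tf_free` (unless supplied)
#' from [calibrate_from_references()] applied to the smoothed frequencies,
#' and the Kds by inverting the frequency transformation.  Enrichment ratios
#' implying binding probabilities at or above 1 (possible in noisy data) are
#' clamped into (0, 1) here only; the inversion itself refuses them.
#'
#' @param os An [oligo_set()].
#' @param pseudocount Smoothing pseudocount added to every count
#'   (default 0.5).
#' @param tf_free Optional fixed/known free TF concentration (nM); required
#'   when fewer than 2 references are available.
#' @param tf_total Optional total TF concentration bound (nM).
#' @return A [binding_state()].
#' @export
initialize_state <- function(os, pseudocount = 0.5, tf_free = NULL,
                             tf_total = NULL) {
  K <- length(os$sequences)
  p <- (os$pre_counts + pseudocount) / (os$n_pre + K * pseudocount)
  b <- (os$bound_counts + pseudocount) / (os$n_bound + K * pseudocount)
  nref <- length(os$ref_kds)
  if (is.null(tf_free)) {
    if (nref < 2)
      stop("identifiability: supply tf_free or at least 2 reference Kds")
    cal <- tryCatch(calibrate_from_references(p, b, os$ref_kds),
                    error = function(e) NULL)
    if (!is.null(cal) && is.finite(cal$tf_free) && cal$tf_free > 0) {
      tf_free <- cal$tf_free
      scale <- cal$enrichment_scale
    } else {
      # noisy counts can make the exact calibration infeasible; fall back
      # to a half-bound guess anchored at the reference Kd scale
      r <- names(os$ref_kds)[1]
      tf_free <- exp(mean(log(os$ref_kds)))
      scale <- fraction_bound(tf_free, os$ref_kds[[1]]) /
        (b[[r]] / p[[r]])
    }
  } else {
    if (tf_free <= 0) stop("tf_free must be strictly positive")
    if (nref >= 1) {
      r <- names(os$ref_kds)[1]
      theta_r <- fraction_bound(tf_free, os$ref_kds[[1]])
      scale <- theta_r / (b[[r]] / p[[r]])
    } else {
      # no references: anchor the scale so the median ligand is half bound
      scale <- 0.5 / stats::median(b / p)
    }
  }
  theta <- pmin(pmax(scale * b / p, 1e-6), 1 - 1e-6)
  kd <- tf_free * (1 - theta) / theta
  if (!is.null(tf_total) && tf_free >= tf_total)
    tf_free <- 0.99 * tf_total
  binding_state(p = p, kd = kd, tf_free = tf_free,
                ref_kds = os$ref_kds, tf_total = tf_total)
}
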