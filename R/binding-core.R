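#' Fraction of a ligand bound at equilibrium
#'
#' The hyperbolic binding isotherm: a ligand with dissociation constant `kd`
#' exposed to free transcription factor at concentration `tf_free` is bound
#' with probability `theta = tf_free / (tf_free + kd)`.  Both arguments are
#' in nM and are recycled against each other.
#'
#' @param tf_free Free transcription-factor concentration(s), nM, > 0.
#' @param kd Dissociation constant(s), nM, > 0.
#' @return Binding probabilities, strictly inside (0, 1).
#' @examples
#' fraction_bound(9, 1)        # 0.9
#' fraction_bound(5, 5)        # 0.5 for any kd = tf_free
#' @export
fraction_bound <- function(tf_free, kd) {
  if (any(!is.finite(tf_free)) || any(tf_free <= 0))
    stop("tf_free must be strictly positive")
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be strictly positive")
  tf_free / (tf_free + kd)
}

#' Bound-fraction frequencies from pre-bound frequencies
#'
#' The physical transformation between the two pools: the relative frequency
#' of ligand i in the bound fraction is its pre-bound frequency multiplied by
#' its probability of binding, renormalized over the ligands considered:
#' `B_i = P_i * theta_i / sum_j P_j * theta_j`.
#'
#' @param p Pre-bound frequency vector (simplex).
#' @param theta Per-ligand binding probabilities in (0, 1), same length.
#' @return Bound frequency vector summing to 1.
#' @export
bound_freqs <- function(p, theta) {
  if (length(p) != length(theta))
    stop("p and theta must have the same length")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a frequency vector on the simplex")
  if (any(theta <= 0) || any(theta >= 1))
    stop("theta entries must lie strictly in (0, 1)")
  num <- p * theta
  s <- sum(num)
  if (s <= 0) stop("all-zero numerator in bound_freqs")
  num / s
}

#' Calibrate free TF concentration and enrichment scale from references
#'
#' Given pre-bound and bound frequencies and at least two reference ligands
#' with known Kds, solves for the free TF concentration and the
#' proportionality constant `s` linking enrichment ratios to binding
#' probabilities, `theta_i = s * B_i / P_i` (in the exact model
#' `s = sum_j P_j theta_j`).  Each reference contributes one equation
#' `theta_r (tf + Kd_r) = tf`; two references give two equations in the two
#' unknowns, more give a least-squares solution.  The system is linear in
#' `(s, s/tf)` and is solved that way.
#'
#' @param p Named pre-bound frequency vector (or frequencies for the
#'   reference ligands only).
#' @param b Named bound frequency vector, same names as `p`.
#' @param ref_kds Named numeric vector (>= 2 entries) of known Kds in nM;
#'   names select the reference entries of `p` and `b`.
#' @return A list with `tf_free` (nM), `enrichment_scale`, and `residual`
#'   (root-mean-square residual of the calibration equations; 0 for an exact
#'   two-reference system).
#' @export
calibrate_from_references <- function(p, b, ref_kds) {
  if (length(ref_kds) < 2) stop("at least 2 reference Kds are required")
  if (is.null(names(ref_kds))) stop("ref_kds must be named by sequence")
  refs <- names(ref_kds)
  if (!is.null(names(p))) p <- p[refs]
  if (!is.null(names(b))) b <- b[refs]
  if (length(p) != length(refs) || length(b) != length(refs) ||
      any(is.na(p)) || any(is.na(b)))
    stop("p and b must contain entries for every reference sequence")
  if (any(p <= 0) || any(b <= 0))
    stop("reference entries of p and b must be strictly positive")
  r <- as.numeric(b / p)
  kd <- as.numeric(ref_kds)
  # theta_r = s * r_r and theta_r = tf/(tf + kd_r)
  # =>  s * r_r * kd_r / tf + s * r_r = 1: linear in (alpha, beta) = (s, s/tf)
  X <- cbind(r, r * kd)
  if (qr(X)$rank < 2)
    stop("degenerate reference system: identical enrichment ratios and Kds")
  fit <- stats::lm.fit(X, rep(1, length(r)))
  alpha <- fit$coefficients[1]
  beta <- fit$coefficients[2]
  if (!is.finite(alpha) || !is.finite(beta) || beta <= 0 || alpha <= 0)
    stop("calibration has no positive solution; check reference ",
         "enrichment ratios")
  tf_free <- as.numeric(alpha / beta)
  theta <- alpha * r
  if (any(theta <= 0) || any(theta >= 1 - 1e-12))
    stop("calibration implies reference binding probabilities outside (0,1)")
  list(tf_free = tf_free,
       enrichment_scale = as.numeric(alpha),
       residual = sqrt(mean(fit$residuals^2)))
}

#' Invert the frequency transformation to estimate one Kd
#'
#' Given one ligand's pre-bound and bound frequencies and a calibrated
#' `(tf_free, enrichment_scale)` pair, recovers its dissociation constant:
#' `theta_i = enrichment_scale * b_i / p_i`, then
#' `kd = tf_free * (1 - theta_i) / theta_i`.  An implied `theta_i >= 1` is an
#' error (inconsistent frequencies or a wrong calibration), never silently
#' truncated.
#'
#' @param p_i,b_i Pre-bound and bound frequencies, > 0 (vectorized).
#' @param tf_free Free TF concentration, nM.
#' @param enrichment_scale Proportionality constant from
#'   [calibrate_from_references()].
#' @return Dissociation constant(s) in nM.
#' @export
kd_from_freqs <- function(p_i, b_i, tf_free, enrichment_scale) {
  if (any(p_i <= 0) || any(b_i <= 0))
    stop("p_i and b_i must be strictly positive")
  if (tf_free <= 0) stop("tf_free must be strictly positive")
  theta <- enrichment_scale * b_i / p_i
  if (any(theta >= 1))
    stop("implied binding probability >= 1; frequencies are inconsistent ",
         "with the calibration")
  if (any(theta <= 0)) stop("implied binding probability <= 0")
  tf_free * (1 - theta) / theta
}

#' Map between dissociation constants and relative binding energies
#'
#' Binding energies are dimensionless (units of RT) and defined relative to
#' the optimal (lowest-Kd) sequence: `energy = ln(kd / kd_opt)`, so the
#' optimal sequence has energy 0 and weaker binders have positive energy.
#' Only the ratio `kd / kd_opt` ever enters the model, so the absolute RT*T
#' product is never needed.
#'
#' @param kd Dissociation constant(s), nM, > 0.
#' @param kd_opt Dissociation constant of the optimal sequence, nM, > 0.
#' @return `kd_to_energy`: energies in RT units; `energy_to_kd`: Kds in nM.
#' @export
kd_to_energy <- function(kd, kd_opt) {
  if (any(kd <= 0) || any(kd_opt <= 0))
    stop("kd and kd_opt must be strictly positive")
  log(kd / kd_opt)
}

#' @param energy Relative binding energy (RT units).
#' @rdname kd_to_energy
#' @export
energy_to_kd <- function(energy, kd_opt) {
  if (any(kd_opt <= 0)) stop("kd_opt must be strictly positive")
  kd_opt * exp(energy)
}
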