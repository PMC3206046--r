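#' RMSE of log10 dissociation constants
#'
#' The headline accuracy metric: `sqrt(mean((log10 est - log10 truth)^2))`
#' over the ligands common to both vectors, optionally excluding reference
#' ligands (whose Kds are inputs, not estimates).  Invariant to ligand
#' ordering; 0 iff every estimate is exact; 1.0 when every estimate is off
#' by a factor of 10.
#'
#' @param estimated Named vector of estimated Kds (nM).
#' @param truth Named vector of true Kds (nM).
#' @param exclude Optional character vector of sequences to exclude
#'   (typically the references).
#' @return Scalar RMSE (log10 units).
#' @export
log_kd_rmse <- function(estimated, truth, exclude = NULL) {
  common <- intersect(names(estimated), names(truth))
  common <- setdiff(common, exclude)
  if (!length(common)) stop("no ligands in common to score")
  if (any(estimated[common] <= 0) || any(truth[common] <= 0))
    stop("Kds must be positive")
  sqrt(mean((log10(estimated[common]) - log10(truth[common]))^2))
}

#' Categorize a Kd against a target distribution
#'
#' Labels a dissociation constant relative to the Kds of the target
#' sequences: `"low"` below the minimum target Kd (a stronger binder than
#' any target), `"medium"` within `factor` times the minimum (close to the
#' strongest targets), `"high"` otherwise (in the middle/upper range).
#'
#' @param kd Kd value(s), nM.
#' @param kd_distribution Kds of the target sequences, nM.
#' @param factor "Close to the lowest" multiplier (default 3).
#' @return Character vector of labels.
#' @export
categorize_kd <- function(kd, kd_distribution, factor = 3) {
  if (!length(kd_distribution)) stop("empty target Kd distribution")
  lo <- min(kd_distribution)
  ifelse(kd < lo, "low", ifelse(kd <= factor * lo, "medium", "high"))
}

#' Compare per-ligand posterior coefficients of variation of two fits
#'
#' The CV (posterior std over posterior mean of Kd) measures relative
#' uncertainty per ligand; comparing the count-only model against the
#' energy model shows where information sharing tightens the posterior.
#'
#' @param bbm_fit,gem_fit Two [fit_bbm()]/[fit_gem()] results over the same
#'   ligand set (>= 100 pooled draws each).
#' @return data.frame with `sequence`, `cv_bbm`, `cv_gem`.
#' @export
cv_compare <- function(bbm_fit, gem_fit) {
  if (!identical(bbm_fit$sequences, gem_fit$sequences))
    stop("fits cover different ligand sets")
  if (nrow(bbm_fit$samples) < 100 || nrow(gem_fit$samples) < 100)
    stop("need >= 100 posterior draws per fit")
  cv <- function(fit) {
    d <- kd_draws(fit)
    mu <- colMeans(d)
    if (any(mu <= 0)) stop("non-positive posterior mean Kd")
    apply(d, 2, stats::sd) / mu
  }
  data.frame(sequence = bbm_fit$sequences,
             cv_bbm = unname(cv(bbm_fit)), cv_gem = unname(cv(gem_fit)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior summary table of position-specific energy terms
#'
#' Per (position, nucleotide): posterior mean and std of the energy term,
#' counting a term as 0 in draws where it is excluded from the model.  The
#' minimum-mean-energy nucleotide at each position is marked `optimal`, and
#' variants never observed in the data are marked untested and carry no
#' numbers.
#'
#' @param samples Posterior sample matrix containing `e.<pos><nuc>` columns
#'   (pooled across chains), as in a [fit_gem()] result.
#' @param delta Matching matrix of 0/1 inclusion draws.
#' @param model The [energy_model()] supplying anchors and the testable
#'   mask.
#' @return data.frame with columns `position`, `nucleotide`, `mean`, `sd`,
#'   `optimal` (logical), `untested` (logical).
#' @export
energy_table <- function(samples, delta, model) {
  L <- nchar(model$optimal_sequence)
  ecols <- paste0("e.", rep(seq_len(L), each = 4), rep(NUCS, L))
  e <- samples[, ecols, drop = FALSE]
  out <- data.frame(position = rep(seq_len(L), each = 4),
                    nucleotide = rep(NUCS, L),
                    mean = colMeans(e),
                    sd = apply(e, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  tm <- as.vector(t(model$testable_mask))   # position-major
  out$untested <- !tm
  out$mean[out$untested] <- NA_real_
  out$sd[out$untested] <- NA_real_
  out$optimal <- FALSE
  for (k in seq_len(L)) {
    rows <- which(out$position == k & !out$untested)
    if (length(rows))
      out$optimal[rows[which.min(out$mean[rows])]] <- TRUE
  }
  out
}

#' Coverage of credible intervals against known truth
#'
#' Fraction of (non-reference) ligands whose true Kd falls inside the
#' central credible interval of the fitted posterior.
#'
#' @param fit A [fit_bbm()]/[fit_gem()] result.
#' @param truth Named true Kd vector (nM).
#' @param level Interval mass (default 0.95).
#' @return Scalar coverage in `[0, 1]`.
#' @export
ci_coverage <- function(fit, truth, level = 0.95) {
  a <- (1 - level) / 2
  d <- kd_draws(fit)
  seqs <- setdiff(intersect(colnames(d), names(truth)),
                  names(fit$ref_kds))
  lo <- apply(d[, seqs, drop = FALSE], 2, stats::quantile, a)
  hi <- apply(d[, seqs, drop = FALSE], 2, stats::quantile, 1 - a)
  mean(truth[seqs] >= lo & truth[seqs] <= hi)
}

#' Accuracy report for a fit against simulation truth
#'
#' Bundles the evaluation metrics used when validating designs on simulated
#' data: log10-Kd RMSE over non-reference ligands, signed per-ligand log
#' errors, Kd categories, and 95% CI coverage.
#'
#' @param fit A [fit_bbm()]/[fit_gem()] result.
#' @param truth Named true Kd vector (nM).
#' @param factor Category factor for [categorize_kd()].
#' @return Object of class `accuracy_report`: list with `rmse_log_kd`,
#'   `per_oligo` (data.frame: sequence, true_kd, est_kd, log10_error,
#'   category), `coverage95`.
#' @export
accuracy_report <- function(fit, truth, factor = 3) {
  est <- stats::setNames(fit$kd_summary$mean, fit$kd_summary$sequence)
  refs <- names(fit$ref_kds)
  nonref <- setdiff(intersect(names(est), names(truth)), refs)
  per <- data.frame(sequence = nonref,
                    true_kd = unname(truth[nonref]),
                    est_kd = unname(est[nonref]),
                    log10_error = log10(est[nonref]) - log10(truth[nonref]),
                    category = categorize_kd(truth[nonref], truth),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rmse_log_kd = log_kd_rmse(est, truth, exclude = refs),
                 per_oligo = per,
                 coverage95 = ci_coverage(fit, truth)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report: log10-Kd RMSE %.3f over %d ligands; ",
              x$rmse_log_kd, nrow(x$per_oligo)))
  cat(sprintf("95%% CI coverage %.1f%%\n", 100 * x$coverage95))
  invisible(x)
}
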