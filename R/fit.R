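#' Fit the basic binding model or the generative energy model
#'
#' Runs `config$n_chains` MCMC chains (seeds `seed, seed + 1009, ...`),
#' pools the post-burn-in draws, and summarizes the posterior of every Kd
#' (nM), the free TF concentration, and -- for the GEM -- the error scale
#' sigma and the position-specific energy terms.  Point estimates are
#' posterior means; intervals are central 95% credible intervals.  With
#' >= 2 chains a Gelman-Rubin-style within/between-chain variance ratio is
#' reported per parameter.
#'
#' @param os An [oligo_set()].  `fit_bbm` requires >= 2 reference Kds unless
#'   `tf_free` is supplied; `fit_gem` accepts a single reference.
#' @param config An [mcmc_config()].
#' @param tf_free,tf_total Optional known free TF concentration (nM; also
#'   used as the starting value) and total-TF upper bound.
#' @param seed Base seed; defaults to `config$seed`.
#' @param ... Passed to [run_mcmc()] (block switches, `init`).
#' @return An object of class `bindkd_fit`: list with `kd_summary`
#'   (data.frame: sequence, mean, sd, q025, q975, is_reference),
#'   `tf_summary`, `chains` (list of [run_mcmc()] results), pooled
#'   `samples`, `convergence` (PSRF per parameter or NULL), `model`, and for
#'   the GEM `sigma_summary`, `energy_summary` (see [energy_table()]),
#'   `inclusion` (see [inclusion_probability()]).
#' @export
fit_bbm <- function(os, config = mcmc_config(), tf_free = NULL,
                    tf_total = NULL, seed = config$seed, ...) {
  if (length(os$ref_kds) < 2 && is.null(tf_free))
    stop("fit_bbm needs >= 2 reference Kds, or a known tf_free")
  fit_engine(os, "bbm", config, tf_free, tf_total, seed,
             optimal_sequence = NULL, ...)
}

#' @param optimal_sequence GEM: consensus sequence (member of the set);
#'   default: smallest-initial-Kd member.
#' @rdname fit_bbm
#' @export
fit_gem <- function(os, config = mcmc_config(), optimal_sequence = NULL,
                    tf_free = NULL, tf_total = NULL, seed = config$seed,
                    ...) {
  if (length(os$ref_kds) < 1 && is.null(tf_free))
    stop("fit_gem needs at least 1 reference Kd, or a known tf_free")
  fit_engine(os, "gem", config, tf_free, tf_total, seed,
             optimal_sequence = optimal_sequence, ...)
}

fit_engine <- function(os, model, config, tf_free, tf_total, seed,
                       optimal_sequence, ...) {
  fixed_tf <- !is.null(tf_free) && length(os$ref_kds) < 2
  chains <- lapply(seq_len(config$n_chains), function(i)
    run_mcmc(os, model = model, config = config,
             tf_free = tf_free, tf_total = tf_total,
             optimal_sequence = optimal_sequence,
             sample_tf = if (fixed_tf) FALSE else TRUE,
             seed = seed + (i - 1L) * 1009L, ...))
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  conv <- if (length(chains) >= 2) convergence_ratio(chains) else NULL

  kd_cols <- paste0("kd.", os$sequences)
  kd_draws <- samples[, kd_cols, drop = FALSE]
  kd_summary <- data.frame(
    sequence = os$sequences,
    mean = colMeans(kd_draws),
    sd = apply(kd_draws, 2, stats::sd),
    q025 = apply(kd_draws, 2, stats::quantile, 0.025),
    q975 = apply(kd_draws, 2, stats::quantile, 0.975),
    is_reference = os$sequences %in% names(os$ref_kds),
    row.names = NULL, stringsAsFactors = FALSE)
  tf_summary <- c(mean = mean(samples[, "tf_free"]),
                  sd = stats::sd(samples[, "tf_free"]),
                  q025 = unname(stats::quantile(samples[, "tf_free"], 0.025)),
                  q975 = unname(stats::quantile(samples[, "tf_free"], 0.975)))

  out <- list(model = model, kd_summary = kd_summary,
              tf_summary = tf_summary, samples = samples, chains = chains,
              convergence = conv, config = config, sequences = os$sequences,
              ref_kds = os$ref_kds)
  if (model == "gem") {
    out$optimal_sequence <- chains[[1]]$optimal_sequence
    out$sigma_summary <- c(mean = mean(samples[, "sigma"]),
                           sd = stats::sd(samples[, "sigma"]))
    em <- energy_model(out$optimal_sequence,
                       testable_mask = testable_mask(os$sequences))
    delta <- do.call(rbind, lapply(chains, `[[`, "delta"))
    out$inclusion <- inclusion_probability(delta, em)
    out$energy_summary <- energy_table(samples, delta, em)
    out$delta <- delta
  }
  class(out) <- "bindkd_fit"
  out
}

#' @export
print.bindkd_fit <- function(x, ...) {
  cat(sprintf("bindkd_fit (%s): %d ligands, %d pooled posterior draws\n",
              toupper(x$model), nrow(x$kd_summary), nrow(x$samples)))
  cat(sprintf("  tf_free: %.3g nM (95%% CI %.3g-%.3g)\n",
              x$tf_summary["mean"], x$tf_summary["q025"],
              x$tf_summary["q975"]))
  if (!is.null(x$sigma_summary))
    cat(sprintf("  energy-model error sigma: %.3g (sd %.2g)\n",
                x$sigma_summary["mean"], x$sigma_summary["sd"]))
  if (!is.null(x$convergence)) {
    bad <- sum(x$convergence > 1.1, na.rm = TRUE)
    cat(sprintf("  convergence: max PSRF %.3f (%d parameter(s) > 1.1)\n",
                max(x$convergence, na.rm = TRUE), bad))
  }
  ord <- order(x$kd_summary$mean)
  cat("  strongest binders:\n")
  print(utils::head(x$kd_summary[ord, ], 5), row.names = FALSE)
  invisible(x)
}

#' Posterior Kd draws of a fit
#'
#' @param fit A [fit_bbm()]/[fit_gem()] result.
#' @return Matrix of pooled posterior Kd draws (nM), one column per ligand,
#'   columns named by sequence.
#' @export
kd_draws <- function(fit) {
  m <- fit$samples[, paste0("kd.", fit$sequences), drop = FALSE]
  colnames(m) <- fit$sequences
  m
}
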