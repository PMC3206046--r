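#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings sampler.  Proposals are symmetric
#' Gaussian on each block's unconstrained scale (log Kd, log tf_free,
#' log sigma, logit frequency coordinates, energy terms reflected into
#' `[0, rj_birth_width]`), and flat priors are used throughout, so the
#' acceptance ratio reduces to the likelihood ratio plus the exact Jacobian
#' terms of the constrained moves.  Widths adapt multiplicatively toward the
#' target acceptance rates during burn-in and are frozen afterwards so the
#' post-burn-in kernel is fixed.
#'
#' @param n_generations Total MCMC generations (default 100000).
#' @param burn_in Generations discarded and used for tuning (default 10000).
#' @param thin Keep every `thin`-th post-burn-in generation (default 10).
#' @param seed Integer RNG seed.
#' @param n_chains Chains run by [fit_bbm()]/[fit_gem()] (>= 2 enables the
#'   convergence diagnostic).
#' @param proposal_widths Named list of initial widths for blocks
#'   `p`, `kd`, `tf`, `scale` (the joint translation of log tf_free and all
#'   free log Kds along the likelihood ridge left by the Kd/TF scale
#'   invariance), `sigma`, `term`.
#' @param target_acceptance_1d Tuning target for unidimensional proposals
#'   (0.45).
#' @param target_acceptance_multi Tuning target for joint multidimensional
#'   proposals (0.234); retained for completeness -- all built-in blocks
#'   propose one coordinate at a time and use the 1-D target.
#' @param rj_birth_width `w_E`: upper bound of the uniform birth draw for a
#'   new energy term, RT units (default 3.0, spanning the largest
#'   empirically reported position terms of ~2.3); also the (proper) prior
#'   width of an included term, which makes chain occupancy ratios equal
#'   Bayes factors.
#' @param rj_refine_steps `N_r`: fixed-dimension refinement steps applied to
#'   a freshly accepted energy term (default 10).
#' @param rj_moves_per_gen Reversible-jump attempts per generation.
#' @param tune_interval Generations between width adaptations in burn-in.
#' @param kd_bounds,tf_bounds Support of the flat prior on the log scale,
#'   nM.  The defaults span the physically plausible range of protein-DNA
#'   affinities (1 pM to 0.1 mM) and free TF concentrations; they keep the
#'   posterior proper for ligands with zero counts in both fractions and
#'   limit the prior volume of the weakly constrained joint (tf, Kd) scale
#'   direction (see the methods vignette).
#' @param sigma_bounds Support of the flat prior on sigma.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 100000, burn_in = 10000, thin = 10,
                        seed = 1, n_chains = 2,
                        proposal_widths = list(p = 0.5, kd = 0.5, tf = 0.3,
                                               scale = 0.3, sigma = 0.4,
                                               term = 0.3),
                        target_acceptance_1d = 0.45,
                        target_acceptance_multi = 0.234,
                        rj_birth_width = 3.0, rj_refine_steps = 10,
                        rj_moves_per_gen = 4, tune_interval = 100,
                        kd_bounds = c(1e-3, 1e5), tf_bounds = c(1e-3, 1e4),
                        sigma_bounds = c(1e-4, 1e3)) {
  if (burn_in >= n_generations) stop("burn_in must be < n_generations")
  if (any(unlist(proposal_widths) <= 0)) stop("proposal widths must be > 0")
  if (rj_refine_steps < 1) stop("rj_refine_steps must be >= 1")
  if (rj_birth_width <= 0) stop("rj_birth_width must be > 0")
  structure(as.list(environment()), class = "mcmc_config")
}

#' One symmetric Gaussian Metropolis step
#'
#' The elementary MH update used throughout: perturb the (unconstrained)
#' state by N(0, width) noise and accept with probability
#' `min(1, exp(delta log-lik))`.  Rejected proposals restore the previous
#' state exactly.  A proposal evaluating to `NaN` is a hard failure (a bug
#' in the target), reported with the offending state.
#'
#' @param x Numeric state (scalar or vector; vector proposals perturb all
#'   coordinates jointly).
#' @param log_lik_fn Function of `x` returning the log target density
#'   (`-Inf` allowed for rejected regions).
#' @param width Proposal standard deviation.
#' @return List with `x` (new state), `log_lik`, `accepted` (logical).
#' @export
mh_step <- function(x, log_lik_fn, width) {
  ll0 <- log_lik_fn(x)
  xp <- x + stats::rnorm(length(x), 0, width)
  ll1 <- log_lik_fn(xp)
  if (is.nan(ll1) || is.nan(ll0))
    stop("NaN log-likelihood in mh_step at state: ",
         paste(signif(xp, 6), collapse = ", "))
  if (log(stats::runif(1)) < ll1 - ll0)
    list(x = xp, log_lik = ll1, accepted = TRUE)
  else list(x = x, log_lik = ll0, accepted = FALSE)
}

#' Single-coordinate frequency move on the simplex
#'
#' Perturbs one frequency on the logit scale and renormalizes the rest,
#' returning the exact log-Jacobian ("Hastings") correction that makes the
#' move satisfy detailed balance with respect to densities on the simplex:
#' for `y = p[index]`, `logit(y') = logit(y) + N(0, width)`, the other
#' coordinates scale by `(1 - y')/(1 - y)`, and the correction is
#' `log(y'(1-y')) - log(y(1-y)) + (K-2) * (log(1-y') - log(1-y))`.
#' Accepting with `min(1, exp(delta log density + correction))` leaves a
#' flat density with Dirichlet(1,...,1) marginals invariant.
#'
#' @param p Frequency vector on the simplex.
#' @param index Coordinate to perturb.
#' @param width Logit-scale proposal standard deviation.
#' @return List with `p` (proposed vector), `log_hastings` (the correction),
#'   and `y_new`.
#' @export
frequency_move <- function(p, index, width) {
  K <- length(p)
  y <- p[index]
  z <- log(y / (1 - y)) + stats::rnorm(1, 0, width)
  y2 <- 1 / (1 + exp(-z))
  if (!is.finite(y2) || y2 <= 0 || y2 >= 1)  # numerically degenerate
    return(list(p = p, log_hastings = -Inf, y_new = y))
  s <- (1 - y2) / (1 - y)
  p2 <- p * s
  p2[index] <- y2
  # the scaling amplifies any pre-existing sum error multiplicatively;
  # renormalize so repeated application stays on the simplex
  p2 <- p2 / sum(p2)
  lh <- log(y2 * (1 - y2)) - log(y * (1 - y)) +
    (K - 2) * (log1p(-y2) - log1p(-y))
  list(p = p2, log_hastings = lh, y_new = y2)
}

#' Multiplicative proposal-width adaptation
#'
#' Moves each width toward its target acceptance rate:
#' `width * exp(rate - target)`.  A block already at target is unchanged;
#' high acceptance widens, low acceptance narrows.  Used during burn-in
#' only, then frozen.
#'
#' @param widths Numeric vector of current widths.
#' @param rates Observed acceptance rates in `[0, 1]`.
#' @param targets Target rates (recycled).
#' @param clamp Two-sided bound on the adapted widths.
#' @return Adapted widths.
#' @export
tune_proposals <- function(widths, rates, targets,
                           clamp = c(1e-3, 20)) {
  pmin(pmax(widths * exp(rates - targets), clamp[1]), clamp[2])
}

#' Gelman-Rubin-style convergence diagnostic
#'
#' Potential scale reduction factor per scalar parameter from >= 2 chains of
#' equal length: `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean
#' within-chain variance and `B` the between-chain variance of the means
#' (times n).  Values near 1 indicate the within- and between-chain
#' variances agree.
#'
#' @param chains List of numeric matrices (samples x parameters) with equal
#'   dimensions, or a list of [run_mcmc()] results.
#' @return Named vector of PSRF values (NA for constant parameters).
#' @export
convergence_ratio <- function(chains) {
  if (inherits(chains[[1]], "mcmc_chain"))
    chains <- lapply(chains, function(ch) ch$samples)
  if (length(chains) < 2) stop("need at least 2 chains")
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal lengths")
  mns <- sapply(chains, colMeans)
  vrs <- sapply(chains, function(m) apply(m, 2, stats::var))
  W <- rowMeans(vrs)
  B <- n * apply(mns, 1, stats::var)
  psrf <- sqrt(((n - 1) / n * W + B / n) / W)
  psrf[W == 0] <- NA_real_
  stats::setNames(psrf, colnames(chains[[1]]))
}

reflect_into <- function(x, lo, hi) {
  # reflect a real into [lo, hi]; symmetric for Gaussian walks
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

#' Run one MCMC chain
#'
#' The sampling engine behind [fit_bbm()] and [fit_gem()].  Free parameters
#' are the pre-bound frequencies (one shared-width block of single-coordinate
#' logit moves), the non-reference log Kds (one block per scalar), log
#' tf_free, and -- under the energy model -- log sigma, the included energy
#' terms (reflected Gaussian walks on `[0, w_E]`), and the term-inclusion
#' indicators via reversible-jump birth/death moves.  A birth draws the new
#' term from U(0, w_E); because the included-term prior is the same
#' U(0, w_E), the prior density cancels the proposal density and the jump is
#' accepted with the likelihood ratio times the term-selection ratio.  An
#' accepted birth is followed by `rj_refine_steps` ordinary fixed-dimension
#' refinement steps on the new term (see the methods vignette for why
#' refinement happens after, not before, the accept decision).
#'
#' @param os An [oligo_set()].
#' @param model `"bbm"` (count model only) or `"gem"` (adds the additive
#'   energy model with Gaussian error).
#' @param config An [mcmc_config()].
#' @param init Optional [binding_state()] starting point (default
#'   [initialize_state()]).
#' @param optimal_sequence GEM only: the optimal (consensus) sequence; must
#'   be a member of the set.  Default: the member with the smallest initial
#'   Kd.  Its Kd plays the role of `Kd_opt` (fixed if it is a reference,
#'   sampled otherwise).
#' @param tf_free,tf_total Optional fixed initial free TF concentration and
#'   hard upper bound (nM).
#' @param sample_p,sample_kd,sample_tf,sample_sigma,sample_terms,rj Logical
#'   switches freezing individual blocks (used for conditioned runs and
#'   oracle tests; `sample_p = FALSE` also serves the case where pre-bound
#'   frequencies are taken as known, e.g. from a GSM).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An object of class `mcmc_chain`: list with `samples` (matrix of
#'   thinned draws: `log_lik`, `tf_free`, `kd.*` in nM, `p.*`, and for the
#'   GEM `sigma`, `e.*`, `d.*`), `delta` (0/1 draws, position-major L x 4
#'   layout), `log_lik_trace` (per generation), `acceptance`, `widths`,
#'   `config`, and metadata.
#' @export
run_mcmc <- function(os, model = c("bbm", "gem"), config = mcmc_config(),
                     init = NULL, optimal_sequence = NULL,
                     tf_free = NULL, tf_total = NULL,
                     sample_p = TRUE, sample_kd = TRUE, sample_tf = TRUE,
                     sample_sigma = TRUE, sample_terms = TRUE, rj = TRUE,
                     scale_move = TRUE, seed = config$seed) {
  model <- match.arg(model)
  set.seed(seed)
  seqs <- os$sequences
  K <- length(seqs)
  C <- unname(os$pre_counts); D <- unname(os$bound_counts)
  NC <- os$n_pre; ND <- os$n_bound
  is_ref <- seqs %in% names(os$ref_kds)
  if (is.null(init))
    init <- initialize_state(os, tf_free = tf_free, tf_total = tf_total)
  gem <- model == "gem"

  # --- state ---------------------------------------------------------------
  p <- unname(init$p)
  lkd <- log(unname(init$kd))
  ltf <- log(init$tf_free)
  lkd_lo <- log(config$kd_bounds[1]); lkd_hi <- log(config$kd_bounds[2])
  ltf_lo <- log(config$tf_bounds[1])
  ltf_hi <- log(if (!is.null(tf_total)) min(tf_total, config$tf_bounds[2])
                else config$tf_bounds[2])
  lkd[!is_ref] <- pmin(pmax(lkd[!is_ref], lkd_lo), lkd_hi)
  ltf <- pmin(pmax(ltf, ltf_lo), ltf_hi - 1e-9)
  free_kd <- which(!is_ref)
  w_p <- config$proposal_widths$p
  w_kd <- rep(config$proposal_widths$kd, K)
  w_tf <- config$proposal_widths$tf
  w_sig <- config$proposal_widths$sigma
  w_term <- config$proposal_widths$term
  w_sc <- if (!is.null(config$proposal_widths$scale))
    config$proposal_widths$scale else config$proposal_widths$tf
  tgt <- config$target_acceptance_1d

  # --- GEM structures ------------------------------------------------------
  if (gem) {
    if (is.null(optimal_sequence))
      optimal_sequence <- seqs[which.min(lkd)]
    opt_idx <- match(toupper(optimal_sequence), seqs)
    if (is.na(opt_idx))
      stop("optimal_sequence must be a member of the oligo set")
    opt_is_ref <- is_ref[opt_idx]
    L <- os$L
    sm <- seq_matrix(seqs)                    # L x K nucleotide codes
    idmat <- sm + 4L * (seq_len(L) - 1L)      # term ids, position-major
    opt_codes <- sm[, opt_idx]
    anchor_ids <- opt_codes + 4L * (seq_len(L) - 1L)
    observed_ids <- sort(unique(as.vector(idmat)))
    eligible <- setdiff(observed_ids, anchor_ids)
    carriers <- lapply(seq_len(4 * L), function(t) integer())
    for (t in eligible)
      carriers[[t]] <- which(colSums(idmat == t) > 0)
    w_E <- config$rj_birth_width
    tvec <- numeric(4 * L)
    delta <- integer(4 * L)
    # init: seed single-mutant-supported terms from observed energies
    lkd_opt <- lkd[opt_idx]
    ham <- colSums(sm != opt_codes)
    for (t in eligible) {
      singles <- carriers[[t]][ham[carriers[[t]]] == 1]
      if (length(singles)) {
        e0t <- stats::median(lkd[singles] - lkd_opt)
        if (is.finite(e0t) && e0t > 0.05) {
          tvec[t] <- min(e0t, w_E * 0.99)
          delta[t] <- 1L
        }
      }
    }
    energies <- colSums(matrix(tvec[idmat], L, K))
    eps <- lkd - lkd_opt - energies
    sum_eps2 <- sum(eps^2)
    sigma <- max(sqrt(sum_eps2 / K), 0.1)
    sigma <- min(max(sigma, config$sigma_bounds[1] * 1.01),
                 config$sigma_bounds[2] * 0.99)
    lsig <- log(sigma)
    if (!is.null(init$sigma)) { sigma <- init$sigma; lsig <- log(sigma) }
  } else {
    opt_idx <- NA_integer_; sigma <- NA_real_
    eps <- NULL; sum_eps2 <- 0
  }

  # --- likelihood caches ---------------------------------------------------
  theta <- stats::plogis(ltf - lkd)
  pt <- p * theta
  S <- sum(pt)
  sCp <- sum(C * log(p))
  sDl <- sum(D * log(pt))
  llE <- function() -K * lsig - sum_eps2 / (2 * sigma^2) -
    K * 0.5 * log(2 * pi)
  ll <- sCp + sDl - ND * log(S) + if (gem) llE() else 0

  # acceptance bookkeeping: [1] p, [2] kd (pooled for reporting), [3] tf,
  # [4] sigma, [5] term, [6] rj
  acc <- prop <- numeric(6)
  acc_kd <- prop_kd <- numeric(K)
  tune_acc <- tune_prop <- numeric(6)
  tune_acc_kd <- tune_prop_kd <- numeric(K)

  n_gen <- config$n_generations; burn <- config$burn_in
  thin <- config$thin
  keep <- seq(burn + thin, n_gen, by = thin)
  n_keep <- length(keep)
  par_names <- c("log_lik", "tf_free", paste0("kd.", seqs),
                 paste0("p.", seqs),
                 if (gem) c("sigma",
                            paste0("e.", rep(seq_len(os$L), each = 4),
                                   rep(NUCS, os$L))))
  samples <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
  delta_samples <- if (gem)
    matrix(NA_integer_, n_keep, 4 * os$L,
           dimnames = list(NULL, paste0("d.", rep(seq_len(os$L), each = 4),
                                        rep(NUCS, os$L))))
  ll_trace <- numeric(n_gen)
  keep_i <- 0L

  term_update <- function(t, e_new) {
    # delta log-lik of setting term t to e_new; returns list(dll, cs, deps)
    cs <- carriers[[t]]
    d <- e_new - tvec[t]
    eps_new <- eps[cs] - d
    dsum <- sum(eps_new^2) - sum(eps[cs]^2)
    list(dll = -dsum / (2 * sigma^2), cs = cs, eps_new = eps_new,
         dsum = dsum)
  }

  # full effect of setting term t to e_new while translating the log Kds of
  # carriers `fc` (possibly none) by the same amount; residuals of fc are
  # invariant, residuals of the remaining carriers shift by -d
  rj_move_eval <- function(t, e_new, fc) {
    d <- e_new - tvec[t]
    cs <- carriers[[t]]
    ns <- setdiff(cs, fc)
    dll <- 0
    lk2 <- th2 <- pt2 <- numeric(); S2 <- S; dsDl <- 0
    if (length(fc)) {
      lk2 <- lkd[fc] + d
      th2 <- stats::plogis(ltf - lk2)
      pt2 <- p[fc] * th2
      S2 <- S - sum(pt[fc]) + sum(pt2)
      dsDl <- sum(D[fc] * (log(pt2) - log(pt[fc])))
      dll <- dsDl - ND * (log(S2) - log(S))
    }
    eps_ns <- eps[ns] - d
    dsum <- sum(eps_ns^2) - sum(eps[ns]^2)
    dll <- dll - dsum / (2 * sigma^2)
    list(t = t, e_new = e_new, d = d, cs = cs, fc = fc, ns = ns,
         lk2 = lk2, th2 = th2, pt2 = pt2, S2 = S2, dsDl = dsDl,
         eps_ns = eps_ns, dsum = dsum, dll = dll)
  }

  rj_move_apply <- function(m) {
    if (length(m$fc)) {
      lkd[m$fc] <<- m$lk2; theta[m$fc] <<- m$th2; pt[m$fc] <<- m$pt2
      S <<- m$S2; sDl <<- sDl + m$dsDl
    }
    eps[m$ns] <<- m$eps_ns
    sum_eps2 <<- sum_eps2 + m$dsum
    energies[m$cs] <<- energies[m$cs] + m$d
    tvec[m$t] <<- m$e_new
    ll <<- ll + m$dll
  }

  for (gen in seq_len(n_gen)) {
    ## -- frequency block: sweep of single-coordinate logit moves ----------
    if (sample_p) {
      for (j in sample.int(K)) {
        tune_prop[1] <- tune_prop[1] + 1; prop[1] <- prop[1] + 1
        y <- p[j]
        z <- log(y / (1 - y)) + stats::rnorm(1, 0, w_p)
        y2 <- 1 / (1 + exp(-z))
        if (!is.finite(y2) || y2 <= 0 || y2 >= 1) next
        s <- (1 - y2) / (1 - y)
        ptj2 <- y2 * theta[j]
        S2 <- s * (S - pt[j]) + ptj2
        dsCp <- C[j] * (log(y2) - log(y)) + (NC - C[j]) * log(s)
        dsDl <- D[j] * (log(ptj2) - log(pt[j])) + (ND - D[j]) * log(s)
        dll <- dsCp + dsDl - ND * (log(S2) - log(S))
        jac <- log(y2 * (1 - y2)) - log(y * (1 - y)) +
          (K - 2) * (log1p(-y2) - log1p(-y))
        if (log(stats::runif(1)) < dll + jac) {
          p <- p * s; p[j] <- y2
          pt <- pt * s; pt[j] <- ptj2
          S <- S2; sCp <- sCp + dsCp; sDl <- sDl + dsDl; ll <- ll + dll
          tune_acc[1] <- tune_acc[1] + 1; acc[1] <- acc[1] + 1
        }
      }
      # single-coordinate renormalization amplifies sum drift
      # multiplicatively; re-project after each sweep and refresh the
      # affected caches (an O(eps) cleanup, cheap and exact)
      p <- p / sum(p)
      pt <- p * theta
      S <- sum(pt)
      sCp <- sum(C * log(p))
      sDl <- sum(D * log(pt))
      ll <- sCp + sDl - ND * log(S) + if (gem) llE() else 0
    }

    ## -- Kd blocks: one scalar block per non-reference ligand -------------
    if (sample_kd) {
      for (j in free_kd) {
        tune_prop_kd[j] <- tune_prop_kd[j] + 1; prop_kd[j] <- prop_kd[j] + 1
        lk2 <- lkd[j] + stats::rnorm(1, 0, w_kd[j])
        if (lk2 < lkd_lo || lk2 > lkd_hi) next
        th2 <- stats::plogis(ltf - lk2)
        ptj2 <- p[j] * th2
        S2 <- S - pt[j] + ptj2
        dsDl <- D[j] * (log(ptj2) - log(pt[j]))
        dll <- dsDl - ND * (log(S2) - log(S))
        if (gem) {
          if (j == opt_idx && !opt_is_ref) {
            dshift <- lk2 - lkd[j]
            eps2 <- eps - dshift
            eps2[j] <- 0
            dsum <- sum(eps2^2) - sum_eps2
          } else {
            e2 <- lk2 - lkd_opt - energies[j]
            dsum <- e2^2 - eps[j]^2
          }
          dll <- dll - dsum / (2 * sigma^2)
        }
        if (log(stats::runif(1)) < dll) {
          if (gem) {
            if (j == opt_idx && !opt_is_ref) {
              eps <- eps2; lkd_opt <- lk2
            } else eps[j] <- lk2 - lkd_opt - energies[j]
            sum_eps2 <- sum_eps2 + dsum
          }
          lkd[j] <- lk2; theta[j] <- th2; pt[j] <- ptj2
          S <- S2; sDl <- sDl + dsDl; ll <- ll + dll
          tune_acc_kd[j] <- tune_acc_kd[j] + 1; acc_kd[j] <- acc_kd[j] + 1
        }
      }
    }

    ## -- free TF concentration --------------------------------------------
    if (sample_tf) {
      tune_prop[3] <- tune_prop[3] + 1; prop[3] <- prop[3] + 1
      ltf2 <- ltf + stats::rnorm(1, 0, w_tf)
      if (ltf2 >= ltf_lo && ltf2 < ltf_hi) {
        theta2 <- stats::plogis(ltf2 - lkd)
        pt2 <- p * theta2
        S2 <- sum(pt2)
        sDl2 <- sum(D * log(pt2))
        dll <- (sDl2 - sDl) - ND * (log(S2) - log(S))
        if (log(stats::runif(1)) < dll) {
          ltf <- ltf2; theta <- theta2; pt <- pt2; S <- S2
          sDl <- sDl2; ll <- ll + dll
          tune_acc[3] <- tune_acc[3] + 1; acc[3] <- acc[3] + 1
        }
      }
    }

    ## -- joint scale move along the (tf, Kd) ridge ------------------------
    ## theta depends on Kd/tf only, so translating log tf and all free log
    ## Kds together moves along a likelihood ridge constrained only by the
    ## fixed reference Kds; a dedicated symmetric move mixes it.
    if (scale_move && sample_tf && sample_kd && length(free_kd) &&
        any(is_ref)) {
      tune_prop[2] <- tune_prop[2] + 1; prop[2] <- prop[2] + 1
      d <- stats::rnorm(1, 0, w_sc)
      ltf2 <- ltf + d
      ok <- ltf2 >= ltf_lo && ltf2 < ltf_hi &&
        all(lkd[free_kd] + d >= lkd_lo) && all(lkd[free_kd] + d <= lkd_hi)
      if (ok) {
        lkd2 <- lkd; lkd2[free_kd] <- lkd2[free_kd] + d
        theta2 <- stats::plogis(ltf2 - lkd2)
        pt2 <- p * theta2
        S2 <- sum(pt2)
        sDl2 <- sum(D * log(pt2))
        dll <- (sDl2 - sDl) - ND * (log(S2) - log(S))
        if (gem) {
          lkd_opt2 <- if (opt_is_ref) lkd_opt else lkd_opt + d
          eps2 <- lkd2 - lkd_opt2 - energies
          dsum <- sum(eps2^2) - sum_eps2
          dll <- dll - dsum / (2 * sigma^2)
        }
        if (log(stats::runif(1)) < dll) {
          ltf <- ltf2; lkd <- lkd2; theta <- theta2; pt <- pt2; S <- S2
          sDl <- sDl2; ll <- ll + dll
          if (gem) {
            lkd_opt <- lkd_opt2; eps <- eps2; sum_eps2 <- sum_eps2 + dsum
          }
          tune_acc[2] <- tune_acc[2] + 1; acc[2] <- acc[2] + 1
        }
      }
    }

    if (gem) {
      ## -- sigma: log-scale walk, flat prior on sigma => Jacobian ---------
      if (sample_sigma) {
        tune_prop[4] <- tune_prop[4] + 1; prop[4] <- prop[4] + 1
        lsig2 <- lsig + stats::rnorm(1, 0, w_sig)
        sig2 <- exp(lsig2)
        if (sig2 >= config$sigma_bounds[1] && sig2 <= config$sigma_bounds[2]) {
          dll <- (-K * lsig2 - sum_eps2 / (2 * sig2^2)) -
            (-K * lsig - sum_eps2 / (2 * sigma^2))
          if (log(stats::runif(1)) < dll + (lsig2 - lsig)) {
            lsig <- lsig2; sigma <- sig2; ll <- ll + dll
            tune_acc[4] <- tune_acc[4] + 1; acc[4] <- acc[4] + 1
          }
        }
      }

      ## -- included-term refinement sweep ---------------------------------
      ## Alternates a plain reflected walk on the term with a joint move
      ## translating the term and its non-reference carriers' log Kds
      ## together: residuals of free carriers are invariant under that
      ## translation, so the joint move still mixes when sigma is small and
      ## the Gaussian penalty pins terms to the current Kds.
      if (sample_terms) {
        on_ids <- eligible[delta[eligible] == 1L]
        for (t in on_ids) {
          tune_prop[5] <- tune_prop[5] + 1; prop[5] <- prop[5] + 1
          if (stats::runif(1) < 0.5) {           # plain term move
            e2 <- reflect_into(tvec[t] + stats::rnorm(1, 0, w_term), 0, w_E)
            u <- term_update(t, e2)
            if (log(stats::runif(1)) < u$dll) {
              eps[u$cs] <- u$eps_new
              energies[u$cs] <- energies[u$cs] + (e2 - tvec[t])
              sum_eps2 <- sum_eps2 + u$dsum
              tvec[t] <- e2; ll <- ll + u$dll
              tune_acc[5] <- tune_acc[5] + 1; acc[5] <- acc[5] + 1
            }
          } else {                               # joint term + carrier-Kd
            d <- stats::rnorm(1, 0, w_term)
            e2 <- tvec[t] + d
            cs <- carriers[[t]]
            fc <- cs[!is_ref[cs]]
            rc <- cs[is_ref[cs]]
            ok <- e2 >= 0 && e2 <= w_E &&
              all(lkd[fc] + d >= lkd_lo) && all(lkd[fc] + d <= lkd_hi)
            if (ok) {
              lk2 <- lkd[fc] + d
              th2 <- stats::plogis(ltf - lk2)
              pt2 <- p[fc] * th2
              S2 <- S - sum(pt[fc]) + sum(pt2)
              dsDl <- sum(D[fc] * (log(pt2) - log(pt[fc])))
              dll <- dsDl - ND * (log(S2) - log(S))
              dsum <- 0
              if (length(rc)) {                  # refs keep their Kds
                eps_rc <- eps[rc] - d
                dsum <- sum(eps_rc^2) - sum(eps[rc]^2)
                dll <- dll - dsum / (2 * sigma^2)
              }
              if (log(stats::runif(1)) < dll) {
                lkd[fc] <- lk2; theta[fc] <- th2; pt[fc] <- pt2
                S <- S2; sDl <- sDl + dsDl
                energies[cs] <- energies[cs] + d
                if (length(rc)) {
                  eps[rc] <- eps[rc] - d
                  sum_eps2 <- sum_eps2 + dsum
                }
                tvec[t] <- e2; ll <- ll + dll
                tune_acc[5] <- tune_acc[5] + 1; acc[5] <- acc[5] + 1
              }
            }
          }
        }
      }

      ## -- reversible jumps over the indicator matrix ---------------------
      if (rj && length(eligible)) {
        for (rep_rj in seq_len(config$rj_moves_per_gen)) {
          prop[6] <- prop[6] + 1
          on_ids <- eligible[delta[eligible] == 1L]
          off_ids <- eligible[delta[eligible] == 0L]
          n_on <- length(on_ids); n_off <- length(off_ids)
          p_birth <- if (n_off == 0) 0 else if (n_on == 0) 1 else 0.5
          birth <- stats::runif(1) < p_birth
          ## each jump is plain (term only) or shifted (term and its free
          ## carriers' log Kds translated together, preserving their
          ## residuals); the variant is chosen with probability 1/2 on both
          ## sides so the factor cancels in the proposal ratio
          shifted <- stats::runif(1) < 0.5
          if (birth) {
            t <- off_ids[sample.int(n_off, 1)]
            e_new <- stats::runif(1, 0, w_E)
            cs <- carriers[[t]]
            fc <- if (shifted) cs[!is_ref[cs]] else integer()
            ok <- !shifted ||
              (all(lkd[fc] + e_new >= lkd_lo) &&
               all(lkd[fc] + e_new <= lkd_hi))
            if (ok) {
              move <- rj_move_eval(t, e_new, fc)
              p_death_rev <- if (n_off - 1 == 0) 1 else 0.5
              la <- move$dll + log(p_death_rev) - log(p_birth) +
                log(n_off) - log(n_on + 1)
              if (log(stats::runif(1)) < la) {
                rj_move_apply(move)
                delta[t] <- 1L
                acc[6] <- acc[6] + 1
                # proposal reallocation: refine the freshly born term
                for (rstep in seq_len(config$rj_refine_steps)) {
                  e2 <- reflect_into(tvec[t] + stats::rnorm(1, 0, w_term),
                                     0, w_E)
                  u2 <- term_update(t, e2)
                  if (log(stats::runif(1)) < u2$dll) {
                    eps[u2$cs] <- u2$eps_new
                    energies[u2$cs] <- energies[u2$cs] + (e2 - tvec[t])
                    sum_eps2 <- sum_eps2 + u2$dsum
                    tvec[t] <- e2; ll <- ll + u2$dll
                  }
                }
              }
            }
          } else if (n_on > 0) {
            t <- on_ids[sample.int(n_on, 1)]
            cs <- carriers[[t]]
            fc <- if (shifted) cs[!is_ref[cs]] else integer()
            d0 <- -tvec[t]
            ok <- !shifted ||
              (all(lkd[fc] + d0 >= lkd_lo) && all(lkd[fc] + d0 <= lkd_hi))
            if (ok) {
              move <- rj_move_eval(t, 0, fc)
              p_death <- 1 - p_birth
              p_birth_rev <- if (n_on - 1 == 0) 1 else 0.5
              la <- move$dll + log(p_birth_rev) - log(p_death) +
                log(n_on) - log(n_off + 1)
              if (log(stats::runif(1)) < la) {
                rj_move_apply(move)
                delta[t] <- 0L
                acc[6] <- acc[6] + 1
              }
            }
          }
        }
      }
    }

    ## -- adapt widths during burn-in --------------------------------------
    if (gen <= burn && gen %% config$tune_interval == 0) {
      if (tune_prop[1] > 0)
        w_p <- tune_proposals(w_p, tune_acc[1] / tune_prop[1], tgt)
      upd <- tune_prop_kd > 0
      w_kd[upd] <- tune_proposals(w_kd[upd],
                                  tune_acc_kd[upd] / tune_prop_kd[upd], tgt)
      if (tune_prop[2] > 0)
        w_sc <- tune_proposals(w_sc, tune_acc[2] / tune_prop[2], tgt)
      if (tune_prop[3] > 0)
        w_tf <- tune_proposals(w_tf, tune_acc[3] / tune_prop[3], tgt)
      if (gem && tune_prop[4] > 0)
        w_sig <- tune_proposals(w_sig, tune_acc[4] / tune_prop[4], tgt)
      if (gem && tune_prop[5] > 0)
        w_term <- tune_proposals(w_term, tune_acc[5] / tune_prop[5], tgt)
      tune_acc[] <- 0; tune_prop[] <- 0
      tune_acc_kd[] <- 0; tune_prop_kd[] <- 0
      if (gen == burn ||
          (burn - gen) < config$tune_interval) {  # end of adaptation
        acc[] <- 0; prop[] <- 0; acc_kd[] <- 0; prop_kd[] <- 0
      }
    }

    ## -- periodic full recompute to cancel incremental drift --------------
    if (gen %% 1000L == 0L) {
      ll_old <- ll
      p <- p / sum(p)
      theta <- stats::plogis(ltf - lkd)
      pt <- p * theta
      S <- sum(pt); sCp <- sum(C * log(p)); sDl <- sum(D * log(pt))
      if (gem) {
        energies <- colSums(matrix(tvec[idmat], os$L, K))
        eps <- lkd - lkd_opt - energies
        sum_eps2 <- sum(eps^2)
      }
      ll <- sCp + sDl - ND * log(S) + if (gem) llE() else 0
      if (isTRUE(getOption("bindkd.debug")) && abs(ll - ll_old) > 1e-6)
        message(sprintf("gen %d: incremental log-lik drift %.3g",
                        gen, ll - ll_old))
    }

    ll_trace[gen] <- ll
    if (gen > burn && (gen - burn) %% thin == 0L) {
      keep_i <- keep_i + 1L
      row <- c(ll, exp(ltf), exp(lkd), p, if (gem) c(sigma, tvec))
      samples[keep_i, ] <- row
      if (gem) delta_samples[keep_i, ] <- delta
    }
  }

  rates <- c(p = unname(acc[1] / max(prop[1], 1)),
             kd = sum(acc_kd) / max(sum(prop_kd), 1),
             scale = unname(acc[2] / max(prop[2], 1)),
             tf = unname(acc[3] / max(prop[3], 1)),
             sigma = unname(acc[4] / max(prop[4], 1)),
             term = unname(acc[5] / max(prop[5], 1)),
             rj = unname(acc[6] / max(prop[6], 1)))
  structure(list(samples = samples[seq_len(keep_i), , drop = FALSE],
                 delta = if (gem) delta_samples[seq_len(keep_i), ,
                                                drop = FALSE],
                 log_lik_trace = ll_trace,
                 acceptance = rates,
                 acceptance_kd = acc_kd / pmax(prop_kd, 1),
                 widths = list(p = w_p, kd = w_kd, tf = w_tf, scale = w_sc,
                               sigma = if (gem) w_sig,
                               term = if (gem) w_term),
                 config = config, model = model, seed = seed,
                 sequences = seqs, ref_kds = os$ref_kds,
                 optimal_sequence = if (gem) seqs[opt_idx]),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("mcmc_chain (%s): %d kept samples of %d parameters\n",
              x$model, nrow(x$samples), ncol(x$samples)))
  cat("  acceptance:",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
            collapse = " "), "\n")
  invisible(x)
}
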