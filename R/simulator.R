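#' Enumerate the Hamming neighborhood of a consensus sequence
#'
#' All DNA sequences within `max_mismatches` substitutions of `consensus`,
#' deduplicated, in a deterministic order (by distance, then position of the
#' mutations, then nucleotide).  For a 10-mer and radius 2 this is
#' `1 + 30 + 405 = 436` sequences.
#'
#' @param consensus DNA string over A, C, G, T.
#' @param max_mismatches Hamming radius, `0 <= r <= nchar(consensus)`.
#' @return Character vector of sequences (consensus first).
#' @export
enumerate_neighborhood <- function(consensus, max_mismatches) {
  consensus <- toupper(consensus)
  check_dna(consensus)
  L <- nchar(consensus)
  if (max_mismatches < 0 || max_mismatches > L)
    stop("max_mismatches must be between 0 and sequence length")
  base <- strsplit(consensus, "", fixed = TRUE)[[1]]
  out <- consensus
  if (max_mismatches >= 1) {
    for (r in seq_len(max_mismatches)) {
      pos_sets <- utils::combn(L, r)
      for (ci in seq_len(ncol(pos_sets))) {
        pos <- pos_sets[, ci]
        alts <- lapply(pos, function(k) setdiff(NUCS, base[k]))
        grid <- as.matrix(expand.grid(alts, stringsAsFactors = FALSE))
        for (gi in seq_len(nrow(grid))) {
          s <- base
          s[pos] <- grid[gi, ]
          out <- c(out, paste(s, collapse = ""))
        }
      }
    }
  }
  unique(out)
}

#' Generate an additive Kd landscape around a consensus
#'
#' Draws a position-specific additive energy landscape and assigns each
#' sequence `Kd_i = kd_opt * exp(additive_energy_i + eps_i)` with
#' `eps_i ~ N(0, epsilon_std^2)`; the consensus attains the minimum additive
#' energy (0) and carries no noise, so it is the optimal sequence by
#' construction.
#'
#' @param consensus Consensus (optimal) sequence.
#' @param sequences Sequences to assign Kds to (must include the consensus);
#'   default: the full Hamming-2 neighborhood.
#' @param term_sampler Function `n -> n` non-negative energy draws for the
#'   non-consensus (position, nucleotide) terms; default U(0, 2.3) RT,
#'   matching the span of empirically reported position terms.
#' @param epsilon_std Std of the per-sequence deviation from additivity
#'   (RT units); 0 gives an exactly additive landscape.
#' @param kd_opt Kd of the consensus, nM.
#' @param seed RNG seed.
#' @return Object of class `kd_landscape`: list with `kds` (named vector,
#'   nM), `terms` (L x 4 matrix), `model` (an [energy_model()]),
#'   `consensus`, `kd_opt`, `epsilon_std`.
#' @export
generate_landscape <- function(consensus,
                               sequences = enumerate_neighborhood(consensus, 2),
                               term_sampler = function(n) stats::runif(n, 0, 2.3),
                               epsilon_std = 0.3, kd_opt = 1, seed = 1) {
  set.seed(seed)
  consensus <- toupper(consensus)
  sequences <- toupper(sequences)
  if (!consensus %in% sequences)
    stop("sequences must include the consensus")
  L <- nchar(consensus)
  opt <- seq_matrix(consensus)[, 1]
  terms <- matrix(term_sampler(4 * L), L, 4, dimnames = list(seq_len(L), NUCS))
  if (any(terms < 0)) stop("term_sampler must yield non-negative terms")
  terms[cbind(seq_len(L), opt)] <- 0
  em <- energy_model(consensus, terms = terms, sigma = max(epsilon_std, 1e-6))
  e_add <- additive_energy(sequences, em)
  eps <- stats::rnorm(length(sequences), 0, epsilon_std)
  eps[sequences == consensus] <- 0
  kds <- energy_to_kd(unname(e_add) + eps, kd_opt)
  structure(list(kds = stats::setNames(kds, sequences), terms = terms,
                 model = em, consensus = consensus, kd_opt = kd_opt,
                 epsilon_std = epsilon_std),
            class = "kd_landscape")
}

#' Mix observed pre-bound frequencies with GSM predictions
#'
#' Convex combination `w_obs * observed + (1 - w_obs) * GSM-predicted`,
#' renormalized over the sequence set; used to avoid zero expected
#' generation frequencies when simulating from sparse observed pools (the
#' reported design uses `w_obs = 0.8` with an order-7 model).
#'
#' @param observed_freqs Named frequency vector over the sequence set.
#' @param gsm_model A fitted [gsm_model][fit_gsm()] covering the sequences.
#' @param w_obs Weight on the observed frequencies, in `[0, 1]`.
#' @return Named frequency vector summing to 1.
#' @export
prebound_mixture <- function(observed_freqs, gsm_model, w_obs = 0.8) {
  if (w_obs < 0 || w_obs > 1) stop("w_obs must lie in [0, 1]")
  seqs <- names(observed_freqs)
  if (is.null(seqs)) stop("observed_freqs must be named by sequence")
  gsm_f <- gsm_predicted_count(seqs, gsm_model)
  gsm_f <- gsm_f / sum(gsm_f)
  mix <- w_obs * observed_freqs / sum(observed_freqs) +
    (1 - w_obs) * as.numeric(gsm_f)
  if (any(mix <= 0))
    stop("mixture frequency zero for some sequence: both components vanish")
  stats::setNames(mix / sum(mix), seqs)
}

#' Simulation configuration
#'
#' Describes one in-silico pooled binding experiment: the true Kd landscape,
#' the pre-bound pool composition, the equilibrium free TF concentration,
#' and the sequencing depths of the two fractions.
#'
#' @param kds Named vector of true Kds (nM) -- e.g. `landscape$kds` from
#'   [generate_landscape()] or an explicit list.
#' @param tf_free True free TF concentration at equilibrium, nM.  The
#'   simulator equilibrates at this realized concentration; see
#'   [solve_tf_free()] for the mass-balance mode.
#' @param mean_depth_pre,mean_depth_bound Mean sequencing reads per ligand
#'   in each fraction; total reads are `K * mean_depth` (a fixed read
#'   budget, multinomially allocated).
#' @param prebound_freqs Pre-bound frequency vector: `"equal"` (default), or
#'   a named numeric vector (e.g. from [prebound_mixture()]).
#' @param reference_sequences Sequences whose true Kds are reported as known
#'   references; default: the lowest-Kd and the highest-Kd sequence.  A
#'   strong binder anchors the scale from below; the weak binder is
#'   essential to pin it from above -- with only strong references (Kd
#'   below tf_free) the likelihood is nearly flat along the joint
#'   (tf_free, Kd) scale direction and count-only estimates drift (see the
#'   methods vignette).
#' @param seed Base seed; replicate `r` draws counts with a seed derived
#'   from `seed` and `r`, so replicates share ground truth but not noise.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(kds, tf_free, mean_depth_pre = 100,
                       mean_depth_bound = mean_depth_pre,
                       prebound_freqs = "equal",
                       reference_sequences = NULL, seed = 1) {
  if (is.null(names(kds))) stop("kds must be named by sequence")
  if (any(kds <= 0)) stop("true Kds must be positive")
  if (tf_free <= 0) stop("tf_free must be positive")
  if (mean_depth_pre <= 0 || mean_depth_bound <= 0)
    stop("depths must be positive")
  if (is.null(reference_sequences)) {
    ord <- order(kds)
    reference_sequences <- names(kds)[c(ord[1], ord[length(ord)])]
  }
  if (!all(reference_sequences %in% names(kds)))
    stop("reference_sequences must be drawn from the ligand set")
  structure(list(kds = kds, tf_free = tf_free,
                 mean_depth_pre = mean_depth_pre,
                 mean_depth_bound = mean_depth_bound,
                 prebound_freqs = prebound_freqs,
                 reference_sequences = reference_sequences, seed = seed),
            class = "sim_config")
}

#' Simulate a pooled binding-and-sequencing experiment
#'
#' Mimics the steps of a real experiment with known truth: the pre-bound
#' pool has frequencies `P`; each ligand binds with probability
#' `theta_i = tf_free / (tf_free + Kd_i)`; the bound pool has frequencies
#' `B_i = P_i theta_i / sum_j P_j theta_j`; and each fraction is sequenced
#' to a fixed total read budget, `counts ~ Multinomial(K * mean_depth, .)`.
#' Ground truth satisfies the equilibrium relations exactly, so noise-free
#' inversion recovers every Kd to machine precision.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index; replicates share ground truth and
#'   differ only in the count draws.
#' @return Object of class `sim_experiment`: list with `oligo_set` (counts
#'   and reference annotations filled in), `true_kds`, `true_theta`,
#'   `true_b`, `true_p`, `tf_free`, `config`, `replicate`.
#' @export
simulate_experiment <- function(config, replicate = 1) {
  kds <- config$kds
  seqs <- names(kds)
  K <- length(seqs)
  if (identical(config$prebound_freqs, "equal"))
    p <- rep(1 / K, K)
  else {
    p <- config$prebound_freqs[seqs]
    if (any(is.na(p)) || any(p <= 0))
      stop("prebound_freqs must cover every ligand with positive frequency")
    p <- as.numeric(p) / sum(p)
  }
  theta <- fraction_bound(config$tf_free, kds)
  b <- bound_freqs(p, theta)
  n_pre <- round(K * config$mean_depth_pre)
  n_bound <- round(K * config$mean_depth_bound)
  set.seed((config$seed * 7919L + replicate * 104729L) %% 2147483647L)
  pre <- as.integer(stats::rmultinom(1, n_pre, p))
  bnd <- as.integer(stats::rmultinom(1, n_bound, b))
  os <- oligo_set(seqs, pre, bnd,
                  ref_kds = kds[config$reference_sequences])
  structure(list(oligo_set = os,
                 true_kds = kds,
                 true_theta = stats::setNames(as.numeric(theta), seqs),
                 true_b = stats::setNames(as.numeric(b), seqs),
                 true_p = stats::setNames(p, seqs),
                 tf_free = config$tf_free,
                 config = config, replicate = replicate),
            class = "sim_experiment")
}

#' Solve the free-TF mass balance for a simulated pool
#'
#' Optional mass-balance mode: given a total TF concentration and total
#' ligand concentration, finds the equilibrium free TF concentration
#' satisfying `tf_total = tf_free + sum_i L_i * theta_i(tf_free)` with
#' `L_i = ligand_total * P_i`.
#'
#' @param tf_total Total TF concentration, nM.
#' @param kds Named true Kd vector, nM.
#' @param p Pre-bound frequency vector (default equal).
#' @param ligand_total Total ligand concentration, nM.
#' @return Free TF concentration, nM.
#' @export
solve_tf_free <- function(tf_total, kds, p = rep(1 / length(kds),
                                                 length(kds)),
                          ligand_total = sum(kds) / length(kds)) {
  f <- function(tf) tf + sum(ligand_total * p * tf / (tf + kds)) - tf_total
  stats::uniroot(f, c(tf_total * 1e-12, tf_total), tol = 1e-12)$root
}

#' Named simulation presets
#'
#' Experimental geometries mirroring the published simulation designs, with
#' generated stand-in landscapes (the original Kd sets are external):
#' \describe{
#'   \item{leu3}{43 ligands around the 10-bp palindromic consensus
#'     CCGGTACCGG; equal pre-bound frequencies; TF grid 1/10/50 nM.}
#'   \item{arca}{46 ligands around the 15-bp consensus GTTACCATTATGTTA;
#'     equal pre-bound frequencies; TF grid 1/100/1000 nM.}
#'   \item{zif268}{all 436 ligands within Hamming distance 2 of
#'     GCGTGGGCGT; skewed pre-bound pool (order-3 GSM fitted to a biased
#'     sample, mixed 0.8 observed / 0.2 GSM); TF grid 0.1/1/10/100 nM.}
#' }
#' The consensus and a mid-range binder serve as the two references (three
#' for zif268, mirroring its three-reference design).
#'
#' @param name Preset name.
#' @param tf_free Free TF concentration (nM); default: middle of the
#'   preset's grid.
#' @param mean_depth_pre,mean_depth_bound Reads per ligand.
#' @param epsilon_std Non-additivity of the generated landscape (RT).
#' @param seed Base seed (drives landscape, pool skew, and counts).
#' @return A [sim_config()]; the attribute `"tf_grid"` carries the preset's
#'   design sweep and `"landscape"` the generated [generate_landscape()]
#'   object.
#' @export
sim_preset <- function(name = c("leu3", "arca", "zif268"), tf_free = NULL,
                       mean_depth_pre = 100,
                       mean_depth_bound = mean_depth_pre,
                       epsilon_std = 0.3, seed = 1) {
  name <- match.arg(name)
  spec <- switch(name,
    leu3 = list(consensus = "CCGGTACCGG", n = 43, grid = c(1, 10, 50),
                kd_opt = 1),
    arca = list(consensus = "GTTACCATTATGTTA", n = 46,
                grid = c(1, 100, 1000), kd_opt = 10),
    zif268 = list(consensus = "GCGTGGGCGT", n = 436,
                  grid = c(0.1, 1, 10, 100), kd_opt = 0.15))
  if (is.null(tf_free))
    tf_free <- spec$grid[ceiling(length(spec$grid) / 2)]
  nb <- enumerate_neighborhood(spec$consensus, 2)
  set.seed(seed)
  if (length(nb) > spec$n) {
    # a measured variant panel: consensus, all single mutants, then double
    # mutants to fill -- matching how titration datasets are composed
    n1 <- 3 * nchar(spec$consensus)
    singles <- nb[2:(n1 + 1)]
    doubles <- nb[-seq_len(n1 + 1)]
    n_extra <- spec$n - 1 - length(singles)
    seqs <- c(spec$consensus, singles,
              if (n_extra > 0) sample(doubles, n_extra))
  } else seqs <- nb
  land <- generate_landscape(spec$consensus, sequences = seqs,
                             epsilon_std = epsilon_std,
                             kd_opt = spec$kd_opt, seed = seed)
  prebound <- "equal"
  refs <- NULL
  if (name == "zif268") {
    # skewed synthesis pool: mix a biased observed pool with its GSM
    set.seed(seed + 1L)
    obs <- stats::setNames(stats::rgamma(length(seqs), shape = 2, rate = 1) +
                             0.05, seqs)
    gsm <- fit_gsm(stats::setNames(round(obs * 1e4), seqs), m = 3)
    prebound <- prebound_mixture(obs / sum(obs), gsm, w_obs = 0.8)
    ord <- order(land$kds)
    refs <- names(land$kds)[c(ord[1], ord[2], ord[length(ord)])]
  }
  cfg <- sim_config(land$kds, tf_free = tf_free,
                    mean_depth_pre = mean_depth_pre,
                    mean_depth_bound = mean_depth_bound,
                    prebound_freqs = prebound,
                    reference_sequences = refs, seed = seed)
  attr(cfg, "tf_grid") <- spec$grid
  attr(cfg, "landscape") <- land
  attr(cfg, "preset") <- name
  cfg
}

#' Sequencing-design arithmetic
#'
#' Small helpers for experiment sizing: the number of distinct ds-oligos
#' from fully randomizing `n_sites` positions (`4^n_sites`); the pool size
#' from mixing `n_syntheses` separate syntheses each randomizing `n_sites`
#' positions; the mean per-oligo depth from a read budget; and the relative
#' (Poisson) standard deviation of a count at a given expectation.
#'
#' @param n_sites Number of fully randomized positions.
#' @return `randomized_pool_size`: `4^n_sites`.
#' @export
randomized_pool_size <- function(n_sites) 4^n_sites

#' @param n_syntheses Number of separate syntheses mixed together.
#' @rdname randomized_pool_size
#' @export
mixed_pool_size <- function(n_syntheses, n_sites)
  n_syntheses * 4^n_sites

#' @param total_reads Sequencing reads available.
#' @param n_oligos Distinct ds-oligos in the pool.
#' @rdname randomized_pool_size
#' @export
mean_depth <- function(total_reads, n_oligos) total_reads / n_oligos

#' @param expectation Expected count of one ds-oligo.
#' @rdname randomized_pool_size
#' @export
poisson_relative_std <- function(expectation) 1 / sqrt(expectation)
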