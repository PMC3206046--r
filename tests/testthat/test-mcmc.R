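test_that("mh_step implements the Metropolis rule", {
  # zero-width proposal equals the current state: always accepted
  set.seed(1)
  out <- mh_step(1.3, function(x) dnorm(x, log = TRUE), width = 0)
  expect_true(out$accepted)
  expect_equal(out$x, 1.3)
  # known target: standard normal sampled by repeated steps
  set.seed(2)
  x <- 0; draws <- numeric(1e5)
  target <- function(z) -z^2 / 2
  for (i in seq_len(1e5)) {
    st <- mh_step(x, target, width = 2.4)
    x <- st$x
    draws[i] <- x
  }
  expect_lt(abs(mean(draws)), 0.02)
  expect_lt(abs(var(draws) - 1), 0.05)
  expect_error(mh_step(1, function(x) NaN, 1), "NaN")
})

test_that("frequency_move is a valid simplex kernel", {
  set.seed(3)
  p <- c(0.2, 0.5, 0.3)
  # vanishing width: no movement, no correction
  out <- frequency_move(p, 2, width = 1e-12)
  expect_equal(out$p, p, tolerance = 1e-9)
  expect_equal(out$log_hastings, 0, tolerance = 1e-6)
  # proposal stays on the simplex, strictly positive
  for (i in 1:50) {
    out <- frequency_move(p, sample(3, 1), width = 1.5)
    expect_equal(sum(out$p), 1, tolerance = 1e-12)
    expect_true(all(out$p > 0))
  }
  # detailed-balance audit: the correction for the reverse move is the
  # exact negation (recomputed from the closed form on the state pair)
  corr <- function(y, y2, K) {
    log(y2 * (1 - y2)) - log(y * (1 - y)) +
      (K - 2) * (log1p(-y2) - log1p(-y))
  }
  for (i in 1:25) {
    out <- frequency_move(p, 1, width = 1)
    expect_equal(out$log_hastings, corr(p[1], out$y_new, 3),
                 tolerance = 1e-12)
    expect_equal(corr(out$y_new, p[1], 3), -out$log_hastings,
                 tolerance = 1e-12)
  }
})

test_that("frequency moves leave a flat simplex density invariant", {
  # MH with flat target: stationary distribution is Dirichlet(1,1,1),
  # marginals Beta(1,2); KS on thinned draws at a fixed seed
  set.seed(4)
  p <- rep(1 / 3, 3)
  n <- 1e5
  kept <- matrix(NA_real_, n / 25, 3)
  for (i in seq_len(n)) {
    j <- sample.int(3, 1)
    prop <- frequency_move(p, j, width = 1.2)
    if (log(runif(1)) < prop$log_hastings) p <- prop$p
    if (i %% 25 == 0) kept[i / 25, ] <- p
  }
  for (k in 1:3) {
    ks <- suppressWarnings(stats::ks.test(kept[, k], stats::pbeta,
                                          1, 2))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("tune_proposals adapts multiplicatively toward the target", {
  expect_equal(tune_proposals(0.5, 0.45, 0.45), 0.5)
  expect_gt(tune_proposals(0.5, 0.9, 0.45), 0.5)
  expect_lt(tune_proposals(0.5, 0.05, 0.45), 0.5)
  expect_equal(tune_proposals(c(1, 2), c(0.6, 0.3), 0.45),
               c(1, 2) * exp(c(0.15, -0.15)))
  # clamped
  expect_equal(tune_proposals(1e-3, 0, 0.45), 1e-3)
})

test_that("convergence_ratio is the within/between variance diagnostic", {
  set.seed(5)
  a <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("x", "y")))
  # exact copies: PSRF 1 (up to the (n-1)/n finite-sample factor)
  expect_equal(unname(convergence_ratio(list(a, a))), c(1, 1),
               tolerance = 1e-3)
  # disjoint modes: large
  b <- a; b[, 1] <- b[, 1] + 50
  expect_gt(convergence_ratio(list(a, b))["x"], 10)
  expect_error(convergence_ratio(list(a)), "at least 2")
  expect_error(convergence_ratio(list(a, a[1:10, ])), "equal lengths")
})

test_that("chains are reproducible and tune into the target window", {
  os <- toy_os()
  cfg <- mcmc_config(n_generations = 4000, burn_in = 1500, thin = 5)
  ch1 <- run_mcmc(os, "bbm", cfg, seed = 11)
  ch2 <- run_mcmc(os, "bbm", cfg, seed = 11)
  ch3 <- run_mcmc(os, "bbm", cfg, seed = 12)
  # identical seed + config: bit-identical samples
  expect_identical(ch1$samples, ch2$samples)
  expect_false(identical(ch1$samples, ch3$samples))
  # post-burn-in acceptance near the unidimensional optimum after tuning
  for (blk in c("p", "kd", "tf")) {
    expect_gt(ch1$acceptance[blk], 0.3)
    expect_lt(ch1$acceptance[blk], 0.6)
  }
  # reference Kds never move
  expect_equal(unname(ch1$samples[, "kd.AAAA"]),
               rep(1, nrow(ch1$samples)))
  expect_equal(unname(ch1$samples[, "kd.CCCC"]),
               rep(20, nrow(ch1$samples)))
  # frequencies stay on the simplex
  psum <- rowSums(ch1$samples[, paste0("p.", os$sequences)])
  expect_equal(psum, rep(1, length(psum)), tolerance = 1e-9)
})

test_that("the tf_total bound is a hard rejection boundary", {
  os <- toy_os()
  cfg <- mcmc_config(n_generations = 3000, burn_in = 1000, thin = 2)
  ch <- run_mcmc(os, "bbm", cfg, tf_total = 12, seed = 13)
  expect_true(all(ch$samples[, "tf_free"] < 12))
})

test_that("rj birth width zero leaves the posterior over models flat", {
  # w_E -> 0: every birth adds a zero-valued term, so the likelihood is
  # identical in both models and occupancy ~ 1:1
  os <- oligo_set(c("AA", "AT"), c(100, 100), c(100, 100),
                  ref_kds = c(AA = 1, AT = exp(0.3)))
  cfg <- mcmc_config(n_generations = 20000, burn_in = 2000, thin = 1,
                     rj_birth_width = 1e-9, rj_moves_per_gen = 1,
                     sigma_bounds = c(0.3, 0.3 + 1e-9))
  ch <- run_mcmc(os, "gem", cfg, optimal_sequence = "AA", tf_free = 1,
                 sample_p = FALSE, sample_tf = FALSE, sample_sigma = FALSE,
                 seed = 21)
  occ <- mean(ch$delta[, "d.2T"])
  expect_gt(occ, 0.45)
  expect_lt(occ, 0.55)
})

test_that("untestable terms are never proposed", {
  # position 3 never varies and position-1 G never occurs: their indicator
  # columns must stay off throughout
  os <- oligo_set(c("AAA", "ATA", "CAA"), c(50, 60, 70), c(60, 50, 70),
                  ref_kds = c(AAA = 1, CAA = 10))
  cfg <- mcmc_config(n_generations = 3000, burn_in = 500, thin = 2)
  ch <- run_mcmc(os, "gem", cfg, optimal_sequence = "AAA", seed = 31)
  expect_true(all(ch$delta[, "d.1G"] == 0))
  expect_true(all(ch$delta[, c("d.3C", "d.3G", "d.3T")] == 0))
  # anchors stay off too
  expect_true(all(ch$delta[, "d.1A"] == 0))
})

test_that("fit wrappers validate identifiability requirements", {
  os_noref <- oligo_set(c("AAAA", "CCCC"), c(5, 5), c(5, 5))
  expect_error(fit_bbm(os_noref), "reference")
  expect_error(fit_gem(os_noref), "reference")
})
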