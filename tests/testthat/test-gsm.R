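test_that("degenerate and closed-form chains behave exactly", {
  # all mass on one sequence: point-mass tables, prediction = n_total
  m <- fit_gsm(c(ACGTA = 500), m = 2)
  expect_equal(unname(m$start_freqs["AC"]), 1)
  expect_equal(unname(gsm_predicted_count("ACGTA", m)), 500)
  # uniform chain: closed form n_total / 4^L over the full space
  nucs <- c("A", "C", "G", "T")
  all3 <- do.call(paste0, expand.grid(nucs, nucs, nucs))
  mu <- fit_gsm(stats::setNames(rep(4, 64), all3), m = 1)
  expect_equal(unname(gsm_predicted_count(all3, mu)),
               rep(256 / 64, 64), tolerance = 1e-12)
  expect_error(fit_gsm(numeric()), "empty")
  expect_error(fit_gsm(c(ACG = 1), m = 3), "1 <= m < L")
})

test_that("transition frequencies converge on iid-uniform input", {
  set.seed(101)
  nucs <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, expand.grid(nucs, nucs, nucs, nucs, nucs))
  counts <- stats::setNames(as.numeric(rmultinom(1, 1e6, rep(1, 1024))),
                            all5)
  m1 <- fit_gsm(counts, m = 1)
  expect_true(all(abs(m1$transitions - 0.25) < 0.01))
  expect_true(all(abs(m1$start_freqs - 0.25) < 0.01))
})

test_that("saturated model reproduces observed counts exactly", {
  set.seed(3)
  nucs <- c("A", "C", "G", "T")
  all4 <- do.call(paste0, expand.grid(nucs, nucs, nucs, nucs))
  counts <- stats::setNames(rgamma(256, 2) * 50 + 1, all4)
  msat <- fit_gsm(counts, m = 3)
  expect_equal(unname(gsm_predicted_count(all4, msat)), unname(counts),
               tolerance = 1e-10)
  expect_equal(gsm_rmse(msat, counts), 0, tolerance = 1e-9)
})

test_that("order-3 predictions match the brute-force oracle on 7-mers", {
  set.seed(11)
  seqs <- unique(replicate(400, paste(sample(c("A", "C", "G", "T"), 7,
                                             replace = TRUE),
                                      collapse = "")))
  counts <- stats::setNames(rpois(length(seqs), 40) + 1, seqs)
  m3 <- fit_gsm(counts, m = 3)
  pred <- gsm_predicted_count(seqs, m3, strict = TRUE)
  orc <- oracle_gsm_predict(seqs, counts, 3)
  expect_equal(unname(pred), unname(orc), tolerance = 1e-12)
})

test_that("gsm_rmse is the percentage RMS of relative errors", {
  counts <- c(AAA = 10, CCC = 20, GGG = 40)
  msat <- fit_gsm(counts, m = 2)
  # doubling every prediction scores exactly 100%
  m2x <- msat
  m2x$n_total <- 2 * msat$n_total
  expect_equal(gsm_rmse(m2x, counts), 100, tolerance = 1e-9)
  expect_error(gsm_rmse(msat, c(AAA = 0, CCC = 2)), "positive")
})

test_that("predictions normalize over the full sequence space", {
  set.seed(5)
  nucs <- c("A", "C", "G", "T")
  for (L in c(4, 6)) {
    allL <- do.call(paste0, as.list(expand.grid(rep(list(nucs), L))))
    counts <- stats::setNames(rgamma(4^L, 1) + 0.1, allL)
    for (m in c(1, 2)) {
      fit <- fit_gsm(counts, m = m)
      expect_equal(sum(gsm_predicted_count(allL, fit)), sum(counts),
                   tolerance = 1e-8)
    }
  }
})

test_that("fitting recovers a known order-2 chain and orders by accuracy", {
  set.seed(9)
  nucs <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, as.list(expand.grid(rep(list(nucs), 5))))
  start <- rgamma(16, 2); start <- start / sum(start)
  names(start) <- do.call(paste0, as.list(expand.grid(nucs, nucs)))
  trans <- matrix(rgamma(64, 2), 16, 4)
  trans <- trans / rowSums(trans)
  rownames(trans) <- names(start); colnames(trans) <- nucs
  prob <- vapply(all5, function(s) {
    pr <- start[substr(s, 1, 2)]
    for (k in 3:5) pr <- pr * trans[substr(s, k - 2, k - 1),
                                    substr(s, k, k)]
    as.numeric(pr)
  }, numeric(1))
  counts <- stats::setNames(as.numeric(rmultinom(1, 1e6, prob)), all5)
  counts <- counts[counts > 0]
  # transition recovery within binomial standard error at depth 1e6
  m2 <- fit_gsm(counts, m = 2)
  n_ctx <- 3e6 / 16  # ~3 transitions per read, 16 contexts
  tol <- 4 * sqrt(0.25 / n_ctx)
  expect_lt(max(abs(m2$transitions[rownames(trans), ] - trans)), tol + 0.01)
  # accuracy ordering: order 1 much worse; order 3 ~ order 2
  r <- vapply(1:3, function(m) gsm_rmse(fit_gsm(counts, m = m), counts),
              numeric(1))
  expect_gt(r[1], r[2])
  expect_lt(abs(r[3] - r[2]) / r[2], 0.25)
})

test_that("predictions are orientation-dependent", {
  # direction matters: a sequence and its reverse complement are scored
  # independently (the mononucleotide model's failure mode)
  set.seed(13)
  seqs <- unique(replicate(300, paste(sample(c("A", "C", "G", "T"), 5,
                                             replace = TRUE),
                                      collapse = "")))
  counts <- stats::setNames(rgamma(length(seqs), 1) * 20 + 1, seqs)
  m2 <- fit_gsm(counts, m = 2)
  rc <- vapply(seqs, function(s)
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = ""),
    character(1))
  keep <- rc %in% seqs & rc != seqs
  pred_f <- gsm_predicted_count(seqs[keep], m2)
  pred_r <- gsm_predicted_count(rc[keep], m2)
  expect_gt(max(abs(pred_f - pred_r)), 1e-6)
})

test_that("missing contexts back off or fail loudly in strict mode", {
  counts <- c(AAAA = 50, AACA = 30, CAAA = 20)
  m2 <- fit_gsm(counts, m = 2)
  # GGGA's context GG was never observed
  expect_error(gsm_predicted_count("AGGA", m2, strict = TRUE),
               "context")
  p <- gsm_predicted_count("AAGA", m2)   # falls back to lower orders
  expect_true(is.finite(p) && p >= 0)
})

test_that("order selection and serialization round-trip", {
  set.seed(17)
  nucs <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, as.list(expand.grid(rep(list(nucs), 5))))
  counts <- stats::setNames(rep(100, 1024), all5)  # n_total ~ 1e5
  expect_equal(fit_gsm(counts)$order, select_gsm_order(counts))
  expect_equal(select_gsm_order(counts), 4L)  # 4^5 <= 1024*100/100
  m2 <- fit_gsm(counts[1:500], m = 2)
  prefix <- file.path(withr::local_tempdir(), "gsm")
  write_gsm(m2, prefix, meta = "unit test")
  m2b <- read_gsm(prefix)
  expect_equal(m2b$order, m2$order)
  expect_equal(m2b$n_total, m2$n_total)
  expect_equal(m2b$transitions, m2$transitions, tolerance = 1e-12)
  expect_equal(m2b$start_freqs, m2$start_freqs, tolerance = 1e-12)
})
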