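# Independent oracle implementations used to freeze expected values.
# These deliberately re-derive each quantity by the most direct route
# (element-wise loops, textbook pmfs, brute-force products) and share no
# code with the package internals they check.

# direct term-by-term evaluation of the binding isotherm + renormalization
oracle_bound_freqs <- function(p, kds, tf) {
  num <- numeric(length(p))
  for (i in seq_along(p)) num[i] <- p[i] * (tf / (tf + kds[i]))
  num / sum(num)
}

# textbook multinomial log-pmf product for the two count tables
oracle_bbm_ll <- function(C, D, p, b) {
  stats::dmultinom(C, prob = p, log = TRUE) +
    stats::dmultinom(D, prob = b, log = TRUE)
}

# brute-force chain-rule product for an order-m Markov prediction, fitted
# from scratch with nested loops over positions
oracle_gsm_predict <- function(sequences, counts, m) {
  seqs <- names(counts)
  L <- nchar(seqs[1])
  n_total <- sum(counts)
  starts <- substr(seqs, 1, m)
  p0 <- tapply(counts, starts, sum) / n_total
  num <- list(); den <- list()
  for (k in (m + 1):L) {
    ctx <- substr(seqs, k - m, k - 1)
    nxt <- substr(seqs, k, k)
    for (i in seq_along(seqs)) {
      key <- paste0(ctx[i], ".", nxt[i])
      num[[key]] <- (num[[key]] %||% 0) + counts[i]
      den[[ctx[i]]] <- (den[[ctx[i]]] %||% 0) + counts[i]
    }
  }
  vapply(sequences, function(s) {
    pr <- p0[substr(s, 1, m)]
    if (is.na(pr)) return(0)
    pr <- as.numeric(pr)
    for (k in (m + 1):L) {
      key <- paste0(substr(s, k - m, k - 1), ".", substr(s, k, k))
      top <- num[[key]] %||% 0
      bot <- den[[substr(s, k - m, k - 1)]]
      if (is.null(bot)) stop("oracle: missing context")
      pr <- pr * top / bot
    }
    n_total * pr
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random exact (noise-free rounded) systems for property tests
random_system <- function(K, seed, tf = 10) {
  set.seed(seed)
  seqs <- unique(replicate(K + 10, paste(sample(c("A", "C", "G", "T"), 6,
                                                replace = TRUE),
                                         collapse = "")))[1:K]
  kds <- stats::setNames(exp(stats::runif(K, log(0.5), log(200))), seqs)
  p <- stats::setNames(as.numeric(stats::rgamma(K, 5)), seqs)
  p <- p / sum(p)
  theta <- tf / (tf + kds)
  b <- p * theta / sum(p * theta)
  list(seqs = seqs, kds = kds, p = p, theta = theta, b = b, tf = tf)
}

# tiny deterministic oligo set used across tests
toy_os <- function() {
  oligo_set(c("AAAA", "CCCC", "GGGG"),
            pre_counts = c(120, 90, 90),
            bound_counts = c(150, 60, 90),
            ref_kds = c(AAAA = 1, CCCC = 20))
}
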