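#' Fit an order-m Markov model of ligand synthesis frequencies
#'
#' The generative sequence model (GSM) predicts the relative frequency of
#' each full-length ds-oligo in the pre-bound pool from polynucleotide
#' statistics: a start-frequency table over the first m-mer (capturing any
#' beginning-terminus bias) and conditional next-nucleotide probabilities
#' given the preceding m-mer context.  Transition counts are pooled across
#' positions by default (maximizing counts per context); set
#' `position_specific = TRUE` to condition on position as well.
#'
#' Lower-order pooled tables (down to order 1, plus marginal nucleotide
#' frequencies) are always fitted alongside, to serve as the recursive
#' missing-context fallback at prediction time.
#'
#' @param counts Named numeric vector: ds-oligo sequence -> count.
#' @param m Markov order (polynucleotide length), `1 <= m < L`.  Default
#'   [select_gsm_order()].
#' @param position_specific Condition transition tables on position k
#'   instead of pooling (default `FALSE`).
#' @return Object of class `gsm_model` with elements `order`, `start_freqs`,
#'   `transitions` (contexts x 4 matrix, or a list of them per position),
#'   `backoff` (pooled lower-order tables), `n_total`, `L`.
#' @export
fit_gsm <- function(counts, m = select_gsm_order(counts),
                    position_specific = FALSE) {
  if (!length(counts)) stop("empty input")
  seqs <- toupper(names(counts))
  check_dna(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have uniform length")
  n_total <- sum(counts)
  if (n_total <= 0) stop("total count must be positive")
  if (m < 1 || m >= L) stop("order m must satisfy 1 <= m < L")

  start_mer <- substr(seqs, 1, m)
  start_freqs <- tapply(counts, start_mer, sum) / n_total
  start_freqs <- stats::setNames(as.numeric(start_freqs), names(start_freqs))

  trans_table <- function(ord, positions) {
    ctx <- unlist(lapply(positions, function(k) substr(seqs, k - ord, k - 1)))
    nxt <- unlist(lapply(positions, function(k) substr(seqs, k, k)))
    w <- rep(counts, times = length(positions))
    tab <- tapply(w, list(ctx, factor(nxt, levels = NUCS)), sum)
    tab[is.na(tab)] <- 0
    sweep(tab, 1, rowSums(tab), "/")
  }
  positions <- (m + 1):L
  transitions <- if (position_specific)
    lapply(positions, function(k) trans_table(m, k))
  else trans_table(m, positions)
  if (position_specific) names(transitions) <- positions

  backoff <- list()
  if (m > 1)
    for (ord in (m - 1):1)
      backoff[[ord]] <- trans_table(ord, (ord + 1):L)
  nuc_w <- tapply(rep(counts, each = L),
                  factor(unlist(strsplit(seqs, "")), levels = NUCS), sum)
  nuc_w[is.na(nuc_w)] <- 0
  structure(list(order = m, start_freqs = start_freqs,
                 transitions = transitions, backoff = backoff,
                 nuc_freqs = as.numeric(nuc_w / sum(nuc_w)),
                 n_total = n_total, L = L,
                 position_specific = position_specific),
            class = "gsm_model")
}

#' Default Markov order for a count table
#'
#' The largest order m such that the number of distinct (m+1)-mers does not
#' exceed `n_total / per_context` -- an operationalization of "the longest
#' polynucleotide that can be accurately measured" (default: at least 100
#' observations per possible context on average), clamped to `[1, L - 1]`.
#'
#' @param counts Named count vector.
#' @param per_context Required average observations per (m+1)-mer.
#' @return Integer order.
#' @export
select_gsm_order <- function(counts, per_context = 100) {
  L <- nchar(names(counts)[1])
  n_total <- sum(counts)
  m <- floor(log(n_total / per_context, 4)) - 1
  max(1L, min(L - 1L, as.integer(m)))
}

#' GSM-predicted counts for ds-oligo sequences
#'
#' Chain-rule prediction: `n_total * start_freq(first m-mer) * prod_k
#' P(nucleotide_k | preceding m-mer)`.  A start m-mer never observed yields
#' a prediction of 0.  A missing transition context backs off recursively to
#' the pooled order m-1 table (down to marginal nucleotide frequencies)
#' unless `strict = TRUE`, in which case it is an error naming the context.
#'
#' @param sequences Character vector of sequences of the model's length.
#' @param model A [gsm_model][fit_gsm()].
#' @param strict Disable the missing-context fallback (default `FALSE`).
#' @return Named numeric vector of predicted counts (same scale as the
#'   training counts).
#' @export
gsm_predicted_count <- function(sequences, model, strict = FALSE) {
  sequences <- toupper(sequences)
  check_dna(sequences)
  if (any(nchar(sequences) != model$L))
    stop("sequences must have length ", model$L)
  m <- model$order
  p0 <- model$start_freqs[substr(sequences, 1, m)]
  p0[is.na(p0)] <- 0
  pred <- model$n_total * as.numeric(p0)
  for (k in (m + 1):model$L) {
    ctx <- substr(sequences, k - m, k - 1)
    nuc_i <- match(substr(sequences, k, k), NUCS)
    tab <- if (model$position_specific)
      model$transitions[[as.character(k)]] else model$transitions
    pr <- tab[cbind(match(ctx, rownames(tab)), nuc_i)]
    miss <- which(is.na(pr))
    if (length(miss)) {
      if (strict)
        stop("missing GSM context '", ctx[miss[1]], "' at position ", k)
      pr[miss] <- backoff_prob(model, ctx[miss], nuc_i[miss])
    }
    pred <- pred * pr
  }
  stats::setNames(pred, sequences)
}

# recursive back-off: order m-1, m-2, ..., 1, then marginal nucleotide freqs
backoff_prob <- function(model, ctx, nuc_i) {
  out <- rep(NA_real_, length(ctx))
  ord <- nchar(ctx[1]) - 1
  while (ord >= 1 && anyNA(out)) {
    tab <- if (ord == model$order && !model$position_specific)
      model$transitions else model$backoff[[ord]]
    if (!is.null(tab)) {
      todo <- which(is.na(out))
      sub <- substr(ctx[todo], nchar(ctx[todo]) - ord + 1, nchar(ctx[todo]))
      out[todo] <- tab[cbind(match(sub, rownames(tab)), nuc_i[todo])]
    }
    ord <- ord - 1
  }
  out[is.na(out)] <- model$nuc_freqs[nuc_i[is.na(out)]]
  out
}

#' Root-mean-square relative error of GSM predictions
#'
#' Compares GSM-predicted counts to observed counts over a set of
#' accurately countable sequences and reports the RMSE of the relative
#' errors `(predicted - observed) / observed` as a percentage.  A saturated
#' model (order L-1 fitted to the same data) scores exactly 0%.
#'
#' @param model A [gsm_model][fit_gsm()].
#' @param observed Named count vector; all counts must be positive (the
#'   metric is restricted to sequences whose frequency can be measured by
#'   direct count).
#' @return RMSE as a percentage.
#' @export
gsm_rmse <- function(model, observed) {
  if (any(observed <= 0))
    stop("observed counts must be positive for all scored sequences")
  pred <- gsm_predicted_count(names(observed), model)
  rel <- (pred - observed) / observed
  100 * sqrt(mean(rel^2))
}

#' Serialize / read a GSM
#'
#' Writes two tab-separated tables under a path prefix:
#' `<prefix>.transitions.tsv` with columns (context, A, C, G, T) and
#' `<prefix>.start.tsv` with columns (mer, freq).  `read_gsm()` restores a
#' pooled model (back-off tables are refitted only if training counts are
#' given).
#'
#' @param model A pooled [gsm_model][fit_gsm()].
#' @param prefix Output path prefix.
#' @param meta Optional comment string recorded in a `#` header line.
#' @return `write_gsm`: the two paths, invisibly.  `read_gsm`: a
#'   `gsm_model`.
#' @export
write_gsm <- function(model, prefix, meta = NULL) {
  if (model$position_specific)
    stop("serialization implemented for pooled models only")
  tp <- paste0(prefix, ".transitions.tsv")
  sp <- paste0(prefix, ".start.tsv")
  tdf <- data.frame(context = rownames(model$transitions),
                    model$transitions, check.names = FALSE)
  sdf <- data.frame(mer = names(model$start_freqs),
                    freq = as.numeric(model$start_freqs))
  for (x in list(list(tp, tdf), list(sp, sdf))) {
    con <- file(x[[1]], "w")
    if (!is.null(meta)) writeLines(paste0("# ", meta), con)
    writeLines(paste0("# n_total=", format(model$n_total), " L=", model$L,
                      " order=", model$order), con)
    utils::write.table(x[[2]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(c(tp, sp))
}

#' @rdname write_gsm
#' @export
read_gsm <- function(prefix) {
  tp <- paste0(prefix, ".transitions.tsv")
  sp <- paste0(prefix, ".start.tsv")
  hdr <- grep("^# n_total=", readLines(tp, n = 5), value = TRUE)[1]
  fields <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  kv <- stats::setNames(as.numeric(sub(".*=", "", fields)),
                        sub("=.*", "", fields))
  tdf <- utils::read.table(tp, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = c("character",
                           rep("numeric", 4)))
  sdf <- utils::read.table(sp, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("character", "numeric"))
  trans <- as.matrix(tdf[, NUCS])
  rownames(trans) <- tdf$context
  structure(list(order = as.integer(kv[["order"]]),
                 start_freqs = stats::setNames(sdf$freq, sdf$mer),
                 transitions = trans, backoff = list(),
                 nuc_freqs = rep(0.25, 4),
                 n_total = kv[["n_total"]], L = as.integer(kv[["L"]]),
                 position_specific = FALSE),
            class = "gsm_model")
}

#' @export
print.gsm_model <- function(x, ...) {
  cat(sprintf("gsm_model: order %d %s chain over length-%d ds-oligos\n",
              x$order, if (x$position_specific) "position-specific"
              else "pooled", x$L))
  cat(sprintf("  %d start %d-mers, trained on %.0f counts\n",
              length(x$start_freqs), x$order, x$n_total))
  invisible(x)
}
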