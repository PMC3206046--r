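#' Construct an oligo set
#'
#' An `oligo_set` holds the data of one pooled binding experiment: a set of
#' fixed-length DNA ligands (ds-oligos), their sequencing counts in the
#' pre-bound and bound fractions, and the subset of "reference" ligands whose
#' dissociation constants are independently known (in nM).  Reference Kds
#' anchor the concentration scale of the inference.
#'
#' @param sequences Character vector of unique, same-length DNA strings over
#'   `A`, `C`, `G`, `T` (lower case is accepted and upper-cased).
#' @param pre_counts Non-negative integer counts in the pre-bound fraction,
#'   one per sequence.
#' @param bound_counts Non-negative integer counts in the bound fraction,
#'   one per sequence.
#' @param ref_kds Named numeric vector of known dissociation constants in nM;
#'   names must be members of `sequences` and values strictly positive.
#' @return An object of class `oligo_set`: a list with elements `sequences`,
#'   `pre_counts`, `bound_counts` (both named by sequence), `ref_kds`,
#'   `L` (oligo length), `n_pre` and `n_bound` (count totals).
#' @examples
#' os <- oligo_set(c("ACGT", "AGGT", "ACGA"),
#'                 pre_counts = c(10, 5, 7), bound_counts = c(9, 1, 3),
#'                 ref_kds = c(ACGT = 1, AGGT = 25))
#' os
#' @export
oligo_set <- function(sequences, pre_counts, bound_counts,
                      ref_kds = numeric()) {
  sequences <- toupper(as.character(sequences))
  check_dna(sequences)
  if (anyDuplicated(sequences))
    stop("duplicate sequences in oligo set: ",
         paste(unique(sequences[duplicated(sequences)]), collapse = ", "))
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("all sequences must have the same length (got lengths ",
         paste(sort(L), collapse = ", "), ")")
  K <- length(sequences)
  if (length(pre_counts) != K || length(bound_counts) != K)
    stop("pre_counts and bound_counts must have one entry per sequence")
  check_counts(pre_counts, "pre_counts")
  check_counts(bound_counts, "bound_counts")
  pre_counts <- stats::setNames(as.numeric(pre_counts), sequences)
  bound_counts <- stats::setNames(as.numeric(bound_counts), sequences)
  if (length(ref_kds)) {
    if (is.null(names(ref_kds)) || any(!nzchar(names(ref_kds))))
      stop("ref_kds must be named by sequence")
    names(ref_kds) <- toupper(names(ref_kds))
    missing <- setdiff(names(ref_kds), sequences)
    if (length(missing))
      stop("reference sequences not in the oligo set: ",
           paste(missing, collapse = ", "))
    if (any(!is.finite(ref_kds)) || any(ref_kds <= 0))
      stop("reference Kd values must be strictly positive and finite")
    if (anyDuplicated(names(ref_kds)))
      stop("duplicated reference sequences")
  }
  structure(list(sequences = sequences,
                 pre_counts = pre_counts,
                 bound_counts = bound_counts,
                 ref_kds = ref_kds,
                 L = L,
                 n_pre = sum(pre_counts),
                 n_bound = sum(bound_counts)),
            class = "oligo_set")
}

#' @export
print.oligo_set <- function(x, ...) {
  cat(sprintf("oligo_set: %d ds-oligos of length %d\n",
              length(x$sequences), x$L))
  cat(sprintf("  pre-bound total N_C = %.0f, bound total N_D = %.0f\n",
              x$n_pre, x$n_bound))
  if (length(x$ref_kds))
    cat(sprintf("  %d reference Kd(s): %s\n", length(x$ref_kds),
                paste(sprintf("%s=%.4g nM", names(x$ref_kds), x$ref_kds),
                      collapse = ", ")))
  else cat("  no reference Kds\n")
  invisible(x)
}

#' @export
as.data.frame.oligo_set <- function(x, ...) {
  data.frame(sequence = x$sequences,
             pre_count = unname(x$pre_counts),
             bound_count = unname(x$bound_counts),
             is_reference = x$sequences %in% names(x$ref_kds),
             ref_kd_nM = unname(x$ref_kds[x$sequences]),
             stringsAsFactors = FALSE)
}

check_dna <- function(sequences) {
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T}: ",
         paste(utils::head(sequences[bad], 3), collapse = ", "))
  invisible(TRUE)
}

check_counts <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop(what, " must be non-negative integers")
  invisible(TRUE)
}

NUCS <- c("A", "C", "G", "T")

# L x K integer matrix of nucleotide codes (1..4), one column per sequence
seq_matrix <- function(sequences) {
  m <- vapply(sequences,
              function(s) match(strsplit(s, "", fixed = TRUE)[[1]], NUCS),
              integer(nchar(sequences[1])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}
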