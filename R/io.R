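#' Read and write ds-oligo count tables
#'
#' Counts are stored as two-column TSV `(sequence, count)`; a header line is
#' optional and `#` comment lines are skipped.  Sequences are validated
#' (uniform length, A/C/G/T only, non-negative integer counts; parse errors
#' report the offending line number) and duplicated sequences are summed
#' with a warning.
#'
#' @param path File path.
#' @return `read_counts`: named numeric vector (sequence -> count).
#' @export
read_counts <- function(path) {
  raw <- read_tsv_body(path, c("sequence", "count"))
  df <- raw$df
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop(path, ": invalid count '", df$count[bad[1]], "' at line ",
         raw$lines[bad[1]])
  seqs <- toupper(df$sequence)
  badc <- grepl("[^ACGT]", seqs)
  if (any(badc))
    stop(path, ": invalid sequence characters at line ",
         raw$lines[which(badc)[1]])
  if (length(unique(nchar(seqs))) != 1)
    stop(path, ": ragged sequence lengths (first at line ",
         raw$lines[which(nchar(seqs) != nchar(seqs[1]))[1]], ")")
  if (anyDuplicated(seqs)) {
    warning(path, ": duplicate sequences summed")
    counts <- tapply(counts, seqs, sum)
    return(stats::setNames(as.numeric(counts), names(counts)))
  }
  stats::setNames(counts, seqs)
}

#' @param counts Named count vector.
#' @param meta Optional comment string written as a `#` header.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  writeLines("sequence\tcount", con)
  writeLines(paste(names(counts), format(counts, scientific = FALSE,
                                         trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Read and write reference-Kd tables
#'
#' References are TSV `(sequence, kd_nM)`.  Kds must be strictly positive.
#' The count-only model needs at least two references (or a known free TF
#' concentration) for identifiability; fewer than two raises a warning, not
#' an error, since the energy model can proceed with one.
#'
#' @param path File path.
#' @return `read_references`: named numeric vector (sequence -> Kd, nM).
#' @export
read_references <- function(path) {
  raw <- read_tsv_body(path, c("sequence", "kd_nM"))
  kd <- suppressWarnings(as.numeric(raw$df$kd_nM))
  bad <- which(!is.finite(kd) | kd <= 0)
  if (length(bad))
    stop(path, ": non-positive Kd at line ", raw$lines[bad[1]])
  if (length(kd) < 2)
    warning(path, ": fewer than 2 references; the count-only model needs ",
            "2 unless tf_free is known (1 suffices for the energy model)")
  stats::setNames(kd, toupper(raw$df$sequence))
}

#' @param ref_kds Named Kd vector (nM).
#' @param meta Optional `#` header comment.
#' @rdname read_references
#' @export
write_references <- function(ref_kds, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  writeLines("sequence\tkd_nM", con)
  writeLines(paste(names(ref_kds),
                   format(ref_kds, digits = 12, scientific = FALSE,
                          trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Write and read simulation ground truth
#'
#' TSV with columns `(sequence, true_kd_nM, is_reference)` plus the realized
#' free TF concentration in a `#` header line.
#'
#' @param sim A [simulate_experiment()] result.
#' @param path File path.
#' @param meta Optional extra `#` header comment.
#' @export
write_ground_truth <- function(sim, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  writeLines(paste0("# tf_free_nM=", format(sim$tf_free, digits = 12)), con)
  df <- data.frame(sequence = names(sim$true_kds),
                   true_kd_nM = as.numeric(sim$true_kds),
                   is_reference = names(sim$true_kds) %in%
                     names(sim$oligo_set$ref_kds))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth`: data.frame with attribute `tf_free`.
#' @export
read_ground_truth <- function(path) {
  hdr <- grep("^# tf_free_nM=", readLines(path, n = 10), value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (length(hdr))
    attr(df, "tf_free") <- as.numeric(sub("^# tf_free_nM=", "", hdr[1]))
  df
}

#' FASTA export/import of an oligo set
#'
#' One record per ds-oligo, record ID = the sequence itself (counts live in
#' the TSV tables, FASTA is for interoperability).
#'
#' @param sequences Character vector of sequences.
#' @param path File path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- sequences
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fasta`: character vector of sequences.
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}

#' Write a posterior trace file
#'
#' Tab-separated: generation index, log-likelihood, then every recorded
#' parameter column of the chain (indicator draws included as 0/1 columns).
#'
#' @param chain A [run_mcmc()] result.
#' @param path File path.
#' @param meta Optional `#` header comment.
#' @export
write_trace <- function(chain, path, meta = NULL) {
  cfg <- chain$config
  gen <- seq(cfg$burn_in + cfg$thin, by = cfg$thin,
             length.out = nrow(chain$samples))
  df <- data.frame(generation = gen, chain$samples, check.names = FALSE)
  if (!is.null(chain$delta)) df <- cbind(df, chain$delta)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- internals --------------------------------------------------------------

# read a 2-column TSV with optional header and # comments; returns the body
# data.frame (with the expected column names) and original line numbers
read_tsv_body <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop(path, ": empty file")
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(path, ": expected 2 columns at line ", keep[which(nf < 2)[1]])
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) {
    fields <- fields[-1]
    keep <- keep[-1]
  }
  if (!length(fields)) stop(path, ": no data rows")
  df <- data.frame(a = vapply(fields, `[[`, "", 1),
                   b = vapply(fields, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  names(df) <- cols
  list(df = df, lines = keep)
}

# short content hash used to stamp output files with their configuration
config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}
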