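#' @title Sequence utilities
#' @description Internal helpers shared across modules. Sequences are plain
#'   upper-case character strings; RNA (U) and DNA (T) are accepted
#'   interchangeably and harmonised where an operation needs one alphabet.
#' @noRd
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of a nucleotide string (alphabet preserved)
#' @param x character vector of sequences (A/C/G/U or A/C/G/T)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  is_rna <- grepl("U", x, fixed = TRUE) & !grepl("T", x, fixed = TRUE)
  vapply(seq_along(x), function(i) {
    s <- x[i]
    comp <- if (is_rna[i]) chartr("ACGU", "UGCA", s) else chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1))
}

check_nt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUTacgut]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/U/T: %s",
                 what, paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

rand_seq <- function(n, len, alphabet = DNA_BASES) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector of sequences
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(as.character(set), names(set))
}

#' Largest-remainder allocation of n items to probabilities p
#' Deterministic: exact integer composition with sum n, ordered as p.
#' @noRd
quota_alloc <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9, n >= 0)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    # ties broken by position for determinism
    idx <- order(-frac, seq_along(p))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
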