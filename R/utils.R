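`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning upper-case
#' plain character sequences named by the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "[ \t]"), `[[`, character(1), 1L)
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the IUPAC DNA alphabet: %s",
                 what, paste(utils::head(names(x)[bad] %||% which(bad), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# floor-truncate to `digits` decimal places (reporting convention for
# printed percentages: 76.47 -> 76, 84.78 -> 84.7)
#' Truncate a value at a fixed number of decimal digits
#'
#' Floor-truncation (never rounding up) used when reporting percentages
#' the way assay summary tables print them.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Truncated numeric vector.
#' @export
truncate_reported <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 1e-9) / f
}
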