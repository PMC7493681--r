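#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes accepted in genome sequences
IUPAC_CHARS <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Reverse complement of DNA strings
#'
#' Plain character-vector reverse complement. IUPAC degenerate codes are
#' complemented to their standard counterparts.
#'
#' @param x character vector of DNA sequences (upper case).
#' @return character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("ACGTTT")
revcomp <- function(x) {
  vapply(x, function(s) {
    v <- rev(strsplit(s, NULL, fixed = TRUE)[[1]])
    chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", paste(v, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Draws a uniform random sequence over A/C/G/T from the current RNG
#' stream (used by the simulator; seed it with [set.seed()]).
#'
#' @param n sequence length in nt.
#' @return a single character string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability `rate`, always to a
# different base (so `rate` is the realized per-site divergence from the
# input in expectation). Draws flow from the current RNG stream.
mutate_sequence <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, NULL, fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    # deterministic given the stream: draw an offset 1..3 into the other bases
    idx <- match(v[hit], DNA_BASES)
    off <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- DNA_BASES[((idx - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# validate that sequences contain only the given alphabet
assert_alphabet <- function(x, alphabet = IUPAC_CHARS, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}: %s",
                 what, paste(alphabet, collapse = ","),
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic FASTA writer (70-column wrap), used where byte-identical
# reruns are part of the contract
write_fasta <- function(seqs, path, headers = names(seqs), width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con, sep = "\n")
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con, sep = "\n")
  }
  invisible(path)
}

# FASTA reader via Biostrings; returns named character vector, names are
# full header lines
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}
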