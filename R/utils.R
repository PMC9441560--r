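# Shared sequence helpers. All coordinates in this package are 0-based,
# half-open unless a function's documentation says otherwise.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse complement of nucleotide strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (`A`/`C`/`G`/`T`/`N`).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revComp("ATGC")
revComp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Uppercase and map RNA 'U' to DNA 'T'.
normalizeNt <- function(x) chartr("U", "T", toupper(x))

# TRUE where x contains only A/C/G/T (+N when allow_n).
isValidNt <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

isValidAa <- function(x) {
  nzchar(x) & grepl(paste0("^[", paste(.AA20, collapse = ""), "]+$"), x)
}

# Translate nucleotide strings codon by codon: trailing partial codons are
# dropped, stops come back as '*', any N-containing codon as 'X'.  The first
# codon is NOT treated as an initiator (TTG/CTG stay L).
translateNt <- function(x) {
  x <- substr(x, 1L, 3L * (nchar(x) %/% 3L))
  n <- nchar(x)
  out <- character(length(x))
  ok <- n >= 3L
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[ok]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  names(out) <- names(x)
  out
}

# all 0-based match start positions of `pattern` in `subject`, including
# overlapping occurrences (gregexpr alone reports non-overlapping ones)
fixedMatchStarts <- function(pattern, subject) {
  out <- integer(0)
  from <- 1L
  ns <- nchar(subject)
  while (from <= ns) {
    i <- regexpr(pattern, substr(subject, from, ns), fixed = TRUE)
    if (i == -1L) break
    pos <- from + as.integer(i) - 1L
    out <- c(out, pos - 1L)
    from <- pos + 1L
  }
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
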