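# Independent oracles used across tests. Deliberately naive: per-codon
# lookup in the standard genetic code and explicit rotation scans, so
# they share no code path with the package's batched template scanner.

codonLookup <- function(cod) {
  if (grepl("N", cod, fixed = TRUE)) return("X")
  unname(Biostrings::GENETIC_CODE[[cod]])
}

# translate a linear nucleotide string codon by codon
bruteTranslate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  paste(vapply(seq_len(n), function(i)
    codonLookup(substr(nt, 3L * i - 2L, 3L * i)), character(1)),
    collapse = "")
}

# enumerate all cORFs of a circle by scanning every rotation on an
# unbounded repeat, translating codon by codon until a stop or 3 laps
# (L codons), then keeping one maximal ORF per (frame phase, stop
# position on the circle)
bruteCorfs <- function(seq) {
  L <- nchar(seq)
  big <- strrep(seq, 5L)
  rows <- list()
  for (p in 0:(L - 1L)) {
    if (substr(big, p + 1L, p + 3L) != "ATG") next
    pep <- character(0)
    stopped <- FALSE
    for (ci in seq_len(L)) {
      aa <- codonLookup(substr(big, p + 3L * ci - 2L, p + 3L * ci))
      if (aa == "*") { stopped <- TRUE; break }
      pep <- c(pep, aa)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start_nt = p, nt_length = 3L * length(pep),
      is_infinite = !stopped,
      peptide = paste(pep, collapse = ""), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start_nt = integer(0), nt_length = integer(0),
                      is_infinite = logical(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  phase <- df$start_nt %% 3L
  stop_pos <- ifelse(df$is_infinite, "inf",
                     as.character((df$start_nt + df$nt_length) %% L))
  key <- paste(phase, stop_pos)
  ord <- order(-df$nt_length, df$start_nt)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$start_nt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

randomCircle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
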