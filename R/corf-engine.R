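# Circular ORF enumeration by rolling translation over repeated circle
# copies, the >20 aa AUG-start filter, and lap-group assignment.

#' Enumeration parameters for circular ORFs
#'
#' @param repeats Number of circle copies in the scan template (fixed 3
#'   unless deliberately overridden for experiments).
#' @param tail_nt Extra nucleotides appended from the circle start (fixed
#'   2) so start codons lying across the back-splice junction, e.g.
#'   `A^TG` or `AT^G`, are visible.
#' @param min_peptide_len Strict lower bound on retained peptide length in
#'   amino acids (default 20: peptides of > 20 aa pass).
#' @param start_codon Start codon (default `"ATG"`).
#' @return A named list.
#' @export
corfConfig <- function(repeats = 3L, tail_nt = 2L, min_peptide_len = 20L,
                       start_codon = "ATG") {
  list(repeats = as.integer(repeats), tail_nt = as.integer(tail_nt),
       min_peptide_len = as.integer(min_peptide_len),
       start_codon = toupper(start_codon))
}

#' Build the linear scan template of a circular sequence
#'
#' The circle is repeated three times and 2 nt from its start are appended
#' so that a start codon straddling the back-splice junction is never
#' missed; for a circle of length `L` the template has length `3L + 2`
#' (or `3L + min(2, L)` for very short circles).
#'
#' @param seq Circular nucleotide sequence.
#' @param cfg A [corfConfig()] list.
#' @return The template string.
#' @export
#' @examples
#' buildTemplate("ATGAAATAG")   # 29 nt
buildTemplate <- function(seq, cfg = corfConfig()) {
  seq <- normalizeNt(as.character(seq))
  L <- nchar(seq)
  if (L == 0L) stopf("buildTemplate(): empty sequence")
  paste0(strrep(seq, cfg$repeats), substr(seq, 1L, min(cfg$tail_nt, L)))
}

# Batched cORF enumeration over all circles: one big vectorized
# translation call instead of one per circle.
.enumerateAll <- function(seqs, cfg) {
  seqs <- normalizeNt(seqs)
  L <- nchar(seqs)
  if (any(L < 3L))
    stopf("enumerateCorfs(): sequence shorter than 3 nt (%s)",
          paste(names(seqs)[L < 3L], collapse = ", "))
  tmpl <- vapply(seqs, buildTemplate, character(1), cfg = cfg,
                 USE.NAMES = FALSE)
  m <- gregexpr(cfg$start_codon, tmpl, fixed = TRUE)
  starts <- lapply(seq_along(m), function(i) {
    p <- m[[i]]
    p <- if (p[1L] == -1L) integer(0) else as.integer(p) - 1L
    p[p < L[i]]
  })
  idx <- rep(seq_along(seqs), lengths(starts))
  if (!length(idx)) return(NULL)
  p <- unlist(starts)
  Li <- L[idx]
  # translation needs up to 3 laps (3L nt) from any start in [0, L): read
  # from enough circle copies to always have them available
  work <- strrep(seqs, cfg$repeats + 1L)
  peps <- translateNt(substr(work[idx], p + 1L, p + 3L * Li))
  stop_at <- as.integer(regexpr("*", peps, fixed = TRUE)) # codon idx of stop
  is_inf <- stop_at == -1L
  ncod <- ifelse(is_inf, nchar(peps), stop_at - 1L)
  keep <- ncod >= 1L
  df <- data.frame(
    circ_id = names(seqs)[idx][keep],
    start_nt = p[keep],
    nt_length = 3L * ncod[keep],
    is_infinite = is_inf[keep],
    peptide = substr(peps[keep], 1L, ncod[keep]),
    L = Li[keep],
    stringsAsFactors = FALSE)
  if (!nrow(df)) return(NULL)
  df$frame_phase <- df$start_nt %% 3L
  df$laps <- df$nt_length / df$L
  # dedupe: one maximal ORF per (circ, frame phase, stop position on the
  # circle); infinite ORFs have no stop and are keyed per frame phase
  stop_pos <- ifelse(df$is_infinite, "inf",
                     as.character((df$start_nt + df$nt_length) %% df$L))
  key <- paste(df$circ_id, df$frame_phase, stop_pos)
  ord <- order(-df$nt_length, df$start_nt)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df$L <- NULL
  df
}

#' Enumerate all circular open reading frames
#'
#' Scans each circle's 3-copy (+2 nt) template for start codons at offsets
#' in `[0, L)` — junction-spanning starts are visible because the copies
#' are concatenated — and translates from each start until the first
#' in-frame stop codon or until three full laps (`3L` nt) have been
#' consumed. ORFs with no stop within three laps are flagged infinite
#' (rolling translation); their peptide holds exactly three laps. Among
#' ORFs sharing a frame phase and a stop position on the circle only the
#' longest (5'-most start) is kept, giving one maximal ORF per in-frame
#' stop.
#'
#' @param x A [CircSet-class], or a named character vector of circular
#'   sequences.
#' @param cfg A [corfConfig()] list.
#' @return A [CorfSet-class]; peptides are not yet length-filtered (see
#'   [filterCorfPeptides()]).
#' @export
#' @examples
#' corfTable(enumerateCorfs(c(circ1 = "ATGAAATAA")))
enumerateCorfs <- function(x, cfg = corfConfig()) {
  seqs <- if (methods::is(x, "CircSet")) {
    stats::setNames(as.character(circSequences(x)),
                    names(circSequences(x)))
  } else {
    if (is.null(names(x))) stopf("sequences must be named by circ_id")
    stats::setNames(as.character(x), names(x))
  }
  tab <- if (length(seqs)) .enumerateAll(seqs, cfg) else NULL
  if (is.null(tab))
    tab <- data.frame(circ_id = character(0), start_nt = integer(0),
                      nt_length = integer(0), is_infinite = logical(0),
                      peptide = character(0), frame_phase = integer(0),
                      laps = numeric(0), stringsAsFactors = FALSE)
  tab$group <- if (nrow(tab))
    lapGroup(tab$laps, tab$is_infinite) else character(0)
  tab <- tab[order(tab$circ_id, tab$start_nt), , drop = FALSE]
  idx <- if (nrow(tab))
    stats::ave(seq_len(nrow(tab)), tab$circ_id, FUN = seq_along) else
    integer(0)
  out <- S4Vectors::DataFrame(
    circ_id = tab$circ_id, corf_index = as.integer(idx),
    start_nt = as.integer(tab$start_nt),
    nt_length = as.integer(tab$nt_length), laps = tab$laps,
    is_infinite = tab$is_infinite,
    frame_phase = as.integer(tab$frame_phase),
    peptide = tab$peptide, group = tab$group)
  methods::new("CorfSet", table = out, config = cfg)
}

#' Retain plausible circRNA-derived peptides
#'
#' A putative circRNA-derived peptide must be longer than
#' `min_peptide_len` amino acids (strict: length 21 passes at the default
#' 20, length 20 does not) and start with the AUG-encoded `M`. Ordering
#' is preserved. Enumeration only ever emits `M`-initiated peptides, so at
#' default settings only the length bound removes entries.
#'
#' @param corfs A [CorfSet-class].
#' @param cfg A [corfConfig()] list (uses `min_peptide_len`).
#' @return A filtered `CorfSet`.
#' @export
filterCorfPeptides <- function(corfs, cfg = corfs@config) {
  tab <- corfTable(corfs)
  keep <- nchar(tab$peptide) > cfg$min_peptide_len &
    startsWith(tab$peptide, "M")
  methods::new("CorfSet", table = tab[keep, , drop = FALSE],
               config = corfs@config)
}

#' Lap-group assignment
#'
#' cORFs are grouped by how far they roll around the circle:
#' `"less than one lap"` (laps < 1), `"less than two laps"`
#' (1 <= laps < 2), and `"more than two laps"` for infinite cORFs, which
#' have no stop codon and roll the circle from beginning to end. A finite
#' cORF with laps >= 2 does not fit the three groups cleanly and is
#' assigned `"less than two laps"` with a warning.
#'
#' @param laps Numeric vector of lap counts (`nt_length / L`).
#' @param is_infinite Logical vector.
#' @return Character vector of group labels.
#' @export
lapGroup <- function(laps, is_infinite) {
  stopifnot(length(laps) == length(is_infinite))
  out <- ifelse(is_infinite, "more than two laps",
         ifelse(laps < 1, "less than one lap", "less than two laps"))
  odd <- !is_infinite & laps >= 2
  if (any(odd))
    warnf("%d finite cORF(s) with laps >= 2 assigned to 'less than two laps'",
          sum(odd))
  out
}

#' Write a cORF table and peptide FASTA
#'
#' @param corfs A [CorfSet-class].
#' @param tsv Output TSV path (`circ_id`, `corf_index`, `start_nt`,
#'   `nt_length`, `laps`, `group`, `peptide`).
#' @param fasta Optional peptide FASTA path (headers
#'   `circ_id|corf<index>`).
#' @return Invisibly, the TSV path.
#' @export
writeCorfTable <- function(corfs, tsv, fasta = NULL) {
  tab <- as.data.frame(corfTable(corfs))
  cols <- c("circ_id", "corf_index", "start_nt", "nt_length", "laps",
            "group", "peptide")
  utils::write.table(tab[, cols], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta)) {
    lines <- as.vector(rbind(
      sprintf(">%s|corf%d", tab$circ_id, tab$corf_index), tab$peptide))
    writeLines(lines, fasta)
  }
  invisible(tsv)
}
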