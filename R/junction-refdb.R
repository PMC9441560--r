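# Six-frame reference peptide database around back-splice junctions, and
# the reverse-complement decoy database.

#' Build the BSJ-centred nucleotide window of a circular sequence
#'
#' The diagnostic sequence of a circRNA is the back-splice junction: the
#' joint between its 3' end and 5' start. The window takes the last `k'`
#' nt of the circle followed by its first `k'` nt, where
#' `k' = min(k, L)` caps the flank at the circle length, so the junction
#' always sits at nucleotide offset `k'` (0-based) in the window.
#'
#' @param seq Circular nucleotide sequence (character scalar).
#' @param k Per-side flank width in nt (default 100, i.e. a window of
#'   about 200 bp).
#' @return List with `window`, `junction_nt_offset`, `half_width_k`.
#' @export
#' @examples
#' junctionWindow("ATGAAATAG", k = 3)
junctionWindow <- function(seq, k = 100L) {
  seq <- normalizeNt(as.character(seq))
  L <- nchar(seq)
  if (L == 0L) stopf("junctionWindow(): empty sequence")
  if (k < 1L) stopf("junctionWindow(): k must be >= 1")
  kp <- min(as.integer(k), L)
  window <- paste0(substr(seq, L - kp + 1L, L), substr(seq, 1L, kp))
  list(window = window, junction_nt_offset = kp, half_width_k = as.integer(k))
}

#' Translate a junction window in six reading frames
#'
#' Frames `+1/+2/+3` read the window at offsets 0/1/2; `-1/-2/-3` read its
#' reverse complement, with the junction offset mirrored to
#' `length(window) - junction_nt_offset`. Internal stop codons are kept as
#' `*` (downstream peptide matching cannot cross them, which keeps
#' junction coordinates stable); N-containing codons translate to `X`.
#' For a frame at offset `f` with junction nucleotide offset `j`, the
#' junction amino-acid boundary is `floor((j - f) / 3)` and the junction
#' splits a codon when `(j - f) %% 3 != 0`.
#'
#' @param win A window as returned by [junctionWindow()].
#' @return `DataFrame` with columns `frame`, `peptide`,
#'   `junction_aa_boundary`, `junction_splits_codon`.
#' @export
sixFrameTranslate <- function(win) {
  wlen <- nchar(win$window)
  if (wlen < 3L) stopf("sixFrameTranslate(): window shorter than 3 nt")
  oneStrand <- function(w, j, sign) {
    f <- 0:2
    nt <- vapply(f, function(ff) substr(w, ff + 1L, wlen), character(1))
    pep <- translateNt(nt)
    S4Vectors::DataFrame(
      frame = paste0(sign, f + 1L),
      peptide = pep,
      junction_aa_boundary = as.integer(pmax(0L, (j - f)) %/% 3L),
      junction_splits_codon = ((j - f) %% 3L) != 0L)
  }
  j <- win$junction_nt_offset
  fwd <- oneStrand(win$window, j, "+")
  rev <- oneStrand(revComp(win$window), wlen - j, "-")
  rbind(fwd, rev)
}

#' Build the six-frame junction reference peptide database
#'
#' For every circRNA with a sequence, translates its BSJ-centred window in
#' six reading frames (the junction is expected near the middle of each
#' reference peptide). Both strands are always translated; strand
#' annotation is metadata only at this stage. Per-circRNA failures (e.g.
#' missing sequence) are collected and reported, not fatal.
#'
#' @param circs A [CircSet-class] (sequences required).
#' @param k Per-side flank width in nt, default 100.
#' @return A [JunctionRefDB-class].
#' @export
buildJunctionRefDB <- function(circs, k = 100L) {
  ids <- circIds(circs)
  seqs <- circSequences(circs)
  failures <- setdiff(ids, names(seqs))
  s <- as.character(seqs)
  L <- nchar(s)
  usable <- L >= 2L  # need a window of >= 3 nt; window length is 2*min(k, L)
  failures <- c(failures, names(seqs)[!usable])
  s <- s[usable]; L <- L[usable]
  nm <- names(seqs)[usable]
  if (length(s)) {
    kp <- pmin(as.integer(k), L)
    w <- paste0(substr(s, L - kp + 1L, L), substr(s, 1L, kp))
    wlen <- 2L * kp
    # all six frames in two batched translations (fwd strand, revcomp)
    strand <- function(win, j, sign) {
      n <- length(win)
      f <- rep(0:2, each = n)
      nt <- substr(rep(win, 3L), f + 1L, rep(wlen, 3L))
      S4Vectors::DataFrame(
        circ_id = rep(nm, 3L),
        frame = paste0(sign, f + 1L),
        peptide = translateNt(nt),
        junction_aa_boundary =
          as.integer(pmax(0L, rep(j, 3L) - f) %/% 3L),
        junction_splits_codon = ((rep(j, 3L) - f) %% 3L) != 0L)
    }
    tab <- rbind(strand(w, kp, "+"), strand(revComp(w), wlen - kp, "-"))
    ord <- order(match(tab$circ_id, nm), tab$frame)
    tab <- tab[ord, , drop = FALSE]
  } else {
    tab <- S4Vectors::DataFrame(circ_id = character(0),
                                frame = character(0),
                                peptide = character(0),
                                junction_aa_boundary = integer(0),
                                junction_splits_codon = logical(0))
  }
  if (length(failures))
    message(sprintf("buildJunctionRefDB: skipped %d circRNA(s) (no or too-short sequence)",
                    length(failures)))
  methods::new("JunctionRefDB", table = tab, flank = as.integer(k),
               failures = failures)
}

#' Write the reference database as FASTA plus a sidecar index
#'
#' FASTA headers encode `circ_id|frame|junction_aa_boundary|splits_codon`
#' so the database can be fed to a search engine; the sidecar TSV repeats
#' the junction boundaries so downstream junction judgement can recover
#' them without re-parsing headers.
#'
#' @param db A [JunctionRefDB-class].
#' @param fasta Output FASTA path.
#' @param index Output TSV path (default: `fasta` + `.index.tsv`).
#' @param width Line wrap for sequences (`0` = single line).
#' @return Invisibly, a list with the two paths.
#' @export
writeReferenceDB <- function(db, fasta, index = paste0(fasta, ".index.tsv"),
                             width = 60L) {
  tab <- refTable(db)
  hdr <- sprintf(">%s|%s|%d|%d", tab$circ_id, tab$frame,
                 tab$junction_aa_boundary,
                 as.integer(tab$junction_splits_codon))
  wrap <- function(s) {
    if (width <= 0L || nchar(s) <= width) return(s)
    paste(substring(s, seq(1L, nchar(s), width),
                    pmin(nchar(s), seq(width, nchar(s) + width - 1L, width))),
          collapse = "\n")
  }
  lines <- as.vector(rbind(hdr, vapply(tab$peptide, wrap, character(1))))
  writeLines(lines, fasta)
  idx <- data.frame(circ_id = tab$circ_id, frame = tab$frame,
                    junction_aa_boundary = tab$junction_aa_boundary,
                    splits_codon = as.integer(tab$junction_splits_codon))
  utils::write.table(idx, index, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, index = index))
}

#' Read a reference-database sidecar index
#'
#' @param index Path written by [writeReferenceDB()].
#' @return A `data.frame` mirroring the index columns.
#' @export
readReferenceIndex <- function(index) {
  utils::read.table(index, sep = "\t", header = TRUE,
                    colClasses = c(frame = "character"),
                    stringsAsFactors = FALSE)
}

#' Build the reverse-complement decoy circRNA set
#'
#' Decoy circRNAs are the reverse complements of the target sequences:
#' virtual sequences that do not exist in nature but are otherwise
#' equivalent, so they can flow through the identical pipeline for
#' target-decoy FDR estimation. Decoy ids get the `DECOY_` prefix;
#' applying the operation twice restores the original sequences.
#'
#' @param circs A [CircSet-class] with sequences.
#' @return A `CircSet` of decoys.
#' @export
buildDecoyCircs <- function(circs) {
  seqs <- circSequences(circs)
  if (!length(seqs)) stopf("buildDecoyCircs(): no sequences present")
  keep <- circs[names(seqs)]
  dseq <- revComp(as.character(seqs))
  ids <- paste0("DECOY_", names(seqs))
  names(dseq) <- ids
  CircSet(ids,
          chrom = circChroms(keep),
          strand = circStrands(keep),
          seqs = dseq,
          parent_gene = keep@info$parent_gene)
}
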