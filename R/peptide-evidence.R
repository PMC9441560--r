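# Connecting MS peptides to cORFs and back-splice junctions: deduping,
# cORF substring mapping, junction-span judgement (YY values), the
# linear-protein filter, overlap merging, and ribo-seq support.

.asPeptideVector <- function(peps) {
  if (is.data.frame(peps) || methods::is(peps, "DataFrame"))
    peps <- peps$sequence
  toupper(as.character(peps))
}

#' Remove repeated MS peptides
#'
#' Keeps the first occurrence of each peptide (stable order); comparison
#' is on the uppercased sequence only, so the remaining sequences all
#' differ from each other.
#'
#' @param peps Character vector of peptides, or a `data.frame` with a
#'   `sequence` column.
#' @return Deduplicated character vector.
#' @export
dedupePeptides <- function(peps) {
  x <- .asPeptideVector(peps)
  x[!duplicated(x)]
}

#' Map MS peptides onto cORF peptides
#'
#' Reports every exact substring occurrence of each peptide in each cORF
#' peptide (every cORF, every offset); peptides that map nowhere are
#' simply absent from the result and are discarded downstream. The
#' optional I/L-equivalent mode folds isoleucine and leucine together
#' before matching, since MS cannot distinguish the isobaric pair.
#'
#' @param peps Peptides (character vector or `data.frame` with
#'   `sequence`).
#' @param corfs A [CorfSet-class].
#' @param il_equivalent Fold I and L before matching (default `FALSE`).
#' @return `data.frame` with columns `peptide`, `circ_id`, `corf_index`,
#'   `aa_start`, `aa_end` (0-based half-open on the cORF peptide).
#' @export
mapToCorf <- function(peps, corfs, il_equivalent = FALSE) {
  peps <- unique(.asPeptideVector(peps))
  tab <- corfTable(corfs)
  targets <- tab$peptide
  fold <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  ftargets <- fold(targets)
  out <- vector("list", length(peps))
  for (i in seq_along(peps)) {
    p <- fold(peps[i])
    cand <- which(grepl(p, ftargets, fixed = TRUE))
    if (!length(cand)) next
    rows <- lapply(cand, function(j) {
      s0 <- fixedMatchStarts(p, ftargets[j])
      data.frame(peptide = peps[i], circ_id = tab$circ_id[j],
                 corf_index = tab$corf_index[j], aa_start = s0,
                 aa_end = s0 + nchar(p), stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peptide = character(0), circ_id = character(0),
                      corf_index = integer(0), aa_start = integer(0),
                      aa_end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$circ_id, res$corf_index, res$aa_start, res$peptide), ,
      drop = FALSE]
}

#' Judge whether one peptide spans a back-splice junction
#'
#' Matches the peptide exactly against a reference peptide (matches never
#' cross a `*` because MS peptides contain none) and counts residues
#' wholly before and after the junction boundary `b`. When the junction
#' splits a codon, the residue at index `b` is the junction residue and
#' counts toward neither side. A span requires at least one residue on
#' each side; the YY value is `min(left, right)` ("YY4" = at least four
#' amino acids on each side of the BSJ). With several matches the one
#' maximising YY is kept.
#'
#' @param pep Peptide sequence.
#' @param ref_peptide Reference peptide (one six-frame translation).
#' @param boundary Junction amino-acid boundary `b` (residues `[0, b)`
#'   lie wholly before the BSJ).
#' @param splits_codon Does the BSJ fall inside codon `b`?
#' @return `NULL` for a no-span verdict, else a list with `match_start`,
#'   `left_count`, `right_count`, `yy`.
#' @export
#' @examples
#' ref <- paste(rep("A", 18), collapse = "")
#' junctionSpan(paste(rep("A", 9), collapse = ""), ref, 10, FALSE)$yy
junctionSpan <- function(pep, ref_peptide, boundary, splits_codon) {
  pep <- toupper(pep)
  n <- nchar(pep)
  s0 <- fixedMatchStarts(pep, ref_peptide)
  if (!length(s0)) return(NULL)
  b <- as.integer(boundary)
  if (splits_codon) {
    left <- pmax(0L, b - s0)
    right <- pmax(0L, s0 + n - (b + 1L))
  } else {
    left <- pmax(0L, b - s0)
    right <- pmax(0L, s0 + n - b)
  }
  ok <- left >= 1L & right >= 1L
  if (!any(ok)) return(NULL)
  yy <- pmin(left, right)
  best <- which(ok)[which.max(yy[ok])]
  list(match_start = s0[best], left_count = left[best],
       right_count = right[best], yy = yy[best])
}

#' Find junction-spanning peptides against a reference database
#'
#' Runs [junctionSpan()] for every peptide against every reference
#' peptide and retains hits with `yy >= min_yy`. One peptide may span the
#' BSJs of several circRNAs; all hits are reported and flagged
#' multi-mapped rather than arbitrated.
#'
#' @param peps Peptides (character or `data.frame` with `sequence`).
#' @param db A [JunctionRefDB-class].
#' @param min_yy Minimum YY value to retain (default 2; use 3 to require
#'   spans of more than two amino acids).
#' @param il_equivalent Fold I/L before matching.
#' @return `data.frame`: `peptide`, `circ_id`, `frame`, `match_start`,
#'   `left_count`, `right_count`, `yy`, `multi_mapped`.
#' @export
junctionHits <- function(peps, db, min_yy = 2L, il_equivalent = FALSE) {
  peps <- unique(.asPeptideVector(peps))
  tab <- refTable(db)
  fold <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  refs <- fold(tab$peptide)
  out <- vector("list", length(peps))
  for (i in seq_along(peps)) {
    p <- fold(peps[i])
    cand <- which(grepl(p, refs, fixed = TRUE))
    if (!length(cand)) next
    rows <- lapply(cand, function(j) {
      hit <- junctionSpan(p, refs[j], tab$junction_aa_boundary[j],
                          tab$junction_splits_codon[j])
      if (is.null(hit) || hit$yy < min_yy) return(NULL)
      data.frame(peptide = peps[i], circ_id = tab$circ_id[j],
                 frame = tab$frame[j], match_start = hit$match_start,
                 left_count = hit$left_count, right_count = hit$right_count,
                 yy = hit$yy, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peptide = character(0), circ_id = character(0),
                      frame = character(0), match_start = integer(0),
                      left_count = integer(0), right_count = integer(0),
                      yy = integer(0), multi_mapped = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  ncirc <- stats::ave(res$circ_id, res$peptide,
                      FUN = function(x) length(unique(x)))
  res$multi_mapped <- as.integer(ncirc) > 1L
  res[order(res$circ_id, res$peptide, res$frame), , drop = FALSE]
}

#' Flag junction peptides explainable by linear proteins
#'
#' Because of codon degeneracy a peptide that appears to span a BSJ may
#' in fact originate from a linear protein of the parental gene. Any hit
#' whose peptide occurs as an exact substring of any linear protein is
#' moved to the flagged set; retained hits are linear-unexplainable.
#'
#' @param hits Junction-hit `data.frame` from [junctionHits()].
#' @param proteins Character vector of protein sequences, or a
#'   `data.frame` with a `sequence` column (see [readProteinFasta()]).
#' @return List with elements `retained` and `flagged`.
#' @export
filterLinear <- function(hits, proteins) {
  prot <- if (is.data.frame(proteins)) proteins$sequence else
    as.character(proteins)
  prot <- toupper(prot)
  if (!nrow(hits) || !length(prot))
    return(list(retained = hits, flagged = hits[0, , drop = FALSE]))
  uniq <- unique(hits$peptide)
  inlinear <- vapply(uniq, function(p)
    any(grepl(p, prot, fixed = TRUE)), logical(1))
  flag <- hits$peptide %in% uniq[inlinear]
  list(retained = hits[!flag, , drop = FALSE],
       flagged = hits[flag, , drop = FALSE])
}

#' Merge overlapping mapped peptides into the longest evidenced peptide
#'
#' Within each (circRNA, cORF) group, mapped peptide intervals sharing at
#' least one residue of overlap are unioned transitively (the fixpoint of
#' repeatedly widening start/end, computed with [IRanges::reduce()]).
#' Merging requires genuine overlap — bridging disjoint peptides would
#' fabricate unobserved sequence — so every merged sequence remains a
#' literally evidenced substring of its cORF peptide. The merged interval
#' reflects the longest merged BSJ-spanning peptide when any member is a
#' junction hit.
#'
#' @param corf_hits `data.frame` from [mapToCorf()].
#' @param corfs The [CorfSet-class] the hits were mapped against.
#' @param junction_hits Optional junction-hit `data.frame`
#'   ([junctionHits()]); members found there (by peptide and circ_id) set
#'   `spans_bsj`.
#' @return `data.frame`: `circ_id`, `corf_index`, `aa_start`, `aa_end`,
#'   `sequence`, `member_count`, `spans_bsj`, sorted by circ_id,
#'   corf_index, aa_start. Idempotent: merging the output again changes
#'   nothing.
#' @export
mergeOverlapping <- function(corf_hits, corfs,
                             junction_hits = NULL) {
  empty <- data.frame(circ_id = character(0), corf_index = integer(0),
                      aa_start = integer(0), aa_end = integer(0),
                      sequence = character(0), member_count = integer(0),
                      spans_bsj = logical(0), stringsAsFactors = FALSE)
  if (!nrow(corf_hits)) return(empty)
  tab <- corfTable(corfs)
  corf_pep <- stats::setNames(tab$peptide,
                              paste(tab$circ_id, tab$corf_index))
  jkey <- if (!is.null(junction_hits) && nrow(junction_hits))
    paste(junction_hits$peptide, junction_hits$circ_id) else character(0)
  groups <- split(corf_hits,
                  paste(corf_hits$circ_id, corf_hits$corf_index))
  parts <- lapply(groups, function(g) {
    key <- paste(g$circ_id[1L], g$corf_index[1L])
    pep <- corf_pep[[key]]
    if (is.null(pep))
      stopf("mergeOverlapping(): no cORF peptide for %s", key)
    # I/L folded so hits made in il_equivalent mode still verify
    bad <- chartr("I", "L", substring(pep, g$aa_start + 1L, g$aa_end)) !=
      chartr("I", "L", g$peptide)
    if (any(bad))
      stopf("mergeOverlapping(): member interval does not match its cORF substring (%s)",
            key)
    ir <- IRanges::IRanges(start = g$aa_start + 1L, end = g$aa_end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(
      circ_id = g$circ_id[1L], corf_index = g$corf_index[1L],
      aa_start = IRanges::start(red) - 1L, aa_end = IRanges::end(red),
      sequence = substring(pep, IRanges::start(red), IRanges::end(red)),
      member_count = lengths(revmap),
      spans_bsj = vapply(revmap, function(m)
        any(paste(g$peptide[m], g$circ_id[m]) %in% jkey), logical(1)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res[order(res$circ_id, res$corf_index, res$aa_start), , drop = FALSE]
}

#' Ribosome-profiling support for a circRNA
#'
#' A circRNA is ribo-supported when any supplied ribo-seq-derived
#' nucleotide sequence (or its reverse complement) matches the doubled
#' circle sequence in a position covering the back-splice junction with
#' at least `min_flank` nt on each side.
#'
#' @param seq Circular nucleotide sequence.
#' @param ribo_seqs Character vector of ribo-seq nucleotide sequences.
#' @param min_flank Minimum nt on each side of the BSJ (default 6).
#' @return `TRUE` or `FALSE`.
#' @export
riboEvidence <- function(seq, ribo_seqs, min_flank = 6L) {
  seq <- normalizeNt(as.character(seq))
  L <- nchar(seq)
  if (L == 0L) stopf("riboEvidence(): circRNA has no sequence")
  if (!length(ribo_seqs)) return(FALSE)
  ribo <- normalizeNt(as.character(ribo_seqs))
  doubled <- strrep(seq, 2L)
  for (r in unique(c(ribo, revComp(ribo)))) {
    s0 <- fixedMatchStarts(r, doubled)
    if (length(s0) &&
        any(s0 <= L - min_flank & s0 + nchar(r) >= L + min_flank))
      return(TRUE)
  }
  FALSE
}
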