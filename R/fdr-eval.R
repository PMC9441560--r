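# Target-decoy self-evaluation of the junction pipeline.

# circ_ids called translatable: >= 1 junction-spanning hit whose peptide
# also maps onto a retained cORF of the same circRNA. The cORF
# requirement is what makes the reverse-complement decoy informative: a
# decoy's junction window is the reverse complement of the target's, so
# six-frame window matching alone is mirror-symmetric between the two
# databases; AUG-initiated cORFs are enumerated on the given (decoy)
# strand only and are not.
.junctionCalls <- function(circs, peptides, k, min_yy, il_equivalent,
                           cfg = corfConfig()) {
  db <- buildJunctionRefDB(circs, k = k)
  hits <- junctionHits(peptides, db, min_yy = min_yy,
                       il_equivalent = il_equivalent)
  if (!nrow(hits)) return(character(0))
  corfs <- filterCorfPeptides(enumerateCorfs(circs, cfg), cfg)
  ch <- mapToCorf(unique(hits$peptide), corfs,
                  il_equivalent = il_equivalent)
  ok <- paste(hits$peptide, hits$circ_id) %in%
    paste(ch$peptide, ch$circ_id)
  unique(hits$circ_id[ok])
}

#' Target-decoy FDR of translatable-circRNA prediction
#'
#' Runs the identical junction pipeline twice — once against the real
#' circRNA sequences and once against their reverse complements
#' ([buildDecoyCircs()]), virtual sequences that do not exist in nature —
#' and counts circRNAs with at least one retained junction-spanning hit
#' in each run. `FDR = decoy_calls / target_calls` (the formula is a
#' documented choice; the decoy count may alternatively be related to the
#' total). Decoys never appear in user-facing reports; they exist only
#' for this estimate.
#'
#' @param circs A [CircSet-class] with sequences.
#' @param peptides MS peptides (character or `data.frame` with
#'   `sequence`); deduplicated before searching. One peptide list is
#'   searched against both databases.
#' @param k Junction flank width in nt (default 100).
#' @param min_yy Junction-span threshold; the benchmark condition
#'   "span BSJs by more than two amino acids" is `min_yy = 3`.
#' @param il_equivalent Fold I/L before matching.
#' @return One-row `data.frame`: `target_calls`, `decoy_calls`, `fdr`
#'   (`NA` and `undefined = TRUE` when there are no target calls),
#'   `yy_condition`, `undefined`.
#' @export
runTargetDecoy <- function(circs, peptides, k = 100L, min_yy = 3L,
                           il_equivalent = FALSE) {
  if (!length(peptides)) stopf("runTargetDecoy(): no peptides supplied")
  peptides <- dedupePeptides(peptides)
  target <- .junctionCalls(circs, peptides, k, min_yy, il_equivalent)
  decoys <- buildDecoyCircs(circs)
  decoy <- .junctionCalls(decoys, peptides, k, min_yy, il_equivalent)
  tc <- length(target)
  dc <- length(decoy)
  data.frame(target_calls = tc, decoy_calls = dc,
             fdr = if (tc > 0L) dc / tc else NA_real_,
             yy_condition = as.integer(min_yy),
             undefined = tc == 0L)
}

#' Write a target-decoy evaluation row
#'
#' @param res [runTargetDecoy()] result.
#' @param path Output TSV path.
#' @param seed Optional seed to record alongside the counts.
#' @return `path`, invisibly.
#' @export
writeFdrResult <- function(res, path, seed = NA_integer_) {
  res$seed <- seed
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
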