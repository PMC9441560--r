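---
title: "Predicting translatable circRNAs from MS peptide evidence"
author: "circPepMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting translatable circRNAs from MS peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(circPepMS))
```

## The problem and the model

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice
donor joins an upstream acceptor, closing the transcript into a covalent
circle. The joint — the back-splice junction (BSJ) — is the only sequence
feature that distinguishes a circRNA from its linear host transcript. A
small fraction of circRNAs are translated, sometimes driven by internal
ribosome entry sites (IRES), and a stop-codon-free reading frame on a
circle whose length is divisible by three supports *rolling* translation
of repeated peptide units (an infinite circular ORF, icORF).

Tandem mass spectrometry gives direct protein-level evidence: a peptide
whose residues demonstrably continue *across* the BSJ cannot be explained
by the linear transcript. circPepMS starts downstream of the spectral
search engine (pFind/MaxQuant/Mascot-style exports or plain peptide
lists) and asks, for each circRNA, whether the identified peptides
constitute junction-spanning, ORF-consistent evidence of translation.

The pipeline, stage by stage:

1. **Sequence acquisition** (`readCircInfo()` + three models): sequences
   given directly as FASTA (model 1), extracted from a genome by exon
   blocks (model 2), or sliced from mature transcripts (model 3, the
   recommended route when splice annotation is reliable). Internally all
   coordinates are 0-based half-open; minus-strand extraction
   reverse-complements the concatenated blocks so every stored sequence
   reads 5'→3'.
2. **Junction reference database** (`buildJunctionRefDB()`): for each
   circle, a window of `k` nt on each side of the BSJ (default
   `k = 100`, i.e. about 200 bp) is translated in all six reading
   frames, with the junction boundary carried along in amino-acid
   coordinates. This is the database a search engine would be run
   against; here it also serves the junction judgement directly.
3. **Circular ORF enumeration** (`enumerateCorfs()`): the circle is
   scanned as three concatenated copies plus two extra nucleotides, so
   AUG codons lying across the BSJ (`A^TG`, `AT^G`) are never missed.
   Translation runs from each start until the first in-frame stop or
   three full laps; stop-free frames yield infinite cORFs holding
   exactly three laps of peptide. Peptides longer than 20 amino acids
   that begin with AUG-encoded methionine are retained.
4. **Junction judgement** (`junctionHits()`): each peptide is matched
   exactly against the reference peptides; a hit must keep at least one
   residue strictly on each side of the junction, and the YY value is
   the smaller of the two side counts (YY4 = at least four residues on
   each side).
5. **Evidence consolidation**: duplicate peptides are removed
   (`dedupePeptides()`), junction peptides explainable by linear
   proteins are flagged (`filterLinear()`), peptides are mapped onto
   cORF peptides at every offset (`mapToCorf()`), and overlapping mapped
   intervals are transitively unioned into the longest literally
   evidenced peptide (`mergeOverlapping()`).
6. **Scoring and classification**: cORFs get a 0/1 coding-potential
   score from a Gaussian naive Bayes model (`trainCodingModel()`), IRES
   scores from any external predictor are thresholded at 0.5
   (`labelIres()`), and each predicted translatable circRNA is assigned
   one of six classes from its lap group crossed with IRES status
   (`classifyCirc()`).
7. **Self-evaluation** (`runTargetDecoy()`): the identical pipeline runs
   against reverse-complement decoy circles; the decoy/target call
   ratio estimates the false discovery rate.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `k` (junction flank) | nt | 100 | about 200 bp around the BSJ; capped at the circle length for short circles |
| `min_peptide_len` | aa | 20 (strict) | peptides of more than 20 aa with an AUG start count as plausible products |
| `repeats` / `tail_nt` | copies / nt | 3 / 2 | template covers up to three laps and junction-straddling starts |
| `min_yy` | aa | 2 (reporting), 3 (FDR benchmark) | spans of more than two residues per side are the benchmark condition |
| `ires_threshold` | score | 0.5, strict `>` | scores of exactly 0.5 label Non-IRES |
| `min_flank` (ribo) | nt | 6 | a ribo-seq read must cover the BSJ with this much on each side |
| `train_fraction` | — | 0.8 | 8:2 stratified train/test split for the coding model |
| `il_equivalent` | — | off | MS cannot distinguish Ile/Leu; folding them is opt-in |

## Design choices where the design was open

* **Window capping.** For circles shorter than the flank, the window
  uses `k' = min(k, L)` per side, so a short circle contributes its full
  doubled sequence and the junction stays at offset `k'`. An alternative
  would centre a fixed 200-nt window by wrapping further; capping keeps
  every window position attributable to at most two passes of the
  circle.
* **Junction-split residues count toward neither side.** When the BSJ
  falls inside a codon, the residue encoded by that codon is evidence
  for both sides and for neither exclusively; neutral counting makes YY
  conservative.
* **One maximal ORF per (frame phase, stop).** "All possible longest
  cORFs" is implemented as: among ORFs sharing a reading-frame phase and
  an in-frame stop position on the circle, keep the one with the 5'-most
  start. Every reported ORF is therefore maximal for its stop.
* **Finite ORFs of two to three laps** do not fit the three lap groups
  cleanly (the groups are named "less than one lap", "less than two
  laps", and "more than two laps", with the last defined by
  stoplessness). They are assigned to "less than two laps" with a
  warning rather than silently or fatally.
* **Merging requires genuine overlap.** Taking the min start / max end
  over *disjoint* peptides would fabricate sequence nobody observed;
  intervals are unioned only when they share at least one residue, so
  every merged peptide remains an exact substring of its cORF peptide.
  The union is computed with `IRanges::reduce()` and is idempotent.
* **Translatable call = junction hit + cORF support.** A circRNA is
  called translatable when a junction-spanning peptide also occurs in a
  retained cORF peptide of the same circle. The cORF requirement is
  essential for the decoy estimate: a decoy's junction window is exactly
  the reverse complement of the target's, so six-frame window matching
  alone is mirror-symmetric between the two databases and would be
  uninformative; AUG-initiated ORFs enumerated on the decoy strand break
  the symmetry.
* **FDR formula.** `decoy_calls / target_calls`, not
  `decoy / (target + decoy)`; with decoy counts near zero the two agree
  closely, and the simple ratio matches how the counts are usually
  quoted.
* **IRES scoring is pluggable.** Trained IRES predictors are external
  tools with their own licensing and models; circPepMS consumes any
  two-column score table (`readIresScores()`) and only owns the strict
  0.5 labelling rule. Non-IRES circRNAs are labelled, never dropped —
  cap-independent translation can proceed through other mechanisms
  (e.g. m6A-mediated initiation).
* **Coding-model features.** The feature schema (20 amino-acid
  composition fractions, log length, 400 dipeptide frequencies;
  `"comp_dipep_v1"`) is a deliberately simple, versioned choice.
  The Gaussian naive Bayes is fitted in-package with variance smoothing
  (`var + 1e-9 · max(var)`), since many dipeptide features have zero
  variance within a class and unsmoothed Gaussian likelihoods would
  degenerate; negatives default to length-matched uniform-random
  peptides.
* **Class numbering.** Only class I is pinned down externally
  (sub-one-lap cORF, IRES-driven); the remaining numbering is the fixed
  convention (group 1–3) × (IRES, Non-IRES) → I…VI.

## Numerical and degenerate-input conventions

* `U` is accepted and mapped to `T`; `N` is allowed in genomes and
  translates to `X`, which never equals a stop and never matches a
  peptide residue.
* Internal stops are kept as `*` in reference peptides; matches cannot
  cross them (peptides contain no `*`), keeping junction coordinates
  stable without splitting records.
* Exact substring matching reports *overlapping* occurrences; with
  several matches of one peptide on one reference peptide, the match
  maximising YY is kept.
* Empty sequences, out-of-bounds exon blocks, duplicate identifiers and
  malformed coordinates fail early with the offending record named;
  per-circle failures in database construction are collected and
  reported, not fatal.
* All randomness (simulation, training splits) is seeded; every output
  file is byte-identical across reruns of the same inputs.

## What the synthetic generator emulates — and what it does not

`genCircSet()`/`genPeptides()` stand in for public circRNA catalogues
and search-engine output: uniform-random circles of 120–400 nt (short
exonic circRNA range), a planted `AUG…stop` cORF crossing the BSJ in
60% of circles, a 5% share of planted icORFs, junction peptides sampled
from half of the planted circles with at least three residues on each
side of the BSJ, and uniform-random noise peptides of tryptic length
(7–25 residues). Noise draws are screened exhaustively against all
enumerated cORF peptides and relabelled on collision.

The generator does **not** emulate real nucleotide composition, splice
motifs, homology between circles and their host genes, peptide
detectability (length/charge/hydrophobicity biases of MS), or
search-engine score distributions. Passing the benchmark therefore shows
that the pipeline's logic is correct and self-consistent under planted
truth — not that its error rates transfer to any particular organism or
instrument.

Benchmark problem sizes used by the tests and the acceptance script:
500 circRNAs (~150 true junction peptides + 300 noise) for the
target-decoy FDR; 200 random circles of ≤ 36 nt for exhaustive oracle
comparison of the ORF enumerator; 1,000 peptides (500/500) for the
coding-model split and accuracy checks; 120 circRNAs for planted-
evidence recall and byte-determinism.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 7, n_circ = 50, n_noise_peptides = 40)
sim <- genCircSet(cfg)
pep <- genPeptides(sim$circs, sim$truth, cfg)
out <- runPipeline(sim$circs, pep$peptides)
head(out$reports)
runTargetDecoy(sim$circs, pep$peptides, min_yy = 3)
```

## Known limitations

* Only AUG starts are considered; near-cognate initiation (CUG/GUG) is
  out of scope, as are cORFs rolling more than three laps.
* The coding-potential model reproduces a training *protocol*, not a
  published fitted model; its 0/1 scores are only as meaningful as the
  positive/negative sets supplied.
* Spectrum-level evidence (PSM scores, retention times) is not
  re-examined; the pipeline trusts the upstream search engine's peptide
  calls, and its FDR concerns circRNA calls, not PSMs.
* One peptide spanning the BSJs of several circRNAs is reported for all
  of them (flagged multi-mapped) rather than arbitrated.
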