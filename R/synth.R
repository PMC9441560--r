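# Seeded synthetic data: circRNAs with planted cORFs crossing the BSJ,
# junction-spanning peptides sampled from them, and uniform noise
# peptides. Stands in for public circRNA catalogues and MS search output
# so every pipeline stage and the FDR benchmark run self-contained.

.NONSTOP_CODONS <- {
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Typical amino-acid background frequencies
#'
#' Swiss-Prot-like residue frequencies, used to draw protein-like peptides
#' (e.g. positives for coding-model simulations) as opposed to uniform
#' noise.
#'
#' @return Named numeric vector over the 20 standard residues (sums to 1).
#' @export
proteinAAFrequencies <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f / sum(f)
}

#' Synthetic-data configuration
#'
#' Defaults describe a small realistic benchmark: circles of 120-400 nt
#' (the range of short exonic circRNAs), a planted AUG...stop cORF
#' crossing the BSJ in 60% of circles, a small fraction of stopless
#' infinite cORFs, junction peptides sampled from half of the planted
#' circles, and tryptic-range noise peptides (7-25 residues) drawn
#' uniformly.
#'
#' @param seed Integer RNG seed (all generation is deterministic per
#'   seed).
#' @param n_circ Number of circRNAs.
#' @param length_range Circle length range in nt.
#' @param frac_with_corf Fraction of circles receiving a planted cORF.
#' @param frac_icorf Fraction of planted cORFs made infinite (circle
#'   length forced to a multiple of 3, no stop in the planted frame).
#' @param frac_true_junction_peptides True junction peptides sampled per
#'   planted circle (fraction of planted circles).
#' @param n_noise_peptides Number of uniform-random noise peptides.
#' @param peptide_length_range Noise peptide length range in residues.
#' @return Named list of class `synth_config`.
#' @export
synthConfig <- function(seed = 1L, n_circ = 100L,
                        length_range = c(120L, 400L),
                        frac_with_corf = 0.6, frac_icorf = 0.05,
                        frac_true_junction_peptides = 0.5,
                        n_noise_peptides = 100L,
                        peptide_length_range = c(7L, 25L)) {
  stopifnot(frac_with_corf >= 0, frac_with_corf <= 1,
            frac_icorf >= 0, frac_icorf <= 1,
            frac_true_junction_peptides >= 0,
            frac_true_junction_peptides <= 1,
            length_range[1L] <= length_range[2L], length_range[1L] >= 30L,
            peptide_length_range[1L] <= peptide_length_range[2L])
  structure(list(seed = as.integer(seed), n_circ = as.integer(n_circ),
                 length_range = as.integer(length_range),
                 frac_with_corf = frac_with_corf,
                 frac_icorf = frac_icorf,
                 frac_true_junction_peptides = frac_true_junction_peptides,
                 n_noise_peptides = as.integer(n_noise_peptides),
                 peptide_length_range = as.integer(peptide_length_range)),
            class = "synth_config")
}

# overwrite circle positions ((s + 0:(n-1)) %% L) + 1 with chars
.writeWrapped <- function(chars_circle, s, chars_orf) {
  L <- length(chars_circle)
  pos <- ((s + seq_along(chars_orf) - 1L) %% L) + 1L
  chars_circle[pos] <- chars_orf
  chars_circle
}

#' Generate a synthetic circRNA set with planted cORFs
#'
#' Circles are uniform-random nucleotide sequences; a configured fraction
#' receive a planted `ATG...stop` cORF that crosses the back-splice
#' junction (the planted start sits `b` residues' worth of nucleotides
#' before the circle end, so translation runs through the BSJ). Planted
#' infinite cORFs fill a whole reading frame of a length-divisible-by-3
#' circle with stop-free codons. The ground-truth table records planted
#' coordinates, the junction boundary within the cORF peptide and the
#' codon-split offset.
#'
#' @param cfg A [synthConfig()] list.
#' @return List: `circs` (a [CircSet-class] with sequences) and `truth`
#'   (`data.frame`).
#' @export
genCircSet <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_circ
  ids <- sprintf("scirc_%04d", seq_len(n))
  seqs <- character(n)
  truth <- data.frame(
    circ_id = ids, L = NA_integer_, planted = FALSE,
    start_nt = NA_integer_, nt_length = NA_integer_,
    aa_boundary = NA_integer_, split_offset = NA_integer_,
    is_icorf = FALSE, peptide = NA_character_, stringsAsFactors = FALSE)
  orf_nts <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    L <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]), 1L)
    plant <- stats::runif(1) < cfg$frac_with_corf
    icorf <- plant && stats::runif(1) < cfg$frac_icorf
    if (icorf) {
      L <- 3L * (L %/% 3L)
      m <- L %/% 3L
      b <- sample(5:(m - 5L), 1L)
      s <- L - 3L * b
      codons <- sample(.NONSTOP_CODONS, m, replace = TRUE)
      codons[(s %/% 3L) + 1L] <- "ATG"
      seq <- paste(codons, collapse = "")
      orf_nt <- substr(strrep(seq, 4L), s + 1L, s + 3L * L)
      truth$planted[i] <- TRUE
      truth$is_icorf[i] <- TRUE
      truth$start_nt[i] <- s
      truth$nt_length[i] <- 3L * L
      truth$aa_boundary[i] <- b
      truth$split_offset[i] <- 0L
      orf_nts[i] <- orf_nt
    } else {
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (plant) {
        naa_max <- min(45L, (L - 6L) %/% 3L)
        naa <- sample(21:naa_max, 1L)
        d <- sample(0:2, 1L)
        b <- sample(5:min(naa - 5L, (L - d) %/% 3L - 1L), 1L)
        s <- L - 3L * b - d
        orf_codons <- c("ATG",
                        sample(.NONSTOP_CODONS, naa - 1L, replace = TRUE),
                        sample(.STOP_CODONS, 1L))
        orf <- strsplit(paste(orf_codons, collapse = ""), "")[[1L]]
        chars <- .writeWrapped(chars, s, orf)
        truth$planted[i] <- TRUE
        truth$start_nt[i] <- s
        truth$nt_length[i] <- 3L * naa
        truth$aa_boundary[i] <- b
        truth$split_offset[i] <- d
        orf_nts[i] <- substr(strrep(paste(chars, collapse = ""), 2L),
                             s + 1L, s + 3L * naa)
      }
      seq <- paste(chars, collapse = "")
    }
    seqs[i] <- seq
    truth$L[i] <- nchar(seq)
  }
  truth$peptide[truth$planted] <- translateNt(orf_nts[truth$planted])
  names(seqs) <- ids
  # synthetic genomic placement: one block per circle on one chromosome
  offs <- cumsum(c(0L, utils::head(nchar(seqs), -1L) + 50L))
  blocks <- lapply(seq_len(n), function(i)
    cbind(offs[i], offs[i] + nchar(seqs[i])))
  circs <- CircSet(ids, chrom = "chrS", strand = "+", exons = blocks,
                   seqs = seqs,
                   parent_gene = sprintf("GENE_%04d", seq_len(n)))
  list(circs = circs, truth = truth)
}

#' Sample MS peptide lists with planted junction evidence
#'
#' True peptides are substrings of planted cORF peptides positioned to
#' cross the BSJ with at least three residues on each side (the planted
#' YY value is recorded); noise peptides are uniform draws over the
#' 20-residue alphabet. Each noise peptide is checked exhaustively
#' against all enumerated cORF peptides: accidental matches (negligible
#' at lengths >= 9) are relabelled `noise_corf_collision` so they never
#' count against recall or FDR bookkeeping.
#'
#' @param circs,truth Output of [genCircSet()].
#' @param cfg The same [synthConfig()].
#' @param corfs Optional pre-enumerated [CorfSet-class] for the collision
#'   check (enumerated from `circs` when `NULL`).
#' @return List: `peptides` (`data.frame` with `sequence`, `label`,
#'   `circ_id`, `planted_yy`) and `n_true`, `n_noise`.
#' @export
genPeptides <- function(circs, truth, cfg, corfs = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  planted <- truth[truth$planted, , drop = FALSE]
  n_true <- round(cfg$frac_true_junction_peptides * nrow(planted))
  pick <- if (n_true <= nrow(planted))
    sample(seq_len(nrow(planted)), n_true) else
    sample(seq_len(nrow(planted)), n_true, replace = TRUE)
  rows <- lapply(pick, function(r) {
    pep <- planted$peptide[r]
    naa <- nchar(pep)
    b <- planted$aa_boundary[r]
    d <- planted$split_offset[r]
    left <- sample(3:min(5L, b), 1L)
    right <- sample(3:min(5L, naa - b - (d > 0L)), 1L)
    s <- if (d == 0L) b - left else b - left          # 0-based start residue
    e <- if (d == 0L) b + right else b + 1L + right   # half-open end
    data.frame(sequence = substr(pep, s + 1L, e),
               label = "junction", circ_id = planted$circ_id[r],
               planted_yy = min(left, right), stringsAsFactors = FALSE)
  })
  true_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), label = character(0),
               circ_id = character(0), planted_yy = integer(0))
  noise <- randomPeptides(cfg$n_noise_peptides,
                          length_range = cfg$peptide_length_range)
  noise_df <- data.frame(sequence = noise,
                         label = rep("noise", length(noise)),
                         circ_id = rep(NA_character_, length(noise)),
                         planted_yy = rep(NA_integer_, length(noise)),
                         stringsAsFactors = FALSE)
  if (nrow(noise_df)) {
    if (is.null(corfs)) corfs <- enumerateCorfs(circs)
    corf_peps <- corfTable(corfs)$peptide
    collide <- vapply(noise_df$sequence, function(p)
      any(grepl(p, corf_peps, fixed = TRUE)), logical(1))
    noise_df$label[collide] <- "noise_corf_collision"
  }
  peptides <- rbind(true_df, noise_df)
  rownames(peptides) <- NULL
  list(peptides = peptides, n_true = nrow(true_df),
       n_noise = nrow(noise_df))
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits everything the pipeline's file-based interfaces consume: circRNA
#' FASTA and info TSV, a plain peptide list, a linear-protein FASTA
#' (random protein-like sequences; synthetic, not a real proteome), an
#' IRES score table with uniform scores, and the two ground-truth tables.
#'
#' @param cfg A [synthConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and the
#'   in-memory objects (`circs`, `truth`, `peptides`).
#' @export
writeSynthFixtures <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- genCircSet(cfg)
  pep <- genPeptides(sim$circs, sim$truth, cfg)
  p <- list(
    circ_fasta = file.path(dir, "circ.fa"),
    circ_info = file.path(dir, "circ_info.tsv"),
    peptides = file.path(dir, "peptides.txt"),
    proteins = file.path(dir, "proteins.fa"),
    ires_scores = file.path(dir, "ires_scores.tsv"),
    truth_circ = file.path(dir, "truth_circ.tsv"),
    truth_pep = file.path(dir, "truth_peptides.tsv"))
  seqs <- circSequences(sim$circs)
  writeLines(as.vector(rbind(paste0(">", names(seqs)),
                             as.character(seqs))), p$circ_fasta)
  writeCircInfo(sim$circs, p$circ_info)
  writeLines(pep$peptides$sequence, p$peptides)
  set.seed(cfg$seed + 2L)
  prots <- randomPeptides(50L, c(120L, 400L),
                          freqs = proteinAAFrequencies())
  writeLines(as.vector(rbind(sprintf(">sprot_%02d gene=SGENE_%02d",
                                     seq_along(prots), seq_along(prots)),
                             prots)), p$proteins)
  ires <- round(stats::runif(length(sim$circs)), 4)
  utils::write.table(
    data.frame(circ_id = circIds(sim$circs), score = ires),
    p$ires_scores, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(sim$truth, p$truth_circ, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pep$peptides, p$truth_pep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = p, circs = sim$circs, truth = sim$truth,
                 peptides = pep$peptides))
}
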