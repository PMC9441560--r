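# Coding-potential assessment (Gaussian naive Bayes on peptide features),
# IRES labelling at the 0.5 threshold, and the six-class scheme.

.dipeptideNames <- function() {
  as.vector(outer(.AA20, .AA20, function(a, b) paste0("dp_", a, b)))
}

#' Featurize a peptide for coding-potential classification
#'
#' Deterministic 421-dimensional vector: 20 amino-acid composition
#' fractions, log peptide length, and 400 dipeptide frequencies
#' (schema `"comp_dipep_v1"`, versioned so alternatives can be swapped).
#'
#' @param pep Peptide over the 20 standard residues (non-empty).
#' @return Named numeric vector.
#' @export
#' @examples
#' featurizePeptide("AAAA")[["comp_A"]]   # 1
featurizePeptide <- function(pep) {
  pep <- toupper(pep)
  if (!isValidAa(pep))
    stopf("featurizePeptide(): empty or non-standard peptide")
  chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  comp <- tabulate(match(chars, .AA20), nbins = 20L) / n
  names(comp) <- paste0("comp_", .AA20)
  dp <- stats::setNames(numeric(400L), .dipeptideNames())
  if (n >= 2L) {
    pairs <- paste0("dp_", chars[-n], chars[-1L])
    tt <- table(pairs)
    dp[names(tt)] <- as.numeric(tt) / (n - 1L)
  }
  c(comp, loglen = log(n), dp)
}

# matrix of features, one row per peptide
featurizePeptides <- function(peps) {
  t(vapply(peps, featurizePeptide, numeric(421L), USE.NAMES = FALSE))
}

#' Assemble a coding-potential training dataset
#'
#' Positives are real translated peptides (mRNA proteins plus published
#' ncRNA-encoded peptides); negatives are randomly generated peptides.
#' The pooled set is split stratified at `train_fraction` (default 8:2).
#'
#' @param positives,negatives Character vectors of peptides (>= 10 each,
#'   disjoint as sets).
#' @param train_fraction Fraction used for training, in (0, 1).
#' @param seed Integer seed for the stratified shuffle.
#' @return List of class `coding_dataset`.
#' @export
makeCodingDataset <- function(positives, negatives, train_fraction = 0.8,
                              seed = 1L) {
  positives <- unique(toupper(positives))
  negatives <- unique(toupper(negatives))
  if (length(positives) < 10L || length(negatives) < 10L)
    stopf("each class needs at least 10 examples")
  if (length(intersect(positives, negatives)))
    stopf("positives and negatives must be disjoint")
  if (!(train_fraction > 0 && train_fraction < 1))
    stopf("train_fraction must be in (0, 1)")
  structure(list(positives = positives, negatives = negatives,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "coding_dataset")
}

#' Generate random peptides
#'
#' Uniform draws over the 20 standard residues, the stand-in negative
#' class for coding-potential training ("generated randomly"). With
#' `freqs` given (e.g. natural amino-acid frequencies), draws follow that
#' distribution instead — useful for building protein-like positives in
#' simulations.
#'
#' @param n Number of peptides.
#' @param length_range Length range in residues (inclusive).
#' @param freqs Optional named residue probability vector.
#' @return Character vector of peptides.
#' @export
randomPeptides <- function(n, length_range = c(30L, 80L), freqs = NULL) {
  prob <- if (is.null(freqs)) rep(1 / 20, 20L) else {
    stopifnot(all(.AA20 %in% names(freqs)))
    as.numeric(freqs[.AA20]) / sum(as.numeric(freqs[.AA20]))
  }
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(.AA20, l, replace = TRUE, prob = prob), collapse = ""),
    character(1))
}

#' Train the Gaussian naive Bayes coding-potential model
#'
#' Stratified shuffled split at the dataset's `train_fraction` under its
#' seed (n = 1000 at the default 8:2 gives 800 training and 200 test
#' peptides), Gaussian class-conditional likelihoods per feature with
#' sklearn-style variance smoothing (`var + 1e-9 * max(var)`), and
#' accuracy measured on the held-out split. Deterministic given
#' (dataset, seed).
#'
#' @param ds A [makeCodingDataset()] result.
#' @return A [CodingModel-class].
#' @export
trainCodingModel <- function(ds) {
  stopifnot(inherits(ds, "coding_dataset"))
  set.seed(ds$seed)
  splitClass <- function(x) {
    idx <- sample.int(length(x))
    ntr <- floor(ds$train_fraction * length(x))
    list(train = x[idx[seq_len(ntr)]], test = x[idx[-seq_len(ntr)]])
  }
  sp <- splitClass(ds$positives)
  sn <- splitClass(ds$negatives)
  train_x <- rbind(featurizePeptides(sn$train), featurizePeptides(sp$train))
  train_y <- c(rep("noncoding", length(sn$train)),
               rep("coding", length(sp$train)))
  lev <- c("noncoding", "coding")
  means <- t(vapply(lev, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]), numeric(ncol(train_x))))
  vars <- t(vapply(lev, function(cl)
    apply(train_x[train_y == cl, , drop = FALSE], 2L, stats::var),
    numeric(ncol(train_x))))
  eps <- 1e-9 * max(vars)
  priors <- stats::setNames(as.numeric(table(factor(train_y, lev)) /
                                         length(train_y)), lev)
  model <- methods::new("CodingModel", schema = "comp_dipep_v1",
                        class_levels = lev, priors = priors,
                        means = means, vars = vars + eps, eps = eps,
                        n_train = length(train_y),
                        n_test = length(sp$test) + length(sn$test),
                        test_accuracy = NA_real_, seed = ds$seed)
  test_x <- rbind(featurizePeptides(sn$test), featurizePeptides(sp$test))
  test_y <- c(rep(0L, length(sn$test)), rep(1L, length(sp$test)))
  model@test_accuracy <- mean(.predictNB(model, test_x) == test_y)
  model
}

# 0/1 predictions (1 = coding-like) from log-posteriors
.predictNB <- function(model, x) {
  ll <- vapply(seq_along(model@class_levels), function(k) {
    mu <- model@means[k, ]
    v <- model@vars[k, ]
    rowSums(sweep(-0.5 * sweep(x, 2L, mu)^2, 2L, v, "/") +
              matrix(-0.5 * log(2 * pi * v), nrow(x), ncol(x),
                     byrow = TRUE)) + log(model@priors[k])
  }, numeric(nrow(x)))
  as.integer(ll[, 2L] > ll[, 1L])
}

#' Predict coding potential of peptides
#'
#' @param model A [CodingModel-class].
#' @param peps Character vector of peptides.
#' @return Integer vector of 0/1 scores (1 = predicted coding-like).
#' @export
predictCoding <- function(model, peps) {
  if (!length(peps)) return(integer(0))
  .predictNB(model, featurizePeptides(toupper(peps)))
}

#' Score cORFs 0/1 for coding potential
#'
#' @param corfs A [CorfSet-class].
#' @param model A [CodingModel-class].
#' @return `data.frame` with `circ_id`, `corf_index`, `coding_score`.
#' @export
scoreCorfs <- function(corfs, model) {
  tab <- corfTable(corfs)
  if (!nrow(tab))
    return(data.frame(circ_id = character(0), corf_index = integer(0),
                      coding_score = integer(0)))
  data.frame(circ_id = tab$circ_id, corf_index = tab$corf_index,
             coding_score = predictCoding(model, tab$peptide),
             stringsAsFactors = FALSE)
}

#' Label IRES status from prediction scores
#'
#' Scores strictly greater than the threshold (default 0.5) are labelled
#' `"IRES"`, all others `"Non-IRES"` (a score of exactly 0.5 is
#' Non-IRES). Non-IRES circRNAs are never dropped — they may still be
#' translated through other cap-independent mechanisms — only labelled.
#'
#' @param scores Named numeric vector (circ_id -> score in \[0, 1\]).
#' @param threshold IRES threshold in (0, 1), default 0.5.
#' @return Named character vector of `"IRES"`/`"Non-IRES"` labels.
#' @export
labelIres <- function(scores, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1))
    stopf("threshold must be in (0, 1)")
  s <- as.numeric(scores)
  if (any(is.na(s) | s < 0 | s > 1))
    stopf("IRES scores must lie in [0, 1]")
  stats::setNames(ifelse(s > threshold, "IRES", "Non-IRES"), names(scores))
}

#' Read a precomputed IRES score table
#'
#' Pluggable scorer interface: any external IRES predictor's output can
#' be supplied as a two-column TSV (circ_id, score).
#'
#' @param path TSV path (no header, or header `circ_id`/`score`).
#' @return Named numeric vector.
#' @export
readIresScores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.character(df[[2L]]) && df[[2L]][1L] %in% c("score", "ires_score")) {
    df <- df[-1L, , drop = FALSE]
  }
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Classify a translatable circRNA into one of six classes
#'
#' Two criteria define the classes: how far the cORF rolls the circle
#' (three lap groups) and IRES presence. Class I, for example, is a cORF
#' shorter than the full circle (laps < 1) whose translation may be
#' IRES-driven. The numbering of the remaining classes follows the fixed
#' convention (group, IRES) -> I, (group1, Non-IRES) -> II,
#' (group2, IRES) -> III, (group2, Non-IRES) -> IV, (group3, IRES) -> V,
#' (group3, Non-IRES) -> VI.
#'
#' @param group Lap-group label(s) from [lapGroup()].
#' @param ires `"IRES"`/`"Non-IRES"` label(s).
#' @return Character vector of class labels `"I"` .. `"VI"`.
#' @export
#' @examples
#' classifyCirc("less than one lap", "IRES")   # "I"
classifyCirc <- function(group, ires) {
  groups <- c("less than one lap", "less than two laps",
              "more than two laps")
  labels <- c("IRES", "Non-IRES")
  gi <- match(group, groups)
  li <- match(ires, labels)
  if (anyNA(gi)) stopf("unknown lap group: %s",
                       paste(unique(group[is.na(gi)]), collapse = ", "))
  if (anyNA(li)) stopf("unknown IRES label: %s",
                       paste(unique(ires[is.na(li)]), collapse = ", "))
  c("I", "II", "III", "IV", "V", "VI")[(gi - 1L) * 2L + li]
}
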