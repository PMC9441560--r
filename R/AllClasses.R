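#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CircSet: a set of circRNA definitions
#'
#' Container for circRNA identities, genomic exon blocks and circular exon
#' sequences. Exon blocks are stored 0-based half-open, sorted and
#' non-overlapping; the circular sequence of a record, when present, is the
#' 5'->3' concatenation of its exon blocks (reverse-complemented for minus
#' strand circRNAs) and its length equals the summed block widths.
#'
#' @slot info `DataFrame` with columns `circ_id`, `chrom`, `strand`,
#'   `parent_gene` (one row per circRNA; `chrom`/`strand`/`parent_gene` may
#'   be `NA` for sequence-only records).
#' @slot exons `CompressedIRangesList`, one element per circRNA (may be
#'   empty for sequence-only records). Stored 1-based internally as
#'   `IRanges`; accessors convert.
#' @slot seqs named `DNAStringSet` holding the circular exon sequences of
#'   the subset of records that carry one.
#'
#' @seealso [CircSet()], [readCircInfo()], [genCircSet()]
#' @export
setClass("CircSet",
  slots = c(info = "DataFrame",
            exons = "CompressedIRangesList",
            seqs = "DNAStringSet"))

setValidity("CircSet", function(object) {
  info <- object@info
  msgs <- character(0)
  need <- c("circ_id", "chrom", "strand", "parent_gene")
  if (!all(need %in% colnames(info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  ids <- info$circ_id
  if (anyDuplicated(ids))
    msgs <- c(msgs, paste0("duplicate circ_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad_strand <- !(info$strand %in% c("+", "-")) & !is.na(info$strand)
  if (any(bad_strand))
    msgs <- c(msgs, "strand must be '+', '-' or NA")
  if (length(object@exons) != nrow(info))
    msgs <- c(msgs, "exons must have one element per circRNA")
  else if (!identical(names(object@exons), as.character(ids)))
    msgs <- c(msgs, "names(exons) must equal info$circ_id")
  # sorted, non-overlapping blocks
  st <- IRanges::start(object@exons)
  en <- IRanges::end(object@exons)
  disj <- vapply(seq_along(st), function(i) {
    s <- st[[i]]; e <- en[[i]]
    length(s) < 2L || all(s[-1L] > e[-length(e)])
  }, logical(1))
  if (!all(disj))
    msgs <- c(msgs, paste0("exon blocks overlap or are unsorted for: ",
      paste(ids[!disj], collapse = ", ")))
  if (length(object@seqs)) {
    if (is.null(names(object@seqs)) || !all(names(object@seqs) %in% ids))
      msgs <- c(msgs, "seqs names must be circ_ids present in info")
    else {
      bw <- sum(IRanges::width(object@exons))
      names(bw) <- ids
      has_blocks <- bw[names(object@seqs)] > 0L
      wmatch <- Biostrings::width(object@seqs) == bw[names(object@seqs)]
      bad <- has_blocks & !wmatch
      if (any(bad))
        msgs <- c(msgs, paste0("sequence length != summed block widths for: ",
          paste(names(object@seqs)[bad], collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CircSet
#'
#' @param circ_id Character vector of unique circRNA identifiers.
#' @param chrom,strand,parent_gene Per-record metadata, recycled; strand
#'   must be `"+"`, `"-"` or `NA`.
#' @param exons `IRangesList`-coercible list of exon blocks per circRNA
#'   (1-based closed `IRanges`), or a list of two-column matrices of
#'   0-based half-open `[start, end)` blocks, or `NULL`.
#' @param seqs Named character vector or `DNAStringSet` of circular exon
#'   sequences (names are circ_ids; `U` is mapped to `T`), or `NULL`.
#' @return A [CircSet-class] object.
#' @export
#' @examples
#' cs <- CircSet("circA", "chr1", "+",
#'               exons = list(cbind(c(100, 300), c(200, 350))))
#' circLengths(cs)
CircSet <- function(circ_id, chrom = NA_character_, strand = NA_character_,
                    exons = NULL, seqs = NULL,
                    parent_gene = NA_character_) {
  circ_id <- as.character(circ_id)
  n <- length(circ_id)
  info <- S4Vectors::DataFrame(
    circ_id = circ_id,
    chrom = rep_len(as.character(chrom), n),
    strand = rep_len(as.character(strand), n),
    parent_gene = rep_len(as.character(parent_gene), n))
  if (is.null(exons)) {
    exons <- rep(list(IRanges::IRanges()), n)
  } else if (!methods::is(exons, "IRangesList")) {
    exons <- lapply(exons, function(b) {
      if (methods::is(b, "IRanges")) return(b)
      b <- as.matrix(b)
      if (!nrow(b)) return(IRanges::IRanges())
      IRanges::IRanges(start = b[, 1L] + 1L, end = b[, 2L])
    })
  }
  exons <- methods::as(IRanges::IRangesList(exons), "CompressedIRangesList")
  names(exons) <- circ_id
  if (is.null(seqs)) {
    seqs <- Biostrings::DNAStringSet()
  } else {
    if (!methods::is(seqs, "DNAStringSet")) {
      nm <- names(seqs)
      seqs <- Biostrings::DNAStringSet(normalizeNt(as.character(seqs)))
      names(seqs) <- nm
    }
    if (length(seqs) && is.null(names(seqs))) {
      if (length(seqs) != n)
        stopf("unnamed seqs must match the number of circRNAs")
      names(seqs) <- circ_id
    }
  }
  methods::new("CircSet", info = info, exons = exons, seqs = seqs)
}

#' JunctionRefDB: six-frame BSJ reference peptide database
#'
#' One row per (circRNA, reading frame): the translation of a nucleotide
#' window centred on the back-splice junction, together with the junction
#' boundary in amino-acid coordinates.
#'
#' @slot table `DataFrame` with columns `circ_id`, `frame` (one of
#'   `+1,+2,+3,-1,-2,-3`), `peptide` (may contain `*` for stops, `X` for
#'   ambiguous codons), `junction_aa_boundary` (residues `[0, b)` lie
#'   wholly before the BSJ) and `junction_splits_codon`.
#' @slot flank Integer, the configured per-side window half-width in nt.
#' @slot failures Character vector of circ_ids skipped (e.g. no sequence).
#' @seealso [buildJunctionRefDB()], [junctionHits()]
#' @export
setClass("JunctionRefDB",
  slots = c(table = "DataFrame", flank = "integer", failures = "character"))

setValidity("JunctionRefDB", function(object) {
  tab <- object@table
  need <- c("circ_id", "frame", "peptide", "junction_aa_boundary",
            "junction_splits_codon")
  if (!all(need %in% colnames(tab)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (!all(tab$frame %in% c("+1", "+2", "+3", "-1", "-2", "-3")))
      return("frame must be one of +1,+2,+3,-1,-2,-3")
    b <- tab$junction_aa_boundary
    if (any(b < 0L | b > nchar(tab$peptide)))
      return("junction_aa_boundary out of range")
  }
  TRUE
})

#' CorfSet: predicted circular open reading frames
#'
#' @slot table `DataFrame` with columns `circ_id`, `corf_index`,
#'   `start_nt` (0-based on the circle), `nt_length` (start codon through
#'   last codon before the stop; stop excluded), `laps`
#'   (`nt_length / circle length`), `is_infinite`, `frame_phase`
#'   (`start_nt %% 3`), `peptide`, `group` (lap group label).
#' @slot config List of enumeration parameters (`repeats`, `tail_nt`,
#'   `min_peptide_len`, `start_codon`).
#' @seealso [enumerateCorfs()], [filterCorfPeptides()]
#' @export
setClass("CorfSet", slots = c(table = "DataFrame", config = "list"))

setValidity("CorfSet", function(object) {
  tab <- object@table
  need <- c("circ_id", "corf_index", "start_nt", "nt_length", "laps",
            "is_infinite", "frame_phase", "peptide", "group")
  if (!all(need %in% colnames(tab)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(tab)) {
    fin <- !tab$is_infinite
    if (any(tab$nt_length[fin] %% 3L != 0L))
      return("finite cORF nt_length must be a multiple of 3")
    if (any(nchar(tab$peptide[fin]) * 3L != tab$nt_length[fin]))
      return("finite cORF peptide length must equal nt_length / 3")
    if (any(!startsWith(tab$peptide, "M")))
      return("every cORF peptide must start with M")
    if (any(grepl("*", tab$peptide, fixed = TRUE)))
      return("cORF peptides must not contain stop characters")
  }
  TRUE
})

#' CodingModel: Gaussian naive Bayes coding-potential classifier
#'
#' Per-class Gaussian feature likelihoods with variance smoothing
#' (`var + eps`, `eps` a small fraction of the largest feature variance),
#' fitted on a peptide feature schema of amino-acid composition, log
#' length and dipeptide frequencies.
#'
#' @slot schema Character schema identifier (versioned).
#' @slot class_levels Character(2): negative then positive class label.
#' @slot priors Named numeric class priors.
#' @slot means,vars Feature matrices, one row per class.
#' @slot eps Variance-smoothing value actually used.
#' @slot n_train,n_test Split sizes.
#' @slot test_accuracy Accuracy on the held-out test split.
#' @slot seed Integer seed used for the stratified shuffle.
#' @seealso [trainCodingModel()], [predictCoding()]
#' @export
setClass("CodingModel",
  slots = c(schema = "character", class_levels = "character",
            priors = "numeric", means = "matrix", vars = "matrix",
            eps = "numeric", n_train = "integer", n_test = "integer",
            test_accuracy = "numeric", seed = "integer"))
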