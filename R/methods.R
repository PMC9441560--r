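# Accessors and show() methods.

#' @rdname CircSet-class
#' @export
setMethod("circIds", "CircSet", function(x) as.character(x@info$circ_id))

#' @rdname CircSet-class
#' @export
setMethod("circChroms", "CircSet", function(x) {
  stats::setNames(as.character(x@info$chrom), circIds(x))
})

#' @rdname CircSet-class
#' @export
setMethod("circStrands", "CircSet", function(x) {
  stats::setNames(as.character(x@info$strand), circIds(x))
})

#' @rdname CircSet-class
#' @export
setMethod("exonBlocks", "CircSet", function(x) x@exons)

#' @rdname CircSet-class
#' @export
setMethod("circSequences", "CircSet", function(x) x@seqs)

#' @rdname CircSet-class
#' @export
setReplaceMethod("circSequences", "CircSet", function(x, value) {
  if (!methods::is(value, "DNAStringSet")) {
    nm <- names(value)
    value <- Biostrings::DNAStringSet(normalizeNt(as.character(value)))
    names(value) <- nm
  }
  if (length(value) && is.null(names(value)))
    stopf("replacement sequences must be named by circ_id")
  extra <- setdiff(names(value), circIds(x))
  if (length(extra))
    stopf("unknown circ_id in sequences: %s", paste(extra, collapse = ", "))
  merged <- x@seqs[setdiff(names(x@seqs), names(value))]
  x@seqs <- c(merged, value)[intersect(circIds(x), c(names(merged), names(value)))]
  methods::validObject(x)
  x
})

#' @rdname CircSet-class
#' @export
setMethod("circLengths", "CircSet", function(x) {
  bw <- sum(IRanges::width(x@exons))
  out <- ifelse(bw > 0L, bw, NA_integer_)
  names(out) <- circIds(x)
  if (length(x@seqs))
    out[names(x@seqs)] <- Biostrings::width(x@seqs)
  out
})

#' @rdname CircSet-class
#' @export
setMethod("length", "CircSet", function(x) nrow(x@info))

#' @rdname CircSet-class
#' @param i Index or character vector of circ_ids.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "CircSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, circIds(x))
  if (anyNA(i)) stopf("unknown circ_id in subset")
  info <- x@info[i, , drop = FALSE]
  exons <- x@exons[i]
  ids <- as.character(info$circ_id)
  seqs <- x@seqs[names(x@seqs) %in% ids]
  methods::new("CircSet", info = info, exons = exons, seqs = seqs)
})

setMethod("show", "CircSet", function(object) {
  n <- length(object)
  cat(sprintf("CircSet with %d circRNA%s (%d with sequence)\n",
              n, if (n == 1L) "" else "s", length(object@seqs)))
  if (n) {
    shown <- utils::head(circIds(object), 5L)
    cat("  ids:", paste(shown, collapse = ", "),
        if (n > 5L) "..." else "", "\n")
  }
})

#' @rdname JunctionRefDB-class
#' @export
setMethod("refTable", "JunctionRefDB", function(x) x@table)

#' @rdname JunctionRefDB-class
#' @export
setMethod("junctionFlank", "JunctionRefDB", function(x) x@flank)

#' @rdname JunctionRefDB-class
#' @param object A `JunctionRefDB`.
setMethod("show", "JunctionRefDB", function(object) {
  cat(sprintf(
    "JunctionRefDB: %d reference peptides (%d circRNAs, flank %d nt)\n",
    nrow(object@table), length(unique(object@table$circ_id)), object@flank))
  if (length(object@failures))
    cat("  skipped:", length(object@failures), "circRNA(s)\n")
})

#' @rdname CorfSet-class
#' @export
setMethod("corfTable", "CorfSet", function(x) x@table)

#' @rdname CorfSet-class
#' @param object A `CorfSet`.
setMethod("show", "CorfSet", function(object) {
  tab <- object@table
  cat(sprintf("CorfSet: %d cORF%s on %d circRNA%s\n",
              nrow(tab), if (nrow(tab) == 1L) "" else "s",
              length(unique(tab$circ_id)),
              if (length(unique(tab$circ_id)) == 1L) "" else "s"))
  if (nrow(tab))
    cat("  lap groups:",
        paste(names(table(tab$group)), table(tab$group),
              sep = "=", collapse = ", "), "\n")
})

#' @rdname CodingModel-class
#' @export
setMethod("testAccuracy", "CodingModel", function(x) x@test_accuracy)

#' @rdname CodingModel-class
#' @param object A `CodingModel`.
setMethod("show", "CodingModel", function(object) {
  cat(sprintf(
    "CodingModel (%s): %d features, train n=%d, test n=%d, accuracy %.3f\n",
    object@schema, ncol(object@means), object@n_train, object@n_test,
    object@test_accuracy))
})
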