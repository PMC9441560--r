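# circRNA definition / peptide list / protein input parsing and the three
# sequence-acquisition models.

#' Read a circRNA info table
#'
#' Parses a delimited circRNA definition file into a [CircSet-class]. The
#' default dialect expects columns `circ_id`, `chrom`, `strand`, `blocks`
#' where blocks look like `"100-200,300-350"`. Because published circRNA
#' tables disagree on coordinate conventions, the dialect declares its own
#' (`"0h"` = 0-based half-open, `"1c"` = 1-based closed) and coordinates
#' are converted to the package-internal 0-based half-open form on read.
#'
#' @param path Path to the info file.
#' @param dialect Named list: `cols` (integer positions of circ_id, chrom,
#'   strand, blocks, optionally gene), `sep` field separator, `block_sep`,
#'   `range_sep`, `coords` (`"0h"` or `"1c"`), `header` logical.
#' @return A [CircSet-class] (sequences unset).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("circA\tchr1\t+\t100-200,300-350", f)
#' readCircInfo(f)
readCircInfo <- function(path, dialect = list()) {
  if (!file.exists(path)) stopf("info file not found: %s", path)
  d <- utils::modifyList(list(
    cols = c(circ_id = 1L, chrom = 2L, strand = 3L, blocks = 4L),
    sep = "\t", block_sep = ",", range_sep = "-", coords = "0h",
    header = FALSE), dialect)
  lines <- readLines(path)
  first <- if (d$header) 2L else 1L
  keep <- which(nzchar(trimws(lines)))
  keep <- keep[keep >= first]
  if (!length(keep))
    return(CircSet(character(0)))
  ids <- chrom <- strand <- gene <- character(length(keep))
  blocks <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(lines[ln], d$sep, fixed = TRUE)[[1L]]
    if (length(f) < max(d$cols))
      stopf("line %d: expected at least %d fields, got %d",
            ln, max(d$cols), length(f))
    ids[k] <- trimws(f[d$cols[["circ_id"]]])
    chrom[k] <- trimws(f[d$cols[["chrom"]]])
    strand[k] <- trimws(f[d$cols[["strand"]]])
    gene[k] <- if ("gene" %in% names(d$cols) && length(f) >= d$cols[["gene"]])
      trimws(f[d$cols[["gene"]]]) else NA_character_
    parts <- strsplit(trimws(f[d$cols[["blocks"]]]), d$block_sep,
                      fixed = TRUE)[[1L]]
    se <- vapply(parts, function(p) {
      ab <- strsplit(p, d$range_sep, fixed = TRUE)[[1L]]
      if (length(ab) != 2L || anyNA(suppressWarnings(as.numeric(ab))))
        stopf("line %d: malformed block '%s'", ln, p)
      as.numeric(ab)
    }, numeric(2))
    se <- matrix(se, nrow = 2L)
    st <- se[1L, ]; en <- se[2L, ]
    if (d$coords == "1c") st <- st - 1  # -> 0-based half-open
    if (any(st >= en))
      stopf("line %d: block start >= end (%s)", ln,
            paste(parts[st >= en], collapse = ", "))
    o <- order(st)
    blocks[[k]] <- cbind(st[o], en[o])
  }
  if (anyDuplicated(ids))
    stopf("duplicate circ_id: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  CircSet(ids, chrom = chrom, strand = strand, exons = blocks,
          parent_gene = gene)
}

#' Write a circRNA info table
#'
#' Serialises a [CircSet-class] in the default [readCircInfo()] dialect
#' (0-based half-open blocks). Reading the result back reproduces the
#' original definitions.
#'
#' @param circs A `CircSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCircInfo <- function(circs, path) {
  st <- IRanges::start(circs@exons)
  en <- IRanges::end(circs@exons)
  blocks <- vapply(seq_along(st), function(i) {
    paste(sprintf("%d-%d", st[[i]] - 1L, en[[i]]), collapse = ",")
  }, character(1))
  lines <- paste(circIds(circs), circChroms(circs), circStrands(circs),
                 blocks, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Load circRNA sequences from FASTA (model 1)
#'
#' Direct sequence entry: headers name circ_ids, sequences are uppercased
#' and RNA `U` is converted to `T`.
#'
#' @param fasta Path to a circRNA FASTA file.
#' @return Named `DNAStringSet`.
#' @export
loadCircSequences <- function(fasta) {
  x <- Biostrings::readBStringSet(fasta)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stopf("duplicate FASTA header: %s",
          paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stopf("empty FASTA record: %s",
          paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  s <- normalizeNt(as.character(x))
  bad <- !isValidNt(s)
  if (any(bad))
    stopf("non-nucleotide characters in record: %s",
          paste(names(x)[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(x)
  out
}

#' Extract circRNA sequences from a genome (model 2)
#'
#' Concatenates each circRNA's exon-block substrings in genomic order and
#' reverse-complements the concatenation for minus-strand records, so the
#' result always reads 5'->3'. An optional exon annotation (e.g. from
#' [readExonAnnotation()]) is used to warn about blocks that do not
#' coincide with any annotated exon.
#'
#' @param circs A [CircSet-class] with exon blocks set.
#' @param genome Named `DNAStringSet` (or coercible named character vector)
#'   of chromosome sequences.
#' @param annotation Optional `data.frame`/`DataFrame` with columns
#'   `chrom`, `start`, `end` (0-based half-open exons) used for a
#'   consistency warning only.
#' @return The `CircSet` with sequences filled in.
#' @export
#' @examples
#' cs <- CircSet("circA", "chr1", "+",
#'               exons = list(cbind(c(2, 9), c(6, 12))))
#' cs <- extractSequencesModel2(cs, c(chr1 = "AAATGCAAGGTTT"))
#' as.character(circSequences(cs))
extractSequencesModel2 <- function(circs, genome, annotation = NULL) {
  if (!methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- Biostrings::DNAStringSet(normalizeNt(as.character(genome)))
    names(genome) <- nm
  }
  ids <- circIds(circs)
  chroms <- circChroms(circs)
  strands <- circStrands(circs)
  st <- IRanges::start(circs@exons)
  en <- IRanges::end(circs@exons)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    ch <- chroms[i]
    if (is.na(ch) || !(ch %in% names(genome)))
      stopf("chromosome '%s' (circ %s) not present in genome", ch, ids[i])
    s <- st[[i]]; e <- en[[i]]
    if (!length(s)) stopf("circ %s has no exon blocks", ids[i])
    clen <- Biostrings::width(genome[ch])
    if (any(s < 1L) || any(e > clen))
      stopf("circ %s: exon block outside chromosome bounds (length %d)",
            ids[i], clen)
    if (!is.null(annotation)) {
      ann <- annotation[annotation$chrom == ch, , drop = FALSE]
      hit <- vapply(seq_along(s), function(j)
        any(ann$start == s[j] - 1L & ann$end == e[j]), logical(1))
      if (nrow(ann) && !all(hit))
        warnf("circ %s: %d block(s) not found in the exon annotation",
              ids[i], sum(!hit))
    }
    pieces <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start = s, end = e)))
    seq <- paste(pieces, collapse = "")
    if (isTRUE(unname(strands[i]) == "-")) seq <- revComp(seq)
    out[i] <- seq
  }
  names(out) <- ids
  circSequences(circs) <- out
  circs
}

#' Read exon annotation from a GTF file
#'
#' Uses \pkg{rtracklayer} to import `exon` features and returns a plain
#' table (`chrom`, `start`, `end`, `strand`, `transcript_id`) with 0-based
#' half-open coordinates, the form the rest of the package expects.
#'
#' @param path GTF file path.
#' @return A `data.frame` of exons.
#' @export
readExonAnnotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("readExonAnnotation() requires the rtracklayer package")
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "exon"]
  tx <- if ("transcript_id" %in% names(S4Vectors::mcols(g)))
    as.character(g$transcript_id) else NA_character_
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = BiocGenerics::start(g) - 1L,
    end = BiocGenerics::end(g),
    strand = as.character(BiocGenerics::strand(g)),
    transcript_id = tx,
    stringsAsFactors = FALSE)
}

# transcript-relative offset of genomic position g (0-based): number of
# exonic nt strictly before g in plus orientation
.plusOffset <- function(g, starts0, ends0) {
  sum(pmax(0L, pmin(ends0, g) - starts0))
}

#' Extract circRNA sequences from mature transcripts (model 3)
#'
#' Locates the circle's first-exon start and last-exon end within a single
#' transcript's exon map and returns the contiguous transcript substring
#' between them (intron-free by construction). circRNAs whose boundaries
#' fall in different transcripts are rejected: no chimeric joins are made.
#'
#' @param circs A [CircSet-class] with exon blocks and chrom/strand set.
#' @param transcripts Named `DNAStringSet` (or named character) of mature
#'   transcript sequences, already 5'->3'.
#' @param exon_maps Named list (by transcript id) of two-column matrices of
#'   0-based half-open genomic exon blocks, with an optional
#'   `attr(, "chrom")` and `attr(, "strand")` per element; alternatively a
#'   `data.frame` with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (such as [readExonAnnotation()] output).
#' @return The `CircSet` with sequences filled in.
#' @export
extractSequencesModel3 <- function(circs, transcripts, exon_maps) {
  if (!methods::is(transcripts, "DNAStringSet")) {
    nm <- names(transcripts)
    transcripts <- Biostrings::DNAStringSet(normalizeNt(as.character(transcripts)))
    names(transcripts) <- nm
  }
  if (is.data.frame(exon_maps)) {
    sp <- split(exon_maps, exon_maps$transcript_id)
    exon_maps <- lapply(sp, function(df) {
      m <- cbind(df$start, df$end)
      attr(m, "chrom") <- df$chrom[1L]
      attr(m, "strand") <- df$strand[1L]
      m
    })
  }
  ids <- circIds(circs)
  chroms <- circChroms(circs)
  strands <- circStrands(circs)
  st <- IRanges::start(circs@exons)
  en <- IRanges::end(circs@exons)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    g1 <- st[[i]][1L] - 1L                      # 0-based circle start
    g2 <- en[[i]][length(en[[i]])]              # 0-based half-open end
    found <- FALSE
    tried <- character(0)
    for (tx in names(exon_maps)) {
      m <- exon_maps[[tx]]
      tchrom <- attr(m, "chrom"); tstrand <- attr(m, "strand")
      if (!is.null(tchrom) && !is.na(chroms[i]) && tchrom != chroms[i]) next
      s0 <- m[, 1L]; e0 <- m[, 2L]
      inside <- function(g) any(g >= s0 & g < e0)
      if (!(inside(g1) && inside(g2 - 1L))) { tried <- c(tried, tx); next }
      total <- sum(e0 - s0)
      p1 <- .plusOffset(g1, s0, e0)
      p2 <- .plusOffset(g2, s0, e0)
      minus <- isTRUE(unname(tstrand) == "-") ||
        (is.null(tstrand) && isTRUE(unname(strands[i]) == "-"))
      t1 <- if (minus) total - p2 else p1       # 0-based half-open on tx
      t2 <- if (minus) total - p1 else p2
      if (!(tx %in% names(transcripts)))
        stopf("transcript '%s' has an exon map but no sequence", tx)
      txseq <- as.character(transcripts[[tx]])
      if (t2 > nchar(txseq))
        stopf("circ %s: end beyond transcript %s length", ids[i], tx)
      out[i] <- substr(txseq, t1 + 1L, t2)
      found <- TRUE
      break
    }
    if (!found)
      stopf("circ %s: boundaries not found within any single transcript (tried: %s)",
            ids[i],
            if (length(tried)) paste(tried, collapse = ", ") else "none")
  }
  names(out) <- ids
  circSequences(circs) <- out
  circs
}

#' Read an identified MS/MS peptide list
#'
#' Accepts either a plain one-peptide-per-line file or a delimited search
#' engine export with a peptide-sequence column. Peptides are uppercased
#' and modification annotations in parentheses or square brackets (e.g.
#' `"PEPT(+15.99)IDE"`) are stripped. Rows containing residues outside the
#' 20-letter alphabet after stripping are skipped with a warning; the
#' number skipped is returned as attribute `n_skipped`.
#'
#' @param path Input file.
#' @param dialect `"plain"` or `"delimited"`.
#' @param column Column name or index holding the peptide sequence
#'   (delimited dialect only).
#' @param sep Field separator for the delimited dialect; defaults to `","`
#'   for `.csv` files and tab otherwise.
#' @return A `data.frame` with columns `sequence`, `source_id`,
#'   `engine_score`; attribute `n_skipped`.
#' @export
readPeptideList <- function(path, dialect = c("plain", "delimited"),
                            column = "peptide", sep = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    raw <- readLines(path)
    raw <- trimws(raw)
    raw <- raw[nzchar(raw)]
    src <- rep(NA_character_, length(raw))
    score <- rep(NA_real_, length(raw))
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
    if (is.character(column) && !(column %in% colnames(df)))
      stopf("peptide column '%s' not found (columns: %s)", column,
            paste(colnames(df), collapse = ", "))
    raw <- as.character(df[[column]])
    src <- if ("source_id" %in% colnames(df))
      as.character(df$source_id) else rep(NA_character_, length(raw))
    score <- if ("score" %in% colnames(df))
      suppressWarnings(as.numeric(df$score)) else rep(NA_real_, length(raw))
  }
  seqs <- toupper(gsub("\\([^)]*\\)|\\[[^]]*\\]", "", raw))
  ok <- isValidAa(seqs)
  n_skipped <- sum(!ok)
  if (n_skipped)
    warnf("skipped %d peptide row(s) with non-standard residues", n_skipped)
  out <- data.frame(sequence = seqs[ok], source_id = src[ok],
                    engine_score = score[ok], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a linear protein FASTA
#'
#' @param path Protein FASTA (headers: `id` optionally followed by
#'   `gene=SYMBOL`).
#' @return A `data.frame` with `protein_id`, `sequence`, `gene_id`.
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  gene <- ifelse(grepl("gene[=:]([^ ]+)", full),
                 sub(".*gene[=:]([^ ]+).*", "\\1", full), NA_character_)
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs))) stopf("empty protein record in %s", path)
  data.frame(protein_id = ids, sequence = seqs, gene_id = gene,
             stringsAsFactors = FALSE)
}
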