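# Per-circRNA evidence aggregation, summary/draw-parameter output, SVG
# sketches and the end-to-end pipeline driver.

#' Aggregate evidence into per-circRNA reports
#'
#' A circRNA enters the report when it has at least one merged peptide
#' that spans the back-splice junction (i.e. at least one junction hit at
#' the configured YY threshold survived all filters). For each such
#' circRNA the supporting cORF with the longest spanning merged peptide
#' is chosen as the representative; its lap group plus the IRES label
#' give the class I-VI.
#'
#' @param circs A [CircSet-class].
#' @param corfs The filtered [CorfSet-class].
#' @param merged Merged peptides from [mergeOverlapping()].
#' @param jhits Junction hits from [junctionHits()] (already at the
#'   reporting YY threshold).
#' @param coding Optional [scoreCorfs()] table.
#' @param ires_scores Optional named score vector (see
#'   [readIresScores()]); missing circRNAs are labelled `"Non-IRES"`
#'   with score `NA`.
#' @param ribo Optional named logical vector from [riboEvidence()] calls.
#' @param ires_threshold IRES labelling threshold (default 0.5).
#' @return `data.frame`, one row per predicted translatable circRNA,
#'   sorted by `circ_id`.
#' @export
buildCircReports <- function(circs, corfs, merged, jhits, coding = NULL,
                             ires_scores = NULL, ribo = NULL,
                             ires_threshold = 0.5) {
  empty <- data.frame(
    circ_id = character(0), parent_gene = character(0), L = integer(0),
    n_corfs = integer(0), corf_index = integer(0), start_nt = integer(0),
    nt_length = integer(0), laps = numeric(0), lap_group = character(0),
    merged_peptide = character(0), yy_max = integer(0),
    n_junction_peptides = integer(0), coding_score = integer(0),
    ires_score = numeric(0), ires_label = character(0),
    class = character(0), ribo_evidence = logical(0),
    stringsAsFactors = FALSE)
  span <- merged[merged$spans_bsj, , drop = FALSE]
  if (!nrow(span) || !nrow(jhits)) return(empty)
  ids <- sort(intersect(unique(span$circ_id), unique(jhits$circ_id)))
  if (!length(ids)) return(empty)
  ctab <- corfTable(corfs)
  lens <- circLengths(circs)
  genes <- stats::setNames(as.character(circs@info$parent_gene),
                           circIds(circs))
  rows <- lapply(ids, function(id) {
    sp <- span[span$circ_id == id, , drop = FALSE]
    best <- sp[order(-(sp$aa_end - sp$aa_start), sp$corf_index,
                     sp$aa_start), , drop = FALSE][1L, ]
    corf <- ctab[ctab$circ_id == id &
                   ctab$corf_index == best$corf_index, , drop = FALSE]
    jh <- jhits[jhits$circ_id == id, , drop = FALSE]
    score <- if (!is.null(coding)) {
      m <- coding$coding_score[coding$circ_id == id &
                                 coding$corf_index == best$corf_index]
      if (length(m)) m[1L] else NA_integer_
    } else NA_integer_
    is_sc <- !is.null(ires_scores) && id %in% names(ires_scores)
    iscore <- if (is_sc) unname(ires_scores[[id]]) else NA_real_
    ilabel <- if (is_sc) labelIres(iscore, ires_threshold) else "Non-IRES"
    data.frame(
      circ_id = id,
      parent_gene = if (is.na(genes[[id]])) "unannotated" else genes[[id]],
      L = unname(lens[[id]]),
      n_corfs = sum(ctab$circ_id == id),
      corf_index = best$corf_index,
      start_nt = corf$start_nt[1L],
      nt_length = corf$nt_length[1L],
      laps = corf$laps[1L],
      lap_group = corf$group[1L],
      merged_peptide = best$sequence,
      yy_max = max(jh$yy),
      n_junction_peptides = length(unique(jh$peptide)),
      coding_score = score,
      ires_score = iscore,
      ires_label = unname(ilabel),
      class = classifyCirc(corf$group[1L], ilabel),
      ribo_evidence = if (!is.null(ribo) && id %in% names(ribo))
        unname(ribo[[id]]) else NA,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$circ_id), , drop = FALSE]
}

#' Annotate reports by parental gene
#'
#' @param reports [buildCircReports()] output.
#' @param gene_table Named character vector or two-column `data.frame`
#'   (`circ_id`, annotation) mapping circRNAs to parental-gene
#'   annotations.
#' @return Reports with `parent_gene` filled in (`"unannotated"` when
#'   absent).
#' @export
annotateParentGene <- function(reports, gene_table) {
  if (is.data.frame(gene_table))
    gene_table <- stats::setNames(as.character(gene_table[[2L]]),
                                  as.character(gene_table[[1L]]))
  hit <- reports$circ_id %in% names(gene_table)
  reports$parent_gene[hit] <- unname(gene_table[reports$circ_id[hit]])
  reports$parent_gene[!hit | is.na(reports$parent_gene)] <- "unannotated"
  reports
}

#' Write the summary table
#'
#' One row per predicted translatable circRNA, deterministic column order
#' and row sort, so reruns on the same inputs are byte-identical.
#'
#' @param reports [buildCircReports()] output.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(reports, path) {
  reports <- reports[order(reports$circ_id), , drop = FALSE]
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write draw parameters for the SVG renderer
#'
#' Collects the visualization parameters accumulated along the pipeline
#' (circle length, representative cORF geometry, junction position, IRES
#' score when known) into a plain text table that [renderSvg()] and
#' [readDrawParams()] can parse; missing IRES information becomes
#' `"NA"`.
#'
#' @param reports [buildCircReports()] output.
#' @param path Output path (conventionally `circ_draw.txt`).
#' @return `path`, invisibly.
#' @export
writeDrawParams <- function(reports, path) {
  df <- data.frame(circ_id = reports$circ_id, L = reports$L,
                   corf_start = reports$start_nt,
                   corf_len = reports$nt_length, laps = reports$laps,
                   junction_pos = 0L,
                   ires_score = ifelse(is.na(reports$ires_score), "NA",
                                       as.character(reports$ires_score)),
                   peptide = reports$merged_peptide)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a draw-parameter file back
#'
#' @param path File written by [writeDrawParams()].
#' @return `data.frame` mirroring the written values.
#' @export
readDrawParams <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# spiral polyline: radius grows with each lap so rolling cORFs read as a
# spiral; returns SVG points string
.spiralPoints <- function(laps, r0 = 110, dr = 16, cx = 200, cy = 200) {
  theta <- seq(0, laps * 2 * pi, length.out = max(32L, ceiling(laps * 90)))
  r <- r0 + dr * theta / (2 * pi)
  x <- cx + r * sin(theta)
  y <- cy - r * cos(theta)
  paste(sprintf("%.2f,%.2f", x, y), collapse = " ")
}

#' Render the two SVG sketches for one predicted circRNA
#'
#' Picture 1 shows the circle with the representative cORF drawn as an
#' arc from its start position — with radius increasing per lap (a
#' spiral) when the cORF rolls more than once — a junction tick at the
#' top and an IRES badge when a score is known. Picture 2 is a sequence
#' panel with the merged junction peptide highlighted. Rendering is
#' best-effort; both files are always produced and are well-formed XML.
#'
#' @param report One row of [buildCircReports()] output.
#' @param seq The circRNA's circular sequence (character).
#' @param outdir Output directory (created if needed; conventionally
#'   `draw_circ/`).
#' @return Character vector of the two file paths, invisibly.
#' @export
renderSvg <- function(report, seq, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  id <- report$circ_id[1L]
  L <- report$L[1L]
  laps <- report$laps[1L]
  f1 <- file.path(outdir, paste0(id, "_structure.svg"))
  f2 <- file.path(outdir, paste0(id, "_sequence.svg"))
  start_angle <- 2 * pi * report$start_nt[1L] / L
  ires_txt <- if (!is.na(report$ires_score[1L]))
    sprintf('<text x="200" y="388" text-anchor="middle" font-size="12">IRES score %.3f (%s)</text>',
            report$ires_score[1L], .xmlEscape(report$ires_label[1L])) else ""
  svg1 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="400" height="400" viewBox="0 0 400 400">',
    sprintf('<title>%s</title>', .xmlEscape(id)),
    '<circle cx="200" cy="200" r="110" fill="none" stroke="#888" stroke-width="2"/>',
    '<line x1="200" y1="78" x2="200" y2="102" stroke="#d62728" stroke-width="3"/>',
    '<text x="200" y="70" text-anchor="middle" font-size="11" fill="#d62728">BSJ</text>',
    sprintf('<g transform="rotate(%.2f 200 200)"><polyline points="%s" fill="none" stroke="#1f77b4" stroke-width="3"/></g>',
            start_angle * 180 / pi, .spiralPoints(laps)),
    sprintf('<text x="200" y="205" text-anchor="middle" font-size="13">%s</text>',
            .xmlEscape(id)),
    sprintf('<text x="200" y="222" text-anchor="middle" font-size="11">L=%d nt, cORF %.2f lap(s), %s</text>',
            L, laps, .xmlEscape(report$lap_group[1L])),
    ires_txt,
    '</svg>')
  writeLines(svg1[nzchar(svg1)], f1)
  seq <- as.character(seq)
  per <- 60L
  nrow_ <- ceiling(nchar(seq) / per)
  rows <- substring(seq, (seq_len(nrow_) - 1L) * per + 1L,
                    pmin(nchar(seq), seq_len(nrow_) * per))
  texts <- sprintf(
    '<text x="10" y="%d" font-family="monospace" font-size="10">%s</text>',
    30L + 14L * seq_len(nrow_), .xmlEscape(rows))
  svg2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="420" height="%d">',
            60L + 14L * (nrow_ + 2L)),
    sprintf('<text x="10" y="16" font-size="12">%s — merged junction peptide: %s</text>',
            .xmlEscape(id), .xmlEscape(report$merged_peptide[1L])),
    texts,
    '</svg>')
  writeLines(svg2, f2)
  invisible(c(f1, f2))
}

#' Run the whole prediction pipeline
#'
#' Orchestrates every stage on in-memory inputs: junction reference
#' database, cORF enumeration and filtering, peptide deduplication,
#' junction judgement, optional linear-protein filtering, cORF mapping,
#' overlap merging, coding scoring, IRES labelling and report assembly.
#' Counts at each filtering stage are logged to stderr via `message()` so
#' the evidence funnel stays auditable.
#'
#' @param circs A [CircSet-class] with sequences.
#' @param peptides MS peptides (character vector or `data.frame` with
#'   `sequence`).
#' @param proteins Optional linear proteins for the parental-gene filter.
#' @param ires_scores Optional named IRES score vector.
#' @param coding_model Optional [CodingModel-class].
#' @param ribo_seqs Optional ribo-seq nucleotide sequences.
#' @param k Junction flank width (nt).
#' @param min_yy Reporting YY threshold (default 2).
#' @param min_peptide_len cORF peptide length bound (strict, default 20).
#' @param il_equivalent Fold I/L when matching.
#' @param outdir Optional output directory; when given, writes
#'   `summary.tsv`, `circ_draw.txt` and per-circRNA SVGs under
#'   `draw_circ/`.
#' @return List with `reports`, `corfs`, `jhits`, `flagged`, `corf_hits`,
#'   `merged`.
#' @export
runPipeline <- function(circs, peptides, proteins = NULL,
                        ires_scores = NULL, coding_model = NULL,
                        ribo_seqs = NULL, k = 100L, min_yy = 2L,
                        min_peptide_len = 20L, il_equivalent = FALSE,
                        outdir = NULL) {
  cfg <- corfConfig(min_peptide_len = min_peptide_len)
  peps <- dedupePeptides(peptides)
  message(sprintf("pipeline: %d unique peptides", length(peps)))
  db <- buildJunctionRefDB(circs, k = k)
  corfs <- filterCorfPeptides(enumerateCorfs(circs, cfg), cfg)
  message(sprintf("pipeline: %d cORFs pass the >%d aa AUG filter",
                  nrow(corfTable(corfs)), cfg$min_peptide_len))
  jhits <- junctionHits(peps, db, min_yy = min_yy,
                        il_equivalent = il_equivalent)
  message(sprintf("pipeline: %d junction-spanning hits (yy >= %d) on %d circRNAs",
                  nrow(jhits), min_yy, length(unique(jhits$circ_id))))
  flagged <- jhits[0, , drop = FALSE]
  if (!is.null(proteins)) {
    fl <- filterLinear(jhits, proteins)
    jhits <- fl$retained
    flagged <- fl$flagged
    message(sprintf("pipeline: %d hits flagged as linear-explainable, %d retained",
                    nrow(flagged), nrow(jhits)))
  }
  corf_hits <- mapToCorf(peps, corfs, il_equivalent = il_equivalent)
  merged <- mergeOverlapping(corf_hits, corfs, junction_hits = jhits)
  message(sprintf("pipeline: %d merged peptides (%d spanning the BSJ)",
                  nrow(merged), sum(merged$spans_bsj)))
  coding <- if (!is.null(coding_model)) scoreCorfs(corfs, coding_model)
  ribo <- if (!is.null(ribo_seqs)) {
    seqs <- circSequences(circs)
    vapply(stats::setNames(names(seqs), names(seqs)), function(id)
      riboEvidence(as.character(seqs[[id]]), ribo_seqs), logical(1))
  }
  reports <- buildCircReports(circs, corfs, merged, jhits,
                              coding = coding, ires_scores = ires_scores,
                              ribo = ribo)
  message(sprintf("pipeline: %d predicted translatable circRNAs",
                  nrow(reports)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeSummary(reports, file.path(outdir, "summary.tsv"))
    writeDrawParams(reports, file.path(outdir, "circ_draw.txt"))
    seqs <- circSequences(circs)
    for (i in seq_len(nrow(reports)))
      renderSvg(reports[i, , drop = FALSE],
                as.character(seqs[[reports$circ_id[i]]]),
                file.path(outdir, "draw_circ"))
  }
  list(reports = reports, corfs = corfs, jhits = jhits,
       flagged = flagged, corf_hits = corf_hits, merged = merged)
}
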