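test_that("info files parse to 0-based half-open sorted blocks", {
  f <- withr::local_tempfile()
  writeLines(c("circA\tchr1\t+\t100-200,300-350",
               "circB\tchr2\t-\t300-350,100-200"), f)
  cs <- readCircInfo(f)
  expect_s4_class(cs, "CircSet")
  expect_identical(circIds(cs), c("circA", "circB"))
  expect_identical(unname(circLengths(cs)), c(150L, 150L))
  b <- exonBlocks(cs)[["circB"]]
  expect_identical(IRanges::start(b), c(101L, 301L))  # re-sorted ascending
  expect_identical(IRanges::end(b), c(200L, 350L))
})

test_that("1-based-closed dialect converts on read", {
  f <- withr::local_tempfile()
  writeLines("circA\tchr1\t+\t101-200", f)
  cs <- readCircInfo(f, dialect = list(coords = "1c"))
  expect_identical(unname(circLengths(cs)), 100L)
})

test_that("malformed coordinates and duplicate ids are rejected with context", {
  f <- withr::local_tempfile()
  writeLines(c("circA\tchr1\t+\t100-200", "circB\tchr1\t+\t200-100"), f)
  expect_error(readCircInfo(f), "line 2")
  writeLines(c("circA\tchr1\t+\t100-200", "circA\tchr1\t+\t300-400"), f)
  expect_error(readCircInfo(f), "circA")
})

test_that("info round-trip through write/read is idempotent", {
  f <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c("circA\tchr1\t+\t100-200,300-350",
               "circB\tchr2\t-\t5-20"), f)
  cs1 <- readCircInfo(f)
  writeCircInfo(cs1, f2)
  cs2 <- readCircInfo(f2)
  expect_identical(as.data.frame(cs1@info), as.data.frame(cs2@info))
  expect_identical(exonBlocks(cs1), exonBlocks(cs2))
})

test_that("model 1 FASTA loading normalizes case and U->T, rejects duplicates", {
  f <- withr::local_tempfile()
  writeLines(c(">circA", "augaaa"), f)
  expect_identical(as.character(loadCircSequences(f)), c(circA = "ATGAAA"))
  writeLines(c(">circA", "ATG", ">circA", "CCC"), f)
  expect_error(loadCircSequences(f), "duplicate")
  writeLines(c(">circA", "ATG", ">circB", ""), f)
  expect_error(loadCircSequences(f), "empty")
})

test_that("model 2 extracts blocks from the genome, revcomp on minus strand", {
  genome <- c(chr1 = "AAATGCAAGGTTT")
  plus <- CircSet("c1", "chr1", "+", exons = list(cbind(c(2, 9), c(6, 12))))
  minus <- CircSet("c2", "chr1", "-", exons = list(cbind(c(2, 9), c(6, 12))))
  expect_identical(
    as.character(circSequences(extractSequencesModel2(plus, genome))),
    c(c1 = "ATGCGTT"))
  expect_identical(
    as.character(circSequences(extractSequencesModel2(minus, genome))),
    c(c2 = "AACGCAT"))
  oob <- CircSet("c3", "chr1", "+", exons = list(cbind(2, 50)))
  expect_error(extractSequencesModel2(oob, genome), "bounds")
  nochrom <- CircSet("c4", "chrX", "+", exons = list(cbind(0, 3)))
  expect_error(extractSequencesModel2(nochrom, genome), "chrX")
})

test_that("model 3 slices the mature transcript, rejects chimeras", {
  tx <- c(tx1 = "ATGCGTTAAA")
  maps <- list(tx1 = structure(cbind(c(100, 210), c(105, 215)),
                               chrom = "chr1", strand = "+"))
  cs <- CircSet("c1", "chr1", "+",
                exons = list(cbind(c(100, 210), c(105, 212))))
  out <- extractSequencesModel3(cs, tx, maps)
  expect_identical(as.character(circSequences(out)), c(c1 = "ATGCGTT"))
  # boundaries in no single transcript
  cs2 <- CircSet("c2", "chr1", "+",
                 exons = list(cbind(c(100, 500), c(105, 520))))
  expect_error(extractSequencesModel3(cs2, tx, maps), "single transcript")
})

test_that("models 2 and 3 agree when the transcript is built from the same blocks", {
  set.seed(31)
  genome <- c(chrG = randomCircle(600))
  for (strand in c("+", "-")) {
    blocks <- cbind(c(50, 200, 400), c(110, 290, 460))
    cs <- CircSet("cc", "chrG", strand, exons = list(blocks))
    m2 <- extractSequencesModel2(cs, genome)
    pieces <- substring(genome[["chrG"]], blocks[, 1] + 1, blocks[, 2])
    txseq <- paste(pieces, collapse = "")
    if (strand == "-") txseq <- revComp(txseq)
    maps <- list(txA = structure(blocks, chrom = "chrG", strand = strand))
    m3 <- extractSequencesModel3(cs, c(txA = txseq), maps)
    expect_identical(as.character(circSequences(m2)),
                     as.character(circSequences(m3)))
  }
})

test_that("peptide lists parse, strip modifications and skip bad rows", {
  f <- withr::local_tempfile()
  writeLines(c("klaESAQQDSIK", "", "PEPT(+15.99)IDE", "PEPTIDEX1"), f)
  expect_warning(p <- readPeptideList(f), "skipped 1")
  expect_identical(p$sequence, c("KLAESAQQDSIK", "PEPTIDE"))
  expect_identical(attr(p, "n_skipped"), 1L)
  # delimited with named column
  f2 <- withr::local_tempfile()
  writeLines(c("id\tpeptide\tscore", "s1\tAAAK[42]R\t12.5"), f2)
  p2 <- readPeptideList(f2, "delimited", column = "peptide")
  expect_identical(p2$sequence, "AAAKR")
  expect_error(readPeptideList(f2, "delimited", column = "nope"), "nope")
})

test_that("CircSet validity enforces block/sequence consistency", {
  expect_error(
    CircSet(c("a", "a"), "chr1", "+"), "duplicate")
  expect_error(
    CircSet("a", "chr1", "*", exons = list(cbind(0, 3))), "strand")
  expect_error(
    CircSet("a", "chr1", "+", exons = list(cbind(0, 10)),
            seqs = c(a = "ATG")), "length")
  # sequence matching the blocks is accepted
  cs <- CircSet("a", "chr1", "+", exons = list(cbind(0, 3)),
                seqs = c(a = "AUG"))
  expect_identical(as.character(circSequences(cs)), c(a = "ATG"))
})
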