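test_that("peptide dedup is stable and case-folding", {
  expect_identical(dedupePeptides(c("AAK", "AAK", "AKR")), c("AAK", "AKR"))
  expect_identical(dedupePeptides(c("aak", "AAK")), c("AAK"))
  expect_identical(dedupePeptides(character(0)), character(0))
})

test_that("cORF mapping reports every occurrence, exhaustively", {
  ct <- enumerateCorfs(c(c3 = "ATGGCAGCT"))   # peptide MAAMAAMAA
  hits <- mapToCorf("MAA", ct)
  expect_identical(hits$aa_start, c(0L, 3L, 6L))
  expect_identical(hits$aa_end, c(3L, 6L, 9L))
  # exhaustive substring oracle on random peptide/corf pairs
  set.seed(42)
  for (i in 1:20) {
    s <- randomCircle(90)
    ct2 <- enumerateCorfs(c(x = s))
    tab <- as.data.frame(corfTable(ct2))
    if (!nrow(tab)) next
    target <- tab$peptide[1]
    p <- substr(target, 2, min(nchar(target), 6))
    if (nchar(p) < 3) next
    got <- mapToCorf(p, ct2)
    got <- got[got$corf_index == tab$corf_index[1] &
                 got$circ_id == tab$circ_id[1], ]
    want <- integer(0)
    for (s0 in 0:(nchar(target) - nchar(p)))
      if (substr(target, s0 + 1, s0 + nchar(p)) == p) want <- c(want, s0)
    expect_identical(got$aa_start, want)
  }
  # unmappable / overlong peptides vanish
  expect_identical(nrow(mapToCorf("WWWWW", ct)), 0L)
  expect_identical(nrow(mapToCorf(strrep("MAA", 10), ct)), 0L)
})

test_that("I/L equivalence is opt-in", {
  ct <- enumerateCorfs(c(c1 = paste0("ATG", "ATT", "CTG", strrep("GCA", 20), "TAA")))
  # peptide starts MIL...
  expect_identical(nrow(mapToCorf("MLI", ct)), 0L)
  expect_identical(nrow(mapToCorf("MLI", ct, il_equivalent = TRUE)), 1L)
})

test_that("junction spanning reproduces the worked YY example", {
  # 18-residue reference, boundary b = 10, unique match at s = 6 with
  # n = 9: four residues before the BSJ, five after -> YY4
  pep <- "KAESQWDTV"
  ref <- paste0("GGGGGG", pep, "PPP")
  hit <- junctionSpan(pep, ref, 10, FALSE)
  expect_identical(hit$left_count, 4L)
  expect_identical(hit$right_count, 5L)
  expect_identical(hit$yy, 4L)
})

test_that("junction-span geometry: one-sided matches and split codons", {
  ref <- paste0(strrep("K", 10), strrep("R", 8))   # b = 10
  expect_null(junctionSpan("KKK", ref, 10, FALSE))      # wholly left
  expect_null(junctionSpan("RRR", ref, 10, FALSE))      # wholly right
  h <- junctionSpan("KKRR", ref, 10, FALSE)
  expect_identical(c(h$left_count, h$right_count), c(2L, 2L))
  # split codon: residue b counts toward neither side
  ref2 <- paste0(strrep("G", 7), "KKKWRRRRR")  # 16 aa, match at s = 7
  h2 <- junctionSpan("KKKWRRRRR", ref2, 10, TRUE)
  expect_identical(h2$left_count, 3L)
  expect_identical(h2$right_count, 5L)
  expect_identical(h2$yy, 3L)
  # matches across a '*' are impossible because peptides contain no '*'
  expect_null(junctionSpan("KKRR", paste0(strrep("K", 10), "*RRR"), 10, FALSE))
})

test_that("junctionHits recovers spans and thresholds on yy", {
  set.seed(101)
  cfg <- synthConfig(seed = 11, n_circ = 25, n_noise_peptides = 20)
  sim <- genCircSet(cfg)
  pep <- genPeptides(sim$circs, sim$truth, cfg)
  db <- buildJunctionRefDB(sim$circs)
  all_hits <- junctionHits(pep$peptides, db, min_yy = 1)
  expect_true(all(all_hits$yy == pmin(all_hits$left_count,
                                      all_hits$right_count)))
  for (t in 2:4) {
    th <- junctionHits(pep$peptides, db, min_yy = t)
    expect_equal(th[, 1:7], all_hits[all_hits$yy >= t, 1:7],
                 ignore_attr = TRUE)
  }
  # planted peptides come back on their circle with the planted yy
  tr <- pep$peptides[pep$peptides$label == "junction", ]
  rec <- mapply(function(p, cid, yy)
    any(all_hits$peptide == p & all_hits$circ_id == cid &
          all_hits$yy == yy),
    tr$sequence, tr$circ_id, tr$planted_yy)
  expect_true(all(rec))
})

test_that("linear-protein filter flags exact substrings only", {
  hits <- data.frame(peptide = c("KLAESAQQDSIK", "MMMWWW"),
                     circ_id = c("a", "b"), frame = "+1",
                     match_start = 0L, left_count = 3L, right_count = 3L,
                     yy = 3L, stringsAsFactors = FALSE)
  prot <- c("XXXKLAESAQQDSIKYYY")
  out <- filterLinear(hits, prot)
  expect_identical(out$flagged$peptide, "KLAESAQQDSIK")
  expect_identical(out$retained$peptide, "MMMWWW")
  # one-residue difference is retained; empty protein set retains all
  out2 <- filterLinear(hits, "KLAESAQQDSIR")
  expect_identical(nrow(out2$flagged), 0L)
  out3 <- filterLinear(hits, character(0))
  expect_identical(nrow(out3$retained), 2L)
})

test_that("overlap merging unions transitively and stays literal", {
  ct <- enumerateCorfs(c(c3 = "ATGGCAGCT"))   # MAAMAAMAA
  mkhit <- function(s, e) data.frame(
    peptide = substr("MAAMAAMAA", s + 1, e), circ_id = "c3",
    corf_index = 1L, aa_start = s, aa_end = e, stringsAsFactors = FALSE)
  # [2,10) is out of range for 9 aa; use [2,7)+[5,9) and [0,2) gap case
  m1 <- mergeOverlapping(rbind(mkhit(2, 7), mkhit(5, 9)), ct)
  expect_identical(m1$aa_start, 2L)
  expect_identical(m1$aa_end, 9L)
  expect_identical(m1$member_count, 2L)
  expect_identical(m1$sequence, substr("MAAMAAMAA", 3, 9))
  # disjoint intervals stay separate (adjacency is not overlap)
  m2 <- mergeOverlapping(rbind(mkhit(0, 3), mkhit(3, 6)), ct)
  expect_identical(nrow(m2), 2L)
  # transitive chain collapses to one interval
  m3 <- mergeOverlapping(rbind(mkhit(0, 4), mkhit(3, 7), mkhit(6, 9)), ct)
  expect_identical(nrow(m3), 1L)
  expect_identical(c(m3$aa_start, m3$aa_end), c(0L, 9L))
  expect_identical(m3$member_count, 3L)
  # idempotence: merging the merged intervals changes nothing
  again <- m3
  again$peptide <- again$sequence
  m4 <- mergeOverlapping(
    again[, c("peptide", "circ_id", "corf_index", "aa_start", "aa_end")], ct)
  expect_identical(m4[, c("aa_start", "aa_end", "sequence")],
                   m3[, c("aa_start", "aa_end", "sequence")])
  # merged length >= longest member, sequence literal
  expect_gte(m3$aa_end - m3$aa_start, 4L)
  # inconsistent member interval errors
  bad <- mkhit(0, 4); bad$peptide <- "WWWW"
  expect_error(mergeOverlapping(bad, ct), "does not match")
})

test_that("spans_bsj is set from junction hits", {
  ct <- enumerateCorfs(c(c3 = "ATGGCAGCT"))
  hit <- data.frame(peptide = "MAAM", circ_id = "c3", corf_index = 1L,
                    aa_start = 0L, aa_end = 4L, stringsAsFactors = FALSE)
  jh <- data.frame(peptide = "MAAM", circ_id = "c3", stringsAsFactors = FALSE)
  expect_true(mergeOverlapping(hit, ct, jh)$spans_bsj)
  jh2 <- data.frame(peptide = "MAAM", circ_id = "other",
                    stringsAsFactors = FALSE)
  expect_false(mergeOverlapping(hit, ct, jh2)$spans_bsj)
})

test_that("ribo evidence requires a junction-covering match with flank", {
  set.seed(12)
  s <- randomCircle(80)
  L <- nchar(s)
  doubled <- paste0(s, s)
  covering <- substr(doubled, L - 10 + 1, L + 10)   # [L-10, L+10)
  inside <- substr(s, 5, 30)
  expect_true(riboEvidence(s, covering))
  expect_false(riboEvidence(s, inside))
  expect_false(riboEvidence(s, character(0)))
  # reverse-complement reads count too
  expect_true(riboEvidence(s, revComp(covering)))
  # flank requirement: 4 nt on one side fails min_flank 6
  lop <- substr(doubled, L - 4 + 1, L + 12)
  expect_false(riboEvidence(s, lop, min_flank = 6))
  expect_true(riboEvidence(s, lop, min_flank = 4))
})
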