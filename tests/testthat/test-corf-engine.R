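test_that("the scan template is three copies plus two junction nucleotides", {
  expect_identical(buildTemplate("ATGAAATAG"),
                   "ATGAAATAGATGAAATAGATGAAATAGAT")
  expect_identical(nchar(buildTemplate("ATGAAATAG")), 29L)
  set.seed(3)
  s <- randomCircle(120)
  expect_identical(nchar(buildTemplate(s)), 362L)
  expect_error(buildTemplate(""), "empty")
})

test_that("simple circles enumerate as expected", {
  tab <- as.data.frame(corfTable(enumerateCorfs(c(c1 = "ATGAAATAA"))))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$peptide, "MK")
  expect_identical(tab$start_nt, 0L)
  expect_identical(tab$nt_length, 6L)
  expect_equal(tab$laps, 6 / 9)
  expect_identical(tab$group, "less than one lap")
  # no start codon -> nothing
  expect_identical(nrow(corfTable(enumerateCorfs(c(c2 = "CCCCCCCCC")))), 0L)
  # stopless frame -> infinite cORF holding exactly three laps
  tab3 <- as.data.frame(corfTable(enumerateCorfs(c(c3 = "ATGGCAGCT"))))
  expect_true(tab3$is_infinite)
  expect_identical(tab3$peptide, "MAAMAAMAA")
  expect_equal(tab3$laps, 3)
  expect_identical(tab3$group, "more than two laps")
})

test_that("start codons across the BSJ (A^TG and AT^G) are always found", {
  # ATG wraps: A at position L-1, TG at 0-1
  s1 <- paste0("TG", strrep("C", 3), "TAA", strrep("C", 3), "A")  # L = 12
  tab1 <- as.data.frame(corfTable(enumerateCorfs(c(w1 = s1))))
  expect_true(11L %in% tab1$start_nt)
  # ATG wraps: AT at positions L-2, L-1, G at 0
  s2 <- paste0("G", strrep("C", 3), "TAA", strrep("C", 3), "AT")  # L = 12
  tab2 <- as.data.frame(corfTable(enumerateCorfs(c(w2 = s2))))
  expect_true(10L %in% tab2$start_nt)
})

test_that("enumeration matches the brute-force rotation oracle on random circles", {
  set.seed(1234)
  n_mismatch <- 0L
  for (i in 1:200) {
    L <- sample(9:36, 1)
    s <- randomCircle(L)
    got <- as.data.frame(corfTable(enumerateCorfs(c(x = s))))
    got <- got[, c("start_nt", "nt_length", "is_infinite", "peptide")]
    rownames(got) <- NULL
    want <- bruteCorfs(s)
    if (!isTRUE(all.equal(got, want))) n_mismatch <- n_mismatch + 1L
  }
  expect_identical(n_mismatch, 0L)
})

test_that("reported cORFs start with M, contain no stop, and are unique per stop", {
  set.seed(77)
  for (i in 1:25) {
    s <- randomCircle(sample(60:200, 1))
    tab <- as.data.frame(corfTable(enumerateCorfs(c(x = s))))
    if (!nrow(tab)) next
    expect_true(all(startsWith(tab$peptide, "M")))
    expect_false(any(grepl("*", tab$peptide, fixed = TRUE)))
    stop_key <- ifelse(tab$is_infinite, "inf",
                       (tab$start_nt + tab$nt_length) %% nchar(s))
    expect_false(anyDuplicated(paste(tab$frame_phase, stop_key)) > 0)
    expect_equal(tab$laps, tab$nt_length / nchar(s))
  }
})

test_that("the >20 aa filter boundary is strict", {
  mk <- function(naa) paste0("M", strrep("A", naa - 1L))
  tab <- S4Vectors::DataFrame(
    circ_id = c("a", "b"), corf_index = c(1L, 1L), start_nt = c(0L, 0L),
    nt_length = c(21L * 3L, 20L * 3L), laps = c(0.5, 0.5),
    is_infinite = c(FALSE, FALSE), frame_phase = c(0L, 0L),
    peptide = c(mk(21), mk(20)),
    group = rep("less than one lap", 2))
  cs <- methods::new("CorfSet", table = tab, config = corfConfig())
  out <- corfTable(filterCorfPeptides(cs))
  expect_identical(out$circ_id, "a")   # 21 aa kept, 20 aa removed
  # empty input stays empty
  empty <- methods::new("CorfSet", table = tab[0, ], config = corfConfig())
  expect_identical(nrow(corfTable(filterCorfPeptides(empty))), 0L)
})

test_that("lap groups partition laps with infinity overriding", {
  expect_identical(lapGroup(0.5, FALSE), "less than one lap")
  expect_identical(lapGroup(1.5, FALSE), "less than two laps")
  expect_identical(lapGroup(3, TRUE), "more than two laps")
  expect_warning(g <- lapGroup(2.4, FALSE), "laps >= 2")
  expect_identical(g, "less than two laps")
})

test_that("infinite cORFs only arise on stop-free frames and hold three laps", {
  set.seed(55)
  found <- 0L
  for (i in 1:60) {
    L <- 3L * sample(4:12, 1)
    s <- randomCircle(L)
    tab <- as.data.frame(corfTable(enumerateCorfs(c(x = s))))
    inf <- tab[tab$is_infinite, , drop = FALSE]
    if (!nrow(inf)) next
    found <- found + nrow(inf)
    expect_true(all(inf$nt_length == 3L * L))
    expect_true(all(nchar(inf$peptide) == L))
  }
  expect_gt(found, 0L)
})

test_that("cORF table and peptide FASTA export round-trip", {
  ct <- enumerateCorfs(c(c1 = "ATGAAATAA", c3 = "ATGGCAGCT"))
  tsv <- withr::local_tempfile(); fa <- withr::local_tempfile()
  writeCorfTable(ct, tsv, fa)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_identical(back$peptide, as.character(corfTable(ct)$peptide))
  fasta <- Biostrings::readAAStringSet(fa)
  expect_identical(unname(as.character(fasta)),
                   as.character(corfTable(ct)$peptide))
})
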