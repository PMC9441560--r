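test_that("peptide features are composition + log length + dipeptides", {
  f <- featurizePeptide("AAAA")
  expect_identical(length(f), 421L)
  expect_equal(f[["comp_A"]], 1)
  expect_equal(sum(f[grep("^comp_", names(f))]), 1)
  expect_equal(f[["loglen"]], log(4))
  expect_equal(f[["dp_AA"]], 1)
  # anagrams share composition but not dipeptides
  a <- featurizePeptide("ARND"); b <- featurizePeptide("DNRA")
  expect_equal(a[grep("^comp_", names(a))], b[grep("^comp_", names(b))])
  expect_false(isTRUE(all.equal(a[grep("^dp_", names(a))],
                                b[grep("^dp_", names(b))])))
  expect_error(featurizePeptide(""), "peptide")
  expect_error(featurizePeptide("AB1"), "peptide")
})

test_that("dataset construction validates sizes, disjointness and fraction", {
  pos <- paste0("M", strrep("A", 5:24))
  neg <- paste0("M", strrep("C", 5:24))
  expect_s3_class(makeCodingDataset(pos, neg), "coding_dataset")
  expect_error(makeCodingDataset(pos[1:5], neg), "at least 10")
  expect_error(makeCodingDataset(pos, c(neg, pos[1])), "disjoint")
  expect_error(makeCodingDataset(pos, neg, train_fraction = 1), "fraction")
})

test_that("training splits 8:2, is seed-deterministic, and separates planted classes", {
  set.seed(42)
  pos <- randomPeptides(500, c(30, 80), freqs = proteinAAFrequencies())
  neg <- randomPeptides(500, c(30, 80))
  ds <- makeCodingDataset(pos, neg, seed = 5)
  m <- trainCodingModel(ds)
  expect_identical(m@n_train, 800L)
  expect_identical(m@n_test, 200L)
  expect_gte(testAccuracy(m), 0.9)
  m2 <- trainCodingModel(ds)
  expect_identical(m@means, m2@means)
  expect_identical(testAccuracy(m), testAccuracy(m2))
  # protein-like draws score 1 far more often than not
  set.seed(43)
  probe <- randomPeptides(50, c(40, 80), freqs = proteinAAFrequencies())
  expect_gte(mean(predictCoding(m, probe)), 0.8)
  # scores are 0/1 and empty input gives empty output
  expect_true(all(predictCoding(m, pos[1:20]) %in% c(0L, 1L)))
  expect_identical(predictCoding(m, character(0)), integer(0))
})

test_that("label-shuffled training lands at chance accuracy", {
  set.seed(42)
  pool <- c(randomPeptides(500, c(30, 80), freqs = proteinAAFrequencies()),
            randomPeptides(500, c(30, 80)))
  idx <- sample(length(pool))
  m0 <- trainCodingModel(makeCodingDataset(pool[idx[1:500]],
                                           pool[idx[501:1000]], seed = 5))
  expect_lt(abs(testAccuracy(m0) - 0.5), 0.1)
})

test_that("naive Bayes posterior math agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(99)
  n <- 120L
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0), rnorm(n, 1)),
             cbind(rnorm(n, 1.5), rnorm(n, -1), rnorm(n, 0)))
  colnames(x) <- c("f1", "f2", "f3")
  y <- rep(c("noncoding", "coding"), each = n)
  lev <- c("noncoding", "coding")
  means <- t(vapply(lev, function(cl)
    colMeans(x[y == cl, ]), numeric(3)))
  vars <- t(vapply(lev, function(cl)
    apply(x[y == cl, ], 2, var), numeric(3)))
  model <- methods::new("CodingModel", schema = "raw", class_levels = lev,
                        priors = c(noncoding = 0.5, coding = 0.5),
                        means = means, vars = vars, eps = 0,
                        n_train = 2L * n, n_test = 0L,
                        test_accuracy = NA_real_, seed = 99L)
  ours <- circPepMS:::.predictNB(model, x)
  ref <- e1071::naiveBayes(x, factor(y, lev))
  theirs <- as.integer(predict(ref, x, threshold = 0, eps = 0) == "coding")
  expect_identical(ours, theirs)
})

test_that("cORF 0/1 scoring covers every cORF", {
  set.seed(42)
  m <- trainCodingModel(makeCodingDataset(
    randomPeptides(200, c(30, 80), freqs = proteinAAFrequencies()),
    randomPeptides(200, c(30, 80)), seed = 5))
  ct <- enumerateCorfs(c(c3 = "ATGGCAGCT", c1 = "ATGAAATAA"))
  sc <- scoreCorfs(ct, m)
  expect_identical(nrow(sc), nrow(corfTable(ct)))
  expect_true(all(sc$coding_score %in% c(0L, 1L)))
  empty <- methods::new("CorfSet", table = corfTable(ct)[0, ],
                        config = corfConfig())
  expect_identical(nrow(scoreCorfs(empty, m)), 0L)
})

test_that("IRES labelling uses a strict 0.5 threshold and drops nothing", {
  s <- c(a = 0.51, b = 0.49, c = 0.5, d = 0, e = 1)
  lab <- labelIres(s)
  expect_identical(unname(lab), c("IRES", "Non-IRES", "Non-IRES",
                                  "Non-IRES", "IRES"))
  expect_identical(length(lab), length(s))   # a partition, nothing dropped
  expect_identical(sum(lab == "IRES") + sum(lab == "Non-IRES"), length(s))
  expect_error(labelIres(c(a = 1.2)), "0, 1")
  expect_error(labelIres(c(a = -0.1)), "0, 1")
})

test_that("the six classes enumerate the 3x2 grid injectively", {
  groups <- c("less than one lap", "less than two laps", "more than two laps")
  labels <- c("IRES", "Non-IRES")
  grid <- expand.grid(group = groups, ires = labels,
                      stringsAsFactors = FALSE)
  cls <- classifyCirc(grid$group, grid$ires)
  expect_identical(sort(cls), c("I", "II", "III", "IV", "V", "VI"))
  expect_identical(classifyCirc("less than one lap", "IRES"), "I")
  expect_identical(classifyCirc("more than two laps", "Non-IRES"), "VI")
  expect_error(classifyCirc("seven laps", "IRES"), "unknown lap group")
  expect_error(classifyCirc("less than one lap", "MAYBE"), "unknown IRES")
})

test_that("IRES score tables read as named numeric vectors", {
  f <- withr::local_tempfile()
  writeLines(c("circA\t0.73", "circB\t0.20"), f)
  s <- readIresScores(f)
  expect_equal(s, c(circA = 0.73, circB = 0.20))
})
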