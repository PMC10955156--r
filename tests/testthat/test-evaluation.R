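test_that("negative sampling draws exactly ratio x positives, per seed", {
  set.seed(100)
  Y <- matrix(0, 20, 30)
  Y[sample(600, 20)] <- 1
  s10 <- sampleNegatives(Y, ratio = 10, seed = 1)
  expect_identical(sum(s10$label == 0), 200L)
  expect_identical(sum(s10$label == 1), 20L)
  s1 <- sampleNegatives(Y, ratio = 1, seed = 1)
  expect_identical(sum(s1$label == 0), 20L)

  # positives are exactly the label entries; negatives absent from them
  expect_true(all(Y[cbind(s10$drug, s10$protein)[s10$label == 1, ]] == 1))
  expect_true(all(Y[cbind(s10$drug, s10$protein)[s10$label == 0, ]] == 0))
  expect_false(anyDuplicated(s10[c("drug", "protein")]) > 0)

  expect_identical(sampleNegatives(Y, 10, seed = 7),
                   sampleNegatives(Y, 10, seed = 7))
  expect_false(identical(sampleNegatives(Y, 10, seed = 7)$drug,
                         sampleNegatives(Y, 10, seed = 8)$drug))
})

test_that("negative exhaustion takes all remaining pairs with a warning", {
  Y <- matrix(1, 3, 3); Y[2, 2] <- 0
  expect_warning(s <- sampleNegatives(Y, ratio = 10, seed = 1), "available")
  expect_identical(sum(s$label == 0), 1L)
  expect_error(sampleNegatives(Y, ratio = 0.5), ">= 1")
})

test_that("folds are stratified, balanced and deterministic", {
  set.seed(101)
  Y <- matrix(0, 10, 20)
  Y[sample(200, 10)] <- 1
  s <- sampleNegatives(Y, ratio = 1, seed = 2)  # 10 pos + 10 neg
  folds <- kfoldSplit(s, k = 10, seed = 3)
  for (f in folds) {
    expect_length(f, 2)
    expect_identical(sort(s$label[f]), c(0L, 1L))
  }
  expect_identical(kfoldSplit(s, k = 10, seed = 3), kfoldSplit(s, k = 10, seed = 3))
  expect_identical(sort(unlist(folds)), seq_len(20))  # partition

  # 1100 pairs over 10 folds -> 110 each
  Y2 <- matrix(0, 25, 48)
  set.seed(5); Y2[sample(1200, 100)] <- 1
  s2 <- sampleNegatives(Y2, ratio = 10, seed = 4)
  folds2 <- kfoldSplit(s2, k = 10, seed = 5)
  expect_identical(lengths(folds2), rep(110L, 10))

  expect_error(kfoldSplit(s[s$label == 0, ], k = 10, seed = 1),
               "stratification")
})

test_that("ranking metrics match hand values and conventions", {
  m <- rankingMetrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(m[["auroc"]], 0.75)  # 3 of 4 positive-negative pairs won

  perfect <- rankingMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect[["auroc"]], 1)
  expect_equal(perfect[["aupr"]], 1)

  ties <- rankingMetrics(rep(0.5, 10), c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(ties[["auroc"]], 0.5)

  expect_error(rankingMetrics(c(1, 2), c(1, 1)), "undefined metric")
})

test_that("ranking metrics equal brute-force oracles on 200 random vectors", {
  set.seed(102)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    m <- rankingMetrics(scores, labels)
    expect_equal(m[["auroc"]], bruteAuroc(scores, labels), tolerance = 1e-12)
    expect_equal(m[["aupr"]], bruteAupr(scores, labels), tolerance = 1e-12)
    # sharp lower bound: the worst ranking puts all negatives on top, so
    # AUPR >= (1/P) sum_t t/(N+t) for P positives and N negatives
    P <- sum(labels); N <- n - P
    worst <- mean(seq_len(P) / (N + seq_len(P)))
    expect_gte(m[["aupr"]], worst - 1e-12)
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(103)
  for (i in 1:10) {
    scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
    if (sum(labels) %in% c(0, 40)) next
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(rankingMetrics(scores, labels)[["auroc"]], ref,
                 tolerance = 1e-10)
  }
})

test_that("the redundancy filter applies the threshold rules", {
  # vacuous: orthogonal similarities remove nothing
  Y <- matrix(0, 4, 4); Y[1, 1] <- Y[2, 2] <- 1
  noSim <- diag(4)
  out <- redundancyFilter(Y, drugSims = list(chemical = noSim),
                          proteinSims = list(sequence = noSim))
  expect_identical(out$Y, Y)
  expect_identical(nrow(out$removed), 0L)

  # two positives sharing a protein with chemically similar drugs: drop one
  Y2 <- matrix(0, 3, 3); Y2[1, 2] <- Y2[2, 2] <- 1
  chem <- diag(3); chem[1, 2] <- chem[2, 1] <- 0.9
  out2 <- redundancyFilter(Y2, drugSims = list(chemical = chem))
  expect_identical(sum(out2$Y), 1)
  expect_identical(out2$Y[1, 2], 1)  # lexicographically first kept
  expect_identical(out2$removed$drug, 2L)

  # below threshold: kept
  chem[1, 2] <- chem[2, 1] <- 0.6
  expect_identical(sum(redundancyFilter(Y2, drugSims = list(chemical = chem))$Y), 2)

  # protein rule: shared drug with sequence identity over 0.4
  Y3 <- matrix(0, 3, 3); Y3[1, 1] <- Y3[1, 3] <- 1
  seqs <- diag(3); seqs[1, 3] <- seqs[3, 1] <- 0.5
  out3 <- redundancyFilter(Y3, proteinSims = list(sequence = seqs))
  expect_identical(out3$Y[1, 3], 0)

  expect_error(redundancyFilter(Y3), "configuration error")
})

test_that("the filter satisfies the exhaustive-pairs certificate", {
  set.seed(104)
  for (rep in 1:5) {
    n <- 8; m <- 7
    Y <- matrix(rbinom(n * m, 1, 0.25), n)
    mk <- function(nn) {
      s <- matrix(runif(nn * nn), nn); s <- (s + t(s)) / 2; diag(s) <- 1; s
    }
    dS <- list(chemical = mk(n), disease = mk(n))
    pS <- list(sequence = mk(m))
    out <- redundancyFilter(Y, drugSims = dS, proteinSims = pS,
                            drugThreshold = 0.6, proteinThreshold = 0.4)
    expect_true(checkRedundancyCertificate(Y, out$Y, dS, pS, 0.6, 0.4))
    expect_equal(sum(Y) - sum(out$Y), nrow(out$removed))
    # deterministic
    out2 <- redundancyFilter(Y, drugSims = dS, proteinSims = pS)
    expect_identical(out$Y, out2$Y)
  }
})

test_that("cross-validation produces a coherent report without leakage", {
  sim <- tinyDataset()
  rep <- crossValidate(sim$set, fastCvConfig())
  df <- perFold(rep)
  expect_identical(nrow(df), 5L)
  expect_true(all(df$auroc >= 0 & df$auroc <= 1))
  expect_true(all(df$aupr >= 0 & df$aupr <= 1))
  s <- summary(rep)
  expect_named(s, c("meanAUROC", "sdAUROC", "meanAUPR", "sdAUPR",
                    "folds", "ratio"))

  # determinism end to end
  rep2 <- crossValidate(sim$set, fastCvConfig())
  expect_identical(perFold(rep), perFold(rep2))

  # both sampling ratios run and report both metrics
  rep1 <- crossValidate(sim$set, fastCvConfig(cv = list(ratio = 1)))
  expect_equal(summary(rep1)$ratio, 1)
})

test_that("held-out labels cannot reach the inventory or embeddings", {
  sim <- tinyDataset()
  inv <- buildInventory(sim$set)
  e1 <- embedNodeType(drugNetworks(inv), d = 5)
  set2 <- sim$set
  y <- set2@associations$drug_protein
  y@matrix[] <- 0  # erase every label
  set2@associations$drug_protein <- y
  inv2 <- buildInventory(set2)
  e2 <- embedNodeType(drugNetworks(inv2), d = 5)
  expect_identical(features(e1), features(e2))
})
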