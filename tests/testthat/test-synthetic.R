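test_that("generation is fully deterministic per seed", {
  a <- simulateHetNet(syntheticConfig(nDrugs = 12L, nProteins = 15L,
                                      nDiseases = 6L, nSideEffects = 5L))
  b <- simulateHetNet(syntheticConfig(nDrugs = 12L, nProteins = 15L,
                                      nDiseases = 6L, nSideEffects = 5L))
  expect_identical(labelMatrix(a$set), labelMatrix(b$set))
  expect_identical(a$factors, b$factors)
  expect_identical(as.matrix(a$set@precomputed$drug_chemical),
                   as.matrix(b$set@precomputed$drug_chemical))
  c2 <- simulateHetNet(syntheticConfig(nDrugs = 12L, nProteins = 15L,
                                       nDiseases = 6L, nSideEffects = 5L,
                                       seed = 8L))
  expect_false(identical(labelMatrix(a$set), labelMatrix(c2$set)))
})

test_that("noise-free rank-1 labels are an exact thresholded factor product", {
  cfg <- syntheticConfig(nDrugs = 20L, nProteins = 25L, latentRank = 1L,
                         labelNoise = 0, assocNoise = 0, simNoise = 0)
  sim <- simulateHetNet(cfg)
  sc <- sim$factors$drug %*% t(sim$factors$protein)
  cut <- quantile(sc, 1 - cfg$densities$label)
  expect_identical(unname(sim$noiselessY), (sc > cut) * 1)
  expect_identical(unname(labelMatrix(sim$set)), unname(sim$noiselessY))
})

test_that("every generated matrix passes the container validators", {
  sim <- tinyDataset()
  expect_true(validObject(sim$set))
  for (a in c(sim$set@associations, sim$set@intraType))
    expect_true(validObject(a))
  for (s in sim$set@precomputed) expect_true(validObject(s))
  null <- simulateHetNet(syntheticConfig(nDrugs = 12L, nProteins = 15L,
                                         structured = FALSE))
  expect_true(validObject(null$set))
  expect_null(null$factors)
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulateHetNet(syntheticConfig(latentRank = 100L)),
               "latentRank")
  expect_error(simulateHetNet(syntheticConfig(labelNoise = 1)), "labelNoise")
  expect_error(syntheticConfig(bogus = 1), "unknown configuration key")
  cfgBad <- syntheticConfig()
  cfgBad$densities$label <- 0
  expect_error(simulateHetNet(cfgBad), "densities")
})

test_that("degrade is the identity when asked to change nothing", {
  sim <- tinyDataset()
  d <- degradeHetNet(sim)
  expect_identical(labelMatrix(d$set), labelMatrix(sim$set))
  expect_identical(d$networks$drug, c("chemical", "drug_drug", "drug_disease",
                                      "drug_side_effect"))
})

test_that("dropping a network clears it and shrinks the inventory hint", {
  sim <- tinyDataset()
  d <- degradeHetNet(sim, dropNetwork = "drug_side_effect")
  expect_false("drug_side_effect" %in% d$networks$drug)
  expect_equal(sum(as.matrix(d$set@associations$drug_side_effect)), 0)
  inv <- buildInventory(d$set, drugNetworks = d$networks$drug,
                        proteinNetworks = d$networks$protein)
  expect_length(drugNetworks(inv), 3)
  expect_error(degradeHetNet(sim, dropNetwork = "drug_protein"),
               "unknown network")
})

test_that("extra label noise flips labels reproducibly", {
  sim <- tinyDataset()
  d1 <- degradeHetNet(sim, extraLabelNoise = 0.2, seed = 5)
  d2 <- degradeHetNet(sim, extraLabelNoise = 0.2, seed = 5)
  expect_identical(labelMatrix(d1$set), labelMatrix(d2$set))
  expect_gt(sum(labelMatrix(d1$set) != labelMatrix(sim$set)), 0)
})

test_that("the pipeline recovers planted signal across generator seeds", {
  aurocs <- vapply(1:3, function(s) {
    sim <- simulateHetNet(syntheticConfig(seed = as.integer(100 + s)))
    cfg <- list(embedding = list(dDrug = 10L, dProtein = 16L),
                train = list(epochs = 300L),
                cv = list(folds = 5L, ratio = 5))
    summary(crossValidate(sim$set, cfg))$meanAUROC
  }, numeric(1))
  expect_true(all(aurocs > 0.7))  # well above chance, with margin
})

test_that("heavier label noise degrades mean recovery", {
  base <- 0; noisy <- 0
  cfg <- list(embedding = list(dDrug = 8L, dProtein = 12L),
              train = list(epochs = 300L),
              cv = list(folds = 5L, ratio = 5))
  for (s in 1:3) {
    sim <- simulateHetNet(syntheticConfig(seed = as.integer(200 + s)))
    base <- base + summary(crossValidate(sim$set, cfg))$meanAUROC
    deg <- degradeHetNet(sim, extraLabelNoise = 0.3, seed = s)
    # heavy noise can exhaust the negative pool at this ratio; that warning
    # is part of the sampling contract, not a failure
    noisy <- noisy +
      summary(suppressWarnings(crossValidate(deg$set, cfg)))$meanAUROC
  }
  expect_gt(base, noisy)
})
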