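test_that("bilinear scores match scalar and brute-force evaluations", {
  expect_equal(bilinearScores(matrix(0, 3, 2), matrix(rnorm(8), 4, 2),
                              matrix(1, 2, 2), matrix(1, 2, 2)),
               matrix(0, 3, 4), ignore_attr = TRUE)
  expect_equal(bilinearScores(matrix(2), matrix(7), matrix(3), matrix(5))[1, 1],
               210)

  set.seed(90)
  Hd <- matrix(rnorm(12), 4, 3); Hp <- matrix(rnorm(15), 5, 3)
  Dr <- matrix(rnorm(6), 3, 2); Pr <- matrix(rnorm(6), 3, 2)
  S <- bilinearScores(Hd, Hp, Dr, Pr)
  for (i in 1:4) for (j in 1:5)
    expect_equal(S[i, j],
                 drop(Hd[i, , drop = FALSE] %*% Dr %*% t(Pr) %*% t(Hp[j, , drop = FALSE])),
                 tolerance = 1e-12)
  expect_error(bilinearScores(Hd, Hp, Dr[1:2, ], Pr), "does not match")
  expect_error(bilinearScores(Hd, Hp, Dr, Pr[, 1, drop = FALSE]), "differ")
})

test_that("the masked squared loss honours its contract", {
  Y <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(reconstructionLoss(Y, Y), 0)
  expect_equal(reconstructionLoss(matrix(1), matrix(0.5), matrix(1)), 0.25)
  Yrec <- Y; Yrec[1, 2] <- 1e6
  mask <- matrix(1, 2, 2); mask[1, 2] <- 0
  expect_equal(reconstructionLoss(Y, Yrec, mask), 0)
  expect_error(reconstructionLoss(Y, matrix(0, 3, 2)), "shapes differ")
})

test_that("analytic gradients match central finite differences", {
  set.seed(91)
  n <- 4; m <- 5; hd <- 3; hp <- 3; k <- 2
  Xd <- matrix(rnorm(n * hd), n); Xp <- matrix(rnorm(m * hp), m)
  Y <- matrix(rbinom(n * m, 1, 0.4), n)
  mask <- matrix(rbinom(n * m, 1, 0.8), n)
  Ad <- normalizeAdjacency(as.matrix(randomSimilarity(n, 1)))
  Ap <- normalizeAdjacency(as.matrix(randomSimilarity(m, 2)))
  for (activation in c("relu", "sigmoid", "identity")) {
    fixed <- list(Y = Y, mask = mask, Xd = Xd, Xp = Xp, gcnEnabled = TRUE,
                  activation = activation, AXd = Ad %*% Xd, AXp = Ap %*% Xp)
    par <- list(Dr = matrix(rnorm(hd * k), hd), Pr = matrix(rnorm(hp * k), hp),
                Wd = matrix(rnorm(hd * hd), hd), Wp = matrix(rnorm(hp * hp), hp))
    fg <- hetDTI:::.lossAndGrads(par, fixed)
    eps <- 1e-6
    for (nm in names(par)) {
      gNum <- par[[nm]] * 0
      for (idx in seq_along(par[[nm]])) {
        pp <- par; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        pm <- par; pm[[nm]][idx] <- pm[[nm]][idx] - eps
        gNum[idx] <- (hetDTI:::.lossAndGrads(pp, fixed)$loss -
                      hetDTI:::.lossAndGrads(pm, fixed)$loss) / (2 * eps)
      }
      denom <- max(abs(gNum), 1e-8)
      expect_lt(max(abs(fg$grads[[nm]] - gNum)) / denom, 1e-5,
                label = paste("relative gradient error for", nm, activation))
    }
  }
})

test_that("a noiseless planted rank-1 target is fit to near-zero loss", {
  set.seed(92)
  Xd <- matrix(rnorm(24), 12, 2); Xp <- matrix(rnorm(18), 9, 2)
  Dr <- matrix(c(0.7, -0.3), 2, 1); Pr <- matrix(c(0.5, 0.9), 2, 1)
  Y <- Xd %*% Dr %*% t(Pr) %*% t(Xp)  # exactly representable at k = 1
  fit <- trainModel(Y, Xd, Xp, gcnEnabled = FALSE, k = 1, lr = 0.05,
                    epochs = 500L, optimizer = "adam", seed = 3)
  expect_lt(tail(fit$lossTrace, 1), 1e-3)
})

test_that("full-batch descent decreases the loss monotonically", {
  set.seed(93)
  Xd <- matrix(rnorm(24), 12, 2); Xp <- matrix(rnorm(18), 9, 2)
  Y <- (Xd %*% t(Xp) > 1) * 1
  fit <- trainModel(Y, Xd, Xp, gcnEnabled = FALSE, k = 2, lr = 1e-3,
                    epochs = 500L, optimizer = "gd", seed = 3)
  expect_true(all(diff(fit$lossTrace[10:500]) <= 1e-6))
})

test_that("training is bitwise deterministic per seed", {
  sim <- tinyDataset()
  inv <- buildInventory(sim$set)
  ed <- embedNodeType(drugNetworks(inv), d = 5)
  ep <- embedNodeType(proteinNetworks(inv), d = 6)
  Y <- labelMatrix(sim$set)
  f1 <- trainModel(Y, ed, ep, inventory = inv, epochs = 50L, seed = 4)
  f2 <- trainModel(Y, ed, ep, inventory = inv, epochs = 50L, seed = 4)
  expect_identical(f1$lossTrace, f2$lossTrace)
  expect_identical(f1$scores, f2$scores)
  f3 <- trainModel(Y, ed, ep, inventory = inv, epochs = 50L, seed = 5)
  expect_false(identical(f1$lossTrace, f3$lossTrace))
})

test_that("masked-out label entries affect neither loss nor gradients", {
  set.seed(94)
  Xd <- matrix(rnorm(12), 4, 3); Xp <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rbinom(20, 1, 0.5), 4)
  mask <- matrix(1, 4, 5); mask[2, 3] <- 0
  par <- list(Dr = matrix(rnorm(6), 3), Pr = matrix(rnorm(6), 3))
  fixed <- list(Y = Y, mask = mask, Xd = Xd, Xp = Xp, gcnEnabled = FALSE)
  fg1 <- hetDTI:::.lossAndGrads(par, fixed)
  fixed$Y[2, 3] <- 1e9
  fg2 <- hetDTI:::.lossAndGrads(par, fixed)
  expect_identical(fg1$loss, fg2$loss)
  expect_identical(fg1$grads, fg2$grads)
})

test_that("divergence raises an actionable error", {
  set.seed(95)
  Xd <- matrix(rnorm(40) * 10, 20, 2); Xp <- matrix(rnorm(40) * 10, 20, 2)
  Y <- matrix(1, 20, 20)
  expect_error(trainModel(Y, Xd, Xp, gcnEnabled = FALSE, lr = 10,
                          epochs = 200L, optimizer = "gd", seed = 1),
               "smaller learning rate")
})
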