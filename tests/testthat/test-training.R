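test_that("loss primitives match their closed forms", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(kldLoss(p, p), 0)
  expect_equal(kldLoss(c(1, 0), c(0.5, 0.5)), log(2))
  ## zero-observed terms contribute nothing even at predicted 0
  expect_equal(kldLoss(c(1, 0), c(1, 0)), 0)
  expect_true(kldLoss(randomSimplex(5), randomSimplex(5)) >= 0)
  expect_error(kldLoss(c(1, 0), c(1, 0, 0)), "length mismatch")
  expect_equal(mseLoss(p, p), 0)
  expect_equal(mseLoss(c(0, 1), c(1, 0)), 1)
  a <- runif(4); b <- runif(4)
  expect_equal(mseLoss(a, b), mseLoss(b, a))
})

test_that("training config validates and fills loss-specific defaults", {
  expect_equal(trainConfig("kld")$learning_rate, 0.05)
  expect_equal(trainConfig("mse")$learning_rate, 0.01)
  cfg <- trainConfig("kld")
  expect_equal(cfg$adam_beta1, 0.99)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$lr_decay_gamma, 0.999)
  expect_equal(cfg$batch_size, 200L)
  expect_equal(cfg$early_stop_patience, 2L)
  expect_error(trainConfig("kld", learning_rate = -1))
  expect_error(trainConfig("kld", lr_decay_gamma = 0))
})

test_that("zero training steps leave parameters at initialization", {
  scr <- smallScreen()
  cfg <- trainConfig("kld", max_epochs = 0L, seed = 6)
  fit <- trainDeletionModel(scr$profiles[1:3], scr$catalogues, cfg)
  expect_equal(fit$net@W1, newDeletionNet(6)@W1)
  expect_equal(nrow(fit$history), 0)
})

test_that("training decreases the loss and is seed-reproducible", {
  scr <- smallScreen()
  profiles <- scr$profiles[1:12]
  cfg <- trainConfig("kld", max_epochs = 12L, seed = 3)
  fit1 <- trainDeletionModel(profiles, scr$catalogues, cfg)
  fit2 <- trainDeletionModel(profiles, scr$catalogues, cfg)
  ## bitwise-identical trajectory under the same seed
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$net@W2, fit2$net@W2)
  h <- fit1$history$train_loss
  expect_lt(h[length(h)], h[1])
  ## a different seed gives a different trajectory
  fit3 <- trainDeletionModel(profiles, scr$catalogues,
                             trainConfig("kld", max_epochs = 12L, seed = 4))
  expect_false(identical(fit1$history$train_loss, fit3$history$train_loss))
})

test_that("single-target training strictly reduces that target's loss", {
  scr <- smallScreen()
  tid <- names(scr$profiles)[1]
  cfg <- trainConfig("kld", max_epochs = 10L, seed = 2,
                     validation_fraction = 0)
  fit <- trainDeletionModel(scr$profiles[tid], scr$catalogues, cfg)
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
})

test_that("parameter norm is non-increasing in the L2 penalty", {
  scr <- smallScreen()
  profiles <- scr$profiles[1:15]
  norms <- vapply(c(0, 1e-2, 1), function(l2) {
    cfg <- trainConfig("kld", max_epochs = 15L, seed = 8, l2_lambda = l2,
                       validation_fraction = 0)
    net <- trainDeletionModel(profiles, scr$catalogues, cfg)$net
    sqrt(sum(net@W1^2) + sum(net@W2^2) + sum(net@W3^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("linear models fit degenerate data and honour the patience contract", {
  scr <- smallScreen()
  profiles <- scr$profiles[1:15]
  ## rebuild all-deletion profiles: zero out insertion mass
  allDel <- lapply(profiles, function(p) {
    f <- frequencies(p)
    f[grepl("^ins:", names(f))] <- 0
    new("RepairProfile", targetId = targetId(p), frequencies = f / sum(f),
        nMutatedReads = nMutatedReads(p))
  })
  expect_error(trainLinearModels(allDel, scr$windows, fastConfig("mse")),
               "insertion outcomes")
  ## keep one profile with insertions so the insertion model can train
  mixed <- c(allDel[-1], profiles[1])
  fit <- trainLinearModels(mixed, scr$windows,
                           trainConfig("mse", max_epochs_linear = 25L,
                                       seed = 2))
  ## ratio model driven to near-pure deletion on its training inputs
  pDel <- vapply(names(mixed), function(tid)
    indelRatio(scr$windows[[tid]], fit$ratioModel)[["deletion"]], 0)
  expect_gt(mean(pDel), 0.9)
  ## early stopping: stops within patience epochs of the best epoch
  best <- which.min(fit$insertionHistory)
  expect_lte(length(fit$insertionHistory), best + 2)
})

test_that("insertion model recovers the planted upstream-base preference", {
  scr <- cached("insScreen", simulateScreen(120, seed = 33))
  fit <- trainLinearModels(scr$profiles, scr$windows,
                           trainConfig("mse", max_epochs_linear = 60L,
                                       seed = 1))
  ## targets whose base upstream of the cut is A should rank ins:A first
  ## among single-nucleotide insertions (generator's self-boost)
  hits <- 0L; total <- 0L
  for (tid in names(scr$profiles)) {
    up <- substr(windowSequence(scr$windows[[tid]]), 30, 30)
    q <- insertionDistribution(scr$windows[[tid]], fit$insertionModel)
    singles <- q[paste0("ins:", c("A", "C", "G", "T"))]
    total <- total + 1L
    if (names(which.max(singles)) == paste0("ins:", up)) hits <- hits + 1L
  }
  expect_gt(hits / total, 0.8)
})

test_that("cross-validation selects by mean fold loss with deterministic ties", {
  scr <- smallScreen()
  profiles <- scr$profiles[1:15]
  cfgBase <- trainConfig("kld", max_epochs = 6L, seed = 5,
                         validation_fraction = 0)
  one <- crossValidate(profiles, scr$catalogues,
                       grid = list(list(l2_lambda = 1e-5)),
                       k = 3L, seed = 1, config = cfgBase)
  expect_equal(one$bestIndex, 1L)
  ## duplicate grid points tie-break to the first
  dup <- crossValidate(profiles, scr$catalogues,
                       grid = list(list(l2_lambda = 1e-5),
                                   list(l2_lambda = 1e-5)),
                       k = 3L, seed = 1, config = cfgBase)
  expect_equal(dup$bestIndex, 1L)
  expect_equal(dup$table$mean_loss[1], dup$table$mean_loss[2])
  ## an absurd penalty collapses the model and loses the comparison
  huge <- crossValidate(profiles, scr$catalogues,
                        grid = list(list(l2_lambda = 10),
                                    list(l2_lambda = 1e-5)),
                        k = 3L, seed = 1, config = cfgBase)
  expect_equal(huge$bestIndex, 2L)
  expect_error(crossValidate(profiles[1:3], scr$catalogues,
                             grid = list(list(l2_lambda = 0)), k = 5L),
               "fewer profiles than folds")
  expect_error(crossValidate(profiles, scr$catalogues, grid = list()),
               "empty")
})
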