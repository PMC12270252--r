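## Losses, Adam optimisation with per-epoch exponential learning-rate
## decay, L2 regularisation, early stopping, and 5-fold cross-validated
## hyperparameter selection for the three submodels.
##
## The deletion net is trained against deletion-conditional observed
## frequencies (renormalized over deletion outcomes). Under the KLD loss
## the gradient flows through the per-target sum-normalization of the
## independent sigmoid scores (for scores s_i, total S, q_i = s_i / S:
## dL/ds_i = (1 - p_i/q_i) / S). Under the MSE loss each outcome's raw
## sigmoid score regresses the per-target max-normalized conditional
## frequency p_i / max_t(p) (dL/ds_i = 2 (s_i - p_i/max) / n). The
## sum-normalization is scale-invariant, so coupling MSE through it
## leaves the score scale as a loss-null direction along which
## adaptive-step optimisers drift into sigmoid saturation, while raw
## frequencies (all near zero on 300-500-outcome targets) would pin the
## regression into the sigmoid's flat tail; the max-normalized target
## spans (0, 1], keeps sigmoid gradients healthy, and recovers the same
## predicted distribution after prediction-time normalization since
## q is proportional to p / max(p).

#' Kullback-Leibler divergence loss
#'
#' `sum(observed * log(observed / predicted))` in natural log units;
#' zero-observed terms contribute 0, predicted is floored at 1e-12.
#'
#' @param observed,predicted simplex vectors on the same support.
#' @return non-negative scalar.
#' @export
kldLoss <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  pos <- observed > 0
  sum(observed[pos] * log(observed[pos] / pmax(predicted[pos], EPS)))
}

#' Mean-squared-error loss
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
mseLoss <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  mean((observed - predicted)^2)
}

#' Training configuration
#'
#' Defaults follow the model's training recipe: Adam with beta1 = 0.99 and
#' beta2 = 0.999, batch size 200 targets, learning rate 0.05 for the KLD
#' loss and 0.01 for MSE, exponential learning-rate decay gamma = 0.999
#' per epoch, L2 regularisation, a 10% seeded validation split with
#' best-epoch selection for the deletion net, and a 200-epoch cap with
#' patience-2 early stopping for the linear submodels.
#'
#' @param loss "kld" or "mse" (deletion-net loss; the linear submodels
#'   always train on MSE).
#' @param learning_rate defaults to 0.05 for kld, 0.01 for mse.
#' @param batch_size targets per minibatch.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param lr_decay_gamma per-epoch exponential decay factor.
#' @param l2_lambda L2 penalty weight.
#' @param max_epochs deletion-net epoch budget.
#' @param max_epochs_linear linear-model epoch cap.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (linear models).
#' @param validation_fraction fraction of training targets held out for
#'   validation-based selection.
#' @param seed integer seed controlling initialization and batch order.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(loss = c("kld", "mse"), learning_rate = NULL,
                        batch_size = 200L, adam_beta1 = 0.99,
                        adam_beta2 = 0.999, lr_decay_gamma = 0.999,
                        l2_lambda = 1e-5, max_epochs = 100L,
                        max_epochs_linear = 200L, early_stop_patience = 2L,
                        validation_fraction = 0.1, seed = 1L) {
  loss <- match.arg(loss)
  if (is.null(learning_rate))
    learning_rate <- if (loss == "kld") 0.05 else 0.01
  stopifnot(learning_rate > 0, lr_decay_gamma > 0, lr_decay_gamma <= 1,
            l2_lambda >= 0, batch_size >= 1L, max_epochs >= 0L)
  structure(list(loss = loss, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 lr_decay_gamma = lr_decay_gamma, l2_lambda = l2_lambda,
                 max_epochs = as.integer(max_epochs),
                 max_epochs_linear = as.integer(max_epochs_linear),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

## ---- Adam ---------------------------------------------------------------

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(state, params, grads, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mh <- state$m[[k]] / (1 - b1^state$t)
    vh <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

netToParams <- function(net)
  list(W1 = net@W1, b1 = net@b1, W2 = net@W2, b2 = net@b2,
       W3 = net@W3, b3 = net@b3)

paramsToNet <- function(p)
  new("DeletionNet", W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
      W3 = p$W3, b3 = p$b3)

## ---- deletion model -----------------------------------------------------

## stack deletion-conditional training data; drops targets with zero
## deletion mass
assembleDeletionData <- function(profiles, catalogues) {
  keep <- character(); Xs <- list(); Ps <- list()
  for (tid in names(profiles)) {
    cat <- catalogues[[tid]]
    if (is.null(cat)) stop("no catalogue for training target '", tid, "'")
    delIds <- cat@deletions$outcome_id
    f <- frequencies(profiles[[tid]])[delIds]
    mass <- sum(f)
    if (!is.finite(mass) || mass <= 0) next
    keep <- c(keep, tid)
    Xs[[tid]] <- featurizeDeletions(cat)
    Ps[[tid]] <- unname(f / mass)
  }
  if (!length(keep)) stop("no training targets with deletion outcomes")
  nrows <- vapply(Xs, nrow, 0L)
  p <- unlist(Ps, use.names = FALSE)
  rowIndex <- split(seq_len(sum(nrows)), rep(seq_along(keep), nrows))
  ## per-target max-normalized frequencies: regression target of the MSE
  ## variant
  pMax <- p
  for (rows in rowIndex) pMax[rows] <- pMax[rows] / max(pMax[rows])
  list(targets = keep, X = do.call(rbind, Xs), p = p, pMax = pMax,
       rowIndex = rowIndex)
}

## mean per-target training loss: KLD on the normalized distribution,
## MSE on the raw per-outcome scores
deletionDataLoss <- function(params, data, targets, loss) {
  net <- paramsToNet(params)
  tot <- 0
  for (t in targets) {
    rows <- data$rowIndex[[t]]
    s <- delForward(net, data$X[rows, , drop = FALSE])$s
    tot <- tot + if (loss == "kld") kldLoss(data$p[rows],
                                            deletionDistribution(s))
                 else mseLoss(data$pMax[rows], s)
  }
  tot / length(targets)
}

#' Train the deletion model
#'
#' Mini-batch Adam with per-epoch exponential learning-rate decay and L2
#' penalty. The KLD variant compares observed deletion-conditional
#' frequencies with the normalized predicted deletion distribution of
#' each target; the MSE variant regresses each outcome's raw sigmoid
#' score on the per-target max-normalized conditional frequency (which
#' yields the same distribution after normalization while keeping the
#' regression inside the sigmoid's responsive range; the MSE variant
#' converges more slowly and benefits from a larger epoch budget). With a
#' validation split, the epoch with the lowest validation loss is kept.
#' Fully reproducible under a fixed config seed.
#'
#' @param profiles named list of training [RepairProfile-class].
#' @param catalogues named list of matching [OutcomeCatalogue-class].
#' @param config a [trainConfig()].
#' @param net optional starting [DeletionNet-class] (transfer learning);
#'   defaults to seeded random initialization.
#' @param frozenLayers subset of c("hidden1", "hidden2") held fixed.
#' @return list: `net` (trained [DeletionNet-class]), `history` (per-epoch
#'   train/validation loss data.frame).
#' @export
trainDeletionModel <- function(profiles, catalogues, config = trainConfig(),
                               net = NULL, frozenLayers = character()) {
  stopifnot(inherits(config, "trainConfig"),
            all(frozenLayers %in% c("hidden1", "hidden2")))
  if (!length(profiles)) stop("empty training set")
  data <- assembleDeletionData(profiles, catalogues)
  set.seed(config$seed)
  if (is.null(net)) {
    net <- newDeletionNet(config$seed)
    ## base-rate output-bias initialization for the score regression:
    ## starting at the mean target avoids the large early updates that
    ## can saturate the hidden layers and trap the net at the
    ## mean-prediction plateau
    if (config$loss == "mse")
      net@b3 <- qlogis(min(max(mean(data$pMax), 1e-6), 1 - 1e-6))
  }
  params <- netToParams(net)
  nT <- length(data$targets)
  tids <- seq_len(nT)
  nVal <- if (config$validation_fraction > 0 && nT >= 10L)
    max(1L, round(config$validation_fraction * nT)) else 0L
  valT <- if (nVal) sample(tids, nVal) else integer()
  trT <- setdiff(tids, valT)
  frozenNames <- c(if ("hidden1" %in% frozenLayers) c("W1", "b1"),
                   if ("hidden2" %in% frozenLayers) c("W2", "b2"))
  opt <- adamInit(params)
  best <- list(loss = Inf, params = params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (config$max_epochs == 0L)
    return(list(net = paramsToNet(params), history = history))
  for (epoch in seq_len(config$max_epochs)) {
    lrE <- config$learning_rate * config$lr_decay_gamma^(epoch - 1)
    order <- sample(trT)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    epochLoss <- 0
    for (batch in batches) {
      rows <- unlist(data$rowIndex[batch], use.names = FALSE)
      grp <- rep(seq_along(batch),
                 vapply(data$rowIndex[batch], length, 0L))
      Xb <- data$X[rows, , drop = FALSE]
      pb <- if (config$loss == "kld") data$p[rows] else data$pMax[rows]
      fw <- delForward(paramsToNet(params), Xb)
      nB <- length(batch)
      if (config$loss == "kld") {
        S <- as.numeric(rowsum(fw$s, grp))
        Sg <- S[grp]
        qc <- pmax(fw$s / Sg, EPS)
        pos <- pb > 0
        epochLoss <- epochLoss + sum(pb[pos] * log(pb[pos] / qc[pos]))
        ds <- (1 - pb / qc) / Sg / nB
      } else {
        nPer <- tabulate(grp, nbins = nB)
        epochLoss <- epochLoss + sum((fw$s - pb)^2 / nPer[grp])
        ds <- 2 * (fw$s - pb) / nPer[grp] / nB
      }
      ## backprop through the all-sigmoid stack
      dz3 <- ds * fw$s * (1 - fw$s)
      gW3 <- crossprod(fw$h2, dz3) + config$l2_lambda * params$W3
      gb3 <- sum(dz3)
      dh2 <- outer(dz3, as.numeric(params$W3))
      dz2 <- dh2 * fw$h2 * (1 - fw$h2)
      gW2 <- crossprod(fw$h1, dz2) + config$l2_lambda * params$W2
      gb2 <- colSums(dz2)
      dh1 <- dz2 %*% t(params$W2)
      dz1 <- dh1 * fw$h1 * (1 - fw$h1)
      gW1 <- crossprod(Xb, dz1) + config$l2_lambda * params$W1
      gb1 <- colSums(dz1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3)
      for (k in frozenNames) grads[[k]] <- grads[[k]] * 0
      up <- adamStep(opt, params, grads, lrE, config$adam_beta1,
                     config$adam_beta2)
      opt <- up$state
      params <- up$params
      for (k in frozenNames) params[[k]] <- netToParams(net)[[k]]
    }
    trainLoss <- epochLoss / length(trT)
    valLoss <- if (nVal) deletionDataLoss(params, data, valT, config$loss)
               else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = trainLoss,
                                         val_loss = valLoss))
    sel <- if (nVal) valLoss else trainLoss
    if (sel < best$loss) best <- list(loss = sel, params = params)
  }
  list(net = paramsToNet(best$params), history = history)
}

## ---- linear models ------------------------------------------------------

## softmax regression trained on MSE between softmax output and target
## rows, Adam + decay, early stopping on a seeded validation split
trainSoftmax <- function(X, Y, classes, config, model = NULL,
                         learningRate = NULL, maxEpochs = NULL) {
  n <- nrow(X)
  if (n == 0L) stop("empty training set")
  lr0 <- learningRate %||% 0.01
  maxEpochs <- maxEpochs %||% config$max_epochs_linear
  if (is.null(model))
    model <- newSoftmaxRegression(ncol(X), classes, config$seed)
  params <- list(W = model@W, b = model@b)
  nVal <- if (config$validation_fraction > 0 && n >= 10L)
    max(1L, round(config$validation_fraction * n)) else 0L
  val <- if (nVal) sample(seq_len(n), nVal) else integer()
  tr <- setdiff(seq_len(n), val)
  evalLoss <- function(p, idx) {
    P <- softmax(sweep(X[idx, , drop = FALSE] %*% p$W, 2L, p$b, `+`))
    mean((P - Y[idx, , drop = FALSE])^2)
  }
  opt <- adamInit(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric()
  for (epoch in seq_len(maxEpochs)) {
    lrE <- lr0 * config$lr_decay_gamma^(epoch - 1)
    order <- sample(tr)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    for (batch in batches) {
      Xb <- X[batch, , drop = FALSE]
      Yb <- Y[batch, , drop = FALSE]
      P <- softmax(sweep(Xb %*% params$W, 2L, params$b, `+`))
      G <- 2 * (P - Yb) / ncol(Y)
      dZ <- P * (G - rowSums(G * P))
      grads <- list(W = crossprod(Xb, dZ) / nrow(Xb) +
                      config$l2_lambda * params$W,
                    b = colSums(dZ) / nrow(Xb))
      up <- adamStep(opt, params, grads, lrE, config$adam_beta1,
                     config$adam_beta2)
      opt <- up$state
      params <- up$params
    }
    loss <- if (nVal) evalLoss(params, val) else evalLoss(params, tr)
    history <- c(history, loss)
    if (loss < best$loss) best <- list(loss = loss, params = params,
                                       epoch = epoch)
    if (epoch - best$epoch >= config$early_stop_patience) break
  }
  list(model = new("SoftmaxRegression", W = best$params$W,
                   b = best$params$b, classes = classes),
       history = history, stopped_epoch = length(history),
       best_epoch = best$epoch)
}

## encoded inputs + conditional targets for the two linear submodels
assembleLinearData <- function(profiles, windows) {
  insIds <- enumerateInsertions()$outcome_id
  tids <- names(profiles)
  Xins <- NULL; Yins <- NULL; Xr <- NULL; Yr <- NULL
  insRows <- character()
  for (tid in tids) {
    w <- windows[[tid]]
    if (is.null(w)) stop("no window for training target '", tid, "'")
    f <- frequencies(profiles[[tid]])
    insMass <- sum(f[insIds])
    xr <- encodeMonoDi(substr(windowSequence(w), PROTO_START, PROTO_END))
    Xr <- rbind(Xr, xr)
    Yr <- rbind(Yr, c(1 - insMass, insMass))
    if (insMass > 0) {
      insRows <- c(insRows, tid)
      Xins <- rbind(Xins, encodeMonoDi(substr(windowSequence(w), 28L, 33L)))
      Yins <- rbind(Yins, unname(f[insIds]) / insMass)
    }
  }
  list(Xins = Xins, Yins = Yins, insTargets = insRows,
       Xr = Xr, Yr = Yr, ratioTargets = tids)
}

#' Train the insertion and deletion-insertion submodels
#'
#' The insertion model is fitted to observed insertion-conditional
#' frequencies over the 21 outcomes; the deletion-insertion model to the
#' observed (deletion, insertion) mass split. Both use Adam with
#' exponential learning-rate decay, L2 penalty, a 200-epoch cap and early
#' stopping with patience 2 on a seeded validation split.
#'
#' @inheritParams trainDeletionModel
#' @param windows named list of [TargetWindow-class] for the profiles.
#' @param insertionModel,ratioModel optional starting models (transfer
#'   learning).
#' @return list with `insertionModel`, `ratioModel`
#'   ([SoftmaxRegression-class]) and their training histories.
#' @export
trainLinearModels <- function(profiles, windows, config = trainConfig("mse"),
                              insertionModel = NULL, ratioModel = NULL) {
  if (!length(profiles)) stop("empty training set")
  set.seed(config$seed + 1L)
  data <- assembleLinearData(profiles, windows)
  if (is.null(data$Xins))
    stop("no training targets with insertion outcomes")
  insFit <- trainSoftmax(data$Xins, data$Yins,
                         enumerateInsertions()$outcome_id, config,
                         model = insertionModel, learningRate = 0.01)
  ratioFit <- trainSoftmax(data$Xr, data$Yr, c("deletion", "insertion"),
                           config, model = ratioModel, learningRate = 0.01)
  list(insertionModel = insFit$model, ratioModel = ratioFit$model,
       insertionHistory = insFit$history, ratioHistory = ratioFit$history)
}

#' Train all three submodels into a bundle
#'
#' @inheritParams trainLinearModels
#' @param catalogues named list of [OutcomeCatalogue-class].
#' @param frozenLayers passed to [trainDeletionModel()].
#' @param bundle optional starting [ModelBundle-class] (transfer learning).
#' @return a trained [ModelBundle-class].
#' @export
trainModelBundle <- function(profiles, windows, catalogues,
                             config = trainConfig(), bundle = NULL,
                             frozenLayers = character()) {
  delFit <- trainDeletionModel(profiles, catalogues, config,
                               net = if (!is.null(bundle)) bundle@deletionNet,
                               frozenLayers = frozenLayers)
  linFit <- trainLinearModels(profiles, windows, config,
    insertionModel = if (!is.null(bundle)) bundle@insertionModel,
    ratioModel = if (!is.null(bundle)) bundle@ratioModel)
  new("ModelBundle", deletionNet = delFit$net,
      insertionModel = linFit$insertionModel,
      ratioModel = linFit$ratioModel, config = bundleConfig())
}

#' 5-fold cross-validated hyperparameter selection
#'
#' Trains the deletion model on each of `k` target-disjoint folds'
#' complements for every grid point and returns the grid point with the
#' lowest mean held-out loss; ties break deterministically by grid order.
#'
#' @param profiles named list of training profiles.
#' @param catalogues matching catalogues.
#' @param grid list of config overrides, e.g.
#'   `list(list(l2_lambda = 0), list(l2_lambda = 1e-4))`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param config base [trainConfig()] the overrides are applied to.
#' @return list: `best` (winning override), `bestIndex`, `table`
#'   (data.frame of mean fold losses per grid point).
#' @export
crossValidate <- function(profiles, catalogues, grid, k = 5L, seed = 1L,
                          config = trainConfig()) {
  if (!length(grid)) stop("empty hyperparameter grid")
  tids <- names(profiles)
  if (length(tids) < k) stop("fewer profiles than folds")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), length(tids)))
  meanLoss <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    cfg <- config
    cfg[names(grid[[gi]])] <- grid[[gi]]
    losses <- numeric(k)
    for (f in seq_len(k)) {
      trIds <- tids[fold != f]
      heldIds <- tids[fold == f]
      fit <- trainDeletionModel(profiles[trIds], catalogues, cfg)
      held <- assembleDeletionData(profiles[heldIds], catalogues)
      losses[f] <- deletionDataLoss(netToParams(fit$net), held,
                                    seq_along(held$targets), cfg$loss)
    }
    meanLoss[gi] <- mean(losses)
  }
  bestIndex <- which.min(meanLoss)  # which.min takes the first on ties
  list(best = grid[[bestIndex]], bestIndex = bestIndex,
       table = data.frame(grid_point = seq_along(grid),
                          mean_loss = meanLoss))
}
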