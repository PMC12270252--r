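## Domain adaptation of a pre-trained bundle: baselines (SO source-only,
## TO target-only) and transfer strategies (FT fine-tune; PF0-2 retrain
## with 0/1/2 frozen hidden layers, then fine-tune). Frozen layers refer
## to the deletion net's hidden layers in forward order; the output layer
## is never frozen. The linear submodels have no hidden layers, so every
## transfer strategy reduces to continued training for them.

TL_SCHEDULE <- c(2L, 5L, 10L, 20L, 50L, 200L, 500L)

frozenForStrategy <- function(strategy)
  switch(strategy, PF1 = "hidden1", PF2 = c("hidden1", "hidden2"),
         character())

#' Construct a transfer plan
#'
#' @param strategy one of "SO", "TO", "FT", "PF0", "PF1", "PF2".
#' @param nTargetSamples target-domain training sample count (the study
#'   schedule uses n in {2, 5, 10, 20, 50, 200, 500}).
#' @param retrainLr retraining learning rate (default: the KLD default
#'   0.05).
#' @param fineTuneLr low fine-tuning learning rate (default retrainLr/10).
#' @param seed seed for sample selection and training.
#' @return a [TransferPlan-class].
#' @export
transferPlan <- function(strategy, nTargetSamples = 50L, retrainLr = 0.05,
                         fineTuneLr = retrainLr / 10, seed = 1L) {
  new("TransferPlan", strategy = strategy,
      nTargetSamples = as.integer(nTargetSamples), retrainLr = retrainLr,
      fineTuneLr = fineTuneLr, frozenLayers = frozenForStrategy(strategy),
      seed = as.integer(seed))
}

#' Nested target-domain sample sets
#'
#' A single seeded permutation of the profile ids is prefixed at each
#' requested size, so each subsequent set is a superset of the preceding
#' one.
#'
#' @param profileIds character vector (or named profile list).
#' @param sizes increasing sample sizes.
#' @param seed integer seed.
#' @return named list of id vectors, one per size.
#' @export
sampleSchedule <- function(profileIds, sizes = TL_SCHEDULE, seed = 1L) {
  if (is.list(profileIds)) profileIds <- names(profileIds)
  if (max(sizes) > length(profileIds))
    stop("insufficient profiles: need ", max(sizes), ", have ",
         length(profileIds))
  set.seed(as.integer(seed))
  perm <- sample(profileIds)
  setNames(lapply(sizes, function(n) perm[seq_len(n)]),
           paste0("n", sizes))
}

#' Adapt a pre-trained bundle to a target domain
#'
#' SO returns the bundle unchanged; TO trains from random initialization
#' on the target samples only; FT continues training all weights at the
#' low fine-tune rate; PF0-2 first retrain with the strategy's frozen
#' layers at the retrain rate, then fine-tune (frozen layers are bitwise
#' unchanged after adaptation). All three submodels are adapted.
#'
#' @param bundle source-trained [ModelBundle-class].
#' @param targetProfiles named list of target-domain profiles (at least
#'   `plan@nTargetSamples`).
#' @param windows,catalogues named lists covering the target profiles.
#' @param plan a [TransferPlan-class].
#' @param config base [trainConfig()] (epoch budget, batch size, ...).
#' @return adapted [ModelBundle-class].
#' @export
adaptModel <- function(bundle, targetProfiles, windows, catalogues, plan,
                       config = trainConfig()) {
  stopifnot(is(plan, "TransferPlan"))
  if (plan@strategy == "SO") return(bundle)
  if (length(targetProfiles) < plan@nTargetSamples)
    stop("n = ", plan@nTargetSamples, " exceeds available target profiles (",
         length(targetProfiles), ")")
  ids <- sampleSchedule(targetProfiles, sizes = plan@nTargetSamples,
                        seed = plan@seed)[[1L]]
  train <- targetProfiles[ids]
  cfg <- config
  cfg$seed <- plan@seed
  if (plan@strategy == "TO") {
    cfg$learning_rate <- plan@retrainLr
    return(trainModelBundle(train, windows, catalogues, cfg))
  }
  frozen <- plan@frozenLayers
  current <- bundle
  if (plan@strategy != "FT") {          # PF0-2: retraining phase
    cfg$learning_rate <- plan@retrainLr
    current <- trainModelBundle(train, windows, catalogues, cfg,
                                bundle = current, frozenLayers = frozen)
  }
  cfg$learning_rate <- plan@fineTuneLr  # fine-tuning phase (FT and PF0-2)
  trainModelBundle(train, windows, catalogues, cfg, bundle = current,
                   frozenLayers = frozen)
}
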