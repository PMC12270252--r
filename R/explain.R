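## Per-prediction feature attributions: exact Shapley values for the
## 5-feature deletion net (2^5 coalition enumeration against a background
## expectation), closed-form attributions for the linear submodels on the
## logit scale, and aggregation of binary sequence encodings back to
## per-position nucleotide/dinucleotide values.

#' Exact Shapley attributions for a deletion-net prediction
#'
#' Enumerates all 2^5 feature coalitions; absent features are marginalized
#' by averaging the net's raw score over background rows substituted into
#' the absent positions. Exact and deterministic; satisfies efficiency
#' (attributions sum to the instance score minus the mean background
#' score).
#'
#' @param net a [DeletionNet-class].
#' @param instance length-5 feature vector (mh_len, mh_gc, gap, left_edge,
#'   right_edge).
#' @param background m x 5 matrix of background feature rows (m >= 1).
#' @return named numeric of 5 attributions, with attributes
#'   `instance_value` and `background_mean`.
#' @export
exactShapleyDeletion <- function(net, instance, background) {
  if (is.null(dim(background))) background <- matrix(background, ncol = 5L)
  if (nrow(background) < 1L) stop("background must have at least one row")
  stopifnot(length(instance) == 5L, ncol(background) == 5L)
  nF <- 5L
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nF)))
  ## coalition value: mean score with coalition features set to the
  ## instance and the rest taken from each background row
  v <- apply(masks, 1L, function(mask) {
    Xb <- background
    if (any(mask)) Xb[, mask] <- rep(instance[mask], each = nrow(Xb))
    mean(deletionScores(Xb, net))
  })
  key <- masks %*% 2^(seq_len(nF) - 1L)
  vOf <- function(mask) v[match(sum(2^(which(mask) - 1L)), key)]
  wgt <- function(s) factorial(s) * factorial(nF - s - 1L) / factorial(nF)
  phi <- numeric(nF)
  for (i in seq_len(nF)) {
    others <- setdiff(seq_len(nF), i)
    for (si in 0:(2^(nF - 1L) - 1L)) {
      mask <- logical(nF)
      mask[others] <- as.logical(bitwAnd(si, 2^(seq_len(nF - 1L) - 1L)))
      withI <- mask; withI[i] <- TRUE
      phi[i] <- phi[i] + wgt(sum(mask)) * (vOf(withI) - vOf(mask))
    }
  }
  structure(setNames(phi, DEL_FEATURES),
            instance_value = vOf(rep(TRUE, nF)),
            background_mean = vOf(rep(FALSE, nF)))
}

#' Closed-form attributions for a linear (softmax regression) submodel
#'
#' On the logit scale of the chosen class, the exact Shapley attribution
#' of binary feature j is `W[j, class] * (x_j - mean background_j)`;
#' efficiency holds by linearity.
#'
#' @param model a [SoftmaxRegression-class].
#' @param instance encoded binary input vector.
#' @param classIndex class to explain (index into `model@classes`).
#' @param background m x n_features matrix of background encodings.
#' @return named numeric of per-feature attributions, with attributes
#'   `instance_logit` and `background_mean_logit`.
#' @export
linearAttributions <- function(model, instance, classIndex, background) {
  if (classIndex < 1L || classIndex > length(model@classes))
    stop("class index out of range")
  if (is.null(dim(background)))
    background <- matrix(background, nrow = 1L)
  stopifnot(length(instance) == nrow(model@W),
            ncol(background) == nrow(model@W))
  w <- model@W[, classIndex]
  mu <- colMeans(background)
  vals <- w * (instance - mu)
  names(vals) <- names(instance) %||% rownames(model@W) %||%
    paste0("f", seq_along(vals))
  structure(vals,
            instance_logit = sum(w * instance) + model@b[classIndex],
            background_mean_logit = sum(w * mu) + model@b[classIndex])
}

#' Aggregate binary-encoding attributions to nucleotide level
#'
#' The value for the observed nucleotide at position p is the sum of the
#' attributions of the 4 mononucleotide bits at p (set and unset alike);
#' dinucleotide values sum the 16 bits at p. The total attribution is
#' conserved.
#'
#' @param attributions named attribution vector over a [encodeMonoDi()]
#'   encoding (names `"<token>|<position>"`).
#' @param sequence the encoded ACGT sequence (to label each position with
#'   its observed token).
#' @return data.frame: kind ("mono"/"di"), position, token, value.
#' @export
aggregateNucleotideAttributions <- function(attributions, sequence) {
  n <- nchar(sequence)
  expected <- 4L * n + 16L * (n - 1L)
  if (length(attributions) != expected)
    stop("attribution length ", length(attributions),
         " does not match a ", n, "-base mono+di encoding (", expected, ")")
  tok <- sub("\\|.*$", "", names(attributions))
  pos <- as.integer(sub("^.*\\|", "", names(attributions)))
  kind <- ifelse(nchar(tok) == 1L, "mono", "di")
  bases <- strsplit(sequence, "")[[1]]
  monoVal <- vapply(seq_len(n), function(p)
    sum(attributions[kind == "mono" & pos == p]), 0)
  diVal <- if (n > 1L) vapply(seq_len(n - 1L), function(p)
    sum(attributions[kind == "di" & pos == p]), 0) else numeric()
  rbind(
    data.frame(kind = "mono", position = seq_len(n), token = bases,
               value = monoVal),
    if (n > 1L)
      data.frame(kind = "di", position = seq_len(n - 1L),
                 token = paste0(bases[-n], bases[-1L]), value = diVal))
}

#' Sample a deletion-feature background set from a screen
#'
#' Pools the feature rows of the given catalogues and samples `m` rows,
#' seeded; the standard choice for explaining the deletion net.
#'
#' @param catalogues named list of [OutcomeCatalogue-class].
#' @param m background size (the full-scale default is 10000; tests use
#'   far fewer).
#' @param seed integer seed.
#' @return m x 5 feature matrix.
#' @export
sampleDeletionBackground <- function(catalogues, m = 10000L, seed = 1L) {
  feats <- do.call(rbind, lapply(catalogues, featurizeDeletions))
  set.seed(as.integer(seed))
  feats[sample(nrow(feats), min(m, nrow(feats))), , drop = FALSE]
}
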