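## The three submodels and their composition into a full predicted profile.
##
## Deletion net: 5 -> 16 -> 16 -> 1, sigmoid everywhere, scores each
## outcome independently; per-target sum-normalization turns the scores
## into a conditional deletion distribution. Insertion model: softmax over
## the 21 insertion outcomes from the mono+di encoding of the 6 nt directly
## upstream of the PAM. Ratio model: 2-class softmax from the encoded 20 nt
## protospacer. The full profile is q_del scaled by p_deletion
## concatenated with q_ins scaled by p_insertion.

EPS <- 1e-12

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' One-hot mono- plus dinucleotide encoding of a DNA string
#'
#' For an n-base input: 4n mononucleotide bits followed by 16(n-1)
#' dinucleotide bits, position-major and alphabet-minor (A<C<G<T). Exactly
#' n mono bits and n-1 di bits are set.
#'
#' @param sequence ACGT string.
#' @return named binary numeric vector of length 4n + 16(n-1); names are
#'   `"<token>|<position>"` with 1-based positions.
#' @examples
#' sum(encodeMonoDi("ACGT"))  # 4 mono + 3 di bits
#' @export
encodeMonoDi <- function(sequence) {
  if (grepl("[^ACGT]", sequence)) stop("non-ACGT characters in input")
  b <- match(strsplit(sequence, "")[[1]], DNA_BASES)
  n <- length(b)
  stopifnot(n >= 1L)
  mono <- numeric(4L * n)
  mono[(seq_len(n) - 1L) * 4L + b] <- 1
  names(mono) <- paste0(rep(DNA_BASES, n), "|", rep(seq_len(n), each = 4L))
  if (n == 1L) return(mono)
  di <- numeric(16L * (n - 1L))
  di[(seq_len(n - 1L) - 1L) * 16L + (b[-n] - 1L) * 4L + b[-1L]] <- 1
  diTokens <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
  names(di) <- paste0(rep(diTokens, n - 1L), "|",
                      rep(seq_len(n - 1L), each = 16L))
  c(mono, di)
}

## forward pass returning hidden activations (needed by backprop)
delForward <- function(net, X) {
  h1 <- sigmoid(sweep(X %*% net@W1, 2L, net@b1, `+`))
  h2 <- sigmoid(sweep(h1 %*% net@W2, 2L, net@b2, `+`))
  s <- sigmoid(h2 %*% net@W3 + net@b3)
  list(h1 = h1, h2 = h2, s = as.numeric(s))
}

#' Score deletion outcomes with the deletion net
#'
#' Each outcome row is scored independently in (0, 1); there is no
#' cross-outcome coupling.
#'
#' @param features n x 5 matrix from [featurizeDeletions()].
#' @param net a [DeletionNet-class].
#' @return numeric vector of n scores.
#' @export
deletionScores <- function(features, net) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 5L)
  if (ncol(features) != 5L) stop("deletion features must have 5 columns")
  delForward(net, features)$s
}

#' Normalize independent scores into a deletion distribution
#'
#' @param scores non-negative score vector.
#' @param eps floor below which the score total triggers a uniform fallback.
#' @return simplex vector over the deletion outcomes.
#' @export
deletionDistribution <- function(scores, eps = EPS) {
  total <- sum(scores)
  if (!is.finite(total) || total < eps)
    return(rep(1 / length(scores), length(scores)))
  scores / total
}

#' Predicted insertion distribution of a target
#'
#' Softmax over the 21 insertion outcomes from the 104-dim encoding of the
#' six nucleotides directly upstream of the PAM (window positions 28-33).
#'
#' @param window a [TargetWindow-class].
#' @param model insertion [SoftmaxRegression-class].
#' @return named 21-simplex.
#' @export
insertionDistribution <- function(window, model) {
  stopifnot(is(window, "TargetWindow"))
  x <- encodeMonoDi(substr(windowSequence(window), 28L, 33L))
  setNames(as.numeric(softmax(matrix(x, 1L) %*% model@W +
                              matrix(model@b, 1L))), model@classes)
}

#' Predicted deletion:insertion ratio of a target
#'
#' 2-class softmax from the 384-dim encoding of the 20 nt protospacer
#' (window positions 14-33).
#'
#' @param window a [TargetWindow-class].
#' @param model ratio [SoftmaxRegression-class].
#' @return named vector c(deletion = , insertion = ), summing to 1.
#' @export
indelRatio <- function(window, model) {
  stopifnot(is(window, "TargetWindow"))
  x <- encodeMonoDi(substr(windowSequence(window), PROTO_START, PROTO_END))
  setNames(as.numeric(softmax(matrix(x, 1L) %*% model@W +
                              matrix(model@b, 1L))), model@classes)
}

#' Predict the full repair outcome profile of a target
#'
#' Deletion outcome i receives `p_deletion * q_del(i)`, insertion outcome j
#' receives `p_insertion * q_ins(j)`; the result is a valid distribution
#' over the catalogue.
#'
#' @param window a [TargetWindow-class].
#' @param bundle a [ModelBundle-class].
#' @param catalogue the target's [OutcomeCatalogue-class] (built from the
#'   same window).
#' @return a [RepairProfile-class].
#' @export
predictProfile <- function(window, bundle, catalogue) {
  stopifnot(is(bundle, "ModelBundle"), is(catalogue, "OutcomeCatalogue"))
  if (targetId(window) != targetId(catalogue))
    stop("window/catalogue target mismatch")
  qDel <- deletionDistribution(
    deletionScores(featurizeDeletions(catalogue), bundle@deletionNet))
  qIns <- insertionDistribution(window, bundle@insertionModel)
  ratio <- indelRatio(window, bundle@ratioModel)
  f <- c(setNames(ratio[["deletion"]] * qDel, catalogue@deletions$outcome_id),
         ratio[["insertion"]] * qIns)
  f <- pmax(f, 0)
  f <- f / sum(f)
  new("RepairProfile", targetId = targetId(window), frequencies = f,
      nMutatedReads = 0L)
}

#' The uniform-baseline profile over a catalogue
#'
#' Equal frequency on every enumerated outcome; used as the naive baseline
#' in the synthetic benchmarks.
#'
#' @param catalogue an [OutcomeCatalogue-class].
#' @return a [RepairProfile-class].
#' @export
uniformBaselineProfile <- function(catalogue) {
  ids <- outcomeIds(catalogue)
  new("RepairProfile", targetId = targetId(catalogue),
      frequencies = setNames(rep(1 / length(ids), length(ids)), ids),
      nMutatedReads = 0L)
}

## ---- construction -------------------------------------------------------

#' Randomly initialized submodels and bundles
#'
#' Small-variance seeded Gaussian initialization (sd = 1/sqrt(fan-in) for
#' weights, zero biases).
#'
#' @param seed integer seed.
#' @return a [DeletionNet-class] / [SoftmaxRegression-class] /
#'   [ModelBundle-class].
#' @export
newDeletionNet <- function(seed = 1L) {
  set.seed(as.integer(seed))
  new("DeletionNet",
      W1 = matrix(rnorm(5 * 16, sd = 1 / sqrt(5)), 5L, 16L),
      b1 = numeric(16L),
      W2 = matrix(rnorm(16 * 16, sd = 1 / sqrt(16)), 16L, 16L),
      b2 = numeric(16L),
      W3 = matrix(rnorm(16, sd = 1 / sqrt(16)), 16L, 1L),
      b3 = 0)
}

#' @rdname newDeletionNet
#' @param nFeatures encoded input length.
#' @param classes class labels.
#' @export
newSoftmaxRegression <- function(nFeatures, classes, seed = 1L) {
  set.seed(as.integer(seed))
  new("SoftmaxRegression",
      W = matrix(rnorm(nFeatures * length(classes),
                       sd = 1 / sqrt(nFeatures)), nFeatures, length(classes)),
      b = numeric(length(classes)), classes = classes)
}

#' @rdname newDeletionNet
#' @export
newModelBundle <- function(seed = 1L) {
  seed <- as.integer(seed)
  new("ModelBundle",
      deletionNet = newDeletionNet(seed),
      insertionModel = newSoftmaxRegression(
        104L, enumerateInsertions()$outcome_id, seed + 1L),
      ratioModel = newSoftmaxRegression(
        384L, c("deletion", "insertion"), seed + 2L),
      config = bundleConfig())
}

bundleConfig <- function() {
  list(format_version = 1L,
       feature_order = DEL_FEATURES,
       encoding = "position-major, alphabet-minor (A<C<G<T), mono then di",
       window = list(length = WINDOW_LEN, cut = CUT_INDEX,
                     protospacer = c(PROTO_START, PROTO_END),
                     pam = c(PAM_START, PAM_START + 2L),
                     insertion_context = c(28L, 33L)))
}

## ---- serialization ------------------------------------------------------

#' Write/read a model bundle as JSON
#'
#' The container records layer shapes, the feature order, the encoding spec
#' and a format-version field; round-trips preserve predictions to 1e-10.
#'
#' @param bundle a [ModelBundle-class].
#' @param path file path.
#' @export
writeModelBundle <- function(bundle, path) {
  payload <- list(
    config = bundle@config,
    deletion_net = list(
      W1 = bundle@deletionNet@W1, b1 = bundle@deletionNet@b1,
      W2 = bundle@deletionNet@W2, b2 = bundle@deletionNet@b2,
      W3 = bundle@deletionNet@W3, b3 = bundle@deletionNet@b3),
    insertion_model = list(W = bundle@insertionModel@W,
                           b = bundle@insertionModel@b,
                           classes = bundle@insertionModel@classes),
    ratio_model = list(W = bundle@ratioModel@W, b = bundle@ratioModel@b,
                       classes = bundle@ratioModel@classes))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$config$format_version))
    stop("not a model bundle file (missing format_version)")
  asMat <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  }
  new("ModelBundle",
      deletionNet = new("DeletionNet",
        W1 = asMat(p$deletion_net$W1), b1 = as.numeric(p$deletion_net$b1),
        W2 = asMat(p$deletion_net$W2), b2 = as.numeric(p$deletion_net$b2),
        W3 = asMat(p$deletion_net$W3), b3 = as.numeric(p$deletion_net$b3)),
      insertionModel = new("SoftmaxRegression",
        W = asMat(p$insertion_model$W), b = as.numeric(p$insertion_model$b),
        classes = as.character(p$insertion_model$classes)),
      ratioModel = new("SoftmaxRegression",
        W = asMat(p$ratio_model$W), b = as.numeric(p$ratio_model$b),
        classes = as.character(p$ratio_model$classes)),
      config = p$config)
}
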