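#' @import methods
#' @importFrom stats rnorm runif rmultinom cor median setNames qlogis
#' @importFrom utils read.delim write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

## window geometry constants (1-based coordinates within the 60 bp window):
## the blunt cut falls between positions 30 and 31, so cut-relative offset r
## maps to window position r + 31 for r >= 0 and r + 31 for r < 0 alike
## (half-open cut-relative interval [s, e) deletes window positions
## s+31 .. e+30). The 20 nt protospacer occupies 14..33, the NGG PAM 34..36.
WINDOW_LEN <- 60L
CUT_INDEX <- 30L
PROTO_START <- 14L
PROTO_END <- 33L
PAM_START <- 34L

#' TargetWindow: a standardized 60 bp Cas9 target
#'
#' A 60 bp ACGT sequence centred at the blunt cut site (the cut falls after
#' the 30th base; `cut == 30` is the 0-based offset of the first base
#' downstream of the cut). All outcome enumeration and featurization is
#' defined against this window.
#'
#' @slot id target label.
#' @slot sequence 60 bp ACGT string.
#' @slot cut integer cut offset, always 30 after standardisation.
#' @slot pamOk logical, TRUE when the expected NGG PAM is present
#'   (GG at window positions 35-36).
#' @export
setClass("TargetWindow",
  representation(id = "character", sequence = "character",
                 cut = "integer", pamOk = "logical"))

setValidity("TargetWindow", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || nchar(object@sequence) != WINDOW_LEN)
    msg <- c(msg, "sequence must be a single 60 bp string")
  else if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence contains non-ACGT characters")
  if (length(object@cut) != 1L || object@cut != CUT_INDEX)
    msg <- c(msg, "cut must equal 30 after standardisation")
  if (length(msg)) msg else TRUE
})

#' OutcomeCatalogue: the enumerated repair outcome space of one target
#'
#' Holds the unique deletion outcomes (microhomology-grouped, with the
#' 5-feature annotation), the full alignment-to-outcome map, and the fixed
#' catalogue of 21 insertion outcomes.
#'
#' @slot targetId target label.
#' @slot window the [TargetWindow-class] the catalogue was enumerated from.
#' @slot deletions data.frame, one row per unique deletion outcome:
#'   `outcome_id, dstart, dend, del_len, mh_len, mh_gc, gap, left_edge,
#'   right_edge, n_alignments, product`.
#' @slot alignments data.frame mapping every enumerated interval
#'   (`dstart, dend`) to its `outcome_id`.
#' @slot insertions data.frame with the 21 insertion outcomes
#'   (`outcome_id, kind, inserted`).
#' @slot maxDelLen maximum deletion length used at enumeration.
#' @export
setClass("OutcomeCatalogue",
  representation(targetId = "character", window = "TargetWindow",
                 deletions = "data.frame", alignments = "data.frame",
                 insertions = "data.frame", maxDelLen = "integer"))

#' RepairProfile: a frequency distribution over a target's outcome space
#'
#' @slot targetId target label.
#' @slot frequencies named numeric over the catalogue's outcome ids
#'   (deletions first, then the 21 insertions), non-negative, summing to 1.
#' @slot nMutatedReads number of mutated reads the profile was built from
#'   (0 for analytic ground-truth or predicted profiles).
#' @export
setClass("RepairProfile",
  representation(targetId = "character", frequencies = "numeric",
                 nMutatedReads = "integer"))

setValidity("RepairProfile", function(object) {
  f <- object@frequencies
  msg <- character()
  if (is.null(names(f))) msg <- c(msg, "frequencies must be named by outcome id")
  if (any(f < -1e-12)) msg <- c(msg, "frequencies must be non-negative")
  if (length(f) && abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' DeletionNet: the 5-feature deletion scoring network
#'
#' Fully connected 5 -> 16 -> 16 -> 1 network with sigmoid activation at
#' every layer; scores each deletion outcome independently in (0, 1).
#'
#' @slot W1,b1,W2,b2,W3,b3 layer weights and biases.
#' @export
setClass("DeletionNet",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", W3 = "matrix", b3 = "numeric"))

setValidity("DeletionNet", function(object) {
  ok <- identical(dim(object@W1), c(5L, 16L)) &&
    length(object@b1) == 16L &&
    identical(dim(object@W2), c(16L, 16L)) &&
    length(object@b2) == 16L &&
    identical(dim(object@W3), c(16L, 1L)) &&
    length(object@b3) == 1L
  if (ok) TRUE else "layer shapes must be 5->16->16->1"
})

#' SoftmaxRegression: a multinomial logistic regression submodel
#'
#' @slot W weight matrix, n_features x n_classes.
#' @slot b bias vector, length n_classes.
#' @slot classes class labels (21 insertion outcome ids, or
#'   c("deletion", "insertion")).
#' @export
setClass("SoftmaxRegression",
  representation(W = "matrix", b = "numeric", classes = "character"))

setValidity("SoftmaxRegression", function(object) {
  if (ncol(object@W) != length(object@b) ||
      ncol(object@W) != length(object@classes))
    "W columns, b and classes must agree" else TRUE
})

#' ModelBundle: the three submodels plus featurization config
#'
#' @slot deletionNet [DeletionNet-class] scoring deletion outcomes from the
#'   five features (mh_len, mh_gc, gap, left_edge, right_edge).
#' @slot insertionModel [SoftmaxRegression-class] over the 21 insertion
#'   outcomes, fed the mono+dinucleotide encoding of the 6 nt directly
#'   upstream of the PAM.
#' @slot ratioModel [SoftmaxRegression-class] over (deletion, insertion),
#'   fed the encoding of the 20 nt protospacer.
#' @slot config featurization config: feature order, encoding spec, window
#'   coordinate conventions, format version.
#' @export
setClass("ModelBundle",
  representation(deletionNet = "DeletionNet",
                 insertionModel = "SoftmaxRegression",
                 ratioModel = "SoftmaxRegression",
                 config = "list"))

#' TransferPlan: a domain-adaptation strategy
#'
#' Strategies: SO (source only), TO (target only), FT (fine-tune all
#' weights at a low learning rate), PF0/PF1/PF2 (retrain with 0, 1 or 2
#' frozen hidden layers, then fine-tune; frozen layers stay frozen
#' throughout).
#'
#' @slot strategy one of SO, TO, FT, PF0, PF1, PF2.
#' @slot nTargetSamples number of target-domain training profiles.
#' @slot retrainLr learning rate for the retraining phase.
#' @slot fineTuneLr low learning rate for fine-tuning.
#' @slot frozenLayers subset of c("hidden1", "hidden2").
#' @slot seed integer seed controlling sample selection and training.
#' @export
setClass("TransferPlan",
  representation(strategy = "character", nTargetSamples = "integer",
                 retrainLr = "numeric", fineTuneLr = "numeric",
                 frozenLayers = "character", seed = "integer"))

setValidity("TransferPlan", function(object) {
  msg <- character()
  if (!object@strategy %in% c("SO", "TO", "FT", "PF0", "PF1", "PF2"))
    msg <- c(msg, "unknown strategy")
  if (!all(object@frozenLayers %in% c("hidden1", "hidden2")))
    msg <- c(msg, "frozenLayers must be a subset of hidden1/hidden2")
  expected <- switch(object@strategy,
    PF1 = "hidden1", PF2 = c("hidden1", "hidden2"), character())
  if (!setequal(object@frozenLayers, expected))
    msg <- c(msg, sprintf("strategy %s requires frozen layers {%s}",
                          object@strategy, paste(expected, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' GeneratorParams: the ground-truth frequency law of the synthetic screens
#'
#' Deletion outcome propensity is log-linear in the five outcome features:
#' log phi = mhWeight*M + gcWeight*F - gapWeight*G - leftWeight*|L|
#'   - rightWeight*R + mhlessOffset*1(M = 0) + lenPrefWeight*K(D)
#' with K a Gaussian bump centred at lenPrefCenter (only used by the
#' long-deletion domain shift). Insertion propensities favour re-insertion
#' of the base immediately upstream of the cut.
#'
#' @slot mhWeight,gcWeight,gapWeight,leftWeight,rightWeight log-linear
#'   feature weights (per bp, or per unit GC fraction).
#' @slot mhlessOffset additive log-propensity offset for MH-less outcomes.
#' @slot lenPrefWeight,lenPrefCenter deletion-length preference bump.
#' @slot insSelfBoost log-boost for inserting the base just upstream of the cut.
#' @slot insDiWeight,insLongWeight relative propensity of each dinucleotide
#'   insertion and of the >=3 bp category.
#' @slot delBalance overall deletion fraction (deletion:insertion balance).
#' @slot depth default sequencing depth (reads per target).
#' @export
setClass("GeneratorParams",
  representation(mhWeight = "numeric", gcWeight = "numeric",
                 gapWeight = "numeric", leftWeight = "numeric",
                 rightWeight = "numeric", mhlessOffset = "numeric",
                 lenPrefWeight = "numeric", lenPrefCenter = "numeric",
                 insSelfBoost = "numeric", insDiWeight = "numeric",
                 insLongWeight = "numeric", delBalance = "numeric",
                 depth = "integer"))

setValidity("GeneratorParams", function(object) {
  if (object@delBalance < 0 || object@delBalance > 1)
    return("delBalance must lie in [0,1]")
  if (object@depth < 1L) return("depth must be >= 1")
  TRUE
})

#' EvalReport: per-target metrics plus aggregate and precision-X% tasks
#'
#' @slot perTarget data.frame: target_id, jsd, pearson, mse.
#' @slot precision data.frame: x, precision, recall, mcc, tp, fp, tn, fn,
#'   n_undefined.
#' @slot aggregates data.frame: task, mse, pearson (six aggregate outcome
#'   frequency tasks).
#' @slot summary data.frame: metric, value (median JSD, mean JSD, mean
#'   Pearson, mean MSE).
#' @export
setClass("EvalReport",
  representation(perTarget = "data.frame", precision = "data.frame",
                 aggregates = "data.frame", summary = "data.frame"))

## ---- show methods -------------------------------------------------------

setMethod("show", "TargetWindow", function(object) {
  cat(sprintf("TargetWindow '%s': %s | cut at 30 | PAM %s\n", object@id,
              paste0(substr(object@sequence, 1, 30), "^",
                     substr(object@sequence, 31, 60)),
              if (object@pamOk) "NGG ok" else "absent"))
})

setMethod("show", "OutcomeCatalogue", function(object) {
  cat(sprintf(
    "OutcomeCatalogue '%s': %d deletion outcomes (%d MH-based) over %d intervals + %d insertions\n",
    object@targetId, nrow(object@deletions),
    sum(object@deletions$mh_len > 0), nrow(object@alignments),
    nrow(object@insertions)))
})

setMethod("show", "RepairProfile", function(object) {
  f <- sort(object@frequencies, decreasing = TRUE)
  cat(sprintf("RepairProfile '%s': %d outcomes, %d mutated reads\n",
              object@targetId, length(f), object@nMutatedReads))
  cat("  top outcomes:",
      paste(sprintf("%s=%.3f", names(f)[seq_len(min(3, length(f)))],
                    f[seq_len(min(3, length(f)))]), collapse = ", "), "\n")
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf(
    "ModelBundle: deletion net 5->16->16->1 | insertion softmax (%d x %d) | ratio softmax (%d x %d)\n",
    nrow(object@insertionModel@W), ncol(object@insertionModel@W),
    nrow(object@ratioModel@W), ncol(object@ratioModel@W)))
})

setMethod("show", "TransferPlan", function(object) {
  cat(sprintf("TransferPlan %s: n=%d, retrain lr=%g, fine-tune lr=%g, frozen={%s}\n",
              object@strategy, object@nTargetSamples, object@retrainLr,
              object@fineTuneLr, paste(object@frozenLayers, collapse = ",")))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport over", nrow(object@perTarget), "targets\n")
  print(object@summary, row.names = FALSE)
})

## ---- accessors ----------------------------------------------------------

#' @rdname TargetWindow-class
#' @param object a TargetWindow / catalogue / profile.
#' @export
setGeneric("targetId", function(object) standardGeneric("targetId"))
#' @rdname TargetWindow-class
#' @export
setMethod("targetId", "TargetWindow", function(object) object@id)
#' @rdname OutcomeCatalogue-class
#' @param object an OutcomeCatalogue.
#' @export
setMethod("targetId", "OutcomeCatalogue", function(object) object@targetId)
#' @rdname RepairProfile-class
#' @param object a RepairProfile.
#' @export
setMethod("targetId", "RepairProfile", function(object) object@targetId)

#' @rdname TargetWindow-class
#' @export
setGeneric("windowSequence", function(object) standardGeneric("windowSequence"))
#' @rdname TargetWindow-class
#' @export
setMethod("windowSequence", "TargetWindow", function(object) object@sequence)

#' @rdname TargetWindow-class
#' @export
setGeneric("cutSite", function(object) standardGeneric("cutSite"))
#' @rdname TargetWindow-class
#' @export
setMethod("cutSite", "TargetWindow", function(object) object@cut)

#' @rdname TargetWindow-class
#' @export
setGeneric("pamOk", function(object) standardGeneric("pamOk"))
#' @rdname TargetWindow-class
#' @export
setMethod("pamOk", "TargetWindow", function(object) object@pamOk)

#' @rdname OutcomeCatalogue-class
#' @export
setGeneric("deletionOutcomes", function(object) standardGeneric("deletionOutcomes"))
#' @rdname OutcomeCatalogue-class
#' @export
setMethod("deletionOutcomes", "OutcomeCatalogue", function(object) object@deletions)

#' @rdname OutcomeCatalogue-class
#' @export
setGeneric("insertionOutcomes", function(object) standardGeneric("insertionOutcomes"))
#' @rdname OutcomeCatalogue-class
#' @export
setMethod("insertionOutcomes", "OutcomeCatalogue", function(object) object@insertions)

#' @rdname OutcomeCatalogue-class
#' @export
setGeneric("alignmentMap", function(object) standardGeneric("alignmentMap"))
#' @rdname OutcomeCatalogue-class
#' @export
setMethod("alignmentMap", "OutcomeCatalogue", function(object) object@alignments)

#' @rdname OutcomeCatalogue-class
#' @export
setGeneric("outcomeIds", function(object) standardGeneric("outcomeIds"))
#' @rdname OutcomeCatalogue-class
#' @export
setMethod("outcomeIds", "OutcomeCatalogue", function(object)
  c(object@deletions$outcome_id, object@insertions$outcome_id))

#' @rdname RepairProfile-class
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname RepairProfile-class
#' @export
setMethod("frequencies", "RepairProfile", function(object) object@frequencies)

#' @rdname RepairProfile-class
#' @export
setGeneric("nMutatedReads", function(object) standardGeneric("nMutatedReads"))
#' @rdname RepairProfile-class
#' @export
setMethod("nMutatedReads", "RepairProfile", function(object) object@nMutatedReads)
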