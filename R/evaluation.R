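## Scoring predicted against observed profiles: Jensen-Shannon distance,
## Pearson correlation, MSE, precision-X% classification tasks, and the
## six aggregate outcome-frequency tasks.

#' Jensen-Shannon distance between two distributions
#'
#' Square root of the Jensen-Shannon divergence computed with base-2
#' logarithms against the midpoint distribution; symmetric and bounded in
#' `[0, 1]` (1 for disjoint supports).
#'
#' @param p,q simplex vectors on the same support (sum-to-1 tolerance
#'   1e-6).
#' @return scalar in `[0, 1]`.
#' @examples
#' jsd(c(1, 0), c(0, 1))        # 1
#' jsd(c(1, 0), c(0.5, 0.5))    # ~0.5579
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6 ||
      any(p < -1e-9) || any(q < -1e-9))
    stop("inputs must be valid probability distributions")
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    pos <- a > 0
    sum(a[pos] * log2(a[pos] / b[pos]))
  }
  js <- (kl2(p, m) + kl2(q, m)) / 2
  sqrt(min(max(js, 0), 1))
}

#' Precision-X% classification task
#'
#' A target is labelled positive when its single most frequent outcome
#' accounts for at least X% of the mass over the considered outcomes; the
#' observed labels define the ground truth and the predicted labels the
#' classifier. Undefined ratios (zero denominators) are returned as NaN
#' with a count.
#'
#' @param observed,predicted named lists of matched
#'   [RepairProfile-class] objects.
#' @param x threshold percent (one of 20, 30, 40, 50, 60, 70 in the
#'   standard task set).
#' @return list: precision, recall, mcc, tp/fp/tn/fn, n_undefined.
#' @export
precisionXTask <- function(observed, predicted, x) {
  ids <- names(observed)
  if (!setequal(ids, names(predicted))) stop("mismatched target sets")
  obsPos <- vapply(observed[ids],
                   function(p) max(frequencies(p)) >= x / 100, NA)
  predPos <- vapply(predicted[ids],
                    function(p) max(frequencies(p)) >= x / 100, NA)
  tp <- sum(obsPos & predPos); fp <- sum(!obsPos & predPos)
  tn <- sum(!obsPos & !predPos); fn <- sum(obsPos & !predPos)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen == 0) NaN else (tp * tn - fp * fn) / mccDen
  out <- list(precision = ratio(tp, tp + fp), recall = ratio(tp, tp + fn),
              mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn)
  out$n_undefined <- sum(is.nan(c(out$precision, out$recall, out$mcc)))
  out
}

AGGREGATE_TASKS <- c("deletion", "insertion_1bp", "deletion_1bp",
                     "frameshift_1", "frameshift_2", "frameshift")

#' Aggregate outcome frequencies of a profile
#'
#' Six scalars: overall deletion frequency, 1 bp insertion frequency, 1 bp
#' deletion frequency, and the 1 bp / 2 bp / any frameshift frequencies.
#' Frameshift class of an outcome is its net length change mod 3 (+length
#' for insertions, -deletion length for deletions, so a 1 bp deletion is a
#' 2-frameshift); the ">=3 bp" insertion category contributes a
#' configurable representative length (default 3, i.e. in-frame).
#'
#' @param profile a [RepairProfile-class].
#' @param catalogue the matching [OutcomeCatalogue-class].
#' @param longInsertionLength representative length of the ">=3 bp"
#'   insertion category.
#' @return named numeric of length 6.
#' @export
aggregateOutcomes <- function(profile, catalogue, longInsertionLength = 3L) {
  f <- frequencies(profile)
  del <- catalogue@deletions
  ins <- catalogue@insertions
  fDel <- f[del$outcome_id]
  fIns <- f[ins$outcome_id]
  insLen <- ifelse(ins$kind == "long", longInsertionLength,
                   nchar(ins$inserted))
  netChange <- c(-del$del_len, insLen)
  fAll <- c(fDel, fIns)
  fs <- ((netChange %% 3) + 3) %% 3
  c(deletion = sum(fDel),
    insertion_1bp = sum(fIns[ins$kind == "single"]),
    deletion_1bp = sum(fDel[del$del_len == 1L]),
    frameshift_1 = sum(fAll[fs == 1]),
    frameshift_2 = sum(fAll[fs == 2]),
    frameshift = sum(fAll[fs != 0]))
}

#' Evaluate predicted against observed profiles
#'
#' Fills an [EvalReport-class]: per-target JSD, Pearson r and MSE over the
#' frequency vectors; precision/recall/MCC for the precision-X% tasks
#' (X in 20..70); per-task MSE and Pearson for the six aggregate
#' outcomes; and summary rows (median/mean JSD, mean Pearson, mean MSE).
#'
#' @param predicted,observed named lists of matched
#'   [RepairProfile-class] objects on identical catalogues.
#' @param catalogues named list of [OutcomeCatalogue-class].
#' @param xGrid precision-X% thresholds.
#' @return an [EvalReport-class].
#' @export
evaluateProfiles <- function(predicted, observed, catalogues,
                             xGrid = c(20, 30, 40, 50, 60, 70)) {
  ids <- names(observed)
  if (!setequal(ids, names(predicted))) stop("mismatched target sets")
  perTarget <- data.frame(target_id = ids, jsd = NA_real_,
                          pearson = NA_real_, mse = NA_real_)
  aggPred <- matrix(NA_real_, length(ids), length(AGGREGATE_TASKS),
                    dimnames = list(ids, AGGREGATE_TASKS))
  aggObs <- aggPred
  for (i in seq_along(ids)) {
    tid <- ids[i]
    po <- frequencies(observed[[tid]])
    pp <- frequencies(predicted[[tid]])
    if (!identical(names(po), names(pp)))
      stop("catalogue mismatch for target '", tid, "'")
    perTarget$jsd[i] <- jsd(po, pp)
    perTarget$pearson[i] <- suppressWarnings(cor(po, pp))
    perTarget$mse[i] <- mseLoss(po, pp)
    cat <- catalogues[[tid]]
    aggObs[i, ] <- aggregateOutcomes(observed[[tid]], cat)
    aggPred[i, ] <- aggregateOutcomes(predicted[[tid]], cat)
  }
  precision <- do.call(rbind, lapply(xGrid, function(x) {
    r <- precisionXTask(observed, predicted, x)
    data.frame(x = x, precision = r$precision, recall = r$recall,
               mcc = r$mcc, tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               n_undefined = r$n_undefined)
  }))
  aggregates <- data.frame(
    task = AGGREGATE_TASKS,
    mse = vapply(AGGREGATE_TASKS, function(t)
      mseLoss(aggObs[, t], aggPred[, t]), 0),
    pearson = vapply(AGGREGATE_TASKS, function(t)
      suppressWarnings(cor(aggObs[, t], aggPred[, t])), 0))
  summary <- data.frame(
    metric = c("median_jsd", "mean_jsd", "mean_pearson", "mean_mse"),
    value = c(median(perTarget$jsd), mean(perTarget$jsd),
              mean(perTarget$pearson, na.rm = TRUE), mean(perTarget$mse)))
  new("EvalReport", perTarget = perTarget, precision = precision,
      aggregates = aggregates, summary = summary)
}

#' Write an evaluation report as TSV
#'
#' One row per target per metric plus summary, precision-task and
#' aggregate-task rows, in a single long table
#' (section, target_id/task, metric, value).
#'
#' @param report an [EvalReport-class].
#' @param path output TSV path.
#' @export
writeEvalReportTsv <- function(report, path) {
  pt <- report@perTarget
  long <- rbind(
    data.frame(section = "per_target",
               key = rep(pt$target_id, 3L),
               metric = rep(c("jsd", "pearson", "mse"), each = nrow(pt)),
               value = c(pt$jsd, pt$pearson, pt$mse)),
    data.frame(section = "precision_x",
               key = rep(paste0("precision_", report@precision$x), 3L),
               metric = rep(c("precision", "recall", "mcc"),
                            each = nrow(report@precision)),
               value = c(report@precision$precision,
                         report@precision$recall, report@precision$mcc)),
    data.frame(section = "aggregate",
               key = rep(report@aggregates$task, 2L),
               metric = rep(c("mse", "pearson"),
                            each = nrow(report@aggregates)),
               value = c(report@aggregates$mse, report@aggregates$pearson)),
    data.frame(section = "summary", key = report@summary$metric,
               metric = "value", value = report@summary$value))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
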