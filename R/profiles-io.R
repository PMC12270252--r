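## Event tables -> normalized repair outcome profiles, with the
## >= 100 mutated-read filter, plus all tabular readers/writers.

#' Read an event table (TSV)
#'
#' Tab-separated with header; columns: target_id, event_type
#' ("deletion"/"insertion"), dstart, dend (cut-relative half-open interval,
#' deletions only), inserted_seq (insertions only), count.
#'
#' @param path TSV file path.
#' @return data.frame of event records.
#' @export
readEventsTsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(target_id = "character",
                                  inserted_seq = "character"))
  needed <- c("target_id", "event_type", "dstart", "dend", "inserted_seq",
              "count")
  if (!all(needed %in% names(ev)))
    stop("event table must have columns: ", paste(needed, collapse = ", "))
  ev
}

#' @rdname readEventsTsv
#' @param events event data.frame.
#' @export
writeEventsTsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign observed events to catalogue outcomes
#'
#' Deletion events map to the unique outcome whose equivalent alignments
#' contain their interval (product identity); insertions of length 1 and 2
#' map to their exact outcome and length >= 3 to the "3+" category.
#' Unmappable events (interval outside the enumeration window, deletions
#' longer than the catalogue maximum, non-ACGT insertions) are dropped and
#' reported in the discard log.
#'
#' @param events event data.frame (rows for one target).
#' @param catalogue the target's [OutcomeCatalogue-class].
#' @return list: `counts` (named vector over all outcome ids), `discarded`
#'   (data.frame of dropped events with a reason), `nAssigned`,
#'   `nDiscarded` (read totals).
#' @export
assignEvents <- function(events, catalogue) {
  stopifnot(is(catalogue, "OutcomeCatalogue"))
  events <- events[events$target_id == catalogue@targetId, , drop = FALSE]
  ids <- outcomeIds(catalogue)
  counts <- setNames(numeric(length(ids)), ids)
  if (nrow(events) == 0L)
    return(list(counts = counts,
                discarded = cbind(events, reason = character(0)),
                nAssigned = 0, nDiscarded = 0))
  aln <- catalogue@alignments
  alnKey <- paste(aln$dstart, aln$dend)
  assignedId <- character(nrow(events))
  reason <- character(nrow(events))
  isDel <- events$event_type == "deletion"
  isIns <- events$event_type == "insertion"
  reason[!isDel & !isIns] <- paste("unknown event type",
                                   events$event_type[!isDel & !isIns])
  if (any(isDel)) {
    j <- match(paste(events$dstart[isDel], events$dend[isDel]), alnKey)
    assignedId[isDel] <- ifelse(is.na(j), "", aln$outcome_id[j])
    reason[isDel][is.na(j)] <-
      "deletion interval outside enumerated outcome space"
  }
  if (any(isIns)) {
    ins <- toupper(events$inserted_seq[isIns])
    len <- ifelse(is.na(ins), 0L, nchar(ins))
    id <- character(length(ins))
    rsn <- character(length(ins))
    rsn[len == 0L] <- "insertion without inserted sequence"
    id[len >= 3L] <- "ins:3+"
    short <- len %in% c(1L, 2L)
    bad <- short & grepl("[^ACGT]", ins)
    rsn[bad] <- "non-ACGT inserted sequence"
    ok <- short & !bad
    id[ok] <- paste0("ins:", ins[ok])
    assignedId[isIns] <- id
    reason[isIns] <- rsn
  }
  ok <- assignedId != ""
  if (any(ok)) {
    add <- tapply(events$count[ok], assignedId[ok], sum)
    counts[names(add)] <- counts[names(add)] + add
  }
  list(counts = counts,
       discarded = cbind(events[!ok, , drop = FALSE],
                         reason = reason[!ok]),
       nAssigned = sum(events$count[ok]),
       nDiscarded = sum(events$count[!ok]))
}

#' Build a normalized repair profile from assigned counts
#'
#' Targets with fewer than `minReads` mutated reads are rejected (returns a
#' `profileRejection` object carrying the reason), mirroring the
#' screen-level filter that discards gRNA-targets with under 100 mutated
#' reads.
#'
#' @param counts named count vector over the catalogue's outcome ids.
#' @param catalogue the target's [OutcomeCatalogue-class].
#' @param minReads minimum mutated-read total (default 100).
#' @return a [RepairProfile-class], or an object of class
#'   `profileRejection` (a list with `reason` and `total`) when rejected.
#' @export
buildProfile <- function(counts, catalogue, minReads = 100L) {
  total <- sum(counts)
  if (total == 0) stop("all-zero counts for target '", catalogue@targetId, "'")
  if (total < minReads)
    return(structure(list(reason = "insufficient reads", total = total),
                     class = "profileRejection"))
  ids <- outcomeIds(catalogue)
  stopifnot(setequal(names(counts), ids))
  new("RepairProfile", targetId = catalogue@targetId,
      frequencies = counts[ids] / total, nMutatedReads = as.integer(total))
}

#' Events + catalogues -> profiles for a whole screen
#'
#' @param events event data.frame over many targets.
#' @param catalogues named list of [OutcomeCatalogue-class].
#' @param minReads minimum mutated-read total per target.
#' @return list: `profiles` (named list of [RepairProfile-class]),
#'   `rejected` (data.frame target_id/reason/total),
#'   `discarded` (combined discard log).
#' @export
profilesFromEvents <- function(events, catalogues, minReads = 100L) {
  profiles <- list(); rejected <- list(); discarded <- list()
  for (tid in names(catalogues)) {
    asn <- assignEvents(events, catalogues[[tid]])
    if (nrow(asn$discarded)) discarded[[tid]] <- asn$discarded
    if (sum(asn$counts) == 0) {
      rejected[[tid]] <- data.frame(target_id = tid, reason = "no mapped reads",
                                    total = 0)
      next
    }
    p <- buildProfile(asn$counts, catalogues[[tid]], minReads)
    if (inherits(p, "profileRejection")) {
      rejected[[tid]] <- data.frame(target_id = tid, reason = p$reason,
                                    total = p$total)
    } else profiles[[tid]] <- p
  }
  list(profiles = profiles,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(target_id = character(), reason = character(),
                                  total = numeric()),
       discarded = if (length(discarded)) do.call(rbind, discarded) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split profiles into disjoint train and test sets
#'
#' Seeded random split on target ids; optionally screens for near-duplicate
#' windows across the split by Hamming distance on the standardized 60 bp
#' sequences.
#'
#' @param profiles named list of [RepairProfile-class].
#' @param testFraction fraction of targets in the test set, in (0, 1).
#' @param seed integer seed.
#' @param windows optional named list of [TargetWindow-class] enabling the
#'   duplicate guard.
#' @param hammingThreshold flag cross-split window pairs at or below this
#'   Hamming distance (default 0, i.e. identical windows).
#' @return list: `train`, `test` (named profile lists), `nearDuplicates`
#'   (data.frame of flagged pairs, empty when none or no windows given).
#' @export
splitTrainTest <- function(profiles, testFraction, seed = 1L,
                           windows = NULL, hammingThreshold = 0L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  ids <- names(profiles)
  if (length(ids) < 2L) stop("need at least 2 profiles to split")
  nTest <- max(1L, round(testFraction * length(ids)))
  if (nTest >= length(ids)) nTest <- length(ids) - 1L
  set.seed(as.integer(seed))
  testIds <- sort(sample(ids, nTest))
  trainIds <- setdiff(ids, testIds)
  dup <- data.frame(train_id = character(), test_id = character(),
                    hamming = integer())
  if (!is.null(windows)) {
    trM <- do.call(rbind, lapply(windows[trainIds], function(w)
      strsplit(windowSequence(w), "")[[1]]))
    teM <- do.call(rbind, lapply(windows[testIds], function(w)
      strsplit(windowSequence(w), "")[[1]]))
    for (i in seq_along(trainIds)) {
      hd <- rowSums(sweep(teM, 2L, trM[i, ], `!=`))
      hit <- which(hd <= hammingThreshold)
      if (length(hit))
        dup <- rbind(dup, data.frame(train_id = trainIds[i],
                                     test_id = testIds[hit],
                                     hamming = as.integer(hd[hit])))
    }
  }
  list(train = profiles[trainIds], test = profiles[testIds],
       nearDuplicates = dup)
}

#' Read/write repair profiles as long-format TSV
#'
#' Columns: target_id, outcome_id, frequency, n_mutated_reads. Outcomes
#' absent from the file are zero-frequency; a catalogue list is required on
#' read to restore the full outcome support.
#'
#' @param profiles named list of [RepairProfile-class].
#' @param path TSV path.
#' @param dropZeros omit zero-frequency rows (default TRUE).
#' @export
writeProfilesTsv <- function(profiles, path, dropZeros = TRUE) {
  rows <- lapply(profiles, function(p) {
    f <- frequencies(p)
    if (dropZeros) f <- f[f > 0]
    data.frame(target_id = targetId(p), outcome_id = names(f),
               frequency = unname(f), n_mutated_reads = nMutatedReads(p),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfilesTsv
#' @param catalogues named list of [OutcomeCatalogue-class] giving the full
#'   outcome support of each target.
#' @export
readProfilesTsv <- function(path, catalogues) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(target_id = "character"))
  out <- list()
  for (tid in unique(tab$target_id)) {
    cat <- catalogues[[tid]]
    if (is.null(cat)) stop("no catalogue for target '", tid, "'")
    sub <- tab[tab$target_id == tid, ]
    ids <- outcomeIds(cat)
    f <- setNames(numeric(length(ids)), ids)
    unknown <- setdiff(sub$outcome_id, ids)
    if (length(unknown))
      stop("outcome ids not in catalogue for '", tid, "': ",
           paste(head(unknown, 3), collapse = ", "))
    f[sub$outcome_id] <- sub$frequency
    f <- f / sum(f)
    out[[tid]] <- new("RepairProfile", targetId = tid, frequencies = f,
                      nMutatedReads = as.integer(sub$n_mutated_reads[1]))
  }
  out
}
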