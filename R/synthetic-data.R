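## Fully synthetic screens: random PAM-bearing targets, ground-truth
## profiles from a log-linear frequency law over the five deletion
## features, multinomial read sampling that scatters MH-based reads over
## equivalent alignments, and parameterized domain shifts.

#' Ground-truth generator parameters
#'
#' Defaults encode the qualitative structure the deletion model assumes:
#' microhomology length raises a deletion outcome's propensity, distance
#' of the edges from the cut and the gap between the MH copies lower it,
#' MH GC content has a small positive effect, and single-base insertions
#' preferentially re-insert the base immediately upstream of the cut. The
#' default deletion:insertion balance (0.8) and read depth (2000, well
#' above the 100 mutated-read filter) are the standard screen conditions
#' of the synthetic benchmarks.
#'
#' @param mhWeight,gcWeight,gapWeight,leftWeight,rightWeight log-linear
#'   weights on M, F, G, |L|, R.
#' @param mhlessOffset additive log-offset for MH-less outcomes.
#' @param lenPrefWeight,lenPrefCenter Gaussian deletion-length preference
#'   (0 = off; used by the long-deletion domain shift).
#' @param insSelfBoost log-boost for re-inserting the upstream base.
#' @param insDiWeight,insLongWeight relative weights of each dinucleotide
#'   insertion and of the ">=3 bp" category.
#' @param delBalance overall deletion fraction.
#' @param depth reads per target.
#' @return a [GeneratorParams-class].
#' @export
generatorParams <- function(mhWeight = 0.35, gcWeight = 0.15,
                            gapWeight = 0.10, leftWeight = 0.12,
                            rightWeight = 0.12, mhlessOffset = -1.0,
                            lenPrefWeight = 0, lenPrefCenter = 13,
                            insSelfBoost = 1.5, insDiWeight = 0.15,
                            insLongWeight = 0.5, delBalance = 0.8,
                            depth = 2000L) {
  new("GeneratorParams", mhWeight = mhWeight, gcWeight = gcWeight,
      gapWeight = gapWeight, leftWeight = leftWeight,
      rightWeight = rightWeight, mhlessOffset = mhlessOffset,
      lenPrefWeight = lenPrefWeight, lenPrefCenter = lenPrefCenter,
      insSelfBoost = insSelfBoost, insDiWeight = insDiWeight,
      insLongWeight = insLongWeight, delBalance = delBalance,
      depth = as.integer(depth))
}

#' Generate random standardized target windows
#'
#' Uniform random 60 bp ACGT windows with GG forced at the PAM positions
#' (window bases 35-36) so every window carries an NGG PAM; seeded and
#' reproducible.
#'
#' @param n number of targets.
#' @param seed integer seed.
#' @return named list of [TargetWindow-class].
#' @export
generateTargets <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- sample(DNA_BASES, WINDOW_LEN, replace = TRUE)
    b[(PAM_START + 1L):(PAM_START + 2L)] <- "G"
    id <- sprintf("synth_%05d", i)
    out[[i]] <- new("TargetWindow", id = id,
                    sequence = paste(b, collapse = ""), cut = CUT_INDEX,
                    pamOk = TRUE)
  }
  names(out) <- vapply(out, targetId, "")
  out
}

## insertion propensity table given the base immediately upstream of the
## cut (cut-relative position -1, window position 30)
insertionPropensities <- function(upstreamBase, params) {
  ins <- enumerateInsertions()
  w <- numeric(nrow(ins))
  w[ins$kind == "single"] <-
    exp(params@insSelfBoost * (ins$inserted[ins$kind == "single"] ==
                                 upstreamBase))
  w[ins$kind == "dinucleotide"] <- params@insDiWeight
  w[ins$kind == "long"] <- params@insLongWeight
  setNames(w / sum(w), ins$outcome_id)
}

#' Ground-truth repair profile of a target
#'
#' Deletion outcome frequencies proportional to the log-linear propensity
#' law over the enumerated catalogue; insertion frequencies from the
#' conditional propensity table; combined by the deletion:insertion
#' balance.
#'
#' @param window a [TargetWindow-class].
#' @param params a [GeneratorParams-class].
#' @param catalogue optional pre-built [OutcomeCatalogue-class].
#' @return a [RepairProfile-class].
#' @export
groundTruthProfile <- function(window, params = generatorParams(),
                               catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- buildCatalogue(window)
  d <- catalogue@deletions
  logPhi <- params@mhWeight * d$mh_len + params@gcWeight * d$mh_gc -
    params@gapWeight * d$gap - params@leftWeight * abs(d$left_edge) -
    params@rightWeight * d$right_edge +
    params@mhlessOffset * (d$mh_len == 0)
  if (params@lenPrefWeight != 0)
    logPhi <- logPhi + params@lenPrefWeight *
      exp(-(d$del_len - params@lenPrefCenter)^2 / 18)
  phi <- exp(logPhi - max(logPhi))
  qDel <- phi / sum(phi)
  upstream <- substr(windowSequence(window), CUT_INDEX, CUT_INDEX)
  qIns <- insertionPropensities(upstream, params)
  f <- c(setNames(params@delBalance * qDel, d$outcome_id),
         (1 - params@delBalance) * qIns)
  new("RepairProfile", targetId = targetId(window), frequencies = f / sum(f),
      nMutatedReads = 0L)
}

#' Sample sequencing reads from a ground-truth profile
#'
#' A multinomial draw over the outcome space at the given depth; reads of
#' an MH-based deletion outcome are scattered uniformly over its
#' equivalent alignments, so downstream event assignment must exercise the
#' product-identity grouping to recover the outcome.
#'
#' @param profile ground-truth [RepairProfile-class].
#' @param catalogue the matching [OutcomeCatalogue-class].
#' @param depth total reads (>= 1).
#' @param seed integer seed.
#' @return event data.frame (target_id, event_type, dstart, dend,
#'   inserted_seq, count).
#' @export
sampleReads <- function(profile, catalogue, depth, seed = 1L) {
  stopifnot(depth >= 1L)
  set.seed(as.integer(seed))
  f <- frequencies(profile)
  counts <- as.integer(rmultinom(1L, depth, f))
  names(counts) <- names(f)
  aln <- catalogue@alignments
  ins <- catalogue@insertions
  evType <- character(); evS <- integer(); evE <- integer()
  evIns <- character(); evCnt <- integer()
  hit <- names(counts)[counts > 0L]
  delHit <- hit[startsWith(hit, "del:")]
  if (length(delHit)) {
    ## scatter each outcome's reads uniformly over its equivalent alignments
    a <- aln[aln$outcome_id %in% delHit, , drop = FALSE]
    split <- integer(nrow(a))
    for (oid in delHit) {
      idx <- which(a$outcome_id == oid)
      split[idx] <- if (length(idx) == 1L) counts[[oid]] else
        as.integer(rmultinom(1L, counts[[oid]],
                             rep(1 / length(idx), length(idx))))
    }
    keep <- split > 0L
    evType <- rep("deletion", sum(keep))
    evS <- a$dstart[keep]; evE <- a$dend[keep]
    evIns <- rep("", sum(keep)); evCnt <- split[keep]
  }
  insHit <- hit[!startsWith(hit, "del:")]
  for (oid in insHit) {
    insSeq <- ins$inserted[match(oid, ins$outcome_id)]
    if (insSeq == "")  # ">=3 bp" category: emit a random 3-5 bp insert
      insSeq <- paste(sample(DNA_BASES, sample(3:5, 1L), replace = TRUE),
                      collapse = "")
    evType <- c(evType, "insertion"); evS <- c(evS, NA_integer_)
    evE <- c(evE, NA_integer_); evIns <- c(evIns, insSeq)
    evCnt <- c(evCnt, counts[[oid]])
  }
  data.frame(target_id = profile@targetId, event_type = evType,
             dstart = evS, dend = evE, inserted_seq = evIns, count = evCnt,
             stringsAsFactors = FALSE)
}

#' Apply a named domain shift to generator parameters
#'
#' Shifts emulate repair-pathway perturbations: `mh_boost` raises
#' MH-based deletion propensity (NHEJ-deficient-like), `long_del_shift`
#' moves deletion mass towards 10-16 bp deletions (exonuclease-fusion
#' -like), `insertion_suppress` lowers the overall insertion fraction.
#' Magnitude 0 is the identity.
#'
#' @param params a [GeneratorParams-class].
#' @param shift one of "mh_boost", "long_del_shift", "insertion_suppress".
#' @param magnitude non-negative shift strength.
#' @return perturbed [GeneratorParams-class].
#' @export
shiftDomain <- function(params, shift, magnitude) {
  stopifnot(magnitude >= 0)
  switch(shift,
    mh_boost = {
      params@mhWeight <- params@mhWeight + 0.5 * magnitude
      params@mhlessOffset <- params@mhlessOffset - 0.5 * magnitude
      params
    },
    long_del_shift = {
      params@lenPrefWeight <- params@lenPrefWeight + magnitude
      params
    },
    insertion_suppress = {
      params@delBalance <- 1 - (1 - params@delBalance) * exp(-magnitude)
      params
    },
    stop("unknown shift '", shift, "'"))
}

#' Simulate a complete synthetic screen
#'
#' generate targets -> enumerate catalogues -> ground-truth profiles ->
#' multinomial reads -> event assignment -> filtered, normalized observed
#' profiles.
#'
#' @param n number of targets.
#' @param params a [GeneratorParams-class].
#' @param depth reads per target (default `params@depth`).
#' @param seed integer seed for targets and read sampling.
#' @param minReads mutated-read filter threshold.
#' @return list: `windows`, `catalogues`, `truth` (ground-truth profiles),
#'   `events`, `profiles` (observed), `rejected`.
#' @export
simulateScreen <- function(n, params = generatorParams(), depth = NULL,
                           seed = 1L, minReads = 100L) {
  depth <- depth %||% params@depth
  windows <- generateTargets(n, seed)
  catalogues <- lapply(windows, buildCatalogue)
  truth <- list(); events <- vector("list", n)
  for (i in seq_along(windows)) {
    tid <- names(windows)[i]
    truth[[tid]] <- groundTruthProfile(windows[[tid]], params,
                                       catalogues[[tid]])
    events[[i]] <- sampleReads(truth[[tid]], catalogues[[tid]], depth,
                               seed = seed + i)
  }
  events <- do.call(rbind, events)
  built <- profilesFromEvents(events, catalogues, minReads)
  list(windows = windows, catalogues = catalogues, truth = truth,
       events = events, profiles = built$profiles, rejected = built$rejected)
}
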