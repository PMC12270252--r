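## Outcome space enumeration: deletions up to 30 bp overlapping or adjacent
## to the cut, grouped into unique repair products by microhomology shift
## equivalence, plus the fixed catalogue of 21 insertion outcomes.
##
## Coordinates are cut-relative, 0-based, half-open: position 0 is the first
## base downstream of the blunt cut; interval [dstart, dend) is the deleted
## segment. Window position (1-based) = cut-relative offset + 31.

#' Standardize a raw target sequence into a 60 bp cut-centred window
#'
#' Slices a 60 bp window centred at the canonical SpCas9 blunt cut site,
#' which falls 3 bp upstream of the NGG PAM (between protospacer positions
#' 17 and 18). The resulting window always has the cut after its 30th base.
#'
#' @param rawSequence DNA string (ACGT) containing the protospacer plus at
#'   least 30 bp of context on each side of the cut.
#' @param protospacerEnd 1-based index in `rawSequence` of the last
#'   protospacer base (the base adjacent to the PAM).
#' @param id target label.
#' @param pamCheck if TRUE, error when the window lacks GG at the PAM
#'   positions (window bases 35-36).
#' @return a [TargetWindow-class].
#' @examples
#' raw <- paste0(strrep("A", 30), "CGTACGTACGTACGTACGTA", "TGG", strrep("C", 26))
#' w <- standardizeTarget(raw, protospacerEnd = 50, id = "t1", pamCheck = FALSE)
#' cutSite(w)
#' @export
standardizeTarget <- function(rawSequence, protospacerEnd, id = "target",
                              pamCheck = FALSE) {
  rawSequence <- toupper(rawSequence)
  if (grepl("[^ACGT]", rawSequence))
    stop("non-ACGT characters in target sequence '", id, "'")
  cutAbs <- as.integer(protospacerEnd) - 3L  # last base upstream of the cut
  if (cutAbs < CUT_INDEX || nchar(rawSequence) - cutAbs < CUT_INDEX)
    stop("insufficient context: need >= 30 bp on each side of the cut for '",
         id, "'")
  win <- substr(rawSequence, cutAbs - 29L, cutAbs + 30L)
  pam <- substr(win, PAM_START + 1L, PAM_START + 2L) == "GG"
  if (pamCheck && !pam)
    stop("missing NGG PAM at window positions 34-36 for '", id, "'")
  new("TargetWindow", id = id, sequence = win, cut = CUT_INDEX, pamOk = pam)
}

#' Enumerate candidate deletion intervals
#'
#' All cut-relative half-open intervals `[dstart, dend)` with
#' `-30 <= dstart <= 0 <= dend <= 30` and `1 <= dend - dstart <= maxLen`,
#' i.e. every deletion up to `maxLen` bp that overlaps the cut site or
#' touches it from either side. Deterministic order: by dstart, then dend.
#'
#' @param window a [TargetWindow-class].
#' @param maxLen maximum deletion length in bp (default 30).
#' @return data.frame with columns `dstart`, `dend`.
#' @export
enumerateDeletionIntervals <- function(window, maxLen = 30L) {
  stopifnot(is(window, "TargetWindow"), maxLen >= 1L, maxLen <= 30L)
  g <- expand.grid(dend = 0:30, dstart = -30:0)  # dstart varies slowest
  d <- g$dend - g$dstart
  keep <- d >= 1L & d <= maxLen
  out <- data.frame(dstart = as.integer(g$dstart[keep]),
                    dend = as.integer(g$dend[keep]))
  out[order(out$dstart, out$dend), , drop = FALSE]
}

## repair product string of interval [s, e): window with positions
## s+31 .. e+30 removed
deletionProduct <- function(sequence, dstart, dend) {
  paste0(substr(rep_len(sequence, length(dstart)), 1L, dstart + 30L),
         substring(sequence, dend + 31L, 60L))
}

gcFraction <- function(s) {
  n <- nchar(s)
  ifelse(n == 0L, 0,
         (nchar(gsub("[AT]", "", s))) / pmax(n, 1L))
}

#' Group shift-equivalent deletions into unique outcomes
#'
#' Two intervals belong to the same outcome iff their repair product strings
#' are byte-identical, which happens exactly when the deleted segments are
#' shifts across a flanking microhomology. The canonical alignment is the
#' leftmost (PAM-distal) interval; the microhomology length M is the number
#' of equivalent alignments minus one, with the two MH copies at
#' `[dstart, dstart+M)` and `[dend, dend+M)` of the canonical alignment.
#'
#' Features per outcome: `mh_len` M, `mh_gc` F (GC fraction of the MH, 0
#' when MH-less), `gap` G = D - M (equal to the deletion length for MH-less
#' outcomes), `left_edge` L = dstart + M, `right_edge` R = dend.
#'
#' @param window a [TargetWindow-class].
#' @param intervals data.frame from [enumerateDeletionIntervals()].
#' @return list with `deletions` (one row per unique outcome) and
#'   `alignments` (every interval with its outcome_id).
#' @export
groupEquivalentDeletions <- function(window, intervals) {
  stopifnot(is(window, "TargetWindow"))
  intervals <- intervals[order(intervals$dstart, intervals$dend), , drop = FALSE]
  seqc <- windowSequence(window)
  prod <- deletionProduct(seqc, intervals$dstart, intervals$dend)
  grp <- match(prod, unique(prod))  # first-occurrence order = canonical order
  canon <- which(!duplicated(grp))
  sizes <- tabulate(grp, nbins = length(canon))
  s <- intervals$dstart[canon]
  e <- intervals$dend[canon]
  D <- e - s
  M <- sizes - 1L
  mhSeq <- substr(rep_len(seqc, length(s)), s + 31L, s + M + 30L)
  del <- data.frame(
    outcome_id = sprintf("del:%d:%d", s, e),
    dstart = s, dend = e, del_len = D,
    mh_len = M, mh_gc = ifelse(M == 0L, 0, gcFraction(mhSeq)),
    gap = D - M, left_edge = s + M, right_edge = e,
    n_alignments = sizes, product = prod[canon],
    stringsAsFactors = FALSE)
  aln <- data.frame(
    outcome_id = del$outcome_id[grp],
    dstart = intervals$dstart, dend = intervals$dend,
    stringsAsFactors = FALSE)
  list(deletions = del, alignments = aln)
}

#' The fixed catalogue of 21 insertion outcomes
#'
#' All 4 single-nucleotide insertions, all 16 dinucleotide insertions, and
#' one category for insertions of 3 bp or longer, in fixed canonical order
#' (A, C, G, T; AA..TT lexicographic; 3+).
#'
#' @return data.frame with columns `outcome_id`, `kind`, `inserted`.
#' @export
enumerateInsertions <- function() {
  singles <- DNA_BASES
  dis <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
  data.frame(
    outcome_id = c(paste0("ins:", singles), paste0("ins:", dis), "ins:3+"),
    kind = c(rep("single", 4L), rep("dinucleotide", 16L), "long"),
    inserted = c(singles, dis, ""),
    stringsAsFactors = FALSE)
}

#' Featurize deletion outcomes for the deletion model
#'
#' Fixed column order (mh_len, mh_gc, gap, left_edge, right_edge); integer
#' features are used as-is, with no one-hot encoding.
#'
#' @param deletions data.frame of deletion outcomes (from
#'   [groupEquivalentDeletions()] or an [OutcomeCatalogue-class]).
#' @return numeric matrix, n_outcomes x 5.
#' @export
featurizeDeletions <- function(deletions) {
  if (is(deletions, "OutcomeCatalogue")) deletions <- deletions@deletions
  stopifnot(all(DEL_FEATURES %in% names(deletions)))
  m <- as.matrix(deletions[, DEL_FEATURES])
  rownames(m) <- deletions$outcome_id
  storage.mode(m) <- "double"
  m
}

DEL_FEATURES <- c("mh_len", "mh_gc", "gap", "left_edge", "right_edge")

#' Build the full outcome catalogue of a target window
#'
#' @param window a [TargetWindow-class].
#' @param maxDelLen maximum deletion length (default 30 bp).
#' @return an [OutcomeCatalogue-class].
#' @export
buildCatalogue <- function(window, maxDelLen = 30L) {
  iv <- enumerateDeletionIntervals(window, maxDelLen)
  grp <- groupEquivalentDeletions(window, iv)
  new("OutcomeCatalogue", targetId = targetId(window), window = window,
      deletions = grp$deletions, alignments = grp$alignments,
      insertions = enumerateInsertions(), maxDelLen = as.integer(maxDelLen))
}

#' Read target windows from a FASTA file
#'
#' Each record must contain the 60 bp window context; by default the
#' protospacer is assumed to end 30 + 3 bp into the sequence for 60 bp
#' records (i.e. records are pre-centred windows); longer records require
#' `protospacerEnd`.
#'
#' @param path FASTA file of target sequences.
#' @param protospacerEnd 1-based position of the last protospacer base in
#'   each record; default assumes cut-centred records (cut at the midpoint).
#' @param pamCheck passed to [standardizeTarget()].
#' @return named list of [TargetWindow-class] objects.
#' @export
readTargetFasta <- function(path, protospacerEnd = NULL, pamCheck = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    pe <- if (is.null(protospacerEnd)) nchar(s) %/% 2L + 3L else protospacerEnd
    out[[i]] <- standardizeTarget(s, pe, id = ids[i], pamCheck = pamCheck)
  }
  names(out) <- ids
  out
}

#' Write target windows to FASTA
#'
#' @param windows list of [TargetWindow-class].
#' @param path output file.
#' @export
writeTargetFasta <- function(windows, path) {
  ss <- Biostrings::DNAStringSet(vapply(windows, windowSequence, ""))
  names(ss) <- vapply(windows, targetId, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write one or more outcome catalogues as TSV
#'
#' Columns: target_id, outcome_id, type, dstart, dend, del_len, mh_len,
#' mh_gc, gap, left_edge, right_edge, product.
#'
#' @param catalogues list of [OutcomeCatalogue-class] (or a single one).
#' @param path output TSV path.
#' @export
writeCatalogueTsv <- function(catalogues, path) {
  if (is(catalogues, "OutcomeCatalogue")) catalogues <- list(catalogues)
  rows <- lapply(catalogues, function(cat) {
    d <- cat@deletions
    rbind(
      data.frame(target_id = cat@targetId, outcome_id = d$outcome_id,
                 type = "deletion", d[, c("dstart", "dend", "del_len",
                 "mh_len", "mh_gc", "gap", "left_edge", "right_edge")],
                 product = d$product, stringsAsFactors = FALSE),
      data.frame(target_id = cat@targetId,
                 outcome_id = cat@insertions$outcome_id, type = "insertion",
                 dstart = NA, dend = NA, del_len = NA, mh_len = NA,
                 mh_gc = NA, gap = NA, left_edge = NA, right_edge = NA,
                 product = "", stringsAsFactors = FALSE))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
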