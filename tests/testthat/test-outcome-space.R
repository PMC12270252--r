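test_that("standardizeTarget slices a 60 bp cut-centred window", {
  ## 79 bp construct with the protospacer at a known offset
  set.seed(11)
  proto <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  raw <- paste0(strrep("A", 25), proto, "TGG", strrep("C", 31))
  w <- standardizeTarget(raw, protospacerEnd = 45, id = "t79")
  expect_s4_class(w, "TargetWindow")
  expect_equal(nchar(windowSequence(w)), 60)
  expect_equal(cutSite(w), 30)
  ## the window retains the sequence around the cut: raw cut is after 42
  expect_equal(windowSequence(w), substr(raw, 13, 72))
  expect_true(pamOk(w))  # TGG sits at window positions 34-36

  expect_error(standardizeTarget(paste0(strrep("A", 20), proto, "TGG"),
                                 protospacerEnd = 40),
               "insufficient context")
  expect_error(standardizeTarget(gsub("A", "N", raw), 45), "non-ACGT")
  rawNoPam <- paste0(strrep("A", 25), proto, "TAA", strrep("C", 31))
  expect_error(standardizeTarget(rawNoPam, 45, pamCheck = TRUE),
               "missing NGG PAM")
  expect_false(pamOk(standardizeTarget(rawNoPam, 45, pamCheck = FALSE)))
})

test_that("deletion interval enumeration matches the brute-force count", {
  w <- randomWindow(1)
  iv <- enumerateDeletionIntervals(w)
  ## brute-force count of eligible (dstart, dend) pairs
  brute <- sum(outer(-30:0, 0:30, function(s, e) {
    d <- e - s; d >= 1 & d <= 30
  }))
  expect_equal(nrow(iv), brute)
  expect_equal(nrow(iv), 495)
  expect_true(all(iv$dstart <= 0 & iv$dend >= 0))
  expect_true(all(iv$dend - iv$dstart >= 1 & iv$dend - iv$dstart <= 30))
  ## deterministic order and small-maxLen cases
  expect_false(is.unsorted(iv$dstart))
  iv1 <- enumerateDeletionIntervals(w, 1)
  expect_equal(iv1$dstart, c(-1L, 0L))
  expect_equal(iv1$dend, c(0L, 1L))
  expect_equal(nrow(enumerateDeletionIntervals(w, 2)), 5)
})

test_that("the planted CG microhomology collapses three intervals into one outcome", {
  w <- cgMicrohomologyWindow()
  cat <- buildCatalogue(w)
  d <- deletionOutcomes(cat)
  hit <- d[d$outcome_id == "del:-2:2", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$del_len, 4)
  expect_equal(hit$mh_len, 2)
  expect_equal(hit$mh_gc, 1.0)
  expect_equal(hit$gap, 2)
  expect_equal(hit$left_edge, 0)
  expect_equal(hit$right_edge, 2)
  aln <- alignmentMap(cat)
  members <- aln[aln$outcome_id == "del:-2:2", ]
  expect_equal(members$dstart, c(-2L, -1L, 0L))
  expect_equal(members$dend, c(2L, 3L, 4L))
  ## featurization row for the fixture outcome
  feats <- featurizeDeletions(cat)
  expect_equal(unname(feats["del:-2:2", ]), c(2, 1, 2, 0, 2))
})

test_that("a window with no cross-cut base matches yields 495 MH-less outcomes", {
  cat <- buildCatalogue(allMhLessWindow())
  d <- deletionOutcomes(cat)
  expect_equal(nrow(d), 495)
  expect_true(all(d$mh_len == 0))
  expect_true(all(d$mh_gc == 0))
  expect_true(all(d$gap == d$del_len))
  expect_true(all(d$left_edge == d$dstart & d$right_edge == d$dend))
})

test_that("poly-A window collapses every deletion length to one outcome", {
  for (maxLen in c(4L, 30L)) {
    d <- deletionOutcomes(buildCatalogue(polyAWindow(), maxDelLen = maxLen))
    expect_equal(nrow(d), maxLen)
    expect_equal(sort(d$del_len), seq_len(maxLen))
    ## full tandem-repeat deletions: M = D, G = 0
    expect_equal(d$mh_len, d$del_len)
    expect_true(all(d$gap == 0))
  }
})

test_that("MH grouping equals brute-force product deduplication on random windows", {
  for (seed in c(3, 17, 88)) {
    w <- randomWindow(seed)
    cat <- buildCatalogue(w)
    d <- deletionOutcomes(cat)
    oracle <- bruteForceGrouping(w)
    expect_equal(nrow(d), length(oracle))
    ## same partition, same canonical (leftmost) representatives
    oracleKey <- sort(vapply(oracle, function(o)
      sprintf("del:%d:%d", o$dstart[1], o$dend[1]), ""))
    expect_equal(sort(d$outcome_id), oracleKey)
    ## conservation and the M + 1 alignment-count law
    expect_equal(sum(d$n_alignments), 495)
    expect_equal(d$n_alignments, d$mh_len + 1L)
    ## reconstruction: canonical deletion reproduces the stored product
    s <- windowSequence(w)
    rebuilt <- paste0(substr(rep(s, nrow(d)), 1, d$dstart + 30),
                      substring(s, d$dend + 31, 60))
    expect_equal(rebuilt, d$product)
    ## MH copies flank the deleted segment of the canonical alignment
    mh1 <- substr(rep(s, nrow(d)), d$dstart + 31, d$dstart + d$mh_len + 30)
    mh2 <- substr(rep(s, nrow(d)), d$dend + 31, d$dend + d$mh_len + 30)
    expect_equal(mh1, mh2)
  }
})

test_that("the insertion catalogue has 4 + 16 + 1 members in canonical order", {
  ins <- enumerateInsertions()
  expect_equal(nrow(ins), 21)
  expect_equal(sum(ins$kind == "single"), 4)
  expect_equal(sum(ins$kind == "dinucleotide"), 16)
  expect_equal(ins$outcome_id[1:4], paste0("ins:", c("A", "C", "G", "T")))
  expect_equal(ins$outcome_id[5], "ins:AA")
  expect_equal(ins$outcome_id[21], "ins:3+")
  expect_equal(anyDuplicated(ins$outcome_id), 0)
})

test_that("featurization keeps the fixed (M, F, G, L, R) column order as-is", {
  cat <- buildCatalogue(randomWindow(5))
  feats <- featurizeDeletions(cat)
  expect_equal(colnames(feats),
               c("mh_len", "mh_gc", "gap", "left_edge", "right_edge"))
  d <- deletionOutcomes(cat)
  ## an MH-less deletion (-3, 0) has features (0, 0, 3, -3, 0)
  mhless <- d[d$mh_len == 0 & d$dstart == -3 & d$dend == 0, ]
  if (nrow(mhless) == 1)
    expect_equal(unname(feats[mhless$outcome_id, ]), c(0, 0, 3, -3, 0))
  expect_true(all(feats[, "mh_gc"][feats[, "mh_len"] == 0] == 0))
  expect_true(all(feats[, "gap"] == d$del_len - d$mh_len))
})

test_that("target FASTA round-trips through Biostrings", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  windows <- generateTargets(4, seed = 2)
  writeTargetFasta(windows, tmp)
  back <- readTargetFasta(tmp)
  expect_equal(names(back), names(windows))
  expect_equal(vapply(back, windowSequence, ""),
               vapply(windows, windowSequence, ""))
  expect_true(all(vapply(back, pamOk, NA)))
})
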