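test_that("Jensen-Shannon distance has its closed-form values and bounds", {
  p <- randomSimplex(8)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  ## hand-computed: m = (0.75, 0.25), JS = (KL(p||m) + KL(q||m)) / 2
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.5579230, tolerance = 1e-6)
  expect_error(jsd(c(0.7, 0.7), c(0.5, 0.5)), "probability")
  expect_error(jsd(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("jsd is a metric: symmetry and triangle inequality on random triples", {
  set.seed(404)
  for (i in 1:300) {
    k <- sample(2:12, 1)
    p <- randomSimplex(k); q <- randomSimplex(k); r <- randomSimplex(k)
    expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-12)
    expect_lte(jsd(p, r), jsd(p, q) + jsd(q, r) + 1e-12)
    d <- jsd(p, q)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("precision-X% labels threshold the modal outcome frequency", {
  mk <- function(id, f) new("RepairProfile", targetId = id,
                            frequencies = setNames(f, paste0("o", seq_along(f))),
                            nMutatedReads = 100L)
  ## max frequency 0.25: positive at X=20, negative at X=30
  obs <- list(a = mk("a", c(0.25, 0.25, 0.25, 0.25)),
              b = mk("b", c(0.7, 0.1, 0.1, 0.1)))
  r20 <- precisionXTask(obs, obs, 20)
  expect_equal(r20$tp, 2)
  expect_equal(c(r20$precision, r20$recall, r20$mcc), c(1, 1, NaN))
  r30 <- precisionXTask(obs, obs, 30)
  expect_equal(r30$tp, 1)
  expect_equal(r30$tn, 1)
  expect_equal(c(r30$precision, r30$recall, r30$mcc), c(1, 1, 1))
  ## balanced confusion TP=FP=TN=FN=1 gives MCC 0
  obs4 <- list(a = mk("a", c(0.9, 0.1)), b = mk("b", c(0.9, 0.1)),
               c = mk("c", c(0.5, 0.5)), d = mk("d", c(0.5, 0.5)))
  pred4 <- list(a = mk("a", c(0.9, 0.1)), b = mk("b", c(0.5, 0.5)),
                c = mk("c", c(0.9, 0.1)), d = mk("d", c(0.5, 0.5)))
  r <- precisionXTask(obs4, pred4, 70)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(1, 1, 1, 1))
  expect_equal(r$mcc, 0)
  expect_error(precisionXTask(obs, obs[1], 20), "mismatched")
})

test_that("aggregate outcomes follow the net-length-change mod-3 rule", {
  w <- allMhLessWindow()
  cat <- buildCatalogue(w)
  ids <- outcomeIds(cat)
  f <- setNames(numeric(length(ids)), ids)
  d <- deletionOutcomes(cat)
  del1 <- d$outcome_id[d$del_len == 1][1]
  del3 <- d$outcome_id[d$del_len == 3][1]
  f[c(del1, del3, "ins:A", "ins:AC")] <- c(0.3, 0.2, 0.4, 0.1)
  p <- new("RepairProfile", targetId = targetId(cat), frequencies = f,
           nMutatedReads = 100L)
  agg <- aggregateOutcomes(p, cat)
  expect_equal(unname(agg["deletion"]), 0.5)
  expect_equal(unname(agg["insertion_1bp"]), 0.4)
  expect_equal(unname(agg["deletion_1bp"]), 0.3)
  ## net changes: -1 (fs2), -3 (in-frame), +1 (fs1), +2 (fs2)
  expect_equal(unname(agg["frameshift_1"]), 0.4)
  expect_equal(unname(agg["frameshift_2"]), 0.4)
  expect_equal(unname(agg["frameshift"]), 0.8)
  ## all-in-frame profile has frameshift 0
  f0 <- setNames(numeric(length(ids)), ids)
  f0[c(del3, "ins:3+")] <- c(0.5, 0.5)
  p0 <- new("RepairProfile", targetId = targetId(cat), frequencies = f0,
            nMutatedReads = 100L)
  agg0 <- aggregateOutcomes(p0, cat)
  expect_equal(unname(agg0["frameshift"]), 0)
  ## frameshift always partitions into the 1- and 2-classes
  expect_equal(unname(agg["frameshift"]),
               unname(agg["frameshift_1"] + agg["frameshift_2"]))
})

test_that("aggregates are linear in profile mixtures", {
  scr <- smallScreen()
  tid <- names(scr$profiles)[1]
  cat <- scr$catalogues[[tid]]
  p1 <- scr$profiles[[tid]]
  p2 <- uniformBaselineProfile(cat)
  lambda <- 0.3
  mix <- new("RepairProfile", targetId = tid,
             frequencies = lambda * frequencies(p1) +
               (1 - lambda) * frequencies(p2),
             nMutatedReads = 0L)
  expect_equal(aggregateOutcomes(mix, cat),
               lambda * aggregateOutcomes(p1, cat) +
                 (1 - lambda) * aggregateOutcomes(p2, cat),
               tolerance = 1e-12)
})

test_that("positivity rate is non-increasing in the precision threshold X", {
  scr <- smallScreen()
  obs <- scr$profiles
  rates <- vapply(c(20, 30, 40, 50, 60, 70), function(x) {
    r <- precisionXTask(obs, obs, x)
    (r$tp + r$fn) / length(obs)
  }, 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("the evaluation report is complete, self-consistent, and serializable", {
  scr <- smallScreen()
  ids <- names(scr$profiles)[1:12]
  obs <- scr$profiles[ids]
  ## perfect predictions
  rep0 <- evaluateProfiles(obs, obs, scr$catalogues)
  expect_true(all(rep0@perTarget$jsd == 0))
  expect_true(all(rep0@perTarget$mse == 0))
  expect_true(all(rep0@perTarget$pearson > 1 - 1e-12))
  expect_true(all(rep0@aggregates$mse == 0))
  ## uniform predictions against concentrated observations
  unif <- lapply(scr$catalogues[ids], uniformBaselineProfile)
  repU <- evaluateProfiles(unif, obs, scr$catalogues)
  expect_true(all(repU@perTarget$jsd > 0.5))
  expect_equal(repU@summary$metric[1], "median_jsd")
  ## TSV round-trip of the report table
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeEvalReportTsv(repU, tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back),
               3 * nrow(repU@perTarget) + 3 * nrow(repU@precision) +
                 2 * nrow(repU@aggregates) + nrow(repU@summary))
  medBack <- back$value[back$section == "summary" & back$key == "median_jsd"]
  expect_equal(medBack, repU@summary$value[1], tolerance = 1e-6)
})
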