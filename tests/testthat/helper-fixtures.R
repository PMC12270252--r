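## Shared fixtures, independent oracles and cached screens. Everything is
## generated in code under fixed seeds; no data files.

## A window with a planted 2 bp "CG" microhomology: "CG" at cut-relative
## [-2, 0) and [2, 4), chosen so the MH cannot extend in either direction
## (cut-rel -3 != 1 and 0 != 4). Deleting any of (-2,2), (-1,3), (0,4)
## yields the same product, one outcome with D=4, M=2, F=1, G=2, L=0, R=2.
cgMicrohomologyWindow <- function() {
  set.seed(90210)
  b <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  ## cut-rel r maps to 1-based window position r + 31
  b[28:35] <- c("A", "C", "G", "A", "T", "C", "G", "T")
  w <- new("TargetWindow", id = "cg_fixture",
           sequence = paste(b, collapse = ""), cut = 30L, pamOk = FALSE)
  stopifnot(substr(w@sequence, 29, 30) == "CG",
            substr(w@sequence, 33, 34) == "CG")
  w
}

## every interval is its own outcome: left half poly-A, right half poly-C,
## so no cross-cut base pair matches and no shift equivalence exists
allMhLessWindow <- function()
  new("TargetWindow", id = "mhless_fixture",
      sequence = paste0(strrep("A", 30), strrep("C", 30)),
      cut = 30L, pamOk = FALSE)

polyAWindow <- function()
  new("TargetWindow", id = "polyA_fixture", sequence = strrep("A", 60),
      cut = 30L, pamOk = FALSE)

randomWindow <- function(seed, id = paste0("rw_", seed)) {
  set.seed(seed)
  new("TargetWindow", id = id,
      sequence = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                       collapse = ""),
      cut = 30L, pamOk = FALSE)
}

## independent brute-force oracle: computes every interval's product via
## character vectors and partitions intervals by exact product identity
bruteForceGrouping <- function(window, maxLen = 30L) {
  chars <- strsplit(windowSequence(window), "")[[1]]
  rows <- list()
  for (s in -30:0) for (e in 0:30) {
    d <- e - s
    if (d < 1 || d > maxLen) next
    keepIdx <- setdiff(seq_len(60), (s + 31):(e + 30))
    rows[[length(rows) + 1L]] <-
      list(dstart = s, dend = e,
           product = paste(chars[keepIdx], collapse = ""))
  }
  products <- vapply(rows, `[[`, "", "product")
  classes <- split(seq_along(rows), products)
  lapply(unname(classes), function(idx) {
    ds <- vapply(rows[idx], `[[`, 0, "dstart")
    de <- vapply(rows[idx], `[[`, 0, "dend")
    o <- order(ds)
    list(dstart = ds[o], dend = de[o], product = rows[[idx[1]]]$product)
  })
}

## small per-session cache so expensive screens/models are built once
.fixtureCache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## a modest screen for module-level tests
smallScreen <- function()
  cached("smallScreen", simulateScreen(40, seed = 20250925))

fastConfig <- function(loss = "kld", seed = 1L)
  trainConfig(loss, max_epochs = 15L, max_epochs_linear = 30L, seed = seed)

## predictions of a bundle over a set of target ids
predictAll <- function(bundle, windows, catalogues, ids = names(windows)) {
  out <- lapply(ids, function(tid)
    predictProfile(windows[[tid]], bundle, catalogues[[tid]]))
  names(out) <- ids
  out
}

meanTestJsd <- function(bundle, screen, ids) {
  preds <- predictAll(bundle, screen$windows, screen$catalogues, ids)
  mean(vapply(ids, function(tid)
    jsd(frequencies(screen$profiles[[tid]]), frequencies(preds[[tid]])), 0))
}

## independent coalition-value helper used by the Shapley sampling oracle:
## plain per-row loops, no shared code with the package implementation
coalitionValues <- function(net, x, bg) {
  v <- numeric(32)
  for (code in 0:31) {
    mask <- as.logical(bitwAnd(code, 2^(0:4)))
    tot <- 0
    for (r in seq_len(nrow(bg))) {
      z <- bg[r, ]
      z[mask] <- x[mask]
      tot <- tot + deletionScores(matrix(z, 1), net)
    }
    v[code + 1] <- tot / nrow(bg)
  }
  v
}

## random point on the k-simplex
randomSimplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}
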