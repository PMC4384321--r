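test_that("merge concatenates traces and keeps their ids", {
  a <- simulateDataset(nTraces = 2, nPoints = 15, seed = 1)
  b <- simulateDataset(nTraces = 3, nPoints = 15, seed = 2)
  m <- mergeDatasets(a, b, desc = "pooled")
  expect_identical(nTraces(m), 5L)
  expect_identical(vapply(traces(m), smdId, character(1L)),
                   c(vapply(traces(a), smdId, character(1L)),
                     vapply(traces(b), smdId, character(1L))))
  expect_true(all(verifyIds(m)$match))
  expect_identical(summarizeDataset(m)$nPointsTotal,
                   summarizeDataset(a)$nPointsTotal +
                     summarizeDataset(b)$nPointsTotal)
})

test_that("merging a single dataset reproduces its trace list", {
  a <- simulateDataset(nTraces = 2, nPoints = 10, seed = 3)
  m <- mergeDatasets(a)
  expect_identical(vapply(traces(m), smdId, character(1L)),
                   vapply(traces(a), smdId, character(1L)))
})

test_that("merge is associative on trace content and order", {
  ds <- lapply(1:3, function(s)
    simulateDataset(nTraces = 2, nPoints = 10, seed = s))
  m1 <- mergeDatasets(mergeDatasets(ds[[1]], ds[[2]]), ds[[3]])
  m2 <- mergeDatasets(ds[[1]], ds[[2]], ds[[3]])
  expect_identical(vapply(traces(m1), smdId, character(1L)),
                   vapply(traces(m2), smdId, character(1L)))
  expect_identical(smdId(m1), smdId(m2))
})

test_that("merge refuses mismatched type maps, naming the difference", {
  a <- SMDDataset(list(SMDTrace(0, list(donor = 1, acceptor = 2))), "a")
  b <- SMDDataset(list(SMDTrace(0, list(fret = 0.5))), "b")
  expect_error(mergeDatasets(a, b), "donor|fret")
})

test_that("merge attr policies behave as documented", {
  t0 <- SMDTrace(0, list(fret = 0.5))
  a <- SMDDataset(list(t0), "a", attr = list(temp = 22))
  b <- SMDDataset(list(t0), "b", attr = list(temp = 25))
  expect_identical(smdAttr(mergeDatasets(a, b))$temp, 22)
  expect_identical(smdAttr(mergeDatasets(a, b, attrPolicy = "drop")),
                   list())
  expect_error(mergeDatasets(a, b, attrPolicy = "require_equal"), "temp")
  expect_identical(
    smdAttr(mergeDatasets(a, a, attrPolicy = "require_equal"))$temp, 22)
})

test_that("filter keeps ids and order; predicate language works", {
  lens <- c(2L, 3L, 5L)
  trs <- lapply(lens, function(n)
    SMDTrace(seq_len(n) / 10, list(fret = rep(0.5, n)),
             attr = if (n != 3L) list(snr = n) else list()))
  d <- SMDDataset(trs, "lengths")
  kept <- filterTraces(d, "length >= 3")
  expect_identical(nTraces(kept), 2L)
  expect_identical(vapply(traces(kept), smdId, character(1L)),
                   vapply(traces(d)[2:3], smdId, character(1L)))
  ## a trace lacking the attr key fails the predicate (is removed)
  expect_identical(nTraces(filterTraces(d, "attr.snr > 2")), 1L)
  expect_identical(nTraces(filterTraces(d, "attr.snr >= 2")), 2L)
  ## id membership
  want <- smdId(d[[2]])
  byId <- filterTraces(d, sprintf("id in [%s]", want))
  expect_identical(vapply(traces(byId), smdId, character(1L)), want)
  ## function predicates work identically
  expect_identical(
    smdId(filterTraces(d, function(tr) length(tr) >= 3L)),
    smdId(kept))
})

test_that("always-true filters preserve the trace list", {
  d <- simulateDataset(nTraces = 3, nPoints = 10, seed = 5)
  same <- filterTraces(d, "length >= 0")
  expect_identical(vapply(traces(same), smdId, character(1L)),
                   vapply(traces(d), smdId, character(1L)))
  expect_identical(smdId(same), smdId(d))  # same desc/attr/types/traces
})

test_that("text comparisons support equality only", {
  tr <- SMDTrace(0, list(fret = 0.5), attr = list(condition = "A"))
  d <- SMDDataset(list(tr), "txt")
  expect_identical(nTraces(filterTraces(d, "attr.condition == 'A'")), 1L)
  expect_identical(nTraces(filterTraces(d, "attr.condition != 'A'")), 0L)
  expect_error(filterTraces(d, "attr.condition > 'A'"), "text")
})

test_that("filter composition equals a conjunctive filter", {
  for (seed in c(4, 11)) {
    d <- randomDataset(seed)
    p <- "length >= 5"; q <- "attr.snr > 1"
    composed <- filterTraces(filterTraces(d, p), q)
    manual <- filterTraces(d, function(tr) {
      isTRUE(length(tr) >= 5L) && isTRUE(!is.null(traceAttr(tr)$snr) &&
                                           traceAttr(tr)$snr > 1)
    })
    expect_identical(vapply(traces(composed), smdId, character(1L)),
                     vapply(traces(manual), smdId, character(1L)))
  }
})

test_that("split partitions the dataset by attribute value", {
  trs <- lapply(1:5, function(i)
    SMDTrace(i / 10, list(fret = 0.5 + i / 100),
             attr = list(condition = c("A", "A", "B", "B", "B")[i])))
  d <- SMDDataset(trs, "split me")
  parts <- splitByAttr(d, "condition")
  expect_identical(names(parts), c("A", "B"))
  expect_identical(nTraces(parts$A), 2L)
  expect_identical(nTraces(parts$B), 3L)
  expect_setequal(
    unlist(lapply(parts, function(p)
      vapply(traces(p), smdId, character(1L)))),
    vapply(traces(d), smdId, character(1L)))
  for (p in parts) expect_true(all(verifyIds(p)$match))
})

test_that("split requires the key on every trace", {
  trs <- list(SMDTrace(0, list(fret = 0.5), attr = list(condition = "A")),
              SMDTrace(0.1, list(fret = 0.6)))
  d <- SMDDataset(trs, "missing key")
  expect_error(splitByAttr(d, "condition"), smdId(d[[2]]))
})

test_that("split part counts always sum to the original trace count", {
  for (seed in c(2, 9, 30)) {
    d <- randomDataset(seed)
    withCond <- filterTraces(d, function(tr)
      !is.null(traceAttr(tr)$condition))
    if (nTraces(withCond) == 0L) next
    parts <- splitByAttr(withCond, "condition")
    expect_identical(sum(vapply(parts, nTraces, integer(1L))),
                     nTraces(withCond))
  }
})

test_that("attaching a channel changes ids and records provenance", {
  d <- simulateDataset(nTraces = 2, nPoints = 10, seed = 6)
  oldIds <- vapply(traces(d), smdId, character(1L))
  idealized <- lapply(traces(d), function(tr)
    round(1 - traceValues(tr)$fret))
  d2 <- attachChannel(d, "anticorr", idealized, tag = "int")
  expect_true("anticorr" %in% names(channelTypes(d2)))
  expect_identical(unname(channelTypes(d2)["anticorr"]), "int")
  newIds <- vapply(traces(d2), smdId, character(1L))
  expect_false(any(newIds == oldIds))
  expect_identical(vapply(traces(d2), function(tr)
    traceAttr(tr)$prior_id, character(1L)), oldIds)
  expect_true(all(verifyIds(d2)$match))
  expect_true(validateSMD(d2)$valid)
  ## the input is untouched (copy semantics)
  expect_identical(vapply(traces(d), smdId, character(1L)), oldIds)
})

test_that("attach refuses duplicates and length mismatches", {
  d <- simulateDataset(nTraces = 2, nPoints = 10, seed = 6)
  series <- lapply(traces(d), function(tr) rep(0, length(tr)))
  expect_error(attachChannel(d, "state", series), "already exists")
  short <- series; short[[2]] <- short[[2]][-1]
  expect_error(attachChannel(d, "z", short), smdId(d[[2]]))
})

test_that("summary counts points and pools channel statistics", {
  trs <- lapply(1:2, function(i)
    SMDTrace(c(0, 0.1, 0.2), list(c05 = rep(0.5, 3),
                                  gap = c(NA, NA, NA))))
  d <- SMDDataset(trs, "summary fixture",
                  types = c(c05 = "float", gap = "float"))
  s <- summarizeDataset(d)
  expect_identical(s$nTraces, 2L)
  expect_identical(s$nPointsTotal, 6L)
  pc <- s$perChannel
  expect_identical(pc$mean[pc$channel == "c05"], 0.5)
  expect_identical(pc$nNull[pc$channel == "gap"], 6L)
  expect_true(is.na(pc$mean[pc$channel == "gap"]))
  expect_identical(s$traceLength$min, 3L)
  expect_identical(s$traceLength$max, 3L)
})
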