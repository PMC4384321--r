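test_that("trace construction stores data unchanged and computes a hex id", {
  tr <- SMDTrace(index = c(0, 0.1, 0.2),
                 values = list(donor = c(100, 90, 95),
                               acceptor = c(20, 25, 22)))
  expect_s4_class(tr, "SMDTrace")
  expect_length(tr, 3L)
  expect_identical(channelNames(tr), c("acceptor", "donor"))
  expect_identical(traceValues(tr)$donor, c(100, 90, 95))
  expect_match(smdId(tr), "^[0-9a-f]{32}$")
  expect_true(validObject(tr))
})

test_that("empty traces are legal and still carry a 32-hex id", {
  tr <- SMDTrace(index = numeric(), values = list(fret = numeric()))
  expect_length(tr, 0L)
  expect_match(smdId(tr), "^[0-9a-f]{32}$")
})

test_that("trace construction errors name the offending channel", {
  expect_error(SMDTrace(index = c(0, 1), values = list(fret = 0.5)),
               "fret.*length 1.*length 2")
  expect_error(SMDTrace(index = 0, values = list()), "non-empty")
  expect_error(SMDTrace(index = c(0, NA), values = list(a = c(1, 2))),
               "finite")
  expect_error(SMDTrace(index = 0:1, values = list(c(1, 2))),
               "channel names")
})

test_that("dataset construction enforces a fixed channel set", {
  d <- makeDemoDataset()
  expect_identical(nTraces(d), 2L)
  expect_identical(sort(names(channelTypes(d))), c("acceptor", "donor"))
  t1 <- SMDTrace(0, values = list(donor = 1))
  t2 <- SMDTrace(0, values = list(fret = 0.5))
  expect_error(SMDDataset(list(t1, t2)), "donor.*fret|fret.*donor")
})

test_that("empty desc and a dataset of one empty trace are permitted", {
  tr <- SMDTrace(numeric(), list(fret = numeric()))
  d <- SMDDataset(list(tr), desc = "")
  expect_identical(smdDesc(d), "")
  expect_true(validateSMD(d)$valid)
})

test_that("empty datasets require an explicit type map", {
  expect_error(SMDDataset(list()), "explicit 'types'")
  d <- SMDDataset(list(), types = c(fret = "float"))
  expect_identical(nTraces(d), 0L)
  expect_true(validateSMD(d)$valid)
})

test_that("supplied types must match the channel set and the data", {
  tr <- makeDemoTrace()
  expect_error(SMDDataset(list(tr), types = c(donor = "float")),
               "acceptor")
  expect_error(
    SMDDataset(list(SMDTrace(0:1, list(fret = c(0.1, 0.5)))),
               types = c(fret = "int")),
    "row 1.*'int'")
  expect_error(SMDDataset(list(tr), types = c(donor = "double",
                                              acceptor = "float")),
               "unknown type tag")
})

## independent promotion oracle: enumerate the tag lattice and pick the
## narrowest tag whose value set covers every observed value
oracleTag <- function(vectors) {
  covers <- function(tag, v) {
    v <- v[!is.na(v)]
    switch(tag,
      bool = is.logical(v),
      int = is.logical(v) || (is.numeric(v) && all(v == trunc(v))),
      float = is.logical(v) || is.numeric(v),
      string = is.character(v))
  }
  for (tag in c("bool", "int", "float", "string")) {
    if (all(vapply(vectors, function(v) covers(tag, v), logical(1L))))
      return(tag)
  }
  NA_character_
}

test_that("type inference matches brute-force promotion over the lattice", {
  pool <- list(
    c(0, 1, 1, 0), c(0, 0.5), c(-3, 7), c(TRUE, FALSE), c(TRUE, NA),
    c("on", "off"), numeric(), c(2, NA), c(1e9, 2e9), c(0.25, NA, 1))
  set.seed(11)
  for (rep in 1:25) {
    vecs <- pool[sample(length(pool), sample(1:3, 1L), replace = TRUE)]
    expected <- oracleTag(vecs)
    trs <- lapply(vecs, function(v)
      SMDTrace(seq_along(v) * 0.1, stats::setNames(list(v), "ch")))
    if (is.na(expected)) {
      expect_error(inferTypes(trs), "ch")
    } else {
      expect_identical(unname(inferTypes(trs)["ch"]), expected)
    }
  }
})

test_that("type inference promotes int to float and rejects mixed text", {
  t1 <- SMDTrace(0:3 / 10, list(state = c(0, 1, 1, 0)))
  expect_identical(unname(inferTypes(list(t1))), "int")
  t2 <- SMDTrace(0:1 / 10, list(state = c(0, 0.5)))
  expect_identical(unname(inferTypes(list(t1, t2))["state"]), "float")
  t3 <- SMDTrace(0:1 / 10, list(label = c("on", "off")))
  t4 <- SMDTrace(0, list(label = 1))
  expect_error(inferTypes(list(t3, t4)), "label")
})

test_that("type inference is idempotent on a constructed dataset", {
  for (seed in c(3, 17, 92)) {
    d <- randomDataset(seed)
    expect_identical(inferTypes(d)[sort(names(channelTypes(d)))],
                     channelTypes(d)[sort(names(channelTypes(d)))])
  }
})

test_that("stored trace id is reproducible from the data alone", {
  tr <- makeDemoTrace()
  expect_identical(traceId(tr), smdId(tr))
  d <- makeDemoDataset()
  expect_identical(datasetId(d), smdId(d))
})

test_that("constructor outputs always pass strict validation", {
  for (seed in 1:10) {
    rep <- validateSMD(randomDataset(seed), mode = "strict")
    expect_true(rep$valid)
    expect_false(any(rep$issues$severity == "error"))
  }
})

test_that("dataset subsetting keeps trace ids and revalidates", {
  d <- makeDemoDataset()
  sub <- d[2]
  expect_identical(nTraces(sub), 1L)
  expect_identical(smdId(sub[[1]]), smdId(d[[2]]))
  expect_true(all(verifyIds(sub)$match))
})
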