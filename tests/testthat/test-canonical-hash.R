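test_that("canonical bytes have sorted keys and no whitespace", {
  ## attr {"b":1,"a":2} serializes with keys re-sorted
  expect_identical(rawToChar(canonicalBytes(list(b = 1, a = 2))),
                   "{\"a\":2,\"b\":1}")
  tr <- SMDTrace(0:1, list(b = c(1, 2), a = c(3, 4)))
  txt <- rawToChar(canonicalBytes(tr))
  expect_identical(txt,
    "{\"index\":[0,1],\"values\":{\"a\":[3,4],\"b\":[1,2]}}")
  expect_false(grepl("[ \n\t]", txt))
})

test_that("empty trace node serializes to the fixed canonical form", {
  ## degenerate node: no rows, no channels
  expect_identical(smdformat:::.canonTraceBody(numeric(), list()),
                   "{\"index\":[],\"values\":{}}")
})

test_that("canonical number rendering: integers bare, floats shortest", {
  canon <- function(x) rawToChar(canonicalBytes(list(v = x)))
  expect_identical(canon(2), "{\"v\":2}")
  expect_identical(canon(2.5), "{\"v\":2.5}")
  expect_identical(canon(0.1), "{\"v\":0.1}")
  expect_identical(canon(-0), "{\"v\":0}")
  expect_identical(canon(1e6), "{\"v\":1000000}")
  ## shortest form must re-parse to the identical double
  set.seed(5)
  for (x in c(1 / 3, pi, rnorm(50), rexp(10, 1e-6), runif(10) * 1e-9)) {
    s <- sub("\\}$", "", sub("^\\{\"v\":", "", canon(x)))
    expect_identical(as.numeric(s), x)
  }
})

test_that("non-finite numbers are rejected with a JSON path", {
  tr <- SMDTrace(0, list(donor = 1))
  tr@values$donor <- NaN  # bypass the constructor to forge a bad node
  expect_error(canonicalBytes(tr), "values\\.donor.*non-finite")
  expect_error(canonicalBytes(list(a = Inf)), "non-finite")
  ## NA is not rejected: it is the null encoding for dropped frames
  expect_identical(rawToChar(canonicalBytes(list(a = NA_real_))),
                   "{\"a\":null}")
})

test_that("trace ids match an independent MD5 implementation", {
  for (seed in c(1, 8)) {
    d <- randomDataset(seed)
    for (tr in traces(d))
      expect_identical(traceId(tr), md5_oracle(canonicalBytes(tr)))
    expect_identical(datasetId(d), md5_oracle(canonicalBytes(d)))
  }
})

test_that("every produced id is a 32-digit lowercase hex number", {
  for (seed in 1:5) {
    d <- randomDataset(seed)
    ids <- c(smdId(d), vapply(traces(d), smdId, character(1L)))
    expect_true(all(grepl("^[0-9a-f]{32}$", ids)))
  }
})

test_that("trace id ignores attr: annotation does not change identity", {
  base <- SMDTrace(c(0, 0.1), list(fret = c(0.2, 0.8)))
  annotated <- SMDTrace(c(0, 0.1), list(fret = c(0.2, 0.8)),
                        attr = list(k_fold = 1.5, note = "fitted"))
  expect_identical(smdId(base), smdId(annotated))
})

test_that("channel insertion order does not change the trace id", {
  a <- SMDTrace(0:1, list(a = c(1, 2), b = c(3, 4)))
  b <- SMDTrace(0:1, list(b = c(3, 4), a = c(1, 2)))
  expect_identical(smdId(a), smdId(b))
})

test_that("hash domains separate trace data from dataset metadata", {
  d <- makeDemoDataset()
  traceIds <- vapply(traces(d), smdId, character(1L))

  ## editing top-level attr changes only the dataset id
  d2 <- SMDDataset(traces(d), desc = smdDesc(d),
                   attr = c(smdAttr(d), list(extra = 1)),
                   types = channelTypes(d))
  expect_identical(vapply(traces(d2), smdId, character(1L)), traceIds)
  expect_false(smdId(d2) == smdId(d))

  ## editing any channel value changes that trace id (exhaustive over
  ## the fixture's traces and channels)
  for (i in seq_len(nTraces(d))) {
    for (ch in channelNames(d)) {
      tr <- d[[i]]
      vals <- traceValues(tr)
      vals[[ch]][1L] <- vals[[ch]][1L] + 1
      mutated <- SMDTrace(traceIndex(tr), vals, traceAttr(tr))
      expect_false(smdId(mutated) == smdId(tr))
    }
  }

  ## reordering traces changes the dataset id (ordered serialization)
  dRev <- SMDDataset(rev(traces(d)), desc = smdDesc(d),
                     attr = smdAttr(d), types = channelTypes(d))
  expect_false(smdId(dRev) == smdId(d))
  expect_setequal(vapply(traces(dRev), smdId, character(1L)), traceIds)
})

test_that("serialization is deterministic across repeated calls", {
  d <- randomDataset(21)
  expect_identical(canonicalBytes(d), canonicalBytes(d))
  expect_identical(smdToJSON(d), smdToJSON(d))
})

test_that("verifyIds flags exactly the corrupted trace plus the top level", {
  d <- makeDemoDataset()
  expect_true(all(verifyIds(d)$match))

  ## corrupt one channel value through the raw representation
  raw <- jsonlite::parse_json(smdToJSON(d), simplifyVector = FALSE)
  raw$data[[1]]$values$donor[[1]] <- 999
  rep <- verifyIds(raw)
  expect_identical(sum(!rep$match), 2L)
  expect_identical(rep$scope[!rep$match], c("trace", "dataset"))
  expect_identical(rep$position[!rep$match][1L], 1L)

  ## stripping ids reports every entry as missing
  raw2 <- jsonlite::parse_json(smdToJSON(d), simplifyVector = FALSE)
  raw2$id <- NULL
  for (i in seq_along(raw2$data)) raw2$data[[i]]$id <- NULL
  rep2 <- verifyIds(raw2)
  expect_true(all(is.na(rep2$stored)))
  expect_false(any(rep2$match))
})
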