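# Fixtures are built in code: nothing here touches the network or
# external data. randomDataset() draws structurally varied datasets
# (empty traces, nulls, nested/vector attrs, unicode text) for
# property-style tests.

makeDemoTrace <- function() {
  SMDTrace(index = c(0, 0.1, 0.2),
           values = list(donor = c(100, 90, 95),
                         acceptor = c(20, 25, 22)),
           attr = list(snr = 3.2))
}

makeDemoDataset <- function() {
  t1 <- makeDemoTrace()
  t2 <- SMDTrace(index = c(0, 0.1),
                 values = list(donor = c(80.5, 85),
                               acceptor = c(30, 28.25)),
                 attr = list(snr = 2.0, condition = "A"))
  SMDDataset(list(t1, t2), desc = "demo dataset",
             attr = list(instrument = "synthetic rig", temperature_C = 22))
}

.unicodePool <- c("two-state folder", "smFRET träce ✓",
                  "δη dataset", "cond 10 µM", "")

randomTrace <- function(channels, len) {
  vals <- lapply(channels, function(ch) {
    v <- switch(ch,
      donor = round(stats::rnorm(len, 2000, 300), 3),
      acceptor = round(stats::rnorm(len, 8000, 300), 3),
      fret = stats::runif(len),
      state = as.numeric(sample(0:2, len, replace = TRUE)),
      label = sample(c("on", "off", "blinkéd"), len, replace = TRUE),
      ok = sample(c(TRUE, FALSE), len, replace = TRUE))
    if (len > 0 && stats::runif(1) < 0.3)
      v[sample(len, max(1L, len %/% 5L))] <- NA
    v
  })
  names(vals) <- channels
  at <- list()
  if (stats::runif(1) < 0.7) at$snr <- round(stats::runif(1, 0.5, 5), 3)
  if (stats::runif(1) < 0.5) at$condition <- sample(c("A", "B"), 1L)
  if (stats::runif(1) < 0.3)
    at$fit <- list(k_on = round(stats::rexp(1), 4), model = "hmm")
  if (stats::runif(1) < 0.3) at$rates <- round(stats::rexp(3), 4)
  SMDTrace(index = cumsum(stats::runif(len, 0.05, 0.15)),
           values = vals, attr = at)
}

randomDataset <- function(seed) {
  set.seed(seed)
  channels <- c("donor", "acceptor",
                sample(c("fret", "state", "label", "ok"),
                       sample(0:2, 1L)))
  nTr <- sample(1:4, 1L)
  lens <- sample(0:20, nTr, replace = TRUE)
  trs <- lapply(lens, function(l) randomTrace(channels, l))
  at <- list(project = sample(.unicodePool, 1L))
  if (stats::runif(1) < 0.5)
    at$acquisition <- list(rate_hz = 10L, camera = "emccd")
  SMDDataset(trs, desc = sample(.unicodePool, 1L), attr = at)
}

## annotate every trace with an alternating "group" attr (A/B); trace
## ids are unaffected because attr is outside the trace hash domain
attachLabels <- function(d) {
  trs <- lapply(seq_len(nTraces(d)), function(i) {
    tr <- d[[i]]
    SMDTrace(traceIndex(tr), traceValues(tr),
             c(traceAttr(tr), list(group = c("A", "B")[1L + i %% 2L])))
  })
  SMDDataset(trs, desc = smdDesc(d), attr = smdAttr(d),
             types = channelTypes(d))
}

expect_smd_equal <- function(a, b) {
  expect_identical(smdId(a), smdId(b))
  expect_identical(vapply(traces(a), smdId, character(1L)),
                   vapply(traces(b), smdId, character(1L)))
  expect_identical(smdToJSON(a), smdToJSON(b))
}

## independent MD5 route (base R, file-based) used as hashing oracle
md5_oracle <- function(bytes) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(bytes, f)
  unname(tools::md5sum(f))
}
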