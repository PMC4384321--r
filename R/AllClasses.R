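#' @import methods
NULL

#' Scalar type tags understood by the SMD format
#'
#' The closed set of scalar types a channel may declare in a dataset's
#' type map. `"bool"` promotes to `"int"` promotes to `"float"`;
#' `"string"` does not mix with the numeric tags.
#'
#' @export
SMD_TYPE_TAGS <- c("bool", "int", "float", "string")

.isHex32 <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[0-9a-f]{32}$", x)
}

#' SMDTrace: one molecule's time series
#'
#' An `SMDTrace` holds the record of a single molecule: an `index` of
#' numeric row labels (typically acquisition times in seconds), a set of
#' named channels in `values` (each an atomic vector exactly as long as
#' the index; `NA` encodes a missing measurement, serialized as JSON
#' `null`), free-form trace annotations in `attr`, and a content `id` —
#' the lowercase 32-character hexadecimal MD5 digest of the canonical
#' serialization of `index` and `values`. The id is a function of the
#' data alone: annotating a trace does not change its identity.
#'
#' Use the [SMDTrace()] constructor, which establishes all invariants
#' (including the id) at build time, rather than `new()`.
#'
#' @slot id character(1), lowercase 32-digit hexadecimal content id.
#' @slot index numeric vector of finite row labels.
#' @slot values named list of atomic vectors (numeric, character or
#'   logical), one per channel, each the same length as `index`.
#' @slot attr named list of trace annotations.
#'
#' @seealso [SMDDataset()], [traceId()], [traceIndex()], [traceValues()]
#' @export
setClass("SMDTrace", representation(
  id = "character",
  index = "numeric",
  values = "list",
  attr = "list"
))

setValidity("SMDTrace", function(object) {
  msgs <- character()
  if (!.isHex32(object@id))
    msgs <- c(msgs, "'id' must be a 32-character lowercase hex string")
  if (anyNA(object@index) || any(!is.finite(object@index)))
    msgs <- c(msgs, "'index' must be finite")
  v <- object@values
  if (length(v) == 0L)
    msgs <- c(msgs, "at least one channel is required")
  nm <- names(v)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    msgs <- c(msgs, "channel names must be unique and non-empty")
  bad <- names(v)[lengths(v) != length(object@index)]
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "channel '%s' has length %d but index has length %d",
      bad[1L], length(v[[bad[1L]]]), length(object@index)))
  if (length(msgs)) msgs else TRUE
})

#' SMDDataset: a set of traces from one experiment
#'
#' An `SMDDataset` is the top-level SMD container: a description string
#' `desc`, dataset-level annotations `attr` (experimental conditions,
#' acquisition date, summary statistics, ...), a type map `types`
#' declaring the scalar type of every channel, and the ordered list of
#' traces in `data`. All traces share one fixed set of channels — the
#' key set of `types`. The dataset `id` is the MD5 digest of the
#' canonical serialization of the entire structure (`desc`, `attr`,
#' `types` and the trace list, trace ids included; the top-level id
#' itself is excluded from its own hash).
#'
#' Use the [SMDDataset()] constructor rather than `new()`.
#'
#' @slot id character(1), lowercase 32-digit hexadecimal content id.
#' @slot desc character(1) free-text description (may be empty).
#' @slot attr named list of dataset-level annotations.
#' @slot types named character vector mapping each channel name to one
#'   of [SMD_TYPE_TAGS].
#' @slot data list of [SMDTrace-class] objects, order significant.
#'
#' @seealso [SMDDataset()], [readSMD()], [writeSMD()], [datasetId()]
#' @export
setClass("SMDDataset", representation(
  id = "character",
  desc = "character",
  attr = "list",
  types = "character",
  data = "list"
))

setValidity("SMDDataset", function(object) {
  msgs <- character()
  if (!.isHex32(object@id))
    msgs <- c(msgs, "'id' must be a 32-character lowercase hex string")
  if (length(object@desc) != 1L || is.na(object@desc))
    msgs <- c(msgs, "'desc' must be a single string")
  ty <- object@types
  if (length(ty) == 0L)
    msgs <- c(msgs, "'types' must declare at least one channel")
  if (is.null(names(ty)) || any(!nzchar(names(ty))) || anyDuplicated(names(ty)))
    msgs <- c(msgs, "'types' names must be unique and non-empty")
  if (!all(ty %in% SMD_TYPE_TAGS))
    msgs <- c(msgs, sprintf("unknown type tag '%s'",
                            ty[!ty %in% SMD_TYPE_TAGS][1L]))
  want <- sort(names(ty))
  for (i in seq_along(object@data)) {
    tr <- object@data[[i]]
    if (!is(tr, "SMDTrace")) {
      msgs <- c(msgs, sprintf("data[[%d]] is not an SMDTrace", i))
      next
    }
    if (!identical(sort(names(tr@values)), want)) {
      msgs <- c(msgs, sprintf(
        "trace %d channels {%s} do not match the declared set {%s}",
        i, paste(sort(names(tr@values)), collapse = ", "),
        paste(want, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' KineticModel: parameterization of the smFRET trace simulator
#'
#' A discrete-time Markov chain over `K` conformational states observed
#' through donor and acceptor fluorescence intensities. At every frame
#' the state advances according to the row-stochastic per-frame
#' transition matrix `A`; the initial state is drawn from `pi0`.
#' Each channel's emission is the state's mean intensity plus Gaussian
#' noise of standard deviation `noiseSd`.
#'
#' @slot A K x K row-stochastic transition probability matrix (per
#'   frame, dimensionless).
#' @slot pi0 initial state distribution, length K, sums to 1.
#' @slot dt frame interval in seconds (> 0).
#' @slot donorMean,acceptorMean per-state emission means, length K
#'   (arbitrary intensity units).
#' @slot noiseSd Gaussian emission noise standard deviation (> 0), same
#'   units as the means, applied to both channels.
#'
#' @seealso [kineticModel()], [simulateTrace()], [simulateDataset()]
#' @export
setClass("KineticModel", representation(
  A = "matrix",
  pi0 = "numeric",
  dt = "numeric",
  donorMean = "numeric",
  acceptorMean = "numeric",
  noiseSd = "numeric"
))

setValidity("KineticModel", function(object) {
  msgs <- character()
  A <- object@A
  K <- nrow(A)
  if (is.null(K) || K < 2L || ncol(A) != K)
    msgs <- c(msgs, "'A' must be a square matrix with K >= 2")
  else {
    if (any(A < 0) || any(A > 1))
      msgs <- c(msgs, "entries of 'A' must lie in [0, 1]")
    if (any(abs(rowSums(A) - 1) > 1e-12))
      msgs <- c(msgs, "rows of 'A' must sum to 1 (tolerance 1e-12)")
    if (length(object@pi0) != K || abs(sum(object@pi0) - 1) > 1e-12 ||
        any(object@pi0 < 0))
      msgs <- c(msgs, "'pi0' must be a length-K distribution summing to 1")
    if (length(object@donorMean) != K || length(object@acceptorMean) != K)
      msgs <- c(msgs, "emission means must have length K")
  }
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "'dt' must be a positive scalar (seconds)")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd <= 0)
    msgs <- c(msgs, "'noiseSd' must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})
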