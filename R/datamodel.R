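## In-memory SMD object model. Constructors establish every invariant —
## including content ids — at build time, so a constructed object always
## passes strict validation.

.TAG_RANK <- c(bool = 1L, int = 2L, float = 3L)

## narrowest tag for one stored channel vector
.tagOfVector <- function(v) {
  if (is.factor(v)) v <- as.character(v)
  if (is.logical(v)) "bool"
  else if (is.numeric(v)) {
    x <- v[!is.na(v)]
    if (all(x == trunc(x))) "int" else "float"
  }
  else if (is.character(v)) "string"
  else stop(sprintf("unsupported channel storage class '%s'", class(v)[1L]))
}

.promoteTags <- function(tags, channel) {
  tags <- unique(tags)
  if ("string" %in% tags) {
    if (length(tags) > 1L)
      stop(sprintf(
        "channel '%s' mixes text and non-text values; no common type",
        channel), call. = FALSE)
    return("string")
  }
  names(.TAG_RANK)[max(.TAG_RANK[tags])]
}

## coerce a channel vector to its declared tag; returns the vector or
## stops naming the first offending row
.coerceTag <- function(v, tag, channel) {
  if (is.factor(v)) v <- as.character(v)
  offend <- function(i) stop(sprintf(
    "channel '%s' value at row %d does not conform to declared type '%s'",
    channel, i, tag), call. = FALSE)
  firstBad <- function(bad) { i <- which(bad); if (length(i)) offend(i[1L]) }
  switch(tag,
    float = {
      if (is.character(v)) firstBad(!is.na(v))
      as.numeric(v)
    },
    int = {
      if (is.character(v)) firstBad(!is.na(v))
      x <- as.numeric(v)
      firstBad(!is.na(x) & x != trunc(x))
      x
    },
    bool = {
      if (!is.logical(v)) firstBad(!is.na(v))
      as.logical(v)
    },
    string = {
      if (!is.character(v)) firstBad(!is.na(v))
      as.character(v)
    },
    stop(sprintf("unknown type tag '%s'", tag), call. = FALSE))
}

#' Construct a single-molecule trace
#'
#' Builds an [SMDTrace-class] from a numeric index (row labels,
#' typically acquisition times in seconds) and a named list of channel
#' vectors, computing the trace's MD5 content id from the canonical
#' serialization of `index` and `values`. Sequences are stored exactly
#' as given, without reordering; `NA` in a channel encodes a missing
#' measurement (JSON `null`).
#'
#' @param index numeric vector of finite row labels (may be empty).
#' @param values named list of atomic vectors (numeric, logical,
#'   character or factor), each the same length as `index`. At least
#'   one channel is required.
#' @param attr named list of trace annotations (fitted parameters,
#'   pre-processing settings, ...). Defaults to empty.
#' @return An [SMDTrace-class] object.
#' @examples
#' tr <- SMDTrace(index = c(0, 0.1, 0.2),
#'                values = list(donor = c(100, 90, 95),
#'                              acceptor = c(20, 25, 22)))
#' smdId(tr)
#' @export
SMDTrace <- function(index, values, attr = list()) {
  index <- as.numeric(index)
  if (anyNA(index) || any(!is.finite(index)))
    stop("'index' must contain only finite numbers", call. = FALSE)
  if (!is.list(values) || length(values) == 0L)
    stop("'values' must be a non-empty named list of channels",
         call. = FALSE)
  nm <- names(values)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("channel names must be unique and non-empty", call. = FALSE)
  values <- lapply(values, function(v) {
    if (is.factor(v)) as.character(v)
    else if (is.atomic(v)) unname(v)
    else stop("channels must be atomic vectors", call. = FALSE)
  })
  badLen <- which(lengths(values) != length(index))
  if (length(badLen))
    stop(sprintf("channel '%s' has length %d but index has length %d",
                 nm[badLen[1L]], length(values[[badLen[1L]]]),
                 length(index)), call. = FALSE)
  attr <- .checkAttrList(attr, "attr")
  id <- .md5(.canonTraceBody(index, values))
  new("SMDTrace", id = id, index = index, values = values, attr = attr)
}

.checkAttrList <- function(attr, what) {
  if (is.null(attr)) return(list())
  if (!is.list(attr))
    stop(sprintf("'%s' must be a named list", what), call. = FALSE)
  if (length(attr) && (is.null(names(attr)) || any(!nzchar(names(attr)))))
    stop(sprintf("'%s' entries must all be named", what), call. = FALSE)
  if (anyDuplicated(names(attr)))
    stop(sprintf("'%s' keys must be unique", what), call. = FALSE)
  attr
}

#' Infer the channel type map from a set of traces
#'
#' Determines, for every channel, the narrowest scalar type tag that
#' covers all observed values across the traces, using the promotion
#' order `bool < int < float`. Any text value forces `"string"`; a
#' channel mixing text with numeric or logical values has no common
#' type and is an error. `NA` values carry no type information.
#'
#' @param traces a list of [SMDTrace-class] objects (at least one),
#'   all sharing the same channel set, or an [SMDDataset-class].
#' @return A named character vector mapping channel names to tags in
#'   [SMD_TYPE_TAGS].
#' @examples
#' t1 <- SMDTrace(0:1, list(fret = c(0, 1)))    # whole numbers: int
#' t2 <- SMDTrace(0:1, list(fret = c(0, 0.5)))  # forces float
#' inferTypes(list(t1, t2))
#' @export
inferTypes <- function(traces) {
  if (is(traces, "SMDDataset")) traces <- traces@data
  if (is(traces, "SMDTrace")) traces <- list(traces)
  if (length(traces) == 0L)
    stop("cannot infer types from zero traces; supply an explicit type map",
         call. = FALSE)
  channels <- sort(names(traces[[1L]]@values))
  out <- vapply(channels, function(ch) {
    tags <- vapply(traces, function(tr) {
      if (!ch %in% names(tr@values))
        stop(sprintf("channel '%s' missing from a trace", ch), call. = FALSE)
      .tagOfVector(tr@values[[ch]])
    }, character(1L))
    .promoteTags(tags, ch)
  }, character(1L))
  out
}

#' Construct a single-molecule dataset
#'
#' Assembles traces into an [SMDDataset-class]. All traces must share
#' one fixed set of channels; the channel type map is inferred with
#' [inferTypes()] when not supplied. Channel storage is coerced to the
#' declared tags (so a channel declared `float` is stored numerically
#' in every trace), trace ids are recomputed if coercion changed any
#' storage, and the dataset's MD5 content id is computed over the
#' entire structure. Trace order is significant and preserved.
#'
#' @param traces a list of [SMDTrace-class] objects (possibly empty if
#'   `types` is supplied), or a single trace.
#' @param desc character(1) free-text description of the dataset.
#' @param attr named list of dataset-level annotations.
#' @param types optional named character vector of type tags; required
#'   when `traces` is empty, otherwise its key set must equal the
#'   traces' channel set.
#' @return An [SMDDataset-class] object.
#' @examples
#' tr <- SMDTrace(c(0, 0.1), list(donor = c(100, 90), acceptor = c(20, 25)))
#' d <- SMDDataset(list(tr), desc = "demo")
#' channelTypes(d)
#' @export
SMDDataset <- function(traces, desc = "", attr = list(), types = NULL) {
  if (is(traces, "SMDTrace")) traces <- list(traces)
  if (!is.list(traces) || !all(vapply(traces, is, logical(1L), "SMDTrace")))
    stop("'traces' must be a list of SMDTrace objects", call. = FALSE)
  desc <- as.character(desc)
  if (length(desc) != 1L || is.na(desc))
    stop("'desc' must be a single string", call. = FALSE)
  attr <- .checkAttrList(attr, "attr")

  if (length(traces)) {
    ref <- sort(names(traces[[1L]]@values))
    for (i in seq_along(traces)) {
      cur <- sort(names(traces[[i]]@values))
      if (!identical(cur, ref)) {
        only1 <- setdiff(ref, cur); only2 <- setdiff(cur, ref)
        stop(sprintf(
          "traces do not share a fixed channel set: trace 1 vs trace %d differ by {%s}",
          i, paste(c(only1, only2), collapse = ", ")), call. = FALSE)
      }
    }
  } else ref <- NULL

  if (is.null(types)) {
    if (!length(traces))
      stop("an explicit 'types' map is required for an empty dataset",
           call. = FALSE)
    types <- inferTypes(traces)
  } else {
    types <- .checkTypesMap(types)
    if (!is.null(ref) && !identical(sort(names(types)), ref)) {
      only1 <- setdiff(ref, names(types)); only2 <- setdiff(names(types), ref)
      stop(sprintf("'types' keys do not match the trace channel set: {%s}",
                   paste(c(only1, only2), collapse = ", ")), call. = FALSE)
    }
  }

  traces <- lapply(traces, function(tr) {
    changed <- FALSE
    vals <- tr@values
    for (ch in names(vals)) {
      coerced <- .coerceTag(vals[[ch]], types[[ch]], ch)
      if (!identical(coerced, vals[[ch]])) { vals[[ch]] <- coerced; changed <- TRUE }
    }
    if (changed) SMDTrace(tr@index, vals, tr@attr) else tr
  })

  entries <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    .canonTraceEntry(tr@id, tr@attr, tr@index, tr@values,
                     sprintf("$.data[%d]", i))
  }, character(1L))
  id <- .md5(.canonDatasetBody(desc, attr, types, entries))
  new("SMDDataset", id = id, desc = desc, attr = attr,
      types = types, data = traces)
}

.checkTypesMap <- function(types) {
  if (is.list(types)) types <- unlist(types)
  types <- vapply(types, as.character, character(1L))
  if (length(types) == 0L)
    stop("'types' must declare at least one channel", call. = FALSE)
  nm <- names(types)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("'types' names must be unique and non-empty", call. = FALSE)
  bad <- setdiff(types, SMD_TYPE_TAGS)
  if (length(bad))
    stop(sprintf("unknown type tag '%s' (legal: %s)", bad[1L],
                 paste(SMD_TYPE_TAGS, collapse = ", ")), call. = FALSE)
  types
}

## accessors ----------------------------------------------------------

#' Accessors for SMD objects
#'
#' Small accessor generics in place of direct slot access: `smdId()`
#' (the stored content id), `smdDesc()`, `smdAttr()`, `channelTypes()`
#' (the type map), `channelNames()`, `traces()` (the trace list),
#' `nTraces()`, and on traces `traceIndex()`, `traceValues()`,
#' `traceAttr()`. `length()` of a trace is its number of points;
#' `length()` of a dataset is its number of traces. `x[[i]]` extracts
#' one trace; `x[i]` subsets a dataset to the chosen traces (keeping
#' their ids and recomputing the dataset id).
#'
#' @param x an [SMDTrace-class] or [SMDDataset-class] object.
#' @return The corresponding component.
#' @name smdAccessors
NULL

#' @rdname smdAccessors
#' @export
setMethod("smdId", "SMDTrace", function(x) x@id)
#' @rdname smdAccessors
#' @export
setMethod("smdId", "SMDDataset", function(x) x@id)
#' @rdname smdAccessors
#' @export
setMethod("smdAttr", "SMDTrace", function(x) x@attr)
#' @rdname smdAccessors
#' @export
setMethod("smdAttr", "SMDDataset", function(x) x@attr)
#' @rdname smdAccessors
#' @export
setMethod("smdDesc", "SMDDataset", function(x) x@desc)
#' @rdname smdAccessors
#' @export
setMethod("channelTypes", "SMDDataset", function(x) x@types)
#' @rdname smdAccessors
#' @export
setMethod("channelNames", "SMDDataset", function(x) sort(names(x@types)))
#' @rdname smdAccessors
#' @export
setMethod("channelNames", "SMDTrace", function(x) sort(names(x@values)))
#' @rdname smdAccessors
#' @export
setMethod("traces", "SMDDataset", function(x) x@data)
#' @rdname smdAccessors
#' @export
setMethod("nTraces", "SMDDataset", function(x) length(x@data))
#' @rdname smdAccessors
#' @export
setMethod("traceIndex", "SMDTrace", function(x) x@index)
#' @rdname smdAccessors
#' @export
setMethod("traceValues", "SMDTrace", function(x) x@values)
#' @rdname smdAccessors
#' @export
setMethod("traceAttr", "SMDTrace", function(x) x@attr)

#' @rdname smdAccessors
#' @export
setMethod("length", "SMDTrace", function(x) length(x@index))
#' @rdname smdAccessors
#' @export
setMethod("length", "SMDDataset", function(x) length(x@data))

#' @rdname smdAccessors
#' @export
setMethod("[[", "SMDDataset", function(x, i) x@data[[i]])

#' @rdname smdAccessors
#' @param i trace indices (numeric or logical) for `[`/`[[`.
#' @export
setMethod("[", "SMDDataset", function(x, i) {
  SMDDataset(x@data[i], desc = x@desc, attr = x@attr, types = x@types)
})

setMethod("show", "SMDTrace", function(object) {
  cat(sprintf("SMDTrace: %d points, %d channel(s) [%s]\n",
              length(object@index), length(object@values),
              paste(sort(names(object@values)), collapse = ", ")))
  cat(sprintf("  id: %s\n", object@id))
  if (length(object@attr))
    cat(sprintf("  attr: %s\n", paste(names(object@attr), collapse = ", ")))
})

setMethod("show", "SMDDataset", function(object) {
  cat(sprintf("SMDDataset: %d trace(s)\n", length(object@data)))
  if (nzchar(object@desc)) cat(sprintf("  desc: %s\n", object@desc))
  ty <- object@types
  ord <- order(names(ty))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s<%s>", names(ty)[ord], ty[ord]),
                    collapse = ", ")))
  cat(sprintf("  id: %s\n", object@id))
  if (length(object@attr))
    cat(sprintf("  attr: %s\n", paste(names(object@attr), collapse = ", ")))
})
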