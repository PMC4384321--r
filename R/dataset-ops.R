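## Dataset algebra: merge, filter, split, derived-channel attachment and
## summaries. Every operation copies — inputs are never modified, which
## content ids make the only safe semantics — and every output passes
## strict validation with consistent ids.

.sameTypeMap <- function(a, b) {
  identical(a[sort(names(a))], b[sort(names(b))])
}

#' Merge datasets with a common channel set
#'
#' Concatenates the traces of several datasets, in argument order, into
#' one dataset. All inputs must declare identical type maps (same
#' channels, same tags). Trace ids are unchanged — merging does not
#' touch trace data — and the new dataset id is computed from the
#' merged structure.
#'
#' @param ... [SMDDataset-class] objects, or a single list of them.
#' @param desc description for the merged dataset; defaults to the
#'   first input's description.
#' @param attrPolicy how to combine top-level attributes:
#'   `"keep_first"` (default) keeps the first dataset's,
#'   `"require_equal"` insists all inputs agree (error naming the first
#'   differing key otherwise), `"drop"` discards them.
#' @return An [SMDDataset-class].
#' @examples
#' a <- simulateDataset(nTraces = 2, nPoints = 10, seed = 1)
#' b <- simulateDataset(nTraces = 3, nPoints = 10, seed = 2)
#' nTraces(mergeDatasets(a, b))
#' @export
mergeDatasets <- function(..., desc = NULL,
                          attrPolicy = c("keep_first", "require_equal",
                                         "drop")) {
  attrPolicy <- match.arg(attrPolicy)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1L]]) &&
      !is(dots[[1L]], "SMDDataset"))
    dots <- dots[[1L]]
  if (!length(dots) || !all(vapply(dots, is, logical(1L), "SMDDataset")))
    stop("supply at least one SMDDataset", call. = FALSE)
  ref <- dots[[1L]]@types
  for (i in seq_along(dots)) {
    if (!.sameTypeMap(ref, dots[[i]]@types)) {
      cur <- dots[[i]]@types
      diffCh <- c(setdiff(names(ref), names(cur)),
                  setdiff(names(cur), names(ref)))
      common <- intersect(names(ref), names(cur))
      diffTag <- common[ref[common] != cur[common]]
      stop(sprintf(
        "type maps differ between dataset 1 and dataset %d: %s", i,
        paste(c(sprintf("channel '%s' absent", diffCh),
                sprintf("channel '%s' tagged '%s' vs '%s'", diffTag,
                        ref[diffTag], cur[diffTag])), collapse = "; ")),
        call. = FALSE)
    }
  }
  attrOut <- switch(attrPolicy,
    keep_first = dots[[1L]]@attr,
    drop = list(),
    require_equal = {
      first <- dots[[1L]]@attr
      for (i in seq_along(dots)[-1L]) {
        cur <- dots[[i]]@attr
        keys <- union(names(first), names(cur))
        for (k in keys) {
          if (!identical(first[[k]], cur[[k]]))
            stop(sprintf(
              "attrPolicy 'require_equal': attribute '%s' differs between dataset 1 and dataset %d",
              k, i), call. = FALSE)
        }
      }
      first
    })
  if (is.null(desc)) desc <- dots[[1L]]@desc
  SMDDataset(do.call(c, lapply(dots, function(d) d@data)),
             desc = desc, attr = attrOut, types = ref)
}

## compact predicate language for trace selection:
##   "length >= 3"                   index length bounds
##   "attr.snr > 2"                  numeric attr comparison
##   "attr.condition == 'A'"         text attr equality (== / !=)
##   "id in [abc..., def...]"        id membership
## a predicate naming an attr key a trace lacks is FALSE for that trace
.parsePredicate <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec(
    "^length\\s*(==|!=|>=|<=|>|<|=)\\s*([0-9]+)$", txt))[[1L]]
  if (length(m)) {
    op <- if (m[2L] == "=") "==" else m[2L]
    n <- as.numeric(m[3L])
    return(function(tr) do.call(op, list(length(tr@index), n)))
  }
  m <- regmatches(txt, regexec("^id\\s+in\\s+\\[?([^]]+)\\]?$", txt))[[1L]]
  if (length(m)) {
    ids <- trimws(strsplit(m[2L], "[,[:space:]]+")[[1L]])
    ids <- tolower(ids[nzchar(ids)])
    return(function(tr) tolower(tr@id) %in% ids)
  }
  m <- regmatches(txt, regexec(
    "^attr\\.([^[:space:]<>=!]+)\\s*(==|!=|>=|<=|>|<|=)\\s*(.+)$",
    txt))[[1L]]
  if (length(m)) {
    key <- m[2L]
    op <- if (m[3L] == "=") "==" else m[3L]
    rhs <- trimws(m[4L])
    qm <- regmatches(rhs, regexec("^(['\"])(.*)\\1$", rhs))[[1L]]
    if (length(qm)) {
      val <- qm[3L]
      if (!op %in% c("==", "!="))
        stop(sprintf("operator '%s' is not defined for text values", op),
             call. = FALSE)
    } else {
      val <- suppressWarnings(as.numeric(rhs))
      if (is.na(val))
        stop(sprintf("cannot parse comparison value '%s'", rhs),
             call. = FALSE)
    }
    return(function(tr) {
      v <- tr@attr[[key]]
      if (is.null(v) || length(v) != 1L || is.na(v)) return(FALSE)
      if (is.character(val) && !is.character(v)) return(FALSE)
      if (is.numeric(val) && !is.numeric(v)) return(FALSE)
      isTRUE(do.call(op, list(v, val)))
    })
  }
  stop(sprintf("cannot parse predicate '%s'", txt), call. = FALSE)
}

#' Filter traces by predicate
#'
#' Keeps the traces satisfying a predicate; survivors keep their ids
#' and relative order, and the dataset id is recomputed. The predicate
#' is either an R function of one [SMDTrace-class] returning a single
#' logical, or a string in the compact predicate language:
#' `"length >= 3"`, `"attr.snr > 2"`, `"attr.condition == 'A'"`,
#' `"id in [<id1>, <id2>]"`. A predicate that references an attribute
#' key a trace does not carry evaluates to FALSE for that trace (the
#' trace is removed), as does any non-TRUE result.
#'
#' @param dataset an [SMDDataset-class].
#' @param predicate function or predicate string.
#' @return An [SMDDataset-class] with the surviving traces.
#' @examples
#' d <- simulateDataset(nTraces = 4, nPoints = 10, seed = 1)
#' nTraces(filterTraces(d, "length >= 5"))
#' @export
filterTraces <- function(dataset, predicate) {
  stopifnot(is(dataset, "SMDDataset"))
  f <- if (is.character(predicate)) .parsePredicate(predicate)
       else if (is.function(predicate)) predicate
       else stop("'predicate' must be a function or a predicate string",
                 call. = FALSE)
  keep <- vapply(dataset@data, function(tr) isTRUE(f(tr)), logical(1L))
  SMDDataset(dataset@data[keep], desc = dataset@desc, attr = dataset@attr,
             types = dataset@types)
}

#' Partition a dataset by a trace attribute
#'
#' Splits the dataset into one part per distinct value of the named
#' trace attribute, in order of first appearance. Every trace must
#' carry the key (error listing the offending trace ids otherwise); the
#' union of the parts is exactly the original trace set, and each part
#' is a fully re-hashed, valid dataset.
#'
#' @param dataset an [SMDDataset-class].
#' @param key a trace attribute key.
#' @return A named list of [SMDDataset-class] objects.
#' @export
splitByAttr <- function(dataset, key) {
  stopifnot(is(dataset, "SMDDataset"))
  vals <- lapply(dataset@data, function(tr) tr@attr[[key]])
  miss <- vapply(vals, is.null, logical(1L))
  if (any(miss))
    stop(sprintf("trace(s) missing attr key '%s': %s", key,
                 paste(vapply(dataset@data[miss], function(t) t@id,
                              character(1L)), collapse = ", ")),
         call. = FALSE)
  labels <- vapply(vals, function(v) as.character(v)[1L], character(1L))
  out <- lapply(unique(labels), function(lb) {
    SMDDataset(dataset@data[labels == lb], desc = dataset@desc,
               attr = dataset@attr, types = dataset@types)
  })
  names(out) <- unique(labels)
  out
}

#' Attach a derived channel to every trace
#'
#' Adds a new channel — typically a post-processing product such as an
#' idealized state trajectory — to every trace and to the type map.
#' Because trace ids are content hashes over `index` and `values`,
#' attaching a channel changes every trace's id; each trace's previous
#' id is preserved in its `attr` under `"prior_id"` so provenance
#' survives the identity change.
#'
#' @param dataset an [SMDDataset-class].
#' @param name new channel name (must not already exist).
#' @param series list with one value vector per trace, lengths matching
#'   each trace's index.
#' @param tag scalar type tag for the new channel; inferred from
#'   `series` when omitted.
#' @return A new [SMDDataset-class]; the input is unchanged.
#' @examples
#' d <- simulateDataset(nTraces = 2, nPoints = 10, seed = 1)
#' d2 <- attachChannel(d, "smoothed",
#'                     lapply(traces(d), function(t) traceValues(t)$fret))
#' "prior_id" %in% names(traceAttr(d2[[1]]))
#' @export
attachChannel <- function(dataset, name, series, tag = NULL) {
  stopifnot(is(dataset, "SMDDataset"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (name %in% names(dataset@types))
    stop(sprintf("channel '%s' already exists", name), call. = FALSE)
  if (!is.list(series) || length(series) != length(dataset@data))
    stop("'series' must be a list with one element per trace",
         call. = FALSE)
  if (is.null(tag)) {
    tags <- vapply(series, .tagOfVector, character(1L))
    tag <- .promoteTags(tags, name)
  } else if (!tag %in% SMD_TYPE_TAGS) {
    stop(sprintf("unknown type tag '%s'", tag), call. = FALSE)
  }
  newTraces <- lapply(seq_along(dataset@data), function(i) {
    tr <- dataset@data[[i]]
    s <- series[[i]]
    if (length(s) != length(tr@index))
      stop(sprintf(
        "series for trace %s has length %d but the trace has %d points",
        tr@id, length(s), length(tr@index)), call. = FALSE)
    vals <- tr@values
    vals[[name]] <- .coerceTag(s, tag, name)
    at <- tr@attr
    at[["prior_id"]] <- tr@id
    SMDTrace(tr@index, vals, at)
  })
  types <- c(dataset@types, stats::setNames(tag, name))
  SMDDataset(newTraces, desc = dataset@desc, attr = dataset@attr,
             types = types)
}

#' Summary statistics for a dataset
#'
#' Deterministic counts and pooled per-channel statistics: number of
#' traces, total number of points, trace-length min/median/max, and for
#' every channel the pooled mean, standard deviation, min, max
#' (numeric channels; excluding nulls) and the null count.
#'
#' @param dataset an [SMDDataset-class].
#' @return A list of class `SMDSummary` with elements `nTraces`,
#'   `nPointsTotal`, `traceLength` (min/median/max) and `perChannel`
#'   (data.frame with one row per channel).
#' @examples
#' summarizeDataset(simulateDataset(nTraces = 2, nPoints = 50, seed = 1))
#' @export
summarizeDataset <- function(dataset) {
  stopifnot(is(dataset, "SMDDataset"))
  lens <- vapply(dataset@data, function(tr) length(tr@index), integer(1L))
  chans <- sort(names(dataset@types))
  per <- lapply(chans, function(ch) {
    pooled <- unlist(lapply(dataset@data, function(tr) tr@values[[ch]]),
                     use.names = FALSE)
    nNull <- sum(is.na(pooled))
    obs <- pooled[!is.na(pooled)]
    if (is.numeric(obs) && length(obs)) {
      data.frame(channel = ch, type = unname(dataset@types[[ch]]),
                 mean = mean(obs), sd = stats::sd(obs),
                 min = min(obs), max = max(obs), nNull = nNull,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(channel = ch, type = unname(dataset@types[[ch]]),
                 mean = NA_real_, sd = NA_real_, min = NA_real_,
                 max = NA_real_, nNull = nNull, stringsAsFactors = FALSE)
    }
  })
  structure(list(
    nTraces = length(dataset@data),
    nPointsTotal = sum(lens),
    traceLength = list(
      min = if (length(lens)) min(lens) else 0L,
      median = if (length(lens)) stats::median(lens) else NA_real_,
      max = if (length(lens)) max(lens) else 0L),
    perChannel = do.call(rbind, per)),
    class = "SMDSummary")
}

#' @export
print.SMDSummary <- function(x, ...) {
  cat(sprintf("SMD summary: %d trace(s), %d point(s) total\n",
              x$nTraces, x$nPointsTotal))
  cat(sprintf("  trace length: min %s, median %s, max %s\n",
              x$traceLength$min, x$traceLength$median, x$traceLength$max))
  if (!is.null(x$perChannel) && nrow(x$perChannel)) {
    cat("  channels:\n")
    print(x$perChannel, row.names = FALSE)
  }
  invisible(x)
}
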