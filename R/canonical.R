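## Canonical serialization and MD5 content ids.
##
## One byte representation per value: UTF-8 JSON with object keys in
## ascending code-point order, no insignificant whitespace, integers
## rendered bare and non-integers in shortest round-trip decimal form.
## Equal in-memory nodes therefore always hash to equal digests,
## independent of key insertion order, file formatting or platform.

.stopSMD <- function(class, path, msg, ...) {
  stop(structure(
    class = c(class, "smd_error", "error", "condition"),
    list(message = sprintf("%s: %s", path, sprintf(msg, ...)),
         call = sys.call(-1), path = path)))
}

## numbers ------------------------------------------------------------

## NA (not NaN) renders as null; NaN / +-Inf are rejected: raw JSON has
## no spelling for them, so they must be encoded upstream (null in a
## channel, or an attr-level sentinel).
.canonNumber <- function(x, path) {
  x <- as.numeric(x)
  n <- length(x)
  out <- character(n)
  isNull <- is.na(x) & !is.nan(x)
  bad <- which(is.nan(x) | (!isNull & !is.finite(x)))
  if (length(bad))
    .stopSMD("smd_serialization_error", sprintf("%s[%d]", path, bad[1L]),
             "non-finite number (%s) cannot be serialized", x[bad[1L]])
  out[isNull] <- "null"
  idx <- which(!isNull)
  if (!length(idx)) return(out)
  xr <- x[idx]
  res <- character(length(xr))
  whole <- xr == trunc(xr) & abs(xr) < 2^53
  if (any(whole)) {
    w <- sprintf("%.0f", xr[whole])
    w[xr[whole] == 0] <- "0"  # never emit -0
    res[whole] <- w
  }
  todo <- which(!whole)
  ## shortest round-trip decimal: fewest significant digits (15..17)
  ## whose %g-trimmed form re-parses to the identical double under both
  ## C strtod and the JSON parser the reader uses (whose decimal
  ## conversion can differ from strtod by one ulp on short forms)
  for (d in c(15L, 16L, 17L)) {
    if (!length(todo)) break
    s <- formatC(xr[todo], digits = d, format = "g", width = 1L)
    ok <- suppressWarnings(as.numeric(s)) == xr[todo]
    if (any(ok)) {
      reparsed <- jsonlite::parse_json(
        paste0("[", paste(s[ok], collapse = ","), "]"),
        simplifyVector = TRUE)
      ok[ok] <- reparsed == xr[todo][ok]
    }
    res[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  if (length(todo))
    res[todo] <- formatC(xr[todo], digits = 17L, format = "g", width = 1L)
  out[idx] <- res
  out
}

## strings ------------------------------------------------------------

.ESCAPES <- local({
  m <- character(31L)
  for (i in 1:31) m[i] <- sprintf("\\u%04x", i)
  m[8L] <- "\\b"; m[9L] <- "\\t"; m[10L] <- "\\n"
  m[12L] <- "\\f"; m[13L] <- "\\r"
  m
})

.canonString <- function(x, path) {
  x <- enc2utf8(as.character(x))
  out <- character(length(x))
  isNull <- is.na(x)
  out[isNull] <- "null"
  s <- x[!isNull]
  if (length(s)) {
    s <- gsub("\\", "\\\\", s, fixed = TRUE)
    s <- gsub("\"", "\\\"", s, fixed = TRUE)
    if (any(grepl("[\x01-\x1f]", s, perl = TRUE, useBytes = TRUE))) {
      for (i in 1:31) {
        ch <- rawToChar(as.raw(i))
        s <- gsub(ch, .ESCAPES[i], s, fixed = TRUE, useBytes = TRUE)
      }
    }
    out[!isNull] <- paste0("\"", s, "\"")
  }
  out
}

.canonLogical <- function(x) {
  out <- ifelse(x, "true", "false")
  out[is.na(x)] <- "null"
  out
}

.canonAtomic <- function(x, path) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) .canonLogical(x)
  else if (is.numeric(x)) .canonNumber(x, path)
  else if (is.character(x)) .canonString(x, path)
  else .stopSMD("smd_serialization_error", path,
                "unsupported value of class '%s'", class(x)[1L])
}

.sortKeys <- function(nm) sort(enc2utf8(nm), method = "radix")

.checkKeys <- function(nm, path) {
  if (any(is.na(nm)) || any(!nzchar(nm)))
    .stopSMD("smd_serialization_error", path, "empty or missing object key")
  if (anyDuplicated(nm))
    .stopSMD("smd_serialization_error", path, "duplicate object key '%s'",
             nm[duplicated(nm)][1L])
}

## arbitrary attr subtree: named list -> object, unnamed list -> array,
## length-1 unnamed atomic -> scalar, other atomic -> array
.canonValue <- function(x, path = "$", forceObject = FALSE) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) || forceObject) {
      if (length(x) == 0L) return("{}")
      .checkKeys(nm, path)
      ord <- order(enc2utf8(nm), method = "radix")
      parts <- vapply(ord, function(i) {
        paste0(.canonString(nm[i], path), ":",
               .canonValue(x[[i]], paste0(path, ".", nm[i])))
      }, character(1L))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(seq_along(x), function(i) {
      .canonValue(x[[i]], sprintf("%s[%d]", path, i))
    }, character(1L))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (!is.atomic(x))
    .stopSMD("smd_serialization_error", path,
             "unsupported value of class '%s'", class(x)[1L])
  nm <- names(x)
  if (!is.null(nm)) {
    if (length(x) == 0L) return("{}")
    .checkKeys(nm, path)
    ord <- order(enc2utf8(nm), method = "radix")
    vals <- .canonAtomic(x, path)
    return(paste0("{", paste(paste0(.canonString(nm[ord], path), ":",
                                    vals[ord]), collapse = ","), "}"))
  }
  if (length(x) == 1L) return(.canonAtomic(x, path))
  paste0("[", paste(.canonAtomic(x, path), collapse = ","), "]")
}

.canonArray <- function(x, path) {
  paste0("[", paste(.canonAtomic(x, path), collapse = ","), "]")
}

## trace / dataset bodies ---------------------------------------------

.canonChannels <- function(values, path) {
  nm <- names(values)
  if (length(values) == 0L) return("{}")
  ord <- order(enc2utf8(nm), method = "radix")
  parts <- vapply(ord, function(i) {
    paste0(.canonString(nm[i], path), ":",
           .canonArray(values[[i]], paste0(path, ".", nm[i])))
  }, character(1L))
  paste0("{", paste(parts, collapse = ","), "}")
}

## hash domain of a trace id: index + values only (attr and id excluded,
## so post-hoc annotation does not change a trace's identity)
.canonTraceBody <- function(index, values, path = "$") {
  paste0("{\"index\":", .canonArray(index, paste0(path, ".index")),
         ",\"values\":", .canonChannels(values, paste0(path, ".values")), "}")
}

## full trace entry as embedded in the dataset hash / file output
.canonTraceEntry <- function(id, attr, index, values, path = "$") {
  paste0("{\"attr\":", .canonValue(attr, paste0(path, ".attr"), forceObject = TRUE),
         ",\"id\":\"", id, "\"",
         ",\"index\":", .canonArray(index, paste0(path, ".index")),
         ",\"values\":", .canonChannels(values, paste0(path, ".values")), "}")
}

.canonTypes <- function(types, path = "$.types") {
  if (length(types) == 0L) return("{}")
  nm <- names(types)
  ord <- order(enc2utf8(nm), method = "radix")
  paste0("{", paste(paste0(.canonString(nm[ord], path), ":",
                           .canonString(unname(types[ord]), path)),
                    collapse = ","), "}")
}

## hash domain of the dataset id: attr, data (trace ids included),
## desc, types — the top-level id never hashes itself
.canonDatasetBody <- function(desc, attr, types, traceEntries) {
  paste0("{\"attr\":", .canonValue(attr, "$.attr", forceObject = TRUE),
         ",\"data\":[", paste(traceEntries, collapse = ","), "]",
         ",\"desc\":", .canonString(desc, "$.desc"),
         ",\"types\":", .canonTypes(types), "}")
}

.md5 <- function(txt) digest::digest(charToRaw(txt), algo = "md5",
                                     serialize = FALSE)

#' Canonical byte representation of SMD nodes
#'
#' Serializes a trace, a dataset or an attribute subtree to its one
#' canonical UTF-8 JSON byte sequence: object keys in ascending
#' code-point order, no insignificant whitespace, integers bare,
#' non-integer numbers in shortest round-trip decimal form, `NA` as
#' `null`. Content ids are MD5 digests of these bytes, which is what
#' makes them stable across whitespace, key order and platform.
#'
#' For an [SMDTrace-class] the serialized node is `{"index":...,
#' "values":...}` — the trace id's hash domain (its `attr` and `id` are
#' excluded, so annotating a trace never changes its identity). For an
#' [SMDDataset-class] it is `{"attr":..., "data":[...], "desc":...,
#' "types":...}` with every trace embedded as `{"attr":..., "id":...,
#' "index":..., "values":...}` — the dataset id's hash domain (trace
#' ids included, the top-level id excluded).
#'
#' @param x an [SMDTrace-class], an [SMDDataset-class], or a list /
#'   atomic value (an attribute subtree).
#' @return A raw vector of UTF-8 bytes.
#' @examples
#' tr <- SMDTrace(index = c(0, 0.1), values = list(fret = c(0.2, 0.8)))
#' rawToChar(canonicalBytes(tr))
#' @rdname canonicalBytes
#' @export
setMethod("canonicalBytes", "SMDTrace", function(x) {
  charToRaw(.canonTraceBody(x@index, x@values))
})

#' @rdname canonicalBytes
#' @export
setMethod("canonicalBytes", "SMDDataset", function(x) {
  entries <- vapply(seq_along(x@data), function(i) {
    tr <- x@data[[i]]
    .canonTraceEntry(tr@id, tr@attr, tr@index, tr@values,
                     sprintf("$.data[%d]", i))
  }, character(1L))
  charToRaw(.canonDatasetBody(x@desc, x@attr, x@types, entries))
})

#' @rdname canonicalBytes
#' @export
setMethod("canonicalBytes", "ANY", function(x) {
  charToRaw(.canonValue(x))
})

#' MD5 content identifiers for traces and datasets
#'
#' `traceId()` returns the lowercase 32-digit hexadecimal MD5 digest of
#' a trace's canonical bytes (`index` + `values` only). `datasetId()`
#' returns the digest over the entire dataset structure (`attr`, the
#' trace list with per-trace ids, `desc`, `types`; the stored top-level
#' id is excluded). Both are recomputed from the data — the stored
#' `@id` slot is ignored — so they can be used to check integrity; see
#' [verifyIds()].
#'
#' @param x an [SMDTrace-class] or [SMDDataset-class] object.
#' @return A 32-character lowercase hexadecimal string.
#' @examples
#' tr <- SMDTrace(index = 0:2, values = list(donor = c(100, 90, 95)))
#' traceId(tr) == smdId(tr)
#' @rdname contentIds
#' @export
setMethod("traceId", "SMDTrace", function(x) {
  .md5(.canonTraceBody(x@index, x@values))
})

#' @rdname contentIds
#' @export
setMethod("datasetId", "SMDDataset", function(x) {
  .md5(rawToChar(canonicalBytes(x)))
})

#' Verify stored content ids against recomputed ones
#'
#' Recomputes every trace id and the dataset id from the data and
#' compares them with the stored ids. Mismatches are report rows, never
#' errors, so the function can triage corrupted or hand-edited files.
#'
#' @param x an [SMDDataset-class], a file path to an SMD JSON file, or
#'   a parsed JSON value (nested list).
#' @return A data.frame with one row per trace plus one for the top
#'   level: columns `scope` ("trace"/"dataset"), `position` (trace
#'   number, NA for the top level), `path`, `stored`, `recomputed` and
#'   `match`. A stored id that is absent or unusable is reported with
#'   `stored = NA` and `match = FALSE`.
#' @examples
#' d <- simulateDataset(nTraces = 2, nPoints = 10, seed = 1)
#' all(verifyIds(d)$match)
#' @export
verifyIds <- function(x) {
  if (is(x, "SMDDataset")) {
    storedTr <- vapply(x@data, function(t) t@id, character(1L))
    recompTr <- vapply(x@data, traceId, character(1L))
    storedTop <- x@id
    recompTop <- datasetId(x)
    n <- length(x@data)
  } else {
    raw <- .asRawSMD(x)
    ids <- .rawIds(raw)
    storedTr <- ids$storedTr; recompTr <- ids$recompTr
    storedTop <- ids$storedTop; recompTop <- ids$recompTop
    n <- length(ids$storedTr)
  }
  paths <- c(sprintf("$.data[%d].id", seq_len(n)), "$.id")
  out <- data.frame(
    scope = c(rep("trace", n), "dataset"),
    position = c(seq_len(n), NA_integer_),
    path = paths,
    stored = c(storedTr, storedTop),
    recomputed = c(recompTr, recompTop),
    stringsAsFactors = FALSE)
  out$match <- !is.na(out$stored) & out$stored == out$recomputed
  out
}

## ---- raw-side (parsed JSON) hashing, shared with the validator ------

.asRawSMD <- function(x) {
  if (is.character(x) && length(x) == 1L) .parseSMD(x)$value
  else if (is.list(x)) x
  else stop("expected an SMDDataset, a file path, or a parsed JSON value")
}

.rawChannelVector <- function(ch, path) {
  if (!is.list(ch)) ch <- as.list(ch)
  isNull <- vapply(ch, is.null, logical(1L))
  cls <- unique(vapply(ch[!isNull], function(v) {
    if (is.logical(v)) "logical"
    else if (is.numeric(v)) "numeric"
    else if (is.character(v)) "character"
    else "other"
  }, character(1L)))
  if ("other" %in% cls)
    .stopSMD("smd_serialization_error", path, "non-scalar channel value")
  if ("character" %in% cls && length(cls) > 1L)
    .stopSMD("smd_serialization_error", path,
             "channel mixes text and non-text values")
  target <- if (!length(cls)) "logical"
            else if ("character" %in% cls) "character"
            else if ("numeric" %in% cls) "numeric"
            else "logical"
  out <- vector(target, length(ch))
  out[isNull] <- NA
  if (any(!isNull))
    out[!isNull] <- vapply(ch[!isNull], function(v) as.vector(v, target),
                           vector(target, 1L))
  out
}

.rawTraceCanonical <- function(tr, path) {
  idx <- .rawChannelVector(tr[["index"]], paste0(path, ".index"))
  vals <- tr[["values"]]
  vecs <- lapply(names(vals), function(ch) {
    .rawChannelVector(vals[[ch]], paste0(path, ".values.", ch))
  })
  names(vecs) <- names(vals)
  list(index = as.numeric(idx), values = vecs,
       body = .canonTraceBody(as.numeric(idx), vecs, path))
}

.rawStoredId <- function(node) {
  id <- node[["id"]]
  if (is.null(id) || !is.character(id) || length(id) != 1L || is.na(id))
    return(NA_character_)
  tolower(id)
}

.rawIds <- function(raw) {
  trs <- raw[["data"]]
  n <- if (is.list(trs)) length(trs) else 0L
  storedTr <- character(n); recompTr <- character(n)
  entries <- character(n)
  for (i in seq_len(n)) {
    tr <- trs[[i]]
    path <- sprintf("$.data[%d]", i)
    storedTr[i] <- .rawStoredId(tr)
    canon <- .rawTraceCanonical(tr, path)
    recompTr[i] <- .md5(canon$body)
    at <- tr[["attr"]]; if (is.null(at)) at <- list()
    idEmbed <- if (is.na(storedTr[i])) recompTr[i] else storedTr[i]
    entries[i] <- .canonTraceEntry(idEmbed, at, canon$index, canon$values,
                                   path)
  }
  desc <- raw[["desc"]]; if (is.null(desc)) desc <- ""
  at <- raw[["attr"]]; if (is.null(at)) at <- list()
  types <- raw[["types"]]
  tyv <- if (is.list(types)) unlist(lapply(types, as.character))
         else as.character(types)
  if (is.null(tyv)) tyv <- character()
  body <- .canonDatasetBody(as.character(desc), at, tyv, entries)
  list(storedTr = storedTr, recompTr = recompTr,
       storedTop = .rawStoredId(raw), recompTop = .md5(body))
}
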