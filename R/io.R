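## SMD JSON reading and writing.
##
## File layout: one top-level object {attr, data, desc, id, types}; data
## is an array of trace objects {attr, id, index, values}; values is an
## object of channel-name -> array. Conventional extension: .smd.json
## (plain .json accepted). Encoding is UTF-8 without byte-order mark;
## compact output is the canonical serialization plus a trailing
## newline, so a compact file's bytes are themselves reproducible.

.parseSMD <- function(source) {
  txt <- if (grepl("^[[:space:]]*[{[]", source)) source
         else {
           if (!file.exists(source))
             .stopSMD("smd_parse_error", "$",
                      "file not found: %s", source)
           readChar(source, file.info(source)$size, useBytes = TRUE)
         }
  value <- tryCatch(
    jsonlite::parse_json(txt, simplifyVector = FALSE),
    error = function(e) {
      .stopSMD("smd_parse_error", "$", "malformed JSON: %s",
               conditionMessage(e))
    })
  list(value = value, text = txt)
}

## parsed-JSON attr subtree -> R representation: objects become named
## lists, homogeneous scalar arrays of length > 1 become atomic vectors
## (so user-built attrs round-trip structurally), other arrays stay
## lists
.rawAttrToR <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    out <- lapply(x, .rawAttrToR)
    names(out) <- nm
    return(out)
  }
  if (length(x) > 1L) {
    kinds <- vapply(x, .scalarKind, character(1L))
    if (all(kinds == kinds[1L]) && kinds[1L] %in% c("bool", "number", "string"))
      return(unlist(x, use.names = FALSE))
  }
  lapply(x, .rawAttrToR)
}

#' Read an SMD file
#'
#' Parses and validates an SMD JSON document and constructs an
#' [SMDDataset-class]. In `strict` mode any validation error aborts the
#' read with a condition of class `smd_validation_error` that carries
#' the full report; stored ids must match the ids recomputed from the
#' data. In `lenient` mode structurally recoverable files load with the
#' issues attached: a missing `desc` becomes the empty string, a
#' missing `types` map is inferred from the data, missing or mismatched
#' ids are recomputed and flagged, uppercase ids are normalized, and
#' unknown keys are preserved under an `"x-"` extension namespace in
#' the nearest `attr` so no data is silently lost.
#'
#' The issues found during reading are attached to the returned object
#' and retrievable with [readIssues()]; in strict mode that report
#' never contains errors.
#'
#' @param source path to an SMD JSON file, or a JSON string.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return An [SMDDataset-class]; see also [readIssues()].
#' @examples
#' f <- tempfile(fileext = ".smd.json")
#' writeSMD(simulateDataset(nTraces = 2, nPoints = 10, seed = 1), f)
#' d <- readSMD(f)
#' nTraces(d)
#' @export
readSMD <- function(source, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  raw <- .parseSMD(source)$value
  report <- .validateRaw(raw, mode)
  if (!report$valid) {
    msg <- paste0(
      "SMD validation failed (", sum(report$issues$severity == "error"),
      " error(s)); first: [", report$issues$code[1L], "] ",
      report$issues$path[1L], ": ", report$issues$message[1L])
    stop(structure(
      class = c("smd_validation_error", "smd_error", "error", "condition"),
      list(message = msg, call = sys.call(-1), report = report)))
  }

  ## lenient repairs: unknown keys -> "x-" extension namespace
  attrTop <- .rawAttrToR(raw[["attr"]])
  if (is.null(attrTop)) attrTop <- list()
  for (k in setdiff(names(raw), .TOP_KEYS))
    attrTop[[paste0("x-", k)]] <- .rawAttrToR(raw[[k]])

  desc <- raw[["desc"]]
  if (is.null(desc)) desc <- ""

  types <- NULL
  ty <- raw[["types"]]
  if (.isJsonObject(ty) && length(ty) &&
      all(vapply(ty, function(t) is.character(t) && t %in% SMD_TYPE_TAGS,
                 logical(1L))))
    types <- vapply(ty, as.character, character(1L))

  dat <- raw[["data"]]
  if (is.null(dat)) dat <- list()
  tracesList <- lapply(seq_along(dat), function(i) {
    tr <- dat[[i]]
    path <- sprintf("$.data[%d]", i)
    at <- .rawAttrToR(tr[["attr"]])
    if (is.null(at)) at <- list()
    for (k in setdiff(names(tr), .TRACE_KEYS))
      at[[paste0("x-", k)]] <- .rawAttrToR(tr[[k]])
    idx <- .rawChannelVector(tr[["index"]], paste0(path, ".index"))
    vals <- tr[["values"]]
    vecs <- lapply(names(vals), function(ch) {
      v <- .rawChannelVector(vals[[ch]], paste0(path, ".values.", ch))
      if (!is.null(types) && ch %in% names(types))
        v <- .coerceTag(v, types[[ch]], ch)
      v
    })
    names(vecs) <- names(vals)
    SMDTrace(index = as.numeric(idx), values = vecs, attr = at)
  })

  ds <- SMDDataset(tracesList, desc = as.character(desc), attr = attrTop,
                   types = types)
  attr(ds, "smdIssues") <- report
  ds
}

#' Validation issues recorded while reading
#'
#' Returns the `SMDValidationReport` attached to a dataset by
#' [readSMD()] (an empty report for objects built directly).
#'
#' @param x an [SMDDataset-class].
#' @return An `SMDValidationReport`.
#' @export
readIssues <- function(x) {
  rep <- attr(x, "smdIssues", exact = TRUE)
  if (is.null(rep)) rep <- .issuesToReport(list())
  rep
}

.smdText <- function(dataset) {
  validObject(dataset)
  entries <- vapply(seq_along(dataset@data), function(i) {
    tr <- dataset@data[[i]]
    .canonTraceEntry(tr@id, tr@attr, tr@index, tr@values,
                     sprintf("$.data[%d]", i))
  }, character(1L))
  paste0("{\"attr\":",
         .canonValue(dataset@attr, "$.attr", forceObject = TRUE),
         ",\"data\":[", paste(entries, collapse = ","), "]",
         ",\"desc\":", .canonString(dataset@desc, "$.desc"),
         ",\"id\":\"", dataset@id, "\"",
         ",\"types\":", .canonTypes(dataset@types), "}")
}

#' Serialize a dataset to SMD JSON text
#'
#' @param dataset a valid [SMDDataset-class].
#' @param pretty if TRUE, indent for human reading; the default compact
#'   form is the canonical serialization (sorted keys, no whitespace),
#'   so writing the same dataset always produces identical bytes.
#' @return A character scalar of JSON text (no trailing newline; the
#'   file writer adds one).
#' @export
smdToJSON <- function(dataset, pretty = FALSE) {
  txt <- .smdText(dataset)
  if (pretty) txt <- as.character(jsonlite::prettify(txt, indent = 2L))
  txt
}

#' Write an SMD file
#'
#' Serializes a dataset to SMD JSON. The output top level has exactly
#' the keys `{attr, data, desc, id, types}` and every trace object
#' exactly the four keys `{attr, id, index, values}`. Compact output
#' (the default) is the canonical byte form plus a trailing newline, so
#' write–read–write round trips are byte identical. An invalid dataset
#' — including any non-finite number in a channel — is refused with an
#' error naming the offending JSON path.
#'
#' @param dataset a valid [SMDDataset-class].
#' @param path output file path (conventionally `.smd.json`).
#' @param pretty pretty-print for human reading (ids unaffected).
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile(fileext = ".smd.json")
#' writeSMD(simulateDataset(nTraces = 1, nPoints = 5, seed = 3), f)
#' @export
writeSMD <- function(dataset, path, pretty = FALSE) {
  txt <- smdToJSON(dataset, pretty = pretty)
  if (!endsWith(txt, "\n")) txt <- paste0(txt, "\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}
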