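## Structural and semantic validation of SMD documents with enumerated,
## machine-readable issue codes.

#' Issue codes emitted by the SMD validator
#'
#' The closed enumeration of issue codes. The `E_`/`W_`/`I_` prefix
#' names each code's lenient-mode severity; the report's `severity`
#' column is authoritative (in strict mode recoverable omissions and
#' unknown keys are escalated to errors, and an id mismatch is
#' reported as `E_ID_MISMATCH` instead of `W_ID_MISMATCH`).
#'
#' @format A character vector of code names.
#' @export
SMD_ISSUE_CODES <- c(
  "E_TOP_NOT_OBJECT",      # document root is not a JSON object
  "E_MISSING_FIELD",       # required top-level or trace field absent
  "E_BAD_ID_FORMAT",       # id is not a 32-character hex string
  "E_BAD_TYPE_TAG",        # a types entry outside {float,int,string,bool}
  "E_TYPES_EMPTY",         # types declares no channels
  "E_CHANNEL_SET_MISMATCH",# trace channel set != types key set
  "E_LENGTH_MISMATCH",     # channel length != index length
  "E_TYPE_MISMATCH",       # value violates its declared tag / wrong node kind
  "E_ID_MISMATCH",         # stored id != recomputed id (strict mode)
  "W_ID_MISMATCH",         # same finding, lenient mode
  "W_INDEX_NOT_MONOTONE",  # index not non-decreasing
  "W_UPPERCASE_ID",        # id is hex but not lowercase
  "W_UNKNOWN_KEY",         # key outside the documented field sets
  "W_DUPLICATE_TRACE_ID",  # two traces share a content id
  "I_NULL_VALUE"           # nulls present in a channel (informational)
)

.newCollector <- function() {
  env <- new.env(parent = emptyenv())
  env$issues <- list()
  env$add <- function(code, severity, path, message) {
    env$issues[[length(env$issues) + 1L]] <-
      list(code = code, severity = severity, path = path, message = message)
  }
  env
}

.issuesToReport <- function(issues) {
  if (length(issues)) {
    df <- data.frame(
      code = vapply(issues, `[[`, character(1L), "code"),
      severity = vapply(issues, `[[`, character(1L), "severity"),
      path = vapply(issues, `[[`, character(1L), "path"),
      message = vapply(issues, `[[`, character(1L), "message"),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(code = character(), severity = character(),
                     path = character(), message = character(),
                     stringsAsFactors = FALSE)
  }
  structure(list(issues = df, valid = !any(df$severity == "error")),
            class = "SMDValidationReport")
}

#' @export
print.SMDValidationReport <- function(x, ...) {
  cat(sprintf("SMD validation report: %s (%d issue%s)\n",
              if (x$valid) "VALID" else "INVALID",
              nrow(x$issues), if (nrow(x$issues) == 1L) "" else "s"))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s %s: %s\n", x$issues$severity[i],
                  x$issues$code[i], x$issues$path[i], x$issues$message[i]))
  }
  invisible(x)
}

.TOP_KEYS <- c("attr", "data", "desc", "id", "types")
.TRACE_KEYS <- c("attr", "id", "index", "values")

.isJsonObject <- function(x) is.list(x) && !is.null(names(x))
.isJsonArray <- function(x) is.list(x) && is.null(names(x))

.checkIdNode <- function(id, path, add, mode) {
  ## returns normalized id or NA if unusable
  if (!is.character(id) || length(id) != 1L || is.na(id) ||
      !grepl("^[0-9a-fA-F]{32}$", id)) {
    add("E_BAD_ID_FORMAT", "error", path,
        "id must be a 32-digit hexadecimal string")
    return(NA_character_)
  }
  if (grepl("[A-F]", id)) {
    add("W_UPPERCASE_ID", "warning", path,
        "id uses uppercase hex digits; canonical ids are lowercase")
  }
  tolower(id)
}

.scalarKind <- function(v) {
  if (is.null(v)) "null"
  else if (is.logical(v) && length(v) == 1L) "bool"
  else if (is.numeric(v) && length(v) == 1L) "number"
  else if (is.character(v) && length(v) == 1L) "string"
  else "other"
}

#' Validate an SMD document
#'
#' Runs the full battery of structural and semantic checks on an SMD
#' document and returns a report of coded issues in document order.
#' Nothing short of unparseable input raises an error: every finding —
#' missing fields, malformed ids, channel/type violations, id
#' mismatches — is a report row with a `code` from [SMD_ISSUE_CODES], a
#' `severity` (`error`, `warning` or `info`) and a JSON-path location
#' (array indices are 1-based, following R convention).
#'
#' In `strict` mode all required fields must be present, unknown keys
#' are errors, and a stored id that does not match the id recomputed
#' from the data is an error (`E_ID_MISMATCH`). In `lenient` mode
#' recoverable omissions (missing `desc`, `attr`, `types` or ids) and
#' unknown keys are warnings, and an id mismatch is downgraded to
#' `W_ID_MISMATCH` — files written by tools that predate a canonical
#' hashing convention still load. Id verification is skipped when
#' structural errors make the canonical hash ill-defined.
#'
#' @param x what to validate: an [SMDDataset-class], a path to an SMD
#'   JSON file, a JSON string, or an already-parsed JSON value (nested
#'   list, e.g. from [jsonlite::parse_json()] with
#'   `simplifyVector = FALSE`).
#' @param mode `"strict"` or `"lenient"`.
#' @return An object of class `SMDValidationReport`: a list with
#'   `issues` (data.frame of code/severity/path/message) and `valid`
#'   (TRUE iff no issue has severity `error`).
#' @examples
#' d <- simulateDataset(nTraces = 2, nPoints = 20, seed = 1)
#' validateSMD(d)$valid
#' @export
validateSMD <- function(x, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  raw <- if (is(x, "SMDDataset")) .datasetToRaw(x) else .asRawSMD(x)
  .validateRaw(raw, mode)
}

.validateRaw <- function(raw, mode) {
  strict <- identical(mode, "strict")
  col <- .newCollector()
  add <- col$add
  recoverable <- if (strict) "error" else "warning"
  unknownSev <- if (strict) "error" else "warning"

  if (!.isJsonObject(raw)) {
    add("E_TOP_NOT_OBJECT", "error", "$",
        "document root must be a JSON object")
    return(.issuesToReport(col$issues))
  }

  for (k in setdiff(names(raw), .TOP_KEYS))
    add("W_UNKNOWN_KEY", unknownSev, paste0("$.", k),
        sprintf("unexpected top-level key '%s'", k))

  for (k in setdiff(.TOP_KEYS, names(raw))) {
    sev <- if (k == "data") "error" else recoverable
    add("E_MISSING_FIELD", sev, paste0("$.", k),
        sprintf("required top-level field '%s' is missing", k))
  }

  structuralError <- FALSE  # anything that makes hashing ill-defined

  ## desc / attr node kinds
  if ("desc" %in% names(raw) &&
      !(is.character(raw$desc) && length(raw$desc) == 1L && !is.na(raw$desc))) {
    add("E_TYPE_MISMATCH", "error", "$.desc", "'desc' must be a string")
    structuralError <- TRUE
  }
  if ("attr" %in% names(raw) && !is.null(raw$attr) &&
      !.isJsonObject(raw$attr) && !identical(raw$attr, list())) {
    add("E_TYPE_MISMATCH", "error", "$.attr", "'attr' must be an object")
    structuralError <- TRUE
  }

  ## types
  types <- NULL
  if ("types" %in% names(raw)) {
    ty <- raw$types
    if (!.isJsonObject(ty)) {
      if (is.list(ty) && length(ty) == 0L) {
        add("E_TYPES_EMPTY", "error", "$.types",
            "'types' must declare at least one channel")
      } else {
        add("E_TYPE_MISMATCH", "error", "$.types", "'types' must be an object")
      }
      structuralError <- TRUE
    } else if (length(ty) == 0L) {
      add("E_TYPES_EMPTY", "error", "$.types",
          "'types' must declare at least one channel")
      structuralError <- TRUE
    } else {
      ok <- TRUE
      for (ch in names(ty)) {
        tag <- ty[[ch]]
        if (!is.character(tag) || length(tag) != 1L ||
            !tag %in% SMD_TYPE_TAGS) {
          add("E_BAD_TYPE_TAG", "error", paste0("$.types.", ch),
              sprintf("type tag must be one of {%s}",
                      paste(SMD_TYPE_TAGS, collapse = ", ")))
          ok <- FALSE
        }
      }
      if (ok) types <- vapply(ty, as.character, character(1L))
    }
  }

  if ("id" %in% names(raw))
    .checkIdNode(raw$id, "$.id", add, mode)

  ## traces
  traceHashable <- logical(0)
  if ("data" %in% names(raw)) {
    dat <- raw$data
    if (!is.list(dat) || (.isJsonObject(dat) && length(dat) > 0L)) {
      add("E_TYPE_MISMATCH", "error", "$.data", "'data' must be an array")
      structuralError <- TRUE
    } else {
      traceHashable <- rep(TRUE, length(dat))
      for (i in seq_along(dat)) {
        tp <- sprintf("$.data[%d]", i)
        tr <- dat[[i]]
        if (!.isJsonObject(tr)) {
          add("E_TYPE_MISMATCH", "error", tp, "trace must be an object")
          traceHashable[i] <- FALSE
          next
        }
        for (k in setdiff(names(tr), .TRACE_KEYS))
          add("W_UNKNOWN_KEY", unknownSev, paste0(tp, ".", k),
              sprintf("unexpected trace key '%s'", k))
        for (k in setdiff(.TRACE_KEYS, names(tr))) {
          sev <- if (k %in% c("index", "values")) "error" else recoverable
          add("E_MISSING_FIELD", sev, paste0(tp, ".", k),
              sprintf("required trace field '%s' is missing", k))
          if (k %in% c("index", "values")) traceHashable[i] <- FALSE
        }
        if ("id" %in% names(tr))
          .checkIdNode(tr$id, paste0(tp, ".id"), add, mode)
        if ("attr" %in% names(tr) && !is.null(tr$attr) &&
            !.isJsonObject(tr$attr) && !identical(tr$attr, list()))
          add("E_TYPE_MISMATCH", "error", paste0(tp, ".attr"),
              "trace 'attr' must be an object")

        nIndex <- NA_integer_
        if ("index" %in% names(tr)) {
          ip <- paste0(tp, ".index")
          if (!is.list(tr$index) && !(is.numeric(tr$index))) {
            add("E_TYPE_MISMATCH", "error", ip, "'index' must be an array")
            traceHashable[i] <- FALSE
          } else {
            idx <- if (is.list(tr$index)) tr$index else as.list(tr$index)
            kinds <- vapply(idx, .scalarKind, character(1L))
            if (any(kinds != "number")) {
              j <- which(kinds != "number")[1L]
              add("E_TYPE_MISMATCH", "error", sprintf("%s[%d]", ip, j),
                  "index entries must be finite numbers")
              traceHashable[i] <- FALSE
            } else {
              nIndex <- length(idx)
              iv <- vapply(idx, as.numeric, numeric(1L))
              if (any(!is.finite(iv))) {
                add("E_TYPE_MISMATCH", "error", ip,
                    "index entries must be finite numbers")
                traceHashable[i] <- FALSE
              } else if (is.unsorted(iv)) {
                add("W_INDEX_NOT_MONOTONE", "warning", ip,
                    "index is not non-decreasing")
              }
            }
          }
        }

        if ("values" %in% names(tr)) {
          vp <- paste0(tp, ".values")
          vals <- tr$values
          if (!.isJsonObject(vals) && !identical(vals, list())) {
            add("E_TYPE_MISMATCH", "error", vp, "'values' must be an object")
            traceHashable[i] <- FALSE
          } else {
            chans <- names(vals)
            if (!is.null(types) &&
                !identical(sort(chans), sort(names(types)))) {
              only1 <- setdiff(names(types), chans)
              only2 <- setdiff(chans, names(types))
              add("E_CHANNEL_SET_MISMATCH", "error", vp, sprintf(
                "trace channels do not match declared types; difference: {%s}",
                paste(c(only1, only2), collapse = ", ")))
            }
            for (ch in chans) {
              cp <- paste0(vp, ".", ch)
              v <- vals[[ch]]
              if (!is.list(v) && !is.atomic(v)) {
                add("E_TYPE_MISMATCH", "error", cp, "channel must be an array")
                traceHashable[i] <- FALSE
                next
              }
              vl <- if (is.list(v)) v else as.list(v)
              if (!is.na(nIndex) && length(vl) != nIndex)
                add("E_LENGTH_MISMATCH", "error", cp, sprintf(
                  "channel has length %d but index has length %d",
                  length(vl), nIndex))
              kinds <- vapply(vl, .scalarKind, character(1L))
              if (any(kinds == "other")) {
                j <- which(kinds == "other")[1L]
                add("E_TYPE_MISMATCH", "error", sprintf("%s[%d]", cp, j),
                    "channel entries must be scalars or null")
                traceHashable[i] <- FALSE
                next
              }
              nNull <- sum(kinds == "null")
              if (nNull > 0L)
                add("I_NULL_VALUE", "info", cp, sprintf(
                  "channel contains %d null value%s", nNull,
                  if (nNull == 1L) "" else "s"))
              if (!is.null(types) && ch %in% names(types)) {
                tag <- types[[ch]]
                want <- switch(tag, float = "number", int = "number",
                               bool = "bool", string = "string")
                bad <- which(kinds != "null" & kinds != want)
                if (length(bad)) {
                  add("E_TYPE_MISMATCH", "error",
                      sprintf("%s[%d]", cp, bad[1L]), sprintf(
                        "value of kind '%s' violates declared type '%s'",
                        kinds[bad[1L]], tag))
                } else if (tag == "int") {
                  nums <- vapply(vl[kinds == "number"], as.numeric,
                                 numeric(1L))
                  if (any(is.finite(nums) & nums != trunc(nums))) {
                    j <- which(kinds == "number")[
                      which(is.finite(nums) & nums != trunc(nums))[1L]]
                    add("E_TYPE_MISMATCH", "error",
                        sprintf("%s[%d]", cp, j),
                        "non-integer value violates declared type 'int'")
                  }
                }
              }
            }
          }
        }
      }

      ## duplicate trace ids (content-hash collisions are legitimate for
      ## identical molecules measured twice, hence a warning)
      storedIds <- vapply(dat, function(tr) {
        if (.isJsonObject(tr)) .rawStoredId(tr) else NA_character_
      }, character(1L))
      dup <- storedIds[!is.na(storedIds) & duplicated(storedIds)]
      for (idv in unique(dup)) {
        at <- which(storedIds == idv)
        add("W_DUPLICATE_TRACE_ID", "warning",
            sprintf("$.data[%d].id", at[2L]),
            sprintf("trace id '%s' occurs %d times", idv, length(at)))
      }
    }
  }

  ## id verification — only when no prior error makes the canonical
  ## hash ill-defined (a structurally broken file cannot be re-hashed
  ## meaningfully, and reporting cascading mismatches would obscure the
  ## primary defect)
  anyError <- structuralError ||
    any(vapply(col$issues, function(x) x$severity == "error", logical(1L)))
  hashSafe <- !anyError
  if (hashSafe && "data" %in% names(raw) && .isJsonArray(raw$data)) {
    ids <- tryCatch(.rawIds(raw), smd_error = function(e) NULL)
    if (!is.null(ids)) {
      mmCode <- if (strict) "E_ID_MISMATCH" else "W_ID_MISMATCH"
      mmSev <- if (strict) "error" else "warning"
      for (i in seq_along(ids$storedTr)) {
        if (!is.na(ids$storedTr[i]) && isTRUE(traceHashable[i]) &&
            ids$storedTr[i] != ids$recompTr[i])
          add(mmCode, mmSev, sprintf("$.data[%d].id", i), sprintf(
            "stored trace id %s does not match recomputed id %s",
            ids$storedTr[i], ids$recompTr[i]))
      }
      if (!is.na(ids$storedTop) && all(traceHashable) &&
          ids$storedTop != ids$recompTop)
        add(mmCode, mmSev, "$.id", sprintf(
          "stored dataset id %s does not match recomputed id %s",
          ids$storedTop, ids$recompTop))
    }
  }

  .issuesToReport(col$issues)
}

## serialize an in-memory dataset into the raw (parsed-JSON-like)
## representation the validator operates on; read-only view
.datasetToRaw <- function(d) {
  vecToList <- function(v) {
    out <- lapply(seq_along(v), function(i) {
      if (is.na(v[i]) && !(is.numeric(v) && is.nan(v[i]))) NULL
      else v[i]
    })
    out
  }
  attrToRaw <- function(a) {
    if (is.null(a)) return(NULL)
    if (is.list(a)) {
      out <- lapply(a, attrToRaw)
      names(out) <- names(a)
      if (!length(out) && is.null(names(out))) names(out) <- character(0)
      return(out)
    }
    if (is.atomic(a)) {
      if (!is.null(names(a))) return(as.list(a))
      if (length(a) == 1L) return(if (is.na(a)) NULL else a)
      return(vecToList(a))
    }
    a
  }
  list(
    attr = { x <- attrToRaw(d@attr); if (is.null(names(x))) names(x) <- character(0); x },
    data = lapply(seq_along(d@data), function(i) {
      tr <- d@data[[i]]
      at <- attrToRaw(tr@attr)
      if (is.null(names(at))) names(at) <- character(0)
      list(attr = at, id = tr@id, index = as.list(tr@index),
           values = {
             v <- lapply(tr@values, vecToList)
             names(v) <- names(tr@values)
             if (is.null(names(v))) names(v) <- character(0)
             v
           })
    }),
    desc = d@desc,
    id = d@id,
    types = { t <- as.list(d@types); if (is.null(names(t))) names(t) <- character(0); t }
  )
}
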