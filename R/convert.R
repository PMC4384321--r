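## Lossless translation between SMD and long-format delimited tables
## (one row per time point), the lingua franca of lab acquisition
## scripts.

#' Describe the layout of a long-format table
#'
#' Names the columns of a long-format (one row per time point) table so
#' it can be imported into an SMD dataset: which column identifies the
#' trace, which holds the index (time), which hold channel values, and
#' which hold per-trace annotations (constant within a trace).
#'
#' @param traceKey column naming the trace each row belongs to.
#' @param indexCol column holding the numeric row label (time).
#' @param channelCols columns holding channel values, in order.
#' @param attrCols optional columns folded into per-trace `attr`; their
#'   value must be constant within each trace.
#' @return An object of class `LongTableSpec`.
#' @examples
#' longTableSpec("molecule", "time", c("donor", "acceptor"))
#' @export
longTableSpec <- function(traceKey, indexCol, channelCols,
                          attrCols = character()) {
  stopifnot(is.character(traceKey), length(traceKey) == 1L,
            is.character(indexCol), length(indexCol) == 1L,
            is.character(channelCols), length(channelCols) >= 1L)
  all <- c(traceKey, indexCol, channelCols, attrCols)
  if (any(!nzchar(all)) || anyDuplicated(all))
    stop("column roles must name distinct, non-empty columns",
         call. = FALSE)
  structure(list(traceKey = traceKey, indexCol = indexCol,
                 channelCols = channelCols,
                 attrCols = as.character(attrCols)),
            class = "LongTableSpec")
}

.readDelim <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "")
}

#' Import a long-format table as an SMD dataset
#'
#' Builds one trace per distinct value of the trace-key column,
#' preserving row order within each trace as index order. Values of
#' `attrCols` are attached to the trace's `attr` (they must be constant
#' within a trace), the original trace key is stored in the trace
#' `attr` under `"source_key"`, empty cells become `NA` (null), and the
#' channel type map is inferred.
#'
#' @param x a data.frame, or a path to a CSV/TSV file with a header row
#'   (delimiter auto-detected between comma and tab unless `sep` is
#'   given; decimal point is always `"."`).
#' @param spec a [longTableSpec()].
#' @param desc dataset description.
#' @param sep optional delimiter override when `x` is a path.
#' @return An [SMDDataset-class].
#' @examples
#' tab <- data.frame(mol = rep(c("m1", "m2"), each = 3), t = rep(0:2, 2),
#'                   donor = rnorm(6, 100), acceptor = rnorm(6, 30))
#' d <- importLongTable(tab, longTableSpec("mol", "t", c("donor", "acceptor")))
#' nTraces(d)
#' @export
importLongTable <- function(x, spec, desc = "", sep = NULL) {
  stopifnot(inherits(spec, "LongTableSpec"))
  tab <- if (is.character(x)) .readDelim(x, sep) else as.data.frame(x)
  need <- c(spec$traceKey, spec$indexCol, spec$channelCols, spec$attrCols)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop(sprintf("table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  key <- as.character(tab[[spec$traceKey]])
  groups <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  tracesList <- lapply(names(groups), function(k) {
    rows <- groups[[k]]
    at <- list(source_key = k)
    for (ac in spec$attrCols) {
      vals <- unique(tab[[ac]][rows])
      if (length(vals) != 1L)
        stop(sprintf(
          "attribute column '%s' is not constant within trace '%s'",
          ac, k), call. = FALSE)
      at[[ac]] <- vals
    }
    vals <- lapply(spec$channelCols, function(cc) tab[[cc]][rows])
    names(vals) <- spec$channelCols
    SMDTrace(index = as.numeric(tab[[spec$indexCol]][rows]),
             values = vals, attr = at)
  })
  SMDDataset(tracesList, desc = desc)
}

.flattenAttrForTable <- function(at, traceId) {
  out <- list()
  for (k in names(at)) {
    v <- at[[k]]
    if (is.atomic(v) && is.null(names(v)) && length(v) == 1L) {
      out[[k]] <- v
    } else if (is.atomic(v) && length(v) > 1L) {
      for (j in seq_along(v)) {
        nm <- if (!is.null(names(v))) names(v)[j] else j
        out[[paste0(k, ".", nm)]] <- v[[j]]
      }
    } else if (is.list(v)) {
      for (nm in names(v)) {
        vv <- v[[nm]]
        if (!(is.atomic(vv) && length(vv) == 1L && is.null(names(vv))))
          stop(sprintf(
            "trace %s attr '%s.%s' is nested too deeply for a long table",
            traceId, k, nm), call. = FALSE)
        out[[paste0(k, ".", nm)]] <- vv
      }
    } else {
      stop(sprintf("trace %s attr '%s' cannot be flattened", traceId, k),
           call. = FALSE)
    }
  }
  out
}

#' Export an SMD dataset as a long-format table
#'
#' Emits one row per (trace, index position): columns `id` (the trace
#' content id), `source_key` when any trace carries one, `index`, one
#' column per channel (sorted by name), and per-trace attribute columns
#' (constant within each trace; list/vector attributes are flattened
#' one level with dotted keys, deeper nesting is refused). `NA`/null
#' channel values become empty cells on disk. Rows are ordered by trace
#' then index position.
#'
#' @param dataset a valid [SMDDataset-class].
#' @param path optional output file; written as delimited text with a
#'   header row and empty cells for missing values.
#' @param sep field delimiter for `path` (default comma).
#' @param attrs include flattened per-trace attributes as columns.
#' @return The data.frame (invisibly when `path` is given).
#' @examples
#' d <- simulateDataset(nTraces = 2, nPoints = 5, seed = 1)
#' head(exportLongTable(d, attrs = FALSE))
#' @export
exportLongTable <- function(dataset, path = NULL, sep = ",", attrs = TRUE) {
  stopifnot(is(dataset, "SMDDataset"))
  chans <- sort(names(dataset@types))
  trs <- dataset@data
  haveSource <- any(vapply(trs, function(t) "source_key" %in% names(t@attr),
                           logical(1L)))
  attrCols <- character()
  flat <- vector("list", length(trs))
  if (attrs) {
    for (i in seq_along(trs)) {
      at <- trs[[i]]@attr
      at <- at[setdiff(names(at), "source_key")]
      flat[[i]] <- .flattenAttrForTable(at, trs[[i]]@id)
      attrCols <- union(attrCols, names(flat[[i]]))
    }
    clash <- intersect(attrCols, c("id", "source_key", "index", chans))
    if (length(clash))
      stop(sprintf("attr name(s) collide with table columns: %s",
                   paste(clash, collapse = ", ")), call. = FALSE)
  }
  pieces <- lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    n <- length(tr@index)
    if (n == 0L) return(NULL)
    df <- data.frame(id = rep(tr@id, n), stringsAsFactors = FALSE)
    if (haveSource) {
      sk <- tr@attr[["source_key"]]
      df$source_key <- if (is.null(sk)) NA_character_ else as.character(sk)
    }
    df$index <- tr@index
    for (ch in chans) df[[ch]] <- tr@values[[ch]]
    for (ac in attrCols) {
      v <- flat[[i]][[ac]]
      df[[ac]] <- if (is.null(v)) NA else v
    }
    df
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  out <- if (length(pieces)) do.call(rbind, pieces) else {
    df <- data.frame(id = character(), stringsAsFactors = FALSE)
    if (haveSource) df$source_key <- character()
    df$index <- numeric()
    for (ch in chans) df[[ch]] <- vector(mode = "logical", 0L)
    df
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    disk <- out
    ## canonical (shortest round-trip) number rendering so the on-disk
    ## table is lossless; write.table's default formatting keeps only
    ## 15 significant digits
    for (col in names(disk)) {
      if (is.numeric(disk[[col]])) {
        s <- .canonNumber(disk[[col]], col)
        s[s == "null"] <- NA_character_
        disk[[col]] <- s
      }
    }
    utils::write.table(disk, path, sep = sep, na = "", row.names = FALSE,
                       quote = which(vapply(out, is.character,
                                            logical(1L))),
                       qmethod = "double")
    return(invisible(out))
  }
  out
}
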