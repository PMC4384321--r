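## Conformance corpus runner. The corpus (shipped under
## inst/extdata/conformance) pairs each .smd.json fixture with a
## .expect.json sidecar naming the validation mode, the expected issue
## codes and the expected validity, so independent implementations of
## the format can check themselves against the same files.

#' Path to the shipped conformance corpus
#' @return Directory path.
#' @export
conformanceCorpus <- function() {
  system.file("extdata", "conformance", package = "smdformat")
}

#' Run the conformance corpus
#'
#' For every fixture/sidecar pair in a corpus directory, validates the
#' fixture and compares the set of issue codes and the validity flag
#' with the sidecar's expectation (order-insensitive; duplicate codes
#' collapse). A malformed sidecar marks the case as broken, not failed.
#'
#' Sidecar format (`<name>.expect.json` next to `<name>.smd.json`):
#' `{"mode": "strict"|"lenient", "expected_codes": [...],
#' "expected_valid": true|false}`.
#'
#' @param dir corpus directory; defaults to the shipped corpus.
#' @return A data.frame with one row per case: `case`, `pass`,
#'   `broken`, `expected`, `observed` (comma-joined code sets).
#' @examples
#' res <- runConformance()
#' all(res$pass)
#' @export
runConformance <- function(dir = conformanceCorpus()) {
  fixtures <- sort(list.files(dir, pattern = "\\.smd\\.json$",
                              full.names = TRUE))
  if (!length(fixtures))
    stop(sprintf("no conformance fixtures found in '%s'", dir),
         call. = FALSE)
  rows <- lapply(fixtures, function(fx) {
    case <- sub("\\.smd\\.json$", "", basename(fx))
    sidecar <- file.path(dir, paste0(case, ".expect.json"))
    exp <- tryCatch({
      e <- jsonlite::parse_json(readChar(sidecar, file.info(sidecar)$size))
      stopifnot(is.character(e$mode) || is.null(e$mode),
                is.logical(e$expected_valid[[1L]]))
      e
    }, error = function(err) NULL)
    if (is.null(exp))
      return(data.frame(case = case, pass = FALSE, broken = TRUE,
                        expected = NA_character_, observed = NA_character_,
                        stringsAsFactors = FALSE))
    mode <- if (is.null(exp$mode)) "strict" else exp$mode[[1L]]
    rep <- tryCatch(validateSMD(fx, mode = mode),
                    smd_parse_error = function(e) NULL)
    expCodes <- sort(unique(unlist(exp$expected_codes)))
    if (is.null(expCodes)) expCodes <- character()
    obsCodes <- if (is.null(rep)) "<unparseable>"
                else sort(unique(rep$issues$code))
    pass <- !is.null(rep) && identical(obsCodes, expCodes) &&
      identical(rep$valid, isTRUE(exp$expected_valid[[1L]]))
    data.frame(case = case, pass = pass, broken = FALSE,
               expected = paste(expCodes, collapse = ","),
               observed = paste(obsCodes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
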