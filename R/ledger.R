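#' Experiment ledger: append-only parameter record
#'
#' Every user-chosen and automatically assigned parameter of a pipeline
#' run is recorded in a plain-text file (`pipeline.log`) inside the
#' experiment folder, one line per event:
#' `ISO8601-timestamp<TAB>key<TAB>JSON-encoded value`. Writes only ever
#' append; reading a key returns its most recently written value, so the
#' file is a complete, replayable audit trail of the analysis.
#'
#' @param path location of the ledger file; created empty if absent.
#' @return An object of class `experiment_ledger`.
#' @export
ledger_open <- function(path) {
  if (!file.exists(path)) {
    ok <- tryCatch({ file.create(path); TRUE },
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !file.exists(path))
      stop("ledger_open: cannot create ledger at '", path, "'")
  }
  structure(list(path = path), class = "experiment_ledger")
}

#' Record a key/value pair in the ledger
#'
#' @param ledger an [experiment_ledger][ledger_open].
#' @param key non-empty key string.
#' @param value any JSON-serializable value (scalar, vector, list).
#' @return The ledger, invisibly, for chaining.
#' @export
ledger_record <- function(ledger, key, value) {
  stopifnot(inherits(ledger, "experiment_ledger"))
  key <- as.character(key)[1]
  if (!nzchar(key)) stop("ledger_record: 'key' must be non-empty")
  if (grepl("[\t\n]", key)) stop("ledger_record: 'key' may not contain tabs/newlines")
  val <- as.character(jsonlite::toJSON(value, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"), key, val,
                sep = "\t")
  con <- tryCatch(file(ledger$path, open = "a"),
                  error = function(e)
                    stop("ledger_record: cannot write to '", ledger$path, "'"))
  on.exit(close(con))
  writeLines(line, con)
  invisible(ledger)
}

ledger_parse <- function(ledger) {
  lines <- readLines(ledger$path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(timestamp = character(), key = character(),
                      value = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("ledger: malformed line(s) in ", ledger$path)
  data.frame(timestamp = vapply(parts, `[[`, "", 1L),
             key = vapply(parts, `[[`, "", 2L),
             value = vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), ""),
             stringsAsFactors = FALSE)
}

#' Read the last-written value of a ledger key
#'
#' @param ledger an [experiment_ledger][ledger_open].
#' @param key key string.
#' @param default value returned when the key has never been recorded;
#'   by default missing keys are an error.
#' @return The deserialized value of the last entry for `key`.
#' @export
ledger_read <- function(ledger, key, default = NULL) {
  stopifnot(inherits(ledger, "experiment_ledger"))
  df <- ledger_parse(ledger)
  hits <- which(df$key == key)
  if (length(hits) == 0) {
    if (!missing(default)) return(default)
    stop("ledger_read: key '", key, "' not found in ", ledger$path)
  }
  jsonlite::fromJSON(df$value[hits[length(hits)]], simplifyVector = TRUE)
}

#' List all keys present in a ledger
#'
#' @param ledger an [experiment_ledger][ledger_open].
#' @return Character vector of unique keys in first-seen order.
#' @export
ledger_keys <- function(ledger) {
  unique(ledger_parse(ledger)$key)
}
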