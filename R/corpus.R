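#' Default document retrieval window
#'
#' The corpus the analysis targets is bounded by the issue date of the
#' anchoring joint guidance document (23 October 2019) and the retrieval
#' deadline (1 February 2022); both endpoints are inclusive.
#'
#' @return A length-2 Date vector `c(start, end)`.
#' @export
default_retrieval_window <- function() {
  c(as.Date("2019-10-23"), as.Date("2022-02-01"))
}

#' Construct a policy document record
#'
#' One corpus record: a policy document with its issuing agencies, the
#' agencies it mentions (as surface form / code pairs), and per-aspect
#' mention counts. Either `mentions` or `text` must be present; documents
#' carrying only raw text are resolved later by [recognize_entities()].
#'
#' @param doc_id Unique document identifier.
#' @param date Issue date (`Date` or `"YYYY-MM-DD"` string).
#' @param issuers Non-empty character vector of issuing agency codes.
#' @param mentions `NULL`, or a data.frame with columns `surface`, `code`.
#' @param text `NULL`, or the raw document text.
#' @param aspect_counts Named non-negative integer vector, aspect -> number
#'   of mentions attributed to that aspect (may be empty).
#' @return An object of class `policy_document`.
#' @export
policy_document <- function(doc_id, date, issuers, mentions = NULL,
                            text = NULL, aspect_counts = integer(0)) {
  if (length(issuers) == 0L) {
    stop(sprintf("document '%s' has no issuers", doc_id))
  }
  if (is.null(mentions) && is.null(text)) {
    stop(sprintf("document '%s' has neither mentions nor text", doc_id))
  }
  if (!is.null(mentions)) {
    mentions <- as.data.frame(mentions)
    stopifnot(all(c("surface", "code") %in% names(mentions)))
    mentions <- mentions[c("surface", "code")]
    mentions$surface <- as.character(mentions$surface)
    mentions$code <- as.character(mentions$code)
  }
  ac <- as.integer(aspect_counts)
  names(ac) <- names(aspect_counts)
  if (any(ac < 0)) stop(sprintf("document '%s': negative aspect count", doc_id))
  structure(list(doc_id = as.character(doc_id), date = as.Date(date),
                 issuers = as.character(issuers), mentions = mentions,
                 text = text, aspect_counts = ac),
            class = "policy_document")
}

validate_document <- function(doc, dict) {
  codes <- agency_codes(dict)
  unknown <- setdiff(doc$issuers, codes)
  if (length(unknown) > 0L) {
    stop(sprintf("document '%s': unknown issuer code(s): %s",
                 doc$doc_id, paste(unknown, collapse = ", ")))
  }
  if (!is.null(doc$mentions)) {
    unknown <- setdiff(doc$mentions$code, codes)
    if (length(unknown) > 0L) {
      stop(sprintf("document '%s': mention code(s) not in dictionary: %s",
                   doc$doc_id, paste(unknown, collapse = ", ")))
    }
  }
  invisible(doc)
}

#' Read a policy-document corpus from a JSONL file
#'
#' One JSON object per line with fields `doc_id`, `date`, `issuers`,
#' and `mentions` (array of `{surface, code}`) and/or `text`, plus optional
#' `aspect_counts`. Documents dated outside the retrieval window are dropped
#' and the dropped count is reported via `message()`.
#'
#' @param path Path to the JSONL file.
#' @param dict An [agency_dictionary()] used to validate issuer and mention
#'   codes, or `NULL` to skip code validation.
#' @param window Length-2 Date vector, inclusive on both ends; defaults to
#'   [default_retrieval_window()].
#' @return A list of [policy_document()] records, class `hnicn_corpus`.
#' @export
read_corpus <- function(path, dict = NULL,
                        window = default_retrieval_window()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    mentions <- rec$mentions
    if (!is.null(mentions) && length(mentions) == 0L) mentions <- NULL
    if (!is.null(mentions)) mentions <- as.data.frame(mentions)
    ac <- unlist(rec$aspect_counts)
    if (is.null(ac)) ac <- integer(0)
    policy_document(rec$doc_id, rec$date, unlist(rec$issuers),
                    mentions = mentions, text = rec$text, aspect_counts = ac)
  })
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id(s): ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  if (!is.null(dict)) lapply(docs, validate_document, dict = dict)
  dates <- as.Date(vapply(docs, function(d) as.character(d$date), character(1)))
  keep <- dates >= window[1] & dates <= window[2]
  if (any(!keep)) {
    message(sprintf("read_corpus: dropped %d document(s) outside %s..%s",
                    sum(!keep), window[1], window[2]))
  }
  structure(docs[keep], class = "hnicn_corpus")
}

#' Write a corpus to a JSONL file
#'
#' Inverse of [read_corpus()]: one JSON object per document per line.
#'
#' @param corpus A list of [policy_document()] records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    rec <- list(doc_id = doc$doc_id, date = as.character(doc$date),
                issuers = doc$issuers)
    if (!is.null(doc$mentions)) rec$mentions <- doc$mentions
    if (!is.null(doc$text)) rec$text <- doc$text
    if (length(doc$aspect_counts) > 0L) {
      rec$aspect_counts <- as.list(doc$aspect_counts)
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.hnicn_corpus <- function(x, ...) {
  cat(sprintf("<hnicn_corpus> %d documents\n", length(x)))
  invisible(x)
}
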