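#' Recognize agency entities in document text
#'
#' Dictionary-driven named entity recognition: every canonical name and
#' alias in the dictionary is matched as a literal substring of `text`.
#' Overlapping candidates are resolved leftmost-longest: candidates are
#' scanned in order of start position, ties broken in favour of the longer
#' surface form, and any candidate overlapping an accepted one is discarded.
#' This makes a canonical name win over an alias nested inside it.
#'
#' @param text A single character string (may be empty).
#' @param dict An [agency_dictionary()] with at least one entry.
#' @return A data.frame with columns `surface`, `code`, `position` (1-based
#'   start offset in characters), sorted by `position`. Zero rows when
#'   nothing matches.
#' @export
recognize_entities <- function(text, dict) {
  stopifnot(inherits(dict, "agency_dictionary"))
  if (length(dict$lookup) == 0L) stop("dictionary is empty")
  empty <- data.frame(surface = character(0), code = character(0),
                      position = integer(0), stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)

  starts <- integer(0); lens <- integer(0); forms <- character(0)
  for (surface in names(dict$lookup)) {
    hit <- gregexpr(surface, text, fixed = TRUE)[[1L]]
    if (hit[1L] == -1L) next
    starts <- c(starts, as.integer(hit))
    lens <- c(lens, rep.int(nchar(surface), length(hit)))
    forms <- c(forms, rep.int(surface, length(hit)))
  }
  if (length(starts) == 0L) return(empty)

  ord <- order(starts, -lens)
  starts <- starts[ord]; lens <- lens[ord]; forms <- forms[ord]
  keep <- logical(length(starts))
  last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > last_end) {
      keep[i] <- TRUE
      last_end <- starts[i] + lens[i] - 1L
    }
  }
  data.frame(surface = forms[keep],
             code = unname(dict$lookup[forms[keep]]),
             position = starts[keep],
             stringsAsFactors = FALSE)
}

#' Resolve text-only documents to mention lists
#'
#' Runs [recognize_entities()] over every document that carries raw text but
#' no pre-extracted mention list, filling in `mentions`.
#'
#' @param corpus A list of [policy_document()] records.
#' @param dict An [agency_dictionary()].
#' @return The corpus with all documents resolved.
#' @export
resolve_mentions <- function(corpus, dict) {
  out <- lapply(corpus, function(doc) {
    if (is.null(doc$mentions)) {
      if (is.null(doc$text)) {
        stop(sprintf("document '%s' has neither mentions nor text",
                     doc$doc_id))
      }
      hits <- recognize_entities(doc$text, dict)
      doc$mentions <- data.frame(surface = hits$surface, code = hits$code,
                                 stringsAsFactors = FALSE)
    }
    doc
  })
  class(out) <- class(corpus)
  out
}
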