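#' Construct an agency dictionary
#'
#' An agency dictionary is the gazetteer driving entity recognition: one row
#' per government department or public organization, with a short code, a
#' canonical name, zero or more aliases (abbreviations, acronyms, pronouns),
#' the prefix/middle/tagged-word decomposition of the name, and a category.
#' A surface-form lookup (every canonical name and alias mapped to its code)
#' is built at construction time and validated for collisions.
#'
#' @param entries A data.frame with columns `code`, `canonical_name`,
#'   `aliases` (a list column of character vectors, or a character column of
#'   semicolon-joined aliases), `prefix`, `middle`, `tagged`, `category`
#'   (one of `"government-department"`, `"public-organization"`).
#' @return An object of class `agency_dictionary`: a list with components
#'   `entries` (the validated data.frame, aliases as a list column) and
#'   `lookup` (named character vector, surface form -> code).
#' @export
agency_dictionary <- function(entries) {
  required <- c("code", "canonical_name", "aliases", "prefix", "middle",
                "tagged", "category")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("dictionary entries missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  entries <- as.data.frame(entries)[required]
  if (!is.list(entries$aliases)) {
    entries$aliases <- lapply(as.character(entries$aliases), function(a) {
      if (is.na(a) || !nzchar(a)) character(0)
      else trimws(strsplit(a, ";", fixed = TRUE)[[1L]])
    })
  }
  entries$aliases <- lapply(entries$aliases,
                            function(a) as.character(a[nzchar(a)]))
  entries$code <- as.character(entries$code)
  entries$canonical_name <- as.character(entries$canonical_name)

  dup <- entries$code[duplicated(entries$code)]
  if (length(dup) > 0L) {
    stop("duplicate agency code(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(entries$tagged))) {
    stop("tagged word must be non-empty for code(s): ",
         paste(entries$code[!nzchar(entries$tagged)], collapse = ", "))
  }
  bad_cat <- setdiff(unique(entries$category),
                     c("government-department", "public-organization"))
  if (length(bad_cat) > 0L) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  }
  self_alias <- mapply(function(name, al) name %in% al,
                       entries$canonical_name, entries$aliases)
  if (nrow(entries) > 0L && any(self_alias)) {
    stop("canonical name listed among its own aliases for code(s): ",
         paste(entries$code[self_alias], collapse = ", "))
  }

  surfaces <- character(0)
  codes <- character(0)
  for (i in seq_len(nrow(entries))) {
    forms <- c(entries$canonical_name[i], entries$aliases[[i]])
    surfaces <- c(surfaces, forms)
    codes <- c(codes, rep(entries$code[i], length(forms)))
  }
  if (anyDuplicated(surfaces)) {
    d <- surfaces[duplicated(surfaces)][1L]
    owners <- unique(codes[surfaces == d])
    stop(sprintf("surface form '%s' maps to more than one code: %s",
                 d, paste(owners, collapse = ", ")))
  }
  lookup <- stats::setNames(codes, surfaces)

  structure(list(entries = entries, lookup = lookup),
            class = "agency_dictionary")
}

#' Read an agency dictionary from a TSV file
#'
#' Expects a tab-separated file with header
#' `code, canonical_name, aliases, prefix, middle, tagged, category`;
#' `aliases` is a semicolon-joined list (may be empty). A header-only file
#' yields an empty dictionary.
#'
#' @param path Path to the TSV file.
#' @return An [agency_dictionary()].
#' @export
read_agency_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = NULL, fileEncoding = "UTF-8")
  agency_dictionary(df)
}

#' Write an agency dictionary to a TSV file
#'
#' Inverse of [read_agency_dictionary()]; aliases are semicolon-joined.
#'
#' @param dict An [agency_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agency_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "agency_dictionary"))
  out <- dict$entries
  out$aliases <- vapply(out$aliases, paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.agency_dictionary <- function(x, ...) {
  n <- nrow(x$entries)
  cat(sprintf("<agency_dictionary> %d entries, %d surface forms\n",
              n, length(x$lookup)))
  if (n > 0L) {
    tab <- table(x$entries$category)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

agency_codes <- function(dict) dict$entries$code
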