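#' Min-max normalize a mention-count matrix into [1, 2]
#'
#' The decision matrix of the weighting stage holds, for agency i and index
#' aspect j, the number of mentions of agency i attributed to aspect j,
#' min-max mapped into the range 1.0 to 2.0:
#' `data = 1 + (raw - min) / (max - min)`. The shift to a strictly positive
#' range keeps every entry usable inside the entropy term p*log(p).
#' A column (or, with `scope = "global"`, a matrix) with zero spread maps to
#' the midpoint 1.5: it carries no discriminating information and will
#' receive zero information utility downstream.
#'
#' @param raw Non-negative numeric matrix, agencies in rows (>= 2), index
#'   aspects in columns. Dimnames, when present, are carried through.
#' @param scope `"column"` (default) applies the min-max map per aspect
#'   column; `"global"` uses the extrema of the whole matrix.
#' @return An object of class `mention_matrix`: list with `raw`,
#'   `normalized`, `aspect_labels`, `agency_codes`.
#' @export
normalize_mentions <- function(raw, scope = c("column", "global")) {
  scope <- match.arg(scope)
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least 2 agencies (rows)")
  if (any(raw < 0)) stop("raw mention counts must be non-negative")
  normalized <- raw
  if (scope == "column") {
    for (j in seq_len(ncol(raw))) {
      lo <- min(raw[, j]); hi <- max(raw[, j])
      normalized[, j] <- if (hi > lo) 1 + (raw[, j] - lo) / (hi - lo) else 1.5
    }
  } else {
    lo <- min(raw); hi <- max(raw)
    normalized[] <- if (hi > lo) 1 + (raw - lo) / (hi - lo) else 1.5
  }
  labels <- colnames(raw)
  if (is.null(labels)) labels <- paste0("aspect_", seq_len(ncol(raw)))
  codes <- rownames(raw)
  if (is.null(codes)) codes <- paste0("N", seq_len(nrow(raw)))
  dimnames(raw) <- dimnames(normalized) <- list(codes, labels)
  structure(list(raw = raw, normalized = normalized,
                 aspect_labels = labels, agency_codes = codes),
            class = "mention_matrix")
}

#' @export
print.mention_matrix <- function(x, ...) {
  cat(sprintf("<mention_matrix> %d agencies x %d aspects, normalized range [%.3f, %.3f]\n",
              nrow(x$raw), ncol(x$raw), min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' Read a raw mention-count matrix from CSV
#'
#' Rows are agencies (first column = agency code), remaining columns are
#' index aspects; values are non-negative counts.
#'
#' @param path CSV path.
#' @param scope Passed to [normalize_mentions()].
#' @return A `mention_matrix`.
#' @export
read_mention_matrix <- function(path, scope = "column") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  normalize_mentions(m, scope = scope)
}
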