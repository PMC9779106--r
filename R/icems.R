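# Natural ordering key for agency codes: alphabetic prefix, then numeric
# suffix, so A3 sorts before A14 and every A before every B.
code_rank <- function(codes) {
  prefix <- sub("^([A-Za-z]*).*$", "\\1", codes)
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z]*", "", codes)))
  num[is.na(num)] <- 0
  order(order(prefix, num, codes))
}

# Orient unordered pairs so the naturally smaller code comes first.
orient_pairs <- function(ci, cj) {
  swap <- code_rank(c(ci, cj))[seq_along(ci)] >
    code_rank(c(ci, cj))[seq_along(ci) + length(ci)]
  tmp <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmp
  data.frame(code_i = ci, code_j = cj, stringsAsFactors = FALSE)
}

#' Collaboration structure entropy
#'
#' `cse = coverage * log_base(coverage)`: an information-entropy style score
#' of a node's tendency to participate in collaboration. Coverage sits on a
#' [1, Inf) scale (see [collaboration_coverage()]), so cse is 0 at the floor
#' coverage of 1 and strictly increasing beyond it. The default logarithm
#' base is 2, the base under which the published coverage-to-cse table is
#' internally consistent; the base is configurable.
#'
#' @param coverage Positive numeric vector of coverage values.
#' @param base Logarithm base, > 1; default 2.
#' @return Numeric vector of cse values.
#' @export
collaboration_structure_entropy <- function(coverage, base = 2) {
  if (any(coverage <= 0)) stop("coverage must be strictly positive")
  if (base <= 1) stop("log base must be > 1")
  coverage * log(coverage, base = base)
}

#' Pairwise collaboration-effect matrix
#'
#' For every unordered pair of distinct nodes the effect is the product of
#' their cse values normalized by the maximum product M over all pairs,
#' expressed as a percentage. The pair(s) attaining M are damped to
#' `M / (M + psi)` so that no effect reaches 100%; all other pairs score
#' `cse_i * cse_j / M`. psi > 0 controls how close the top pair may get to
#' 100% (default 10,000).
#'
#' @param cse Named numeric vector of cse values (names = agency codes),
#'   length >= 2, at least one positive pairwise product.
#' @param psi Positive damping parameter; default 10,000.
#' @return An object of class `effect_matrix`: a symmetric numeric matrix of
#'   effect percentages with `NA` on the diagonal, with attributes `psi`,
#'   `max_product`, and `max_pairs` (data.frame of the pair(s) attaining M).
#' @export
collaboration_effect_matrix <- function(cse, psi = 10000) {
  if (length(cse) < 2L) stop("need at least 2 agencies")
  if (psi <= 0) stop("psi must be positive")
  if (is.null(names(cse))) names(cse) <- paste0("N", seq_along(cse))
  if (any(cse < 0)) stop("cse values must be non-negative")
  P <- outer(cse, cse)
  diag(P) <- NA
  M <- max(P, na.rm = TRUE)
  if (M == 0) stop("all cse values are zero; effect undefined")
  eff <- P / M * 100
  at_max <- !is.na(P) & P == M
  eff[at_max] <- M / (M + psi) * 100
  idx <- which(at_max & upper.tri(P), arr.ind = TRUE)
  max_pairs <- orient_pairs(rownames(P)[idx[, 1L]], colnames(P)[idx[, 2L]])
  max_pairs <- max_pairs[order(code_rank(max_pairs$code_i),
                               code_rank(max_pairs$code_j)), , drop = FALSE]
  rownames(max_pairs) <- NULL
  structure(eff, class = c("effect_matrix", "matrix"), psi = psi,
            max_product = M, max_pairs = max_pairs)
}

#' Rank node pairs by collaboration effect
#'
#' Flattens the upper triangle of an effect matrix, sorts descending by
#' effect with ties broken lexicographically by `(code_i, code_j)`, and
#' returns the top rows.
#'
#' @param effects An `effect_matrix` from [collaboration_effect_matrix()].
#' @param top_n Number of pairs to return (>= 1); default 10. Capped at the
#'   number of pairs.
#' @return A data.frame with columns `rank`, `code_i`, `code_j`, `pair`
#'   (e.g. `"A1-A14"`), `effect_percent` (unrounded numeric).
#' @export
rank_effects <- function(effects, top_n = 10) {
  stopifnot(inherits(effects, "effect_matrix"))
  if (top_n < 1) stop("top_n must be >= 1")
  idx <- which(upper.tri(effects), arr.ind = TRUE)
  df <- orient_pairs(rownames(effects)[idx[, 1L]],
                     colnames(effects)[idx[, 2L]])
  df$effect_percent <- effects[idx]
  df <- df[order(-df$effect_percent, code_rank(df$code_i),
                 code_rank(df$code_j)), , drop = FALSE]
  df <- utils::head(df, top_n)
  df$rank <- seq_len(nrow(df))
  df$pair <- paste(df$code_i, df$code_j, sep = "-")
  rownames(df) <- NULL
  df[c("rank", "code_i", "code_j", "pair", "effect_percent")]
}
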