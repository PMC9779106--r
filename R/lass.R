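#' Entropy-weight method: per-aspect index weights
#'
#' Classic entropy weighting over the normalized decision matrix. For each
#' aspect column j: proportions `p(i,j) = data(i,j) / sum_i data(i,j)`;
#' information entropy `inf_entropy_j = -(1/ln n) * sum_i p ln p` (so a
#' uniform column attains entropy 1); information utility
#' `inf_utility_j = 1 - inf_entropy_j`; and the index weight is the utility
#' normalized over aspects. Aspects on which agencies differ most therefore
#' weigh most. When every column is exactly uniform all utilities vanish and
#' the weights fall back to equal shares, with a warning.
#'
#' @param data A `mention_matrix` from [normalize_mentions()], or a numeric
#'   matrix of strictly positive entries.
#' @return An object of class `index_weights`: data.frame with columns
#'   `aspect`, `inf_entropy`, `inf_utility`, `weight_index`; the proportion
#'   matrix is attached as attribute `p`.
#' @export
entropy_index_weights <- function(data) {
  m <- if (inherits(data, "mention_matrix")) data$normalized else as.matrix(data)
  n <- nrow(m)
  if (n < 2L) stop("entropy normalizer 1/ln(n) requires at least 2 agencies")
  if (any(m <= 0)) stop("decision matrix entries must be strictly positive")
  p <- sweep(m, 2L, colSums(m), "/")
  ent <- -colSums(p * log(p)) / log(n)
  ent <- pmin(pmax(ent, 0), 1)  # guard roundoff at the uniform limit
  utility <- 1 - ent
  if (sum(utility) > 0) {
    w <- utility / sum(utility)
  } else {
    warning("all aspects have zero information utility; using equal weights")
    w <- rep(1 / ncol(m), ncol(m))
  }
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("aspect_", seq_len(ncol(m)))
  out <- data.frame(aspect = labels, inf_entropy = unname(ent),
                    inf_utility = unname(utility), weight_index = unname(w),
                    stringsAsFactors = FALSE)
  attr(out, "p") <- p
  class(out) <- c("index_weights", class(out))
  out
}

#' Relative closeness to the ideal solution
#'
#' The TOPSIS closeness `close = dis_minus / (dis_minus + dis_plus)`:
#' 1 at the ideal solution, 0 at the anti-ideal. A node at zero distance
#' from both (all rows identical) is assigned 0.5 by convention.
#'
#' @param dis_plus Distances from the best (ideal) solution.
#' @param dis_minus Distances from the worst (anti-ideal) solution.
#' @return Numeric vector of closeness values in [0, 1].
#' @export
relative_closeness <- function(dis_plus, dis_minus) {
  stopifnot(length(dis_plus) == length(dis_minus))
  if (any(dis_plus < 0) || any(dis_minus < 0)) {
    stop("distances must be non-negative")
  }
  denom <- dis_plus + dis_minus
  out <- ifelse(denom == 0, 0.5, dis_minus / denom)
  as.numeric(out)
}

#' Node weights from a closeness vector
#'
#' Normalizes TOPSIS relative closeness into node weights summing to one.
#'
#' @param close Non-negative numeric vector (optionally named by code).
#' @return Numeric vector of weights, names preserved.
#' @export
node_weights_from_closeness <- function(close) {
  if (any(close < 0)) stop("closeness must be non-negative")
  s <- sum(close)
  if (s == 0) stop("cannot normalize an all-zero closeness vector")
  close / s
}

#' TOPSIS node weights from the decision matrix and index weights
#'
#' Standard TOPSIS over the normalized mention matrix with benefit-type
#' aspects throughout. The weighted-normalized matrix is
#' `Z(i,j) = (data - col_min) / (col_max - col_min) * weight_index_j`
#' (a column with zero spread contributes 0); the ideal and anti-ideal
#' vectors are column-wise maxima and minima of Z; distances are Euclidean;
#' closeness and node weights follow [relative_closeness()] and
#' [node_weights_from_closeness()].
#'
#' @param data A `mention_matrix` (or numeric matrix already in decision
#'   scale).
#' @param iw An `index_weights` object from [entropy_index_weights()].
#' @return An object of class `node_weights`: data.frame with columns
#'   `code`, `dis_plus`, `dis_minus`, `closeness`, `weight_node`; the Z
#'   matrix and ideal vectors are attached as attributes `Z`, `z_plus`,
#'   `z_minus`.
#' @export
topsis_node_weights <- function(data, iw) {
  m <- if (inherits(data, "mention_matrix")) data$normalized else as.matrix(data)
  stopifnot(inherits(iw, "index_weights"), ncol(m) == nrow(iw))
  w <- iw$weight_index
  Z <- m
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    Z[, j] <- if (hi > lo) (m[, j] - lo) / (hi - lo) * w[j] else 0
  }
  z_plus <- apply(Z, 2L, max)
  z_minus <- apply(Z, 2L, min)
  dis_plus <- sqrt(rowSums(sweep(Z, 2L, z_plus)^2))
  dis_minus <- sqrt(rowSums(sweep(Z, 2L, z_minus)^2))
  close <- relative_closeness(dis_plus, dis_minus)
  codes <- rownames(m)
  if (is.null(codes)) codes <- paste0("N", seq_len(nrow(m)))
  out <- data.frame(code = codes, dis_plus = unname(dis_plus),
                    dis_minus = unname(dis_minus), closeness = close,
                    weight_node = node_weights_from_closeness(close),
                    stringsAsFactors = FALSE)
  attr(out, "Z") <- Z
  attr(out, "z_plus") <- z_plus
  attr(out, "z_minus") <- z_minus
  class(out) <- c("node_weights", class(out))
  out
}

#' Build the distance-1 ego subgroup of every node
#'
#' Each node is in turn the center of a subgroup whose members are all
#' other nodes having a connection with the center in either direction.
#' Each member carries `count(member, center)`: the total document
#' multiplicity between member and center, both directions summed. `amount`
#' counts the center plus its members.
#'
#' @param net A [collab_network()].
#' @return A named list (one element per node, in node order) of `subgroup`
#'   objects: lists with `center`, `members`, `link_counts` (named numeric),
#'   `amount`.
#' @export
build_subgroups <- function(net) {
  stopifnot(inherits(net, "collab_network"))
  e <- net$edges
  out <- lapply(net$nodes, function(center) {
    touch <- e[e$source == center | e$target == center, , drop = FALSE]
    other <- ifelse(touch$source == center, touch$target, touch$source)
    counts <- tapply(touch$multiplicity, other, sum)
    members <- sort(names(counts))
    link_counts <- as.numeric(counts[members])
    names(link_counts) <- members
    structure(list(center = center, members = members,
                   link_counts = link_counts,
                   amount = length(members) + 1L),
              class = "subgroup")
  })
  names(out) <- net$nodes
  out
}

#' Collaboration coverage of one subgroup
#'
#' The adj_par-scaled average connection weight of a subgroup:
#' `coverage = adj_par * sum_j(weight_node_j * count(j, center)) / (amount - 1)`,
#' summed over the members j of the subgroup. Coverage is floored at 1.0 —
#' the neutral point at which the collaboration structure entropy vanishes —
#' so an isolated center, and any center whose averaged weighted link count
#' falls below the floor, reports exactly 1.0. The floor keeps coverage on
#' the `[1, Inf)` scale the downstream entropy assumes and matches the
#' published table, where several connected but weakly collaborating nodes
#' report exactly 1.00 and structure entropy 0.
#'
#' @param sub A `subgroup` from [build_subgroups()].
#' @param nw A `node_weights` data.frame (or any data.frame with columns
#'   `code` and `weight_node` covering the subgroup members).
#' @param adj_par Positive scaling parameter; default 10.
#' @return A single positive number.
#' @export
collaboration_coverage <- function(sub, nw, adj_par = 10) {
  stopifnot(inherits(sub, "subgroup"))
  if (adj_par <= 0) stop("adj_par must be positive")
  if (sub$amount == 1L) return(1.0)
  w <- nw$weight_node[match(sub$members, nw$code)]
  if (anyNA(w)) {
    stop("no node weight for member(s): ",
         paste(sub$members[is.na(w)], collapse = ", "))
  }
  max(adj_par * sum(w * sub$link_counts) / (sub$amount - 1L), 1.0)
}

#' Collaboration coverage for every node
#'
#' Applies [collaboration_coverage()] across a subgroup list.
#'
#' @param subgroups Output of [build_subgroups()].
#' @param nw A `node_weights` data.frame.
#' @param adj_par Positive scaling parameter; default 10.
#' @return A data.frame with columns `code`, `coverage`.
#' @export
coverage_table <- function(subgroups, nw, adj_par = 10) {
  data.frame(code = vapply(subgroups, `[[`, character(1), "center"),
             coverage = vapply(subgroups, collaboration_coverage,
                               numeric(1), nw = nw, adj_par = adj_par),
             row.names = NULL, stringsAsFactors = FALSE)
}
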