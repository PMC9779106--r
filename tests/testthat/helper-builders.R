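# Shared fixture builders: everything constructed in code, no files.

tiny_dictionary <- function() {
  agency_dictionary(data.frame(
    code = c("A1", "A2", "A3"),
    canonical_name = c("Great Xun Ministry", "Yolo Health Commission",
                       "Zeta Aging Bureau"),
    aliases = I(list(c("Xun Ministry", "GXM"),
                     c("YHC"),
                     character(0))),
    prefix = c("Great", "", ""),
    middle = c("Xun", "Yolo Health", "Zeta Aging"),
    tagged = c("Ministry", "Commission", "Bureau"),
    category = c("government-department", "government-department",
                 "public-organization"),
    stringsAsFactors = FALSE))
}

doc <- function(id, issuers, mention_codes = character(0), dict = NULL,
                date = "2020-06-01", text = NULL, aspect_counts = integer(0)) {
  mentions <- NULL
  if (length(mention_codes) > 0L) {
    if (is.null(dict)) stop("dict needed to spell mention surfaces")
    surfaces <- dict$entries$canonical_name[match(mention_codes,
                                                  dict$entries$code)]
    mentions <- data.frame(surface = surfaces, code = mention_codes,
                           stringsAsFactors = FALSE)
  }
  policy_document(id, date, issuers, mentions = mentions, text = text,
                  aspect_counts = aspect_counts)
}

# Star network: one hub connected out to k leaves, multiplicity m.
star_network <- function(k = 5, m = 1) {
  leaves <- paste0("L", seq_len(k))
  collab_network(data.frame(source = "HUB", target = leaves,
                            multiplicity = m, stringsAsFactors = FALSE),
                 nodes = c("HUB", leaves, "ISO"))
}

# Random small directed network over n nodes with edge prob p.
random_network <- function(n, p = 0.4, max_mult = 3) {
  codes <- paste0("N", seq_len(n))
  grid <- expand.grid(source = codes, target = codes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  keep <- stats::runif(nrow(grid)) < p
  edges <- grid[keep, , drop = FALSE]
  edges$multiplicity <- sample.int(max_mult, nrow(edges), replace = TRUE)
  collab_network(edges, nodes = codes)
}

# Independent step-by-step TOPSIS oracle written as explicit loops.
topsis_oracle <- function(m, w) {
  n <- nrow(m); k <- ncol(m)
  Z <- matrix(0, n, k)
  for (j in 1:k) {
    lo <- min(m[, j]); hi <- max(m[, j])
    for (i in 1:n) {
      Z[i, j] <- if (hi > lo) (m[i, j] - lo) / (hi - lo) * w[j] else 0
    }
  }
  zp <- apply(Z, 2, max); zm <- apply(Z, 2, min)
  dp <- dm <- numeric(n)
  for (i in 1:n) {
    dp[i] <- sqrt(sum((Z[i, ] - zp)^2))
    dm[i] <- sqrt(sum((Z[i, ] - zm)^2))
  }
  close <- ifelse(dp + dm == 0, 0.5, dm / (dp + dm))
  list(dis_plus = dp, dis_minus = dm, close = close,
       weight = close / sum(close))
}

# The published coverage/cse reference as a named cse vector.
reference_cse <- function() {
  cv <- hnicn_fixture("coverage")
  stats::setNames(cv$cse, cv$code)
}
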