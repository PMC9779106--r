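# Run code under a private RNG stream, restoring global state afterwards.
with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Specify a synthetic corpus generator
#'
#' The generator emulates the statistical shape of an issuer-led policy
#' corpus over a hub-dominated agency network: a small number of highly
#' active hub agencies issue most documents and are mentioned far more
#' often than the background, producing the two-hub out-degree dominance
#' and long scatter tail the analysis expects. Defaults mirror the study
#' conditions: 22 agencies (3 public organizations), 484 documents, 5 index
#' aspects, 2 planted hubs.
#'
#' @param n_agencies Number of agencies (>= 2); default 22.
#' @param n_docs Number of documents (>= 0); default 484.
#' @param n_aspects Number of index aspects (>= 2); default 5.
#' @param hub_codes Codes of the planted hub agencies; default the first
#'   two government codes.
#' @param hub_activity Per-document issuing probability of a hub; default 0.5.
#' @param base_activity Per-document issuing probability of a non-hub;
#'   default 0.04 (hubs must be strictly more active).
#' @param issuer_activity Optional full named vector of per-agency issuing
#'   probabilities, overriding the two-tier default.
#' @param mention_rate Expected number of agency mentions per document
#'   (>= 1); default 4.
#' @param hub_mention_weight Relative sampling weight of a hub when drawing
#'   mention targets (background weight 1); default 20.
#' @param alias_rate Probability that a mention is written with an alias
#'   rather than the canonical name; default 0.25.
#' @param aspect_skew Optional positive weights (length `n_aspects`) for
#'   assigning mentions to aspects; default uniform.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_agencies = 22, n_docs = 484, n_aspects = 5,
                           hub_codes = NULL, hub_activity = 0.5,
                           base_activity = 0.04, issuer_activity = NULL,
                           mention_rate = 4, hub_mention_weight = 20,
                           alias_rate = 0.25, aspect_skew = NULL,
                           seed = 1L) {
  stopifnot(n_agencies >= 2, n_docs >= 0, n_aspects >= 2, mention_rate >= 1,
            hub_mention_weight > 0, alias_rate >= 0, alias_rate <= 1)
  n_public <- max(0L, min(3L, n_agencies - 19L))
  n_gov <- n_agencies - n_public
  codes <- c(paste0("A", seq_len(n_gov)),
             if (n_public > 0L) paste0("B", seq_len(n_public)))
  if (is.null(hub_codes)) hub_codes <- codes[seq_len(min(2L, n_agencies))]
  if (!all(hub_codes %in% codes)) stop("hub_codes must be among the agency codes")
  if (is.null(issuer_activity)) {
    issuer_activity <- stats::setNames(
      ifelse(codes %in% hub_codes, hub_activity, base_activity), codes)
  } else {
    if (!setequal(names(issuer_activity), codes)) {
      stop("issuer_activity must be named by every agency code")
    }
    issuer_activity <- issuer_activity[codes]
  }
  if (any(issuer_activity < 0) || any(issuer_activity > 1)) {
    stop("issuer activities must be probabilities in [0, 1]")
  }
  hubs <- issuer_activity[hub_codes]
  nonhubs <- issuer_activity[setdiff(codes, hub_codes)]
  if (length(nonhubs) > 0L && length(hubs) > 0L &&
      min(hubs) <= max(nonhubs)) {
    stop("hub issuer activity must be strictly greater than non-hub activity")
  }
  if (!is.null(aspect_skew)) {
    stopifnot(length(aspect_skew) == n_aspects, all(aspect_skew > 0))
  }
  structure(list(n_agencies = as.integer(n_agencies),
                 n_docs = as.integer(n_docs),
                 n_aspects = as.integer(n_aspects),
                 codes = codes, hub_codes = hub_codes,
                 issuer_activity = issuer_activity,
                 mention_rate = mention_rate,
                 hub_mention_weight = hub_mention_weight,
                 alias_rate = alias_rate, aspect_skew = aspect_skew,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

default_aspect_labels <- function(k) {
  base <- c("main_policies", "medical_resources", "natural_resources",
            "economic_support", "personnel_training")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("aspect_", seq_len(k - length(base)) + length(base)))
}

#' Generate a synthetic agency dictionary
#'
#' Builds `n_agencies` agencies with synthetic three-part names
#' (prefix / middle / tagged word), 1-3 aliases each (a short form dropping
#' the prefix, an acronym, and possibly the bare middle word), and unique
#' codes. Middle words are unique across agencies so surface forms never
#' collide. Deterministic given the spec seed.
#'
#' @param spec A [generator_spec()].
#' @return An [agency_dictionary()].
#' @export
generate_dictionary <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_rng(spec$seed, {
    n <- spec$n_agencies
    prefixes <- c("National", "State", "Central", "General", "Provincial")
    gov_tags <- c("Ministry", "Commission", "Administration", "Bureau")
    org_tags <- c("Federation", "Society", "Committee")
    syl <- c("han", "mei", "tai", "lun", "shan", "wei", "jing", "hua",
             "bao", "min", "yong", "qiu", "ren", "fuo", "gua", "xin",
             "ping", "zhong", "lan", "hai", "dei", "zeng", "kuo", "ri")
    middles <- character(0)
    while (length(middles) < n) {
      cand <- paste0(sample(syl, 2L + stats::rbinom(1L, 1L, 0.4),
                            replace = TRUE), collapse = "")
      cand <- paste0(toupper(substr(cand, 1L, 1L)), substr(cand, 2L, nchar(cand)))
      if (!cand %in% middles) middles <- c(middles, cand)
    }
    is_public <- grepl("^B", spec$codes)
    prefix <- sample(prefixes, n, replace = TRUE)
    tagged <- ifelse(is_public,
                     sample(org_tags, n, replace = TRUE),
                     sample(gov_tags, n, replace = TRUE))
    canonical <- paste(prefix, middles, tagged)
    aliases <- vector("list", n)
    for (i in seq_len(n)) {
      acronym <- paste0(toupper(substr(prefix[i], 1L, 1L)),
                        toupper(substr(middles[i], 1L, 2L)),
                        toupper(substr(tagged[i], 1L, 1L)), i)
      cand <- c(paste(middles[i], tagged[i]), acronym, middles[i])
      aliases[[i]] <- cand[seq_len(sample(1:3, 1L))]
    }
    agency_dictionary(data.frame(
      code = spec$codes, canonical_name = canonical,
      aliases = I(aliases), prefix = prefix, middle = middles,
      tagged = tagged,
      category = ifelse(is_public, "public-organization",
                        "government-department"),
      stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic policy corpus with ground truth
#'
#' Each document draws its issuers by per-agency issuing probability (at
#' least one issuer, resampled proportionally to activity if none fires),
#' draws a hub-biased set of mentioned agencies, writes each mention with
#' an alias with probability `alias_rate`, assigns each mention to one index
#' aspect, and composes a plain-text body embedding the surface forms so
#' the recognition stage can re-derive the mention list. The returned
#' ground truth records the exact planted directed multiplicities (under
#' the issuer-to-co-mentioned edge rule), the per-agency per-aspect mention
#' counts, and the hub identities.
#'
#' @param spec A [generator_spec()].
#' @param dict The dictionary from [generate_dictionary()] for the same spec.
#' @return A list with components `corpus` (class `hnicn_corpus`) and
#'   `ground_truth` (class `hnicn_ground_truth`: list with `multiplicity`
#'   data.frame `source,target,multiplicity`, `aspect_counts` matrix,
#'   `hub_codes`, `alias_mentions` count).
#' @export
generate_corpus <- function(spec, dict) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(dict, "agency_dictionary"))
  if (all(spec$issuer_activity == 0)) {
    stop("all issuer activities are zero; no document can be issued")
  }
  codes <- spec$codes
  aspects <- default_aspect_labels(spec$n_aspects)
  skew <- spec$aspect_skew
  if (is.null(skew)) skew <- rep(1, spec$n_aspects)
  mention_w <- ifelse(codes %in% spec$hub_codes, spec$hub_mention_weight, 1)
  window <- default_retrieval_window()
  entries <- dict$entries
  alias_total <- 0L

  docs <- with_rng(spec$seed + 1L, {
    lapply(seq_len(spec$n_docs), function(d) {
      issuers <- codes[stats::runif(length(codes)) < spec$issuer_activity]
      if (length(issuers) == 0L) {
        issuers <- sample(codes, 1L, prob = spec$issuer_activity)
      }
      n_mentions <- 1L + stats::rpois(1L, spec$mention_rate - 1)
      targets <- sample(codes, n_mentions, replace = TRUE, prob = mention_w)
      surfaces <- vapply(targets, function(code) {
        i <- match(code, entries$code)
        al <- entries$aliases[[i]]
        if (length(al) > 0L && stats::runif(1L) < spec$alias_rate) {
          alias_total <<- alias_total + 1L
          sample(al, 1L)
        } else {
          entries$canonical_name[i]
        }
      }, character(1))
      aspect <- sample(aspects, n_mentions, replace = TRUE, prob = skew)
      ac <- table(factor(aspect, levels = aspects))
      date <- window[1] + sample.int(as.integer(window[2] - window[1]) + 1L,
                                     1L) - 1L
      text <- paste0("Joint notice: ", paste(surfaces, collapse = ", "),
                     " shall coordinate on the integration tasks.")
      doc <- policy_document(sprintf("SYN-%05d", d), date, issuers,
                             mentions = data.frame(surface = unname(surfaces),
                                                   code = targets,
                                                   stringsAsFactors = FALSE),
                             text = text, aspect_counts = ac)
      doc$mention_aspects <- aspect
      doc
    })
  })

  pair_keys <- character(0)
  aspect_counts <- matrix(0L, nrow = length(codes), ncol = spec$n_aspects,
                          dimnames = list(codes, aspects))
  for (doc in docs) {
    present <- unique(c(doc$issuers, doc$mentions$code))
    if (length(present) >= 2L) {
      pairs <- expand.grid(source = unique(doc$issuers), target = present,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
      pair_keys <- c(pair_keys,
                     unique(paste(pairs$source, pairs$target, sep = "\r")))
    }
    for (k in seq_along(doc$mention_aspects)) {
      aspect_counts[doc$mentions$code[k], doc$mention_aspects[k]] <-
        aspect_counts[doc$mentions$code[k], doc$mention_aspects[k]] + 1L
    }
  }
  if (length(pair_keys) > 0L) {
    tab <- table(pair_keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    mult <- data.frame(source = vapply(parts, `[`, character(1), 1L),
                       target = vapply(parts, `[`, character(1), 2L),
                       multiplicity = as.integer(tab),
                       stringsAsFactors = FALSE)
    mult <- mult[order(mult$source, mult$target), , drop = FALSE]
    rownames(mult) <- NULL
  } else {
    mult <- data.frame(source = character(0), target = character(0),
                       multiplicity = integer(0), stringsAsFactors = FALSE)
  }
  docs <- lapply(docs, function(doc) { doc$mention_aspects <- NULL; doc })
  class(docs) <- "hnicn_corpus"
  gt <- structure(list(multiplicity = mult, aspect_counts = aspect_counts,
                       hub_codes = spec$hub_codes,
                       alias_mentions = alias_total),
                  class = "hnicn_ground_truth")
  list(corpus = docs, ground_truth = gt)
}

#' Mention matrix from generator ground truth
#'
#' Wraps the planted per-agency per-aspect counts into a normalized
#' mention matrix via [normalize_mentions()].
#'
#' @param spec A [generator_spec()] (carries the normalization scope
#'   implicitly: per-column).
#' @param ground_truth The `hnicn_ground_truth` from [generate_corpus()].
#' @return A `mention_matrix`.
#' @export
generate_mention_matrix <- function(spec, ground_truth) {
  stopifnot(inherits(ground_truth, "hnicn_ground_truth"))
  normalize_mentions(ground_truth$aspect_counts)
}

#' Synthesize a simple directed network realizing given degree sequences
#'
#' Greedy degree-sequence realization (largest remaining out-degree first,
#' matched to the largest remaining in-degrees, no self-loops, no parallel
#' pairs), used to build synthetic stand-in networks whose binary out/in
#' degree sequences equal published values when the underlying edge list is
#' unavailable. All multiplicities are 1. Errors if the sequence pair is
#' not realizable by the greedy procedure.
#'
#' @param out_degree,in_degree Equal-length non-negative integer vectors
#'   with equal sums.
#' @param codes Node codes (defaults to `N1..Nn`).
#' @return A [collab_network()] whose degree sequences match the request.
#' @export
generate_network_from_degrees <- function(out_degree, in_degree,
                                          codes = NULL) {
  stopifnot(length(out_degree) == length(in_degree))
  if (sum(out_degree) != sum(in_degree)) {
    stop("out- and in-degree sums differ; sequences not realizable")
  }
  n <- length(out_degree)
  if (is.null(codes)) codes <- paste0("N", seq_len(n))
  out_rem <- as.integer(out_degree)
  in_rem <- as.integer(in_degree)
  src <- character(0); dst <- character(0)
  repeat {
    i <- which.max(out_rem)
    if (out_rem[i] == 0L) break
    cand <- setdiff(order(-in_rem), i)
    cand <- cand[in_rem[cand] > 0L]
    already <- dst[src == codes[i]]
    cand <- cand[!codes[cand] %in% already]
    if (length(cand) < out_rem[i]) {
      stop("degree sequences not realizable by greedy construction")
    }
    take <- cand[seq_len(out_rem[i])]
    src <- c(src, rep(codes[i], length(take)))
    dst <- c(dst, codes[take])
    in_rem[take] <- in_rem[take] - 1L
    out_rem[i] <- 0L
  }
  net <- collab_network(
    data.frame(source = src, target = dst, multiplicity = 1L,
               stringsAsFactors = FALSE), nodes = codes)
  deg <- degree_centrality(net)
  if (!all(deg$out_degree == out_degree) || !all(deg$in_degree == in_degree)) {
    stop("greedy construction failed to realize the degree sequences")
  }
  net
}
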