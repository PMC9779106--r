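#' Construct a directed collaboration network
#'
#' The co-mention network: nodes are agency codes; a directed pair (i, j)
#' carries multiplicity m(i, j) = number of documents creating an i -> j
#' connection. The binary view `connection(i, j) = 1` iff `m(i, j) >= 1`
#' underlies degree centrality; multiplicities feed subgroup link counts.
#'
#' @param edges A data.frame with columns `source`, `target`, `multiplicity`
#'   (positive integers); no self-loops; one row per ordered pair.
#' @param nodes Character vector of agency codes; must cover every edge
#'   endpoint. Isolated nodes are legal and kept.
#' @return An object of class `collab_network`: list with `nodes` and `edges`.
#' @export
collab_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        multiplicity = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "multiplicity") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$multiplicity <- as.integer(edges$multiplicity)
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (any(edges$multiplicity < 1L)) stop("edge multiplicities must be >= 1")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate ordered pair in edge list")
  endpoints <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) nodes <- sort(endpoints)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node codes")
  missing_nodes <- setdiff(endpoints, nodes)
  if (length(missing_nodes) > 0L) {
    stop("edge endpoint(s) not in node set: ",
         paste(missing_nodes, collapse = ", "))
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat(sprintf("<collab_network> %d nodes, %d directed pairs, total multiplicity %d\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$multiplicity)))
  invisible(x)
}

#' Build the co-mention network from a corpus
#'
#' For each document, one unit of multiplicity is added from every issuer to
#' every other agency appearing in the document — mentioned agencies and
#' fellow co-issuers alike. Within a single document each ordered pair is
#' counted at most once; self-loops are excluded. Documents carrying only raw
#' text are resolved through [recognize_entities()] first.
#'
#' @param corpus A list of [policy_document()] records.
#' @param dict An [agency_dictionary()]; its codes become the node set, so
#'   agencies never observed in the corpus appear as isolated nodes.
#' @return A [collab_network()].
#' @export
build_network <- function(corpus, dict) {
  stopifnot(inherits(dict, "agency_dictionary"))
  corpus <- resolve_mentions(corpus, dict)
  codes <- agency_codes(dict)
  pair_keys <- character(0)
  for (doc in corpus) {
    bad <- setdiff(doc$mentions$code, codes)
    if (length(bad) > 0L) {
      stop(sprintf("nis: document '%s' has unresolvable mention code(s): %s",
                   doc$doc_id, paste(bad, collapse = ", ")))
    }
    bad <- setdiff(doc$issuers, codes)
    if (length(bad) > 0L) {
      stop(sprintf("nis: document '%s' has unknown issuer code(s): %s",
                   doc$doc_id, paste(bad, collapse = ", ")))
    }
    present <- unique(c(doc$issuers, doc$mentions$code))
    issuers <- unique(doc$issuers)
    if (length(present) < 2L) next
    pairs <- expand.grid(source = issuers, target = present,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    pair_keys <- c(pair_keys,
                   unique(paste(pairs$source, pairs$target, sep = "\r")))
  }
  if (length(pair_keys) == 0L) {
    return(collab_network(data.frame(), nodes = codes))
  }
  tab <- table(pair_keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(source = vapply(parts, `[`, character(1), 1L),
                      target = vapply(parts, `[`, character(1), 2L),
                      multiplicity = as.integer(tab),
                      stringsAsFactors = FALSE)
  collab_network(edges, nodes = codes)
}

#' Classify a degree into a connection type
#'
#' Four-way classification by degree centrality: `full` (degree >= 20),
#' `wide-range` (10 <= degree < 20), `small-range` (5 <= degree < 10),
#' `scatter` (degree < 5). Boundaries are half-open; the defaults are the
#' thresholds under which every published degree table row is consistent.
#'
#' @param degree Non-negative integer vector.
#' @param thresholds Named numeric vector `c(full=, wide=, small=)`,
#'   strictly decreasing.
#' @return Character vector of classes, same length as `degree`.
#' @export
classify_connection_type <- function(degree,
                                     thresholds = c(full = 20, wide = 10,
                                                    small = 5)) {
  stopifnot(all(c("full", "wide", "small") %in% names(thresholds)))
  if (!(thresholds["full"] > thresholds["wide"] &&
        thresholds["wide"] > thresholds["small"])) {
    stop("class thresholds must be strictly decreasing")
  }
  if (any(degree < 0)) stop("degree must be non-negative")
  th <- unname(thresholds[c("full", "wide", "small")])
  unname(ifelse(degree >= th[1], "full",
                ifelse(degree >= th[2], "wide-range",
                       ifelse(degree >= th[3], "small-range", "scatter"))))
}

#' Degree centrality and connection-type report
#'
#' Degree centrality counts distinct counterpart nodes on the binary
#' connection view (multiplicity is ignored): `out_degree(i)` is the number
#' of distinct j with connection(i, j) = 1 and `in_degree(j)` the number of
#' distinct i. Each direction is classified by
#' [classify_connection_type()]. An undirected degree (distinct partners in
#' either direction) is included as a derived convenience.
#'
#' @param net A [collab_network()].
#' @param thresholds Passed to [classify_connection_type()].
#' @return A data.frame with columns `code`, `out_degree`, `in_degree`,
#'   `degree` (undirected), `out_class`, `in_class`; one row per node, in
#'   node-set order.
#' @export
degree_centrality <- function(net,
                              thresholds = c(full = 20, wide = 10,
                                             small = 5)) {
  stopifnot(inherits(net, "collab_network"))
  nodes <- net$nodes
  out_deg <- stats::setNames(integer(length(nodes)), nodes)
  in_deg <- out_deg
  und <- out_deg
  if (nrow(net$edges) > 0L) {
    ot <- table(factor(net$edges$source, levels = nodes))
    it <- table(factor(net$edges$target, levels = nodes))
    out_deg[] <- as.integer(ot)
    in_deg[] <- as.integer(it)
    a <- pmin(net$edges$source, net$edges$target)
    b <- pmax(net$edges$source, net$edges$target)
    uk <- unique(paste(a, b, sep = "\r"))
    up <- strsplit(uk, "\r", fixed = TRUE)
    ut <- table(factor(unlist(up), levels = nodes))
    und[] <- as.integer(ut)
  }
  data.frame(code = nodes,
             out_degree = unname(out_deg),
             in_degree = unname(in_deg),
             degree = unname(und),
             out_class = classify_connection_type(unname(out_deg), thresholds),
             in_class = classify_connection_type(unname(in_deg), thresholds),
             stringsAsFactors = FALSE)
}

#' Convert a collaboration network to an igraph object
#'
#' @param net A [collab_network()].
#' @param dict Optional [agency_dictionary()] supplying `name` and
#'   `category` vertex attributes.
#' @param thresholds Passed to [degree_centrality()] for the `class`
#'   vertex attribute.
#' @return An igraph directed graph with edge attribute `multiplicity`
#'   (also copied to `weight`) and vertex attributes `code`, `agency_name`,
#'   `category`, `out_degree`, `in_degree`, `class`.
#' @export
as_igraph <- function(net, dict = NULL,
                      thresholds = c(full = 20, wide = 10, small = 5)) {
  stopifnot(inherits(net, "collab_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  deg <- degree_centrality(net, thresholds)
  idx <- match(igraph::V(g)$name, deg$code)
  igraph::V(g)$code <- deg$code[idx]
  igraph::V(g)$out_degree <- deg$out_degree[idx]
  igraph::V(g)$in_degree <- deg$in_degree[idx]
  igraph::V(g)$class <- deg$out_class[idx]
  if (!is.null(dict)) {
    j <- match(igraph::V(g)$name, dict$entries$code)
    igraph::V(g)$agency_name <- dict$entries$canonical_name[j]
    igraph::V(g)$category <- dict$entries$category[j]
  } else {
    igraph::V(g)$agency_name <- igraph::V(g)$name
    igraph::V(g)$category <- NA_character_
  }
  if (nrow(net$edges) > 0L) {
    igraph::E(g)$weight <- igraph::E(g)$multiplicity
  }
  g
}

write_gexf <- function(net, path, dict = NULL,
                       thresholds = c(full = 20, wide = 10, small = 5)) {
  deg <- degree_centrality(net, thresholds)
  if (!is.null(dict)) {
    j <- match(deg$code, dict$entries$code)
    labels <- dict$entries$canonical_name[j]
    categories <- dict$entries$category[j]
  } else {
    labels <- deg$code
    categories <- rep(NA_character_, nrow(deg))
  }
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  attr_defs <- list(c("0", "category", "string"),
                    c("1", "out_degree", "integer"),
                    c("2", "in_degree", "integer"),
                    c("3", "class", "string"))
  for (a in attr_defs) {
    xml2::xml_add_child(attrs, "attribute", id = a[1], title = a[2],
                        type = a[3])
  }
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(deg))) {
    node <- xml2::xml_add_child(nodes_el, "node", id = deg$code[i],
                                label = labels[i])
    av <- xml2::xml_add_child(node, "attvalues")
    vals <- c(ifelse(is.na(categories[i]), "", categories[i]),
              as.character(deg$out_degree[i]),
              as.character(deg$in_degree[i]),
              deg$out_class[i])
    for (k in seq_along(vals)) {
      xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1L),
                          value = vals[k])
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net$edges))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1L),
                        source = net$edges$source[i],
                        target = net$edges$target[i],
                        weight = as.character(net$edges$multiplicity[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a collaboration network
#'
#' Serializes the network for external graph tools (e.g. Gephi): a plain
#' edge-list CSV (`source, target, multiplicity`), GEXF 1.2, or GraphML.
#' Graph exports carry node attributes (code, name, category, out/in degree,
#' out-degree connection class) and edge multiplicities as weights.
#'
#' @param net A non-empty [collab_network()].
#' @param format One of `"edge-list-csv"`, `"gexf"`, `"graphml"`.
#' @param path Output file path.
#' @param dict Optional [agency_dictionary()] for node names and categories.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format, path, dict = NULL) {
  stopifnot(inherits(net, "collab_network"))
  if (nrow(net$edges) == 0L) stop("cannot export a network with no edges")
  formats <- c("edge-list-csv", "gexf", "graphml")
  if (!format %in% formats) {
    stop("unknown format '", format, "'; choose one of: ",
         paste(formats, collapse = ", "))
  }
  switch(format,
    "edge-list-csv" = utils::write.csv(net$edges, path, row.names = FALSE,
                                       quote = FALSE),
    "gexf" = write_gexf(net, path, dict),
    "graphml" = igraph::write_graph(as_igraph(net, dict), path,
                                    format = "graphml")
  )
  invisible(path)
}

#' Read a collaboration network from an edge-list CSV
#'
#' @param path CSV with columns `source`, `target`, `multiplicity`.
#' @param nodes Optional full node set (codes); defaults to edge endpoints.
#' @return A [collab_network()].
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  collab_network(df, nodes = nodes)
}
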