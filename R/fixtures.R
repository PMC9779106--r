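#' Bundled reference tables of the 22-agency collaboration network
#'
#' The package ships the published summary tables of a healthcare-nursing
#' information collaboration network of 19 Chinese government departments
#' (codes A1-A19) and 3 public organizations (B1-B3), built from 484 policy
#' documents issued between 23 October 2019 and 1 February 2022. The raw
#' corpus is not redistributable, so these intermediate tables are the
#' fixture inputs from which the downstream stages can be recomputed:
#'
#' * `"agencies"` - the agency roster as a dictionary TSV (code, canonical
#'   name, aliases, name decomposition, category).
#' * `"degree_centrality"` - out- and in-degree centrality per node.
#' * `"index_weights"` - entropy, utility and weight of the five index
#'   aspects.
#' * `"node_weights"` - TOPSIS distances, closeness and node weight per
#'   node.
#' * `"coverage"` - collaboration coverage and structure entropy per node.
#'   (The published rank-22 row label disagrees with the roster, which has
#'   B3 as the Red Cross Society; the roster is followed here.)
#' * `"top_effects"` - the top-10 collaboration-effect pairs.
#'
#' @param name Which table to load (see above).
#' @param path Return the file path instead of parsed data.
#' @return A data.frame (an [agency_dictionary()] for `"agencies"`), or a
#'   file path when `path = TRUE`.
#' @export
hnicn_fixture <- function(name = c("agencies", "degree_centrality",
                                   "index_weights", "node_weights",
                                   "coverage", "top_effects"),
                          path = FALSE) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0("hnicn_", name, ".tsv"),
                      package = "hnicn", mustWork = TRUE)
  if (path) return(file)
  if (name == "agencies") return(read_agency_dictionary(file))
  utils::read.delim(file, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
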