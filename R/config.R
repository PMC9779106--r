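#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis: the coverage scaling
#' parameter `adj_par` (default 10), the effect damping parameter `psi`
#' (default 10,000), the collaboration-structure-entropy log base (default
#' 2), the degree-classification thresholds (full/wide/small = 20/10/5),
#' the document retrieval window, the mention-matrix normalization scope,
#' the number of reported top pairs, and the random seed.
#'
#' @param adj_par Positive coverage scaling parameter; default 10.
#' @param psi Positive effect damping parameter; default 10,000.
#' @param cse_log_base Logarithm base for the structure entropy (> 1);
#'   default 2.
#' @param class_thresholds Named numeric `c(full=, wide=, small=)`,
#'   strictly decreasing; default `c(20, 10, 5)`.
#' @param window_start,window_end Retrieval window dates (inclusive).
#' @param normalization_scope `"column"` or `"global"` min-max scope for
#'   the mention matrix.
#' @param top_n Number of top pairs in reports; default 10.
#' @param seed Integer random seed recorded in run manifests.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(adj_par = 10, psi = 10000, cse_log_base = 2,
                            class_thresholds = c(full = 20, wide = 10,
                                                 small = 5),
                            window_start = "2019-10-23",
                            window_end = "2022-02-01",
                            normalization_scope = "column",
                            top_n = 10, seed = 1L) {
  if (adj_par <= 0) stop("adj_par must be positive")
  if (psi <= 0) stop("psi must be positive")
  if (cse_log_base <= 1) stop("cse_log_base must be > 1")
  stopifnot(all(c("full", "wide", "small") %in% names(class_thresholds)))
  if (!(class_thresholds["full"] > class_thresholds["wide"] &&
        class_thresholds["wide"] > class_thresholds["small"])) {
    stop("class thresholds must be strictly decreasing")
  }
  normalization_scope <- match.arg(normalization_scope,
                                   c("column", "global"))
  structure(list(adj_par = adj_par, psi = psi,
                 cse_log_base = cse_log_base,
                 class_thresholds = class_thresholds,
                 window = c(as.Date(window_start), as.Date(window_end)),
                 normalization_scope = normalization_scope,
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] fields may appear in the file
#' (`class_thresholds` as a mapping `full/wide/small`); omitted fields take
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("adj_par", "psi", "cse_log_base", "window_start",
              "window_end", "normalization_scope", "top_n", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$class_thresholds)) {
    args$class_thresholds <- unlist(y$class_thresholds)
  }
  do.call(pipeline_config, args)
}
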