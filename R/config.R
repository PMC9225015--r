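#' Analysis configuration
#'
#' Bundles every tunable threshold used across the four evidence streams.
#' Defaults follow the published settings for dependency analysis on the
#' DepMap CRISPR panel and CCLE proteomics: a dependency score below -0.5
#' marks a dependent line, the top seven co-dependent genes are carried
#' forward, a perturbation-similarity tau above 90 is significant, and
#' co-expression requires BH-adjusted p < 0.01 with |z| > 2 over at least
#' 100 jointly detected lines.
#'
#' @param dependency_threshold Dependency-score cutoff; a cell line with a
#'   score strictly below it counts as dependent. Default -0.5.
#' @param top_k Number of top co-dependent genes carried into enrichment and
#'   evidence integration. Default 7.
#' @param top_k_mode Ranking of co-dependents: `"absolute"` (descending |r|,
#'   the default, so strong negative correlations also rank) or `"positive"`
#'   (descending signed r).
#' @param tau_threshold Perturbation-similarity flag cutoff, strict
#'   inequality. Default 90.
#' @param coexpr_fdr BH-adjusted p cutoff for co-expression significance.
#'   Default 0.01.
#' @param coexpr_z Absolute z-score cutoff for co-expression significance.
#'   Default 2.
#' @param min_shared_lines Minimum jointly detected cell lines for a
#'   co-expression pair to enter testing. Default 100.
#' @param min_dependent_lines Minimum dependent lines for a query gene to be
#'   profiled for co-dependency. Default 3.
#' @param lineage_p Raw two-sided p cutoff for a lineage contrast flag.
#'   Default 0.05.
#' @param lineage_fdr BH q cutoff for a lineage contrast flag. Default 0.1.
#' @param min_lineage_size Minimum non-missing in-group size for a lineage
#'   contrast. Default 5.
#' @param min_codep_overlap Minimum shared non-missing lines for a
#'   dependency correlation. Default 10.
#' @param seed Integer seed for any randomized step.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config(top_k = 5)
#' cfg$dependency_threshold
analysis_config <- function(dependency_threshold = -0.5,
                            top_k = 7L,
                            top_k_mode = c("absolute", "positive"),
                            tau_threshold = 90,
                            coexpr_fdr = 0.01,
                            coexpr_z = 2,
                            min_shared_lines = 100L,
                            min_dependent_lines = 3L,
                            lineage_p = 0.05,
                            lineage_fdr = 0.1,
                            min_lineage_size = 5L,
                            min_codep_overlap = 10L,
                            seed = 1L) {
  top_k_mode <- match.arg(top_k_mode)
  cfg <- list(
    dependency_threshold = as.numeric(dependency_threshold),
    top_k = as.integer(top_k),
    top_k_mode = top_k_mode,
    tau_threshold = as.numeric(tau_threshold),
    coexpr_fdr = as.numeric(coexpr_fdr),
    coexpr_z = as.numeric(coexpr_z),
    min_shared_lines = as.integer(min_shared_lines),
    min_dependent_lines = as.integer(min_dependent_lines),
    lineage_p = as.numeric(lineage_p),
    lineage_fdr = as.numeric(lineage_fdr),
    min_lineage_size = as.integer(min_lineage_size),
    min_codep_overlap = as.integer(min_codep_overlap),
    seed = as.integer(seed)
  )
  num <- c("dependency_threshold", "tau_threshold", "coexpr_fdr", "coexpr_z",
           "lineage_p", "lineage_fdr")
  for (f in num) {
    if (!is.finite(cfg[[f]])) stop("config field '", f, "' must be finite")
  }
  if (cfg$top_k < 1L) stop("top_k must be >= 1")
  if (cfg$min_shared_lines < 3L) stop("min_shared_lines must be >= 3")
  if (cfg$min_codep_overlap < 3L) stop("min_codep_overlap must be >= 3")
  if (cfg$min_lineage_size < 2L) stop("min_lineage_size must be >= 2")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields absent from the file keep their [analysis_config()] defaults;
#' unknown fields are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top level is a
#'   mapping of config field names to values.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension '", ext, "' (use yaml or json)")
  )
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (f in names(x)) cat(sprintf("  %-21s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Return cfg if given, else defaults; accepts a plain list for convenience.
as_config <- function(config) {
  if (is.null(config)) return(analysis_config())
  if (inherits(config, "analysis_config")) return(config)
  if (is.list(config)) return(do.call(analysis_config, config))
  stop("config must be an analysis_config, a list, or NULL")
}
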