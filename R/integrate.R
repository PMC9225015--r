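#' Integrate the four evidence streams into per-pair evidence counts
#'
#' Combines top-k co-dependency, perturbation-similarity flags, significant
#' co-expression and compiled interactions into one row per (query,
#' partner) pair flagged in at least one stream. `evidence_count` is the
#' number of streams flagging the pair (0-4). With `exhaustive = TRUE`
#' every (query, panel gene) pair is emitted, pairs flagged nowhere scoring
#' 0.
#'
#' A partner can be similarity-flagged only if it has a tau row for that
#' query; the auxiliary `sim_status` column distinguishes `"similar"`,
#' `"not_similar"` (tested, below threshold) and `"not_tested"`.
#'
#' @param codep Data frame with columns `query`, `partner`, `r`: the top-k
#'   co-dependent partners per query.
#' @param similarity Data frame with columns `query`, `partner`: tau-flagged
#'   pairs (see [similarity_flags()]).
#' @param coexpression Data frame with columns `query`, `partner`:
#'   significant co-expression pairs (see [coexpression_scan()]).
#' @param interactions A compiled [interaction_set()].
#' @param similarity_tested Optional data frame `query`, `partner` of all
#'   pairs present in the tau table, used for `sim_status`.
#' @param queries Optional character vector fixing the query set; defaults
#'   to every query appearing in any stream.
#' @param exhaustive If TRUE, emit all (query, `panel_genes`) pairs.
#' @param panel_genes Gene universe for `exhaustive` mode and for the
#'   namespace check; partners outside it are kept with `in_panel = FALSE`
#'   and a warning.
#' @return Data frame of class `evidence_table` with columns `query`,
#'   `partner`, `codependency`, `similarity`, `coexpression`,
#'   `interaction`, `evidence_count`, `codep_r`, `sim_status` (and
#'   `in_panel` when `panel_genes` is given), ordered by query, then
#'   descending evidence count, then partner.
#' @export
evidence_table <- function(codep, similarity, coexpression, interactions,
                           similarity_tested = NULL, queries = NULL,
                           exhaustive = FALSE, panel_genes = NULL) {
  stopifnot(inherits(interactions, "interaction_set"))
  norm_pairs <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(query = character(), partner = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(query = canonicalize_symbols(df$query),
               partner = canonicalize_symbols(df$partner),
               stringsAsFactors = FALSE)
  }
  cd <- norm_pairs(codep)
  cd$r <- if (!is.null(codep) && nrow(codep)) codep$r else numeric(0)
  sm <- norm_pairs(similarity)
  cx <- norm_pairs(coexpression)
  st <- norm_pairs(similarity_tested)

  if (is.null(queries)) {
    queries <- sort(unique(c(cd$query, sm$query, cx$query)))
  } else {
    queries <- canonicalize_symbols(queries)
  }
  pkey <- function(df) paste(df$query, df$partner, sep = "\r")
  flagged <- rbind(cd[c("query", "partner")], sm, cx)
  flagged <- flagged[flagged$query %in% queries, , drop = FALSE]
  flagged <- flagged[!duplicated(pkey(flagged)), , drop = FALSE]
  if (exhaustive) {
    if (is.null(panel_genes)) {
      stop("exhaustive mode requires panel_genes")
    }
    panel_genes <- canonicalize_symbols(panel_genes)
    all_pairs <- do.call(rbind, lapply(queries, function(q) {
      data.frame(query = q, partner = setdiff(panel_genes, q),
                 stringsAsFactors = FALSE)
    }))
    extra <- flagged[!pkey(flagged) %in% pkey(all_pairs), , drop = FALSE]
    pairs <- rbind(all_pairs, extra)
  } else {
    pairs <- flagged
  }
  if (!nrow(pairs)) {
    out <- data.frame(query = character(), partner = character(),
                      codependency = logical(), similarity = logical(),
                      coexpression = logical(), interaction = logical(),
                      evidence_count = integer(), codep_r = numeric(),
                      sim_status = character(), stringsAsFactors = FALSE)
    class(out) <- c("evidence_table", "data.frame")
    return(out)
  }

  key <- pkey(pairs)
  cd_key <- pkey(cd); sm_key <- pkey(sm); cx_key <- pkey(cx)
  iset_key <- edge_key(pmin(pairs$query, pairs$partner),
                       pmax(pairs$query, pairs$partner))
  edge_keys <- edge_key(interactions$edges$gene_a, interactions$edges$gene_b)

  out <- data.frame(
    query = pairs$query, partner = pairs$partner,
    codependency = key %in% cd_key,
    similarity = key %in% sm_key,
    coexpression = key %in% cx_key,
    interaction = iset_key %in% edge_keys,
    stringsAsFactors = FALSE
  )
  out$evidence_count <- as.integer(out$codependency + out$similarity +
                                     out$coexpression + out$interaction)
  out$codep_r <- cd$r[match(key, cd_key)]
  tested <- if (nrow(st)) key %in% pkey(st) else rep(FALSE, nrow(out))
  out$sim_status <- ifelse(out$similarity, "similar",
                           ifelse(tested | out$similarity, "not_similar",
                                  "not_tested"))
  if (!is.null(panel_genes)) {
    panel_genes <- canonicalize_symbols(panel_genes)
    out$in_panel <- out$partner %in% panel_genes
    if (any(!out$in_panel)) {
      warning(sum(!out$in_panel), " flagged partner(s) absent from the ",
              "panel gene namespace; retained with in_panel = FALSE")
    }
  }
  out <- out[order(out$query, -out$evidence_count, out$partner), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Extract the DUB-ubiquitin-transferase network
#'
#' Subsets the evidence table to pairs anchored on co-dependency whose
#' partner belongs to the ubiquitin-like transferase gene set (E3 ligases
#' and E2 conjugating enzymes). Each retained edge carries the other three
#' stream flags, matching the edge classes of the published network figure.
#'
#' @param evidence An [evidence_table()].
#' @param transferase_set Character vector of transferase gene symbols (or
#'   a `gene_set_collection` set's `members`).
#' @return Data frame with columns `dub`, `partner`, `codep_r`,
#'   `interaction`, `coexpression`, `similarity`, `evidence_count`.
#' @export
ligase_network <- function(evidence, transferase_set) {
  if (!length(transferase_set)) stop("transferase set is empty")
  transferase_set <- canonicalize_symbols(transferase_set)
  keep <- evidence$codependency & evidence$partner %in% transferase_set
  sub <- evidence[keep, , drop = FALSE]
  out <- data.frame(
    dub = sub$query, partner = sub$partner, codep_r = sub$codep_r,
    interaction = sub$interaction, coexpression = sub$coexpression,
    similarity = sub$similarity, evidence_count = sub$evidence_count,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-gene summary record across all streams
#'
#' The tabular equivalent of the concentric-ring display: essentiality
#' fraction and category, the top enriched gene-set term of the top-k
#' co-dependents (explicit `"none"` marker when no term reaches the q
#' cutoff or the gene was not analyzed), the top-k co-dependents with
#' their correlations, and evidence-pair counts.
#'
#' @param gene Query gene symbol.
#' @param essentiality Output of [summarize_essentiality()] covering the
#'   gene.
#' @param codep_topk Data frame `query`, `partner`, `r` of top-k
#'   co-dependents (may lack the gene if it had too few dependent lines).
#' @param ora_results Named list (by query gene) of [ora()] results, or
#'   NULL entries for unanalyzed genes.
#' @param evidence An [evidence_table()].
#' @param config An [analysis_config()], or NULL.
#' @param go_q_cutoff q cutoff for reporting a top term. Default 0.05.
#' @return One-row data frame with columns `gene`, `fraction`,
#'   `n_dependent`, `category`, `codep_status`, `top_codep`, `top_go_id`,
#'   `top_go_name`, `top_go_q`, `n_evidence_partners`, `max_evidence`.
#' @export
dub_summary <- function(gene, essentiality, codep_topk, ora_results,
                        evidence, config = NULL, go_q_cutoff = 0.05) {
  gene <- canonicalize_symbols(gene)
  ess <- essentiality[essentiality$gene == gene, , drop = FALSE]
  if (!nrow(ess)) stop("gene missing from the dependency stream: ", gene)
  tk <- codep_topk[codep_topk$query == gene, , drop = FALSE]
  analyzed <- nrow(tk) > 0L
  top_codep <- if (analyzed) {
    paste(sprintf("%s(%.3f)", tk$partner, tk$r), collapse = ";")
  } else {
    ""
  }
  enr <- ora_results[[gene]]
  if (analyzed && !is.null(enr) && nrow(enr) && enr$q[1L] < go_q_cutoff) {
    top_go_id <- enr$set_id[1L]
    top_go_name <- enr$name[1L]
    top_go_q <- enr$q[1L]
  } else {
    top_go_id <- "none"; top_go_name <- "none"; top_go_q <- NA_real_
  }
  ev <- evidence[evidence$query == gene, , drop = FALSE]
  data.frame(
    gene = gene, fraction = ess$fraction, n_dependent = ess$n_dependent,
    category = ess$category,
    codep_status = if (analyzed) "analyzed"
                   else "not analyzed for co-dependency",
    top_codep = top_codep, top_go_id = top_go_id,
    top_go_name = top_go_name, top_go_q = top_go_q,
    n_evidence_partners = nrow(ev),
    max_evidence = if (nrow(ev)) max(ev$evidence_count) else 0L,
    stringsAsFactors = FALSE
  )
}

#' Run the full evidence-integration pipeline from files
#'
#' Reads the five inputs, runs every stream for the query genes, integrates
#' them into the evidence table, extracts the transferase network, scans
#' lineages, and writes `evidence.tsv`, `dub_summary.tsv`,
#' `ligase_network.tsv`, `lineage_scan.tsv` and `manifest.json` under
#' `out_dir`. Deterministic given identical inputs and config: rerunning
#' produces byte-identical outputs.
#'
#' Queries with fewer than `min_dependent_lines` dependent lines are
#' summarized but not profiled for co-dependency; queries absent from the
#' abundance panel (or without enough jointly detected partners) skip the
#' co-expression stream. The enrichment universe is the dependency panel's
#' gene set, echoed in the manifest.
#'
#' @param paths Named list of input paths: `dependency`, `sample_info`,
#'   `abundance`, `gmt`, `ppi` (character vector of edge-list paths),
#'   `tau`.
#' @param queries Character vector of query (DUB) gene symbols.
#' @param config An [analysis_config()], or NULL for defaults.
#' @param out_dir Output directory (created if needed).
#' @param transferase_set Set id in the GMT whose members define the
#'   ubiquitin-transferase partners of the network output.
#' @return Invisibly, a list with `evidence`, `summary`, `network`,
#'   `lineage`, `essentiality` and `manifest`.
#' @export
run_pipeline <- function(paths, queries, config = NULL, out_dir,
                         transferase_set = "UBIQUITIN_LIKE_PROTEIN_TRANSFERASE_ACTIVITY") {
  cfg <- as_config(config)
  need <- c("dependency", "sample_info", "abundance", "gmt", "ppi", "tau")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  queries <- canonicalize_symbols(queries)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dep <- stage("read_dependency", suppressMessages(
    read_dependency_matrix(paths$dependency, paths$sample_info)))
  ab <- stage("read_abundance", read_abundance_matrix(paths$abundance))
  gmt <- stage("read_gmt", read_gmt(paths$gmt))
  isets <- stage("read_ppi", lapply(paths$ppi, function(p) {
    read_edge_list(p, source_label = sub("\\.tsv$", "", basename(p)))
  }))
  compiled <- stage("compile_interactions", compile_interactions(isets))
  tau <- stage("read_tau", read_similarity_table(paths$tau))

  absent <- setdiff(queries, colnames(dep$scores))
  if (length(absent)) {
    stop("query gene(s) absent from the dependency panel: ",
         paste(absent, collapse = ", "))
  }
  message("enrichment universe: dependency panel genes (",
          ncol(dep$scores), ")")
  collection <- gene_set_collection(gmt$sets, universe = colnames(dep$scores))

  essentiality <- stage("essentiality",
                        summarize_essentiality(dep, queries, cfg))

  analyzed <- essentiality$gene[essentiality$n_dependent >=
                                  cfg$min_dependent_lines]
  codep_rows <- list(); ora_results <- list()
  for (g in analyzed) {
    prof <- stage(paste0("codependency:", g),
                  suppressMessages(codependency_profile(dep, g, cfg)))
    tk <- top_codependents(prof, cfg$top_k)
    codep_rows[[g]] <- data.frame(query = g, partner = tk$gene, r = tk$r,
                                  n = tk$n, stringsAsFactors = FALSE)
    ora_results[[g]] <- stage(paste0("ora:", g),
                              suppressWarnings(ora(tk$gene, collection)))
  }
  codep_topk <- if (length(codep_rows)) do.call(rbind, codep_rows) else {
    data.frame(query = character(), partner = character(), r = numeric(),
               n = integer(), stringsAsFactors = FALSE)
  }
  rownames(codep_topk) <- NULL

  coexpr_rows <- list(); coexpr_skipped <- character()
  for (g in queries) {
    res <- tryCatch(suppressMessages(coexpression_scan(ab, g, cfg)),
                    error = function(e) NULL)
    if (is.null(res)) {
      coexpr_skipped <- c(coexpr_skipped, g)
    } else {
      sig <- res[res$significant, , drop = FALSE]
      if (nrow(sig)) {
        coexpr_rows[[g]] <- data.frame(query = g, partner = sig$partner,
                                       stringsAsFactors = FALSE)
      }
    }
  }
  coexpr_pairs <- if (length(coexpr_rows)) do.call(rbind, coexpr_rows) else NULL

  sim_rows <- list(); sim_tested_rows <- list()
  for (g in queries) {
    hits <- similarity_flags(tau, g, cfg)
    if (length(hits)) {
      sim_rows[[g]] <- data.frame(query = g, partner = hits,
                                  stringsAsFactors = FALSE)
    }
    tested <- similarity_tested(tau, g)
    if (length(tested)) {
      sim_tested_rows[[g]] <- data.frame(query = g, partner = tested,
                                         stringsAsFactors = FALSE)
    }
  }
  sim_pairs <- if (length(sim_rows)) do.call(rbind, sim_rows) else NULL
  sim_tested <- if (length(sim_tested_rows)) do.call(rbind, sim_tested_rows)
                else NULL

  evidence <- stage("evidence_table", evidence_table(
    codep = codep_topk[c("query", "partner", "r")],
    similarity = sim_pairs, coexpression = coexpr_pairs,
    interactions = compiled, similarity_tested = sim_tested,
    queries = queries, panel_genes = colnames(dep$scores)
  ))

  if (!transferase_set %in% names(gmt$sets)) {
    stop("transferase set '", transferase_set, "' not found in the GMT")
  }
  network <- stage("ligase_network",
                   ligase_network(evidence,
                                  gmt$sets[[transferase_set]]$members))

  lineage <- stage("lineage_scan", scan_lineages(dep, queries, cfg))

  summaries <- do.call(rbind, lapply(queries, function(g) {
    dub_summary(g, essentiality, codep_topk, ora_results, evidence, cfg)
  }))
  rownames(summaries) <- NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_result_tsv(evidence, p("evidence.tsv"))
  write_result_tsv(summaries, p("dub_summary.tsv"))
  write_result_tsv(network, p("ligase_network.tsv"))
  write_result_tsv(lineage, p("lineage_scan.tsv"))

  manifest <- list(
    config = unclass(cfg),
    inputs = lapply(paths, basename),
    queries = queries,
    enrichment_universe = "dependency_panel_genes",
    enrichment_universe_size = ncol(dep$scores),
    n_evidence_pairs = nrow(evidence),
    n_network_edges = nrow(network),
    n_lineage_tests = nrow(lineage),
    coexpression_skipped = coexpr_skipped,
    output_md5 = as.list(tools::md5sum(c(p("evidence.tsv"),
                                         p("dub_summary.tsv"),
                                         p("ligase_network.tsv"),
                                         p("lineage_scan.tsv"))) |>
                           stats::setNames(c("evidence.tsv",
                                             "dub_summary.tsv",
                                             "ligase_network.tsv",
                                             "lineage_scan.tsv")))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, na = "null", digits = NA)

  invisible(list(evidence = evidence, summary = summaries,
                 network = network, lineage = lineage,
                 essentiality = essentiality, manifest = manifest))
}
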