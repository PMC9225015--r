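#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics generator. The generator plants
#' gene complexes whose members share a latent per-cell-line factor in both
#' the dependency and abundance panels (driving co-dependency and
#' co-expression), lineage-specific essentiality shifts, true
#' protein-protein interaction edges concentrated within complexes, and a
#' tau table in which same-complex pairs score near `tau_within`.
#'
#' @param n_genes Number of genes. Default 120.
#' @param n_lines Number of cell lines. Default 300 (so that with 30%
#'   missing abundance the joint-detection rule at 100 shared lines is
#'   comfortably but not trivially satisfied).
#' @param n_lineages Number of lineage labels, assigned to lines as a
#'   random permutation of a balanced allocation. Default 6.
#' @param complexes Integer vector of planted complex sizes; members are
#'   the first `sum(complexes)` genes. Default `c(5, 5, 4, 4, 3)`.
#' @param factor_sd Loading of complex members on their latent factor
#'   (dependency-score and abundance units). Default 0.6.
#' @param noise_sd Independent noise SD. Default 0.3.
#' @param base_mean Baseline dependency score for every gene. Default -0.2.
#' @param lineage_effects Data frame with integer columns `gene`, `lineage`
#'   and numeric `shift`: planted additive shifts applied to that gene's
#'   scores in that lineage. Default: one shift of -0.5 on the first
#'   non-complex gene in lineage 1. Use a zero-row data frame for none.
#' @param abundance_missing_rate Missing-completely-at-random masking rate
#'   of the abundance panel. Default 0.3.
#' @param ppi_within_prob Probability that a same-complex pair is a true
#'   interaction edge. Default 0.8.
#' @param ppi_background_prob Probability for any other pair. Default 0.002.
#' @param tau_within Central tau for same-complex (query, hit) pairs; unit
#'   jitter is added and values are truncated to \[-100, 100\]. Default 95.
#' @param tau_background_sd SD of background tau scores. Default 30.
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 120L,
                       n_lines = 300L,
                       n_lineages = 6L,
                       complexes = c(5L, 5L, 4L, 4L, 3L),
                       factor_sd = 0.6,
                       noise_sd = 0.3,
                       base_mean = -0.2,
                       lineage_effects = NULL,
                       abundance_missing_rate = 0.3,
                       ppi_within_prob = 0.8,
                       ppi_background_prob = 0.002,
                       tau_within = 95,
                       tau_background_sd = 30,
                       seed = 1L) {
  complexes <- as.integer(complexes)
  if (sum(complexes) > n_genes) {
    stop("sum of complex sizes (", sum(complexes),
         ") exceeds n_genes (", n_genes, ")")
  }
  if (is.null(lineage_effects)) {
    lineage_effects <- data.frame(gene = sum(complexes) + 1L,
                                  lineage = 1L, shift = -0.5)
  }
  stopifnot(is.data.frame(lineage_effects),
            all(c("gene", "lineage", "shift") %in% colnames(lineage_effects)))
  if (nrow(lineage_effects)) {
    stopifnot(all(lineage_effects$gene >= 1L),
              all(lineage_effects$gene <= n_genes),
              all(lineage_effects$lineage >= 1L),
              all(lineage_effects$lineage <= n_lineages))
  }
  probs <- c(abundance_missing_rate, ppi_within_prob, ppi_background_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (factor_sd < 0) stop("factor_sd must be >= 0")
  if (noise_sd <= 0 || tau_background_sd <= 0) stop("sds must be > 0")
  structure(list(
    n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
    n_lineages = as.integer(n_lineages), complexes = complexes,
    factor_sd = factor_sd, noise_sd = noise_sd, base_mean = base_mean,
    lineage_effects = lineage_effects,
    abundance_missing_rate = abundance_missing_rate,
    ppi_within_prob = ppi_within_prob,
    ppi_background_prob = ppi_background_prob,
    tau_within = tau_within, tau_background_sd = tau_background_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a linked multi-omics bundle with planted ground truth
#'
#' Draws a dependency panel, abundance panel, interaction set, tau table and
#' gene-set collection that share the planted structure described in
#' [sim_config()], plus a truth object recording exactly what was planted.
#'
#' Dependency scores follow
#' `score(g, c) = base_mean + lambda_g * f[m(g), c] + shift * planted(g, lineage(c)) + eps`
#' with `f` a per-complex per-line standard-normal factor, `lambda_g =
#' factor_sd` for complex members (0 otherwise) and `eps ~ N(0, noise_sd)`.
#' Abundance uses the same factor model with independent factors and MCAR
#' masking. One query gene per complex (its first member) is designated the
#' "DUB" of that complex; the tau table covers every (query, other gene)
#' pair. The gene-set collection holds one set per complex plus a
#' ubiquitin-transferase set containing each complex's designated E3-role
#' gene (its last member) and a few background genes.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`: a list with elements
#'   `dependency` ([dependency_panel()]), `abundance`
#'   ([abundance_panel()]), `interactions` ([interaction_set()]),
#'   `similarity` ([similarity_table()]), `gene_sets`
#'   ([gene_set_collection()]), `truth` (see Details) and `config`.
#'   `truth` carries `complex_membership` (named integer vector, NA for
#'   background genes), `lineage_effects` (symbol/label/shift rows),
#'   `true_edges`, `coexpr_modules`, `query_genes` and `e3_genes`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  lines <- sprintf("ACH-%06d", seq_len(cfg$n_lines))
  lineage_labels <- sprintf("LIN%02d", seq_len(cfg$n_lineages))

  membership <- rep(NA_integer_, cfg$n_genes)
  membership[seq_len(sum(cfg$complexes))] <-
    rep(seq_along(cfg$complexes), cfg$complexes)
  names(membership) <- genes

  # balanced allocation, randomly permuted, keeps every lineage well above
  # the minimum contrast size
  lineage_idx <- sample(rep_len(seq_len(cfg$n_lineages), cfg$n_lines))
  lineage <- stats::setNames(lineage_labels[lineage_idx], lines)

  n_cx <- length(cfg$complexes)
  lambda <- ifelse(is.na(membership), 0, cfg$factor_sd)

  dep_factors <- matrix(stats::rnorm(n_cx * cfg$n_lines), n_cx, cfg$n_lines)
  dep <- matrix(cfg$base_mean, cfg$n_lines, cfg$n_genes,
                dimnames = list(lines, genes))
  for (g in seq_len(cfg$n_genes)) {
    if (!is.na(membership[g])) {
      dep[, g] <- dep[, g] + lambda[g] * dep_factors[membership[g], ]
    }
  }
  if (nrow(cfg$lineage_effects)) {
    for (i in seq_len(nrow(cfg$lineage_effects))) {
      e <- cfg$lineage_effects[i, ]
      in_lines <- lineage_idx == e$lineage
      dep[in_lines, e$gene] <- dep[in_lines, e$gene] + e$shift
    }
  }
  dep <- dep + matrix(stats::rnorm(length(dep), sd = cfg$noise_sd),
                      nrow(dep), ncol(dep))

  ab_factors <- matrix(stats::rnorm(n_cx * cfg$n_lines), n_cx, cfg$n_lines)
  ab <- matrix(0, cfg$n_genes, cfg$n_lines, dimnames = list(genes, lines))
  for (g in seq_len(cfg$n_genes)) {
    if (!is.na(membership[g])) {
      ab[g, ] <- ab[g, ] + lambda[g] * ab_factors[membership[g], ]
    }
  }
  ab <- ab + matrix(stats::rnorm(length(ab), sd = cfg$noise_sd),
                    nrow(ab), ncol(ab))
  mask <- matrix(stats::runif(length(ab)) < cfg$abundance_missing_rate,
                 nrow(ab), ncol(ab))
  ab[mask] <- NA_real_

  # true interaction edges: dense within complexes, sparse elsewhere
  pairs <- utils::combn(cfg$n_genes, 2L)
  same_cx <- !is.na(membership[pairs[1L, ]]) &
    !is.na(membership[pairs[2L, ]]) &
    membership[pairs[1L, ]] == membership[pairs[2L, ]]
  p_edge <- ifelse(same_cx, cfg$ppi_within_prob, cfg$ppi_background_prob)
  keep <- stats::runif(ncol(pairs)) < p_edge
  ea <- genes[pairs[1L, keep]]
  eb <- genes[pairs[2L, keep]]
  src_pool <- c("sim_ppi_a", "sim_ppi_b")
  src <- lapply(seq_along(ea), function(i) {
    src_pool[stats::runif(2L) < c(0.7, 0.5)]
  })
  empty <- lengths(src) == 0L
  src[empty] <- lapply(which(empty), function(i) sample(src_pool, 1L))
  true_edges <- interaction_set(ea, eb, src)

  query_genes <- genes[vapply(seq_len(n_cx), function(k) {
    which(membership == k)[1L]
  }, integer(1))]
  # two background "DUB-like" queries exercise the null path
  bg <- which(is.na(membership))
  if (length(bg) >= 2L) query_genes <- c(query_genes, genes[bg[1:2]])

  tau_rows <- do.call(rbind, lapply(query_genes, function(q) {
    hits <- setdiff(genes, q)
    same <- !is.na(membership[q]) & !is.na(membership[hits]) &
      membership[hits] == membership[q]
    tau <- ifelse(same,
                  cfg$tau_within + stats::rnorm(length(hits)),
                  stats::rnorm(length(hits), sd = cfg$tau_background_sd))
    data.frame(query = q, hit = hits, tau = pmin(100, pmax(-100, tau)),
               stringsAsFactors = FALSE)
  }))
  sim_tab <- similarity_table(tau_rows$query, tau_rows$hit, tau_rows$tau,
                              perturbation_type = rep("knockout",
                                                      nrow(tau_rows)))

  e3_genes <- genes[vapply(seq_len(n_cx), function(k) {
    idx <- which(membership == k)
    idx[length(idx)]
  }, integer(1))]
  bg_e3 <- genes[utils::tail(bg, 10L)]
  sets <- stats::setNames(lapply(seq_len(n_cx), function(k) {
    list(name = sprintf("planted complex %d", k),
         members = genes[which(membership == k)])
  }), sprintf("COMPLEX_%d", seq_len(n_cx)))
  sets[["UBIQUITIN_LIKE_PROTEIN_TRANSFERASE_ACTIVITY"]] <-
    list(name = "ubiquitin-like protein transferase activity",
         members = c(e3_genes, bg_e3))
  gene_sets <- gene_set_collection(sets, universe = genes)

  planted <- cfg$lineage_effects
  truth <- list(
    complex_membership = membership,
    lineage_effects = data.frame(
      gene = genes[planted$gene],
      lineage = lineage_labels[planted$lineage],
      shift = planted$shift,
      stringsAsFactors = FALSE
    ),
    true_edges = true_edges,
    coexpr_modules = membership,
    query_genes = query_genes,
    e3_genes = e3_genes
  )

  structure(list(
    dependency = dependency_panel(dep, lineage),
    abundance = abundance_panel(ab),
    interactions = true_edges,
    similarity = sim_tab,
    gene_sets = gene_sets,
    truth = truth,
    config = cfg
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle\n")
  print(x$dependency); print(x$abundance); print(x$interactions)
  cat(sprintf("  %d tau rows, %d gene sets, %d query genes\n",
              nrow(x$similarity), length(x$gene_sets$sets),
              length(x$truth$query_genes)))
  invisible(x)
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Produces `dependency.csv` + `sample_info.csv`, `abundance.csv`, one edge
#' list per interaction source (`ppi_<source>.tsv`), `tau.tsv`, `sets.gmt`
#' and `truth.json`, all under `dir`.
#'
#' @param bundle A [simulate_panel()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written (elements
#'   `dependency`, `sample_info`, `abundance`, `ppi`, `tau`, `gmt`,
#'   `truth`).
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_dependency_panel(bundle$dependency, p("dependency.csv"),
                         p("sample_info.csv"))
  write_abundance_panel(bundle$abundance, p("abundance.csv"))
  sources <- sort(unique(unlist(bundle$interactions$provenance)))
  ppi_paths <- character()
  for (s in sources) {
    has <- vapply(bundle$interactions$provenance, function(v) s %in% v,
                  logical(1))
    sub <- interaction_set(bundle$interactions$edges$gene_a[has],
                           bundle$interactions$edges$gene_b[has],
                           s)
    path <- p(sprintf("ppi_%s.tsv", s))
    write_interaction_set(sub, path)
    ppi_paths <- c(ppi_paths, path)
  }
  write_similarity_table(bundle$similarity, p("tau.tsv"))
  write_gmt(bundle$gene_sets, p("sets.gmt"))
  truth <- bundle$truth
  jsonlite::write_json(list(
    complex_membership = as.list(truth$complex_membership),
    lineage_effects = truth$lineage_effects,
    true_edges = truth$true_edges$edges,
    query_genes = truth$query_genes,
    e3_genes = truth$e3_genes
  ), p("truth.json"), auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(list(dependency = p("dependency.csv"),
                 sample_info = p("sample_info.csv"),
                 abundance = p("abundance.csv"),
                 ppi = ppi_paths, tau = p("tau.tsv"), gmt = p("sets.gmt"),
                 truth = p("truth.json")))
}

#' Recovery of planted same-complex pairs from an evidence table
#'
#' Scores how well the integrated evidence recovers the planted structure:
#' precision and recall of planted same-complex (query, partner) pairs among
#' pairs with evidence count >= `min_count`, and the mean evidence count of
#' planted versus non-planted pairs (pairs absent from the table count 0).
#'
#' @param truth The `truth` element of a [simulate_panel()] bundle.
#' @param evidence An evidence table from [evidence_table()].
#' @param min_count Evidence-count cutoff defining a recovered pair.
#'   Default 2.
#' @return A list with `precision`, `recall`, `n_planted`, `n_flagged`,
#'   `mean_evidence_planted` and `mean_evidence_background`.
#' @export
truth_recovery_report <- function(truth, evidence, min_count = 2L) {
  genes <- names(truth$complex_membership)
  stray <- setdiff(unique(c(evidence$query, evidence$partner)), genes)
  if (length(stray)) {
    stop("evidence genes absent from the simulated universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  queries <- truth$query_genes
  m <- truth$complex_membership
  planted <- unlist(lapply(queries, function(q) {
    if (is.na(m[q])) return(character())
    partners <- setdiff(genes[!is.na(m) & m == m[q]], q)
    paste(q, partners, sep = "\r")
  }))
  all_pairs <- unlist(lapply(queries, function(q) {
    paste(q, setdiff(genes, q), sep = "\r")
  }))
  counts <- stats::setNames(rep(0, length(all_pairs)), all_pairs)
  if (nrow(evidence)) {
    key <- paste(evidence$query, evidence$partner, sep = "\r")
    hit <- key %in% all_pairs
    counts[key[hit]] <- evidence$evidence_count[hit]
  }
  flagged <- names(counts)[counts >= min_count]
  n_flagged <- length(flagged)
  tp <- length(intersect(flagged, planted))
  background <- setdiff(all_pairs, planted)
  list(
    precision = if (n_flagged) tp / n_flagged else NA_real_,
    recall = if (length(planted)) tp / length(planted) else NA_real_,
    n_planted = length(planted),
    n_flagged = n_flagged,
    mean_evidence_planted = if (length(planted)) mean(counts[planted])
                            else NA_real_,
    mean_evidence_background = if (length(background)) mean(counts[background])
                               else NA_real_
  )
}
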