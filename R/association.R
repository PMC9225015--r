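#' Proteomics co-expression scan for one query gene
#'
#' Pearson correlation of the query protein's abundance with every other
#' protein, computed over cell lines where both are detected. Partners with
#' fewer than `min_shared_lines` jointly detected lines are excluded before
#' testing and never enter the FDR family. The per-partner z-score
#' standardizes the query's vector of partner correlations
#' (`z_i = (r_i - mean(r)) / sd(r)`, sample sd); BH adjustment is applied
#' within the query's family, and a partner is significant when
#' `q < coexpr_fdr` and `|z| > coexpr_z`.
#'
#' @param ab An [abundance_panel()].
#' @param gene Query gene symbol.
#' @param config An [analysis_config()], or NULL for defaults.
#' @return Data frame of class `coexpression_result` with columns `query`,
#'   `partner`, `r`, `n`, `p`, `q`, `z`, `significant`, sorted by `q` then
#'   `p` then `partner`.
#' @export
coexpression_scan <- function(ab, gene, config = NULL) {
  cfg <- as_config(config)
  gene <- canonicalize_symbols(gene)
  if (!gene %in% rownames(ab$abundance)) {
    stop("query gene not in abundance panel: ", gene)
  }
  x <- ab$abundance[gene, ]
  others <- setdiff(rownames(ab$abundance), gene)
  m <- ab$abundance[others, , drop = FALSE]
  joint <- !is.na(m) & matrix(!is.na(x), nrow(m), ncol(m), byrow = TRUE)
  n <- as.integer(rowSums(joint))
  eligible <- n >= cfg$min_shared_lines
  if (!any(eligible)) {
    stop("no partner shares >= ", cfg$min_shared_lines,
         " detected lines with ", gene)
  }
  m <- m[eligible, , drop = FALSE]
  others <- others[eligible]
  n <- n[eligible]
  r <- suppressWarnings(
    as.vector(stats::cor(x, t(m), use = "pairwise.complete.obs"))
  )
  defined <- !is.na(r)
  if (!all(defined)) {
    message("omitted ", sum(!defined),
            " constant-abundance partner(s) for ", gene)
    others <- others[defined]; n <- n[defined]; r <- r[defined]
  }
  if (!length(r)) stop("no partner with defined correlation for ", gene)
  sdr <- stats::sd(r)
  if (!is.finite(sdr) || sdr == 0) {
    stop("partner correlations have zero spread for ", gene,
         "; z-scores undefined - use a larger panel")
  }
  z <- (r - mean(r)) / sdr
  p <- cor_pvalue(r, n)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(query = gene, partner = others, r = r, n = n,
                    p = p, q = q, z = z,
                    significant = q < cfg$coexpr_fdr & abs(z) > cfg$coexpr_z,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coexpression_result", "data.frame")
  out
}

#' Compile interaction sets from multiple sources
#'
#' Union of edges across sources with per-edge provenance accumulating
#' every source label; idempotent.
#'
#' @param sources A list of [interaction_set()] objects (or a single one).
#' @return A merged [interaction_set()].
#' @export
compile_interactions <- function(sources) {
  if (inherits(sources, "interaction_set")) sources <- list(sources)
  stopifnot(length(sources) >= 1L,
            all(vapply(sources, inherits, logical(1), "interaction_set")))
  gene_a <- unlist(lapply(sources, function(s) s$edges$gene_a))
  gene_b <- unlist(lapply(sources, function(s) s$edges$gene_b))
  prov <- do.call(c, lapply(sources, function(s) s$provenance))
  interaction_set(gene_a, gene_b, prov)
}

#' Interaction partners of a gene
#'
#' @param iset An [interaction_set()].
#' @param gene Gene symbol.
#' @return Sorted character vector of neighbors; empty if the gene is
#'   absent from the edge set.
#' @export
interactors <- function(iset, gene) {
  stopifnot(inherits(iset, "interaction_set"))
  gene <- canonicalize_symbols(gene)
  sort(unique(c(iset$edges$gene_b[iset$edges$gene_a == gene],
                iset$edges$gene_a[iset$edges$gene_b == gene])))
}

#' Perturbation-similarity flags for one query
#'
#' Hit genes whose tau score strictly exceeds the threshold (the
#' recommended cutoff is 90; a tau of exactly 90 is not flagged).
#' Duplicate (query, hit) rows are resolved to the maximum tau before
#' thresholding.
#'
#' @param table A [similarity_table()].
#' @param query Query gene symbol.
#' @param config An [analysis_config()] (uses `tau_threshold`), or NULL.
#' @return Sorted character vector of flagged hit genes.
#' @export
similarity_flags <- function(table, query, config = NULL) {
  cfg <- as_config(config)
  query <- canonicalize_symbols(query)
  sub <- table[table$query == query, , drop = FALSE]
  if (!nrow(sub)) return(character())
  best <- tapply(sub$tau, sub$hit, max)
  sort(names(best)[best > cfg$tau_threshold])
}

#' Hit genes tested for a query in a tau table
#'
#' Used by the integrator to distinguish "tested, not similar" from
#' "not tested".
#'
#' @param table A [similarity_table()].
#' @param query Query gene symbol.
#' @return Sorted character vector of hit genes with a tau row.
#' @export
similarity_tested <- function(table, query) {
  query <- canonicalize_symbols(query)
  sort(unique(table$hit[table$query == query]))
}

#' Rank-concordance of two ordered gene lists
#'
#' Kendall-style concordance over the genes common to both lists:
#' `(C - D) / (m * (m - 1) / 2)` where C and D count concordant and
#' discordant pairs of the m shared genes. Genes absent from either list
#' are ignored. This is an auxiliary statistic for comparing ranked
#' signatures; it is not the CMap compendium-percentile tau (consumed tau
#' tables are the fidelity path).
#'
#' @param list_a,list_b Character vectors in rank order (no duplicates).
#' @return A number in \[-1, 1\]: 1 for identical order of the shared
#'   genes, -1 for reversed order.
#' @export
rank_similarity <- function(list_a, list_b) {
  list_a <- canonicalize_symbols(list_a)
  list_b <- canonicalize_symbols(list_b)
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stop("ranked lists must not contain duplicate genes")
  }
  common <- intersect(list_a, list_b)
  m <- length(common)
  if (m < 2L) stop("fewer than 2 genes common to both lists")
  ra <- match(common, list_a)
  rb <- match(common, list_b)
  conc <- 0L; disc <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      s <- sign(ra[i] - ra[j]) * sign(rb[i] - rb[j])
      if (s > 0) conc <- conc + 1L else disc <- disc + 1L
    }
  }
  (conc - disc) / (m * (m - 1L) / 2)
}
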