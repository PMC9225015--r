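#' Fraction of cell lines dependent on a gene
#'
#' The number of cell lines with dependency scores strictly below the
#' threshold, divided by the number of lines with a non-missing score for
#' the gene. With the default threshold of -0.5 this is the standard
#' "fraction of dependent lines" essentiality summary.
#'
#' @param panel A [dependency_panel()].
#' @param gene Gene symbol.
#' @param threshold Dependency-score cutoff (strict `<`). Default -0.5.
#' @return A list with `fraction`, `n_dependent` and `n_tested`.
#' @export
dependent_fraction <- function(panel, gene, threshold = -0.5) {
  stopifnot(inherits(panel, "dependency_panel"), is.finite(threshold))
  gene <- canonicalize_symbols(gene)
  if (!gene %in% colnames(panel$scores)) {
    stop("gene not in panel: ", gene)
  }
  x <- panel$scores[, gene]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing scores for gene ", gene)
  n_dep <- sum(x < threshold)
  list(fraction = n_dep / length(x), n_dependent = n_dep,
       n_tested = length(x))
}

#' Essentiality categories for a gene list
#'
#' One row per gene with its dependent fraction and a mutually exclusive
#' category assigned by the first matching rule:
#' `pan` (fraction >= 0.9), `strong` (fraction >= 0.30), `partial`
#' (dependent in at least 1% of its tested lines), `rare` (dependent in at
#' least `min_dependent_lines` lines), else `none`.
#'
#' @param panel A [dependency_panel()].
#' @param genes Character vector of gene symbols, all present in the panel.
#' @param config An [analysis_config()] (threshold and
#'   `min_dependent_lines`), or NULL for defaults.
#' @return Data frame with columns `gene`, `fraction`, `n_dependent`,
#'   `n_tested`, `category`.
#' @export
summarize_essentiality <- function(panel, genes, config = NULL) {
  cfg <- as_config(config)
  genes <- canonicalize_symbols(genes)
  rows <- lapply(genes, function(g) {
    f <- dependent_fraction(panel, g, cfg$dependency_threshold)
    category <- if (f$fraction >= 0.9) "pan"
      else if (f$fraction >= 0.30) "strong"
      else if (f$n_dependent >= 0.01 * f$n_tested) "partial"
      else if (f$n_dependent >= cfg$min_dependent_lines) "rare"
      else "none"
    data.frame(gene = g, fraction = f$fraction, n_dependent = f$n_dependent,
               n_tested = f$n_tested, category = category,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(), fraction = numeric(),
               n_dependent = integer(), n_tested = integer(),
               category = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Welch contrast of one lineage's scores against all other lines.
# Returns a one-row data frame, or a reason string when ineligible.
lineage_contrast_row <- function(panel, gene, lineage, min_lineage_size) {
  x <- panel$scores[, gene]
  in_grp <- x[panel$lineage == lineage]
  out_grp <- x[panel$lineage != lineage]
  in_grp <- in_grp[!is.na(in_grp)]
  out_grp <- out_grp[!is.na(out_grp)]
  if (length(in_grp) < min_lineage_size) return("in_group_too_small")
  if (length(out_grp) < 2L) return("out_group_too_small")
  tt <- tryCatch(stats::t.test(out_grp, in_grp, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) return("degenerate_scores")
  data.frame(
    gene = gene, lineage = lineage,
    n_in = length(in_grp), n_out = length(out_grp),
    mean_in = mean(in_grp), mean_out = mean(out_grp),
    diff = mean(out_grp) - mean(in_grp),
    t_stat = unname(tt$statistic), p = tt$p.value, q = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Lineage-specific essentiality contrast for one gene
#'
#' Welch (unequal-variance) two-sided t-test comparing the gene's
#' dependency scores in one lineage against all other cell lines. `diff`
#' is `mean_out - mean_in`, so it is positive when the lineage is more
#' sensitive (more negative scores) than the rest of the panel.
#'
#' @param panel A [dependency_panel()].
#' @param gene Gene symbol.
#' @param lineage Lineage label.
#' @param config An [analysis_config()] (uses `min_lineage_size`), or NULL.
#' @return One-row data frame with columns `gene`, `lineage`, `n_in`,
#'   `n_out`, `mean_in`, `mean_out`, `diff`, `t_stat`, `p`, `q` (`q` is NA
#'   here; it is filled by [scan_lineages()], whose BH family spans the
#'   whole scan).
#' @export
lineage_contrast <- function(panel, gene, lineage, config = NULL) {
  cfg <- as_config(config)
  gene <- canonicalize_symbols(gene)
  if (!gene %in% colnames(panel$scores)) stop("gene not in panel: ", gene)
  if (!lineage %in% panel$lineage) stop("lineage not in panel: ", lineage)
  row <- lineage_contrast_row(panel, gene, lineage, cfg$min_lineage_size)
  if (is.character(row)) {
    stop("lineage contrast ineligible for ", gene, " / ", lineage,
         ": ", row)
  }
  row
}

#' Scan all (gene, lineage) pairs for lineage-specific essentiality
#'
#' Runs [lineage_contrast()] for every gene against every eligible lineage
#' and applies Benjamini-Hochberg correction across the whole table (one
#' family per scan). A pair is flagged significant when `p < lineage_p`
#' and `q < lineage_fdr`. Lines with lineage `"UNKNOWN"` never form an
#' in-group but remain in every out-group.
#'
#' @param panel A [dependency_panel()].
#' @param genes Gene symbols to scan.
#' @param config An [analysis_config()], or NULL for defaults.
#' @return Data frame of contrasts sorted by `q`, `p`, `gene`, `lineage`,
#'   with a logical `significant` column. Pairs skipped for eligibility are
#'   reported in the `"skipped"` attribute (columns `gene`, `lineage`,
#'   `reason`).
#' @export
scan_lineages <- function(panel, genes, config = NULL) {
  cfg <- as_config(config)
  genes <- canonicalize_symbols(genes)
  missing <- setdiff(genes, colnames(panel$scores))
  if (length(missing)) {
    stop("genes not in panel: ", paste(missing, collapse = ", "))
  }
  lineages <- setdiff(sort(unique(panel$lineage)), "UNKNOWN")
  rows <- list(); skipped <- list()
  for (g in genes) {
    for (l in lineages) {
      row <- lineage_contrast_row(panel, g, l, cfg$min_lineage_size)
      if (is.character(row)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene = g, lineage = l, reason = row,
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else {
    data.frame(gene = character(), lineage = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    if (nrow(skipped)) {
      out <- data.frame(gene = character(), lineage = character(),
                        n_in = integer(), n_out = integer(),
                        mean_in = numeric(), mean_out = numeric(),
                        diff = numeric(), t_stat = numeric(), p = numeric(),
                        q = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
      attr(out, "skipped") <- skipped
      return(out)
    }
    stop("no eligible (gene, lineage) pairs to scan")
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < cfg$lineage_p & out$q < cfg$lineage_fdr
  out <- out[order(out$q, out$p, out$gene, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Co-dependency profile of a gene
#'
#' Pairwise-complete Pearson correlation between the query gene's
#' dependency scores and every other gene in the panel, keeping partners
#' with at least `min_codep_overlap` shared non-missing lines. Partners
#' whose scores are constant over the shared lines have undefined
#' correlation and are omitted (recorded in the `omitted` element).
#' Ranking follows `config$top_k_mode`: `"absolute"` sorts by descending
#' |r|, `"positive"` by descending r; ties break by symbol.
#'
#' @param panel A [dependency_panel()].
#' @param gene Query gene symbol.
#' @param config An [analysis_config()], or NULL for defaults.
#' @return An object of class `codependency_profile`: list with `query`,
#'   `partners` (data frame `gene`, `r`, `n` in rank order) and `omitted`
#'   (character vector of zero-variance partners).
#' @export
codependency_profile <- function(panel, gene, config = NULL) {
  cfg <- as_config(config)
  gene <- canonicalize_symbols(gene)
  if (!gene %in% colnames(panel$scores)) stop("gene not in panel: ", gene)
  x <- panel$scores[, gene]
  if (stats::sd(x, na.rm = TRUE) == 0 || sum(!is.na(x)) < 2L) {
    stop("query gene ", gene, " has constant dependency scores")
  }
  others <- setdiff(colnames(panel$scores), gene)
  m <- panel$scores[, others, drop = FALSE]
  obs <- !is.na(m) & !is.na(x)
  n <- colSums(obs)
  r <- suppressWarnings(
    as.vector(stats::cor(x, m, use = "pairwise.complete.obs"))
  )
  eligible <- n >= cfg$min_codep_overlap
  zero_var <- eligible & is.na(r)
  omitted <- others[zero_var]
  if (length(omitted)) {
    message("omitted ", length(omitted),
            " zero-variance partner(s) for ", gene)
  }
  keep <- eligible & !is.na(r)
  partners <- data.frame(gene = others[keep], r = r[keep],
                         n = as.integer(n[keep]), stringsAsFactors = FALSE)
  key <- if (cfg$top_k_mode == "absolute") -abs(partners$r) else -partners$r
  partners <- partners[order(key, partners$gene), , drop = FALSE]
  rownames(partners) <- NULL
  if (!nrow(partners)) {
    stop("no partner with >= ", cfg$min_codep_overlap,
         " shared lines for ", gene)
  }
  structure(list(query = gene, partners = partners, omitted = omitted),
            class = "codependency_profile")
}

#' @export
print.codependency_profile <- function(x, ...) {
  cat(sprintf("codependency_profile for %s: %d ranked partners\n",
              x$query, nrow(x$partners)))
  print(utils::head(x$partners, 7L))
  invisible(x)
}

#' Top k co-dependent genes of a profile
#'
#' @param profile A [codependency_profile()].
#' @param k Maximum number of partners to return (default 7).
#' @return Data frame of the first `min(k, available)` ranked partners
#'   (`gene`, `r`, `n`).
#' @export
top_codependents <- function(profile, k = 7L) {
  stopifnot(inherits(profile, "codependency_profile"), k >= 1L)
  utils::head(profile$partners, k)
}

#' Correlation between a gene's dependency and its protein abundance
#'
#' Pearson correlation over cell lines present in both panels with both
#' values non-missing, with the two-sided t-based p-value on n - 2 degrees
#' of freedom.
#'
#' @param dep A [dependency_panel()].
#' @param ab An [abundance_panel()].
#' @param gene Gene symbol (must be in both panels).
#' @param config An [analysis_config()] (uses `min_codep_overlap` as the
#'   minimum shared-line count), or NULL.
#' @return A list with `gene`, `r`, `p`, `n` and `status` (`"ok"` or
#'   `"insufficient_overlap"`, in which case `r` and `p` are NA).
#' @export
dependency_abundance_correlation <- function(dep, ab, gene, config = NULL) {
  cfg <- as_config(config)
  gene <- canonicalize_symbols(gene)
  if (!gene %in% colnames(dep$scores)) stop("gene not in dependency panel: ", gene)
  if (!gene %in% rownames(ab$abundance)) stop("gene not in abundance panel: ", gene)
  shared <- intersect(rownames(dep$scores), colnames(ab$abundance))
  x <- dep$scores[shared, gene]
  y <- ab$abundance[gene, shared]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < cfg$min_codep_overlap) {
    return(list(gene = gene, r = NA_real_, p = NA_real_, n = n,
                status = "insufficient_overlap"))
  }
  r <- stats::cor(x[ok], y[ok])
  list(gene = gene, r = r, p = cor_pvalue(r, n), n = n, status = "ok")
}

# two-sided p for a Pearson r at sample size n (t on n - 2 df)
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Cohort summary of dependency-abundance correlations
#'
#' Applies [dependency_abundance_correlation()] to a gene list and reports
#' the per-gene results plus the cohort medians of r and p (the headline
#' "is expression predictive of dependency" summary).
#'
#' @param dep A [dependency_panel()].
#' @param ab An [abundance_panel()].
#' @param genes Gene symbols present in both panels.
#' @param config An [analysis_config()], or NULL.
#' @return A list with `per_gene` (data frame `gene`, `r`, `p`, `n`,
#'   `status`) and `median_r`, `median_p` over genes with status `"ok"`.
#' @export
dependency_abundance_summary <- function(dep, ab, genes, config = NULL) {
  rows <- lapply(genes, function(g) {
    res <- dependency_abundance_correlation(dep, ab, g, config)
    data.frame(gene = res$gene, r = res$r, p = res$p, n = res$n,
               status = res$status, stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  ok <- per_gene$status == "ok"
  list(per_gene = per_gene,
       median_r = stats::median(per_gene$r[ok]),
       median_p = stats::median(per_gene$p[ok]))
}
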