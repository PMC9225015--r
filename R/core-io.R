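#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Idempotent; all containers
#' in the package store symbols in this form so that the five data sources
#' can be joined by symbol.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Stop with a message naming duplicated entries.
check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    stop("duplicate ", what, " after canonicalization: ",
         paste(dup, collapse = ", "))
  }
  invisible(x)
}

# All writers emit UTF-8 text with LF line endings; numbers are written at
# full double precision so that write -> read round-trips bit-for-bit.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out
}

# ---------------------------------------------------------------------------
# DependencyPanel

#' Construct a dependency panel
#'
#' A cell-line x gene matrix of CRISPR dependency scores (CERES-like; more
#' negative = stronger dependence on the gene) together with a lineage label
#' per cell line. Missing score cells are permitted.
#'
#' @param scores Numeric matrix, rows = cell lines, columns = genes, with
#'   dimnames set.
#' @param lineage Named character vector mapping cell-line id to lineage
#'   label. Lines absent from the map get `"UNKNOWN"`.
#' @param entrez Optional named character/integer vector mapping gene symbol
#'   to Entrez id (kept only as a side map; all joins use symbols).
#' @return An object of class `dependency_panel`.
#' @export
dependency_panel <- function(scores, lineage = NULL, entrez = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("scores must be a numeric matrix")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must have cell-line row names and gene column names")
  }
  colnames(scores) <- canonicalize_symbols(colnames(scores))
  check_unique(colnames(scores), "gene symbols")
  check_unique(rownames(scores), "cell-line ids")
  lin <- rep("UNKNOWN", nrow(scores))
  names(lin) <- rownames(scores)
  if (!is.null(lineage)) {
    lineage <- trimws(lineage)
    hit <- intersect(names(lineage), rownames(scores))
    lin[hit] <- lineage[hit]
  }
  if (!is.null(entrez)) {
    names(entrez) <- canonicalize_symbols(names(entrez))
    entrez <- entrez[intersect(names(entrez), colnames(scores))]
  }
  structure(list(scores = scores, lineage = lin, entrez = entrez),
            class = "dependency_panel")
}

#' @export
print.dependency_panel <- function(x, ...) {
  cat(sprintf("dependency_panel: %d cell lines x %d genes, %d lineages, %.1f%% missing\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$lineage)),
              100 * mean(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.dependency_panel <- function(x) dim(x$scores)

#' Read a dependency matrix and sample info into a panel
#'
#' Expects the DepMap gene-effect CSV dialect: one header row whose gene
#' cells read `"SYMBOL (ENTREZ)"`, first column cell-line ids (ACH-style).
#' The parenthesized Entrez suffix is stripped from symbols and retained in
#' the panel's side map. The sample-info CSV must contain a cell-line id
#' column (its first column, or `DepMap_ID` if present) and
#' `lineage_column`; lines absent from it get lineage `"UNKNOWN"` with a
#' warning.
#'
#' @param matrix_path Path to the gene-effect CSV.
#' @param sample_info_path Path to the sample-info CSV.
#' @param lineage_column Name of the lineage column in the sample info.
#' @return A [dependency_panel()].
#' @export
read_dependency_matrix <- function(matrix_path, sample_info_path,
                                   lineage_column = "lineage") {
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L) {
    stop("empty dependency matrix: ", matrix_path)
  }
  ids <- as.character(raw[[1L]])
  hdr <- colnames(raw)[-1L]
  sym <- canonicalize_symbols(sub("\\s*\\([0-9]+\\)\\s*$", "", hdr))
  suf <- regexpr("\\(([0-9]+)\\)\\s*$", hdr)
  entrez <- NULL
  if (any(suf > 0L)) {
    entrez <- stats::setNames(gsub("[()]", "", regmatches(hdr, suf)),
                              sym[suf > 0L])
  }
  scores <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(ids, sym)

  info <- utils::read.csv(sample_info_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  idcol <- if ("DepMap_ID" %in% colnames(info)) "DepMap_ID" else colnames(info)[1L]
  if (!lineage_column %in% colnames(info)) {
    stop("sample info lacks lineage column '", lineage_column,
         "'; found: ", paste(colnames(info), collapse = ", "))
  }
  lineage <- stats::setNames(as.character(info[[lineage_column]]),
                             as.character(info[[idcol]]))
  absent <- setdiff(ids, names(lineage))
  if (length(absent)) {
    warning(length(absent), " cell line(s) absent from sample info; ",
            "lineage set to UNKNOWN: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  }
  panel <- dependency_panel(scores, lineage, entrez)
  message(sprintf("read dependency panel: %d lines, %d genes, %.2f%% missing",
                  nrow(scores), ncol(scores), 100 * mean(is.na(scores))))
  panel
}

#' Write a dependency panel back to the gene-effect CSV dialect
#'
#' @param panel A [dependency_panel()].
#' @param matrix_path Output CSV path for the score matrix.
#' @param sample_info_path Output CSV path for the lineage table.
#' @param lineage_column Lineage column name to use in the sample info.
#' @return Invisibly, `matrix_path`.
#' @export
write_dependency_panel <- function(panel, matrix_path, sample_info_path,
                                   lineage_column = "lineage") {
  stopifnot(inherits(panel, "dependency_panel"))
  sym <- colnames(panel$scores)
  hdr <- sym
  if (!is.null(panel$entrez)) {
    has <- sym %in% names(panel$entrez)
    hdr[has] <- sprintf("%s (%s)", sym[has], panel$entrez[sym[has]])
  }
  lines <- c(
    paste(c("DepMap_ID", hdr), collapse = ","),
    vapply(seq_len(nrow(panel$scores)), function(i) {
      paste(c(rownames(panel$scores)[i], format_num(panel$scores[i, ])),
            collapse = ",")
    }, character(1))
  )
  write_lines_lf(lines, matrix_path)
  info <- c(
    paste(c("DepMap_ID", lineage_column), collapse = ","),
    paste(names(panel$lineage), panel$lineage, sep = ",")
  )
  write_lines_lf(info, sample_info_path)
  invisible(matrix_path)
}

# ---------------------------------------------------------------------------
# AbundancePanel

#' Construct a protein-abundance panel
#'
#' Genes (rows) x cell lines (columns) of normalized protein abundances,
#' with missing values permitted and common (a protein is "detected" in a
#' line where its value is non-missing).
#'
#' @param abundance Numeric matrix with gene-symbol row names and cell-line
#'   column names.
#' @return An object of class `abundance_panel` with a derived logical
#'   `detected` mask.
#' @export
abundance_panel <- function(abundance) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop("abundance must be a numeric matrix")
  }
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance must have gene row names and cell-line column names")
  }
  rownames(abundance) <- canonicalize_symbols(rownames(abundance))
  check_unique(rownames(abundance), "gene symbols")
  check_unique(colnames(abundance), "cell-line ids")
  structure(list(abundance = abundance, detected = !is.na(abundance)),
            class = "abundance_panel")
}

#' @export
print.abundance_panel <- function(x, ...) {
  cat(sprintf("abundance_panel: %d proteins x %d cell lines, %.1f%% missing\n",
              nrow(x$abundance), ncol(x$abundance),
              100 * mean(!x$detected)))
  invisible(x)
}

#' Read a protein-abundance CSV (genes x cell lines)
#'
#' First column = gene symbols, remaining columns = cell lines; empty cells
#' or `NA` are missing.
#'
#' @param path CSV path.
#' @return An [abundance_panel()].
#' @export
read_abundance_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L) stop("empty abundance matrix: ", path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1L]])
  abundance_panel(m)
}

#' Write an abundance panel to CSV
#'
#' @param panel An [abundance_panel()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_abundance_panel <- function(panel, path) {
  stopifnot(inherits(panel, "abundance_panel"))
  m <- panel$abundance
  lines <- c(
    paste(c("gene_symbol", colnames(m)), collapse = ","),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format_num(m[i, ])), collapse = ",")
    }, character(1))
  )
  write_lines_lf(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneSetCollection

#' Construct a gene-set collection
#'
#' @param sets Named list; each element is a list with `name` (display name)
#'   and `members` (character vector of gene symbols). Members are
#'   canonicalized and deduplicated.
#' @param universe Optional character vector of eligible gene symbols;
#'   defaults to the union of all members.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list keyed by set id")
  }
  check_unique(names(sets), "set ids")
  sets <- lapply(sets, function(s) {
    list(name = as.character(s$name),
         members = unique(canonicalize_symbols(s$members)))
  })
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(sets, `[[`, "members"),
                                   use.names = FALSE)))
  } else {
    universe <- sort(unique(canonicalize_symbols(universe)))
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member...`. Duplicate members within a set
#' are deduplicated.
#'
#' @param path GMT path.
#' @param universe Optional universe override; defaults to the union of all
#'   members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  raw <- readLines(path, encoding = "UTF-8")
  raw <- raw[nzchar(raw)]
  sets <- list()
  for (i in seq_along(raw)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    sets[[f[1L]]] <- list(name = f[2L], members = f[-(1:2)])
  }
  gene_set_collection(sets, universe = universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output GMT path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$name, s$members), collapse = "\t")
  }, character(1))
  write_lines_lf(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# InteractionSet

edge_key <- function(a, b) paste(a, b, sep = "\r")

#' Construct an undirected interaction set
#'
#' Edges are canonicalized so that `gene_a < gene_b` lexicographically;
#' self-edges are dropped (with a message when any are); duplicate edges are
#' merged with provenance union. Edges are stored sorted lexicographically.
#'
#' @param gene_a,gene_b Character vectors of interacting gene symbols.
#' @param sources Either a single source label recycled to every edge, a
#'   character vector parallel to the edges, or a list of character vectors.
#' @return An object of class `interaction_set`: a list with `edges` (a
#'   data frame with columns `gene_a`, `gene_b`) and `provenance` (a list of
#'   source-label character vectors parallel to `edges` rows).
#' @export
interaction_set <- function(gene_a = character(), gene_b = character(),
                            sources = character()) {
  gene_a <- canonicalize_symbols(gene_a)
  gene_b <- canonicalize_symbols(gene_b)
  stopifnot(length(gene_a) == length(gene_b))
  if (!is.list(sources)) {
    sources <- if (length(sources) == 1L) {
      rep(list(as.character(sources)), length(gene_a))
    } else {
      as.list(as.character(sources))
    }
  }
  if (length(gene_a) && length(sources) != length(gene_a)) {
    stop("sources must parallel the edges")
  }
  self <- gene_a == gene_b
  if (any(self)) {
    message("dropped ", sum(self), " self-edge(s)")
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
    sources <- sources[!self]
  }
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  key <- edge_key(lo, hi)
  prov <- split(unlist(sources, use.names = FALSE),
                rep(key, lengths(sources)))
  prov <- lapply(prov, function(s) sort(unique(s)))
  ukey <- sort(unique(key))
  idx <- match(ukey, key)
  edges <- data.frame(gene_a = lo[idx], gene_b = hi[idx],
                      stringsAsFactors = FALSE)
  provenance <- unname(prov[ukey])
  if (any(lengths(provenance) == 0L)) stop("every edge needs a source label")
  structure(list(edges = edges, provenance = provenance),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("interaction_set: %d edges over %d genes, sources: %s\n",
              nrow(x$edges),
              length(unique(c(x$edges$gene_a, x$edges$gene_b))),
              paste(sort(unique(unlist(x$provenance))), collapse = ", ")))
  invisible(x)
}

#' Read a tabular interaction edge list
#'
#' Tab-separated file with columns `gene_a` and `gene_b`; an optional
#' `source` column overrides `source_label` per row.
#'
#' @param path TSV path.
#' @param source_label Source label recorded for every edge lacking its own.
#' @return An [interaction_set()].
#' @export
read_edge_list <- function(path, source_label = basename(path)) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b")
  if (!all(need %in% colnames(raw))) {
    stop("edge list must have columns gene_a and gene_b; found: ",
         paste(colnames(raw), collapse = ", "))
  }
  src <- if ("source" %in% colnames(raw)) {
    ifelse(is.na(raw$source) | raw$source == "", source_label, raw$source)
  } else {
    rep(source_label, nrow(raw))
  }
  interaction_set(raw$gene_a, raw$gene_b, as.list(src))
}

#' Write an interaction set to TSV
#'
#' Columns `gene_a`, `gene_b`, `sources` (semicolon-joined labels).
#'
#' @param iset An [interaction_set()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_interaction_set <- function(iset, path) {
  stopifnot(inherits(iset, "interaction_set"))
  lines <- c("gene_a\tgene_b\tsources",
             sprintf("%s\t%s\t%s", iset$edges$gene_a, iset$edges$gene_b,
                     vapply(iset$provenance, paste, character(1),
                            collapse = ";")))
  write_lines_lf(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SimilarityTable

#' Construct a perturbation-similarity (tau) table
#'
#' Rows of (query gene, hit gene, tau), tau on the CMap-style scale
#' \[-100, 100\]. Duplicate (query, hit) pairs are resolved by keeping the
#' maximum tau.
#'
#' @param query,hit Character vectors of gene symbols.
#' @param tau Numeric similarity scores in \[-100, 100\].
#' @param perturbation_type Optional character vector (e.g. knockdown vs
#'   overexpression); retained alongside the kept row.
#' @return A data frame of class `similarity_table` with columns `query`,
#'   `hit`, `tau` and optionally `perturbation_type`.
#' @export
similarity_table <- function(query, hit, tau, perturbation_type = NULL) {
  query <- canonicalize_symbols(query)
  hit <- canonicalize_symbols(hit)
  tau <- as.numeric(tau)
  stopifnot(length(query) == length(hit), length(hit) == length(tau))
  if (any(!is.finite(tau)) || any(tau < -100 | tau > 100)) {
    stop("tau values must be finite and within [-100, 100]")
  }
  df <- data.frame(query = query, hit = hit, tau = tau,
                   stringsAsFactors = FALSE)
  if (!is.null(perturbation_type)) {
    df$perturbation_type <- as.character(perturbation_type)
  }
  # keep the max-tau row per (query, hit)
  df <- df[order(df$query, df$hit, -df$tau), , drop = FALSE]
  df <- df[!duplicated(df[c("query", "hit")]), , drop = FALSE]
  df <- df[order(df$query, df$hit), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("similarity_table", "data.frame")
  df
}

#' Read a tau similarity table from TSV
#'
#' Columns `query`, `hit`, `tau`, optional `perturbation_type`.
#'
#' @param path TSV path.
#' @return A [similarity_table()].
#' @export
read_similarity_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("query", "hit", "tau")
  if (!all(need %in% colnames(raw))) {
    stop("similarity table must have columns query, hit, tau; found: ",
         paste(colnames(raw), collapse = ", "))
  }
  similarity_table(raw$query, raw$hit, raw$tau,
                   perturbation_type = raw[["perturbation_type"]])
}

#' Write a tau similarity table to TSV
#'
#' @param table A [similarity_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_similarity_table <- function(table, path) {
  cols <- intersect(c("query", "hit", "tau", "perturbation_type"),
                    colnames(table))
  body <- do.call(paste, c(lapply(cols, function(cn) {
    if (cn == "tau") format_num(table[[cn]]) else table[[cn]]
  }), sep = "\t"))
  write_lines_lf(c(paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

# Generic TSV writer for result tables (LF endings, no quoting).
write_result_tsv <- function(df, path, digits = 10) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), "NA", sprintf("%.*g", digits, col))
    } else {
      as.character(col)
    }
  })
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character()
  write_lines_lf(c(paste(colnames(df), collapse = "\t"), body), path)
  invisible(path)
}
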