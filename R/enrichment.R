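#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more query genes inside a set of
#' size `K`, when `n` genes are drawn without replacement from a universe
#' of `N`:
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' Terms are accumulated in log space (log-binomials plus log-sum-exp) so
#' the sum stays stable for universes up to ~1e5 genes.
#'
#' @param k Observed overlap count.
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (k < 0 || n < 0 || K < 0 || N < 0 || n > N || K > N || k > n) {
    stop("invalid hypergeometric bounds: need 0 <= k <= n <= N, 0 <= K <= N")
  }
  if (k == 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logterms)
  min(1, exp(mx + log(sum(exp(logterms - mx)))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list. The
#' query and every set are first intersected with the collection's
#' universe; query genes outside the universe are dropped with a warning.
#' One upper-tail hypergeometric p-value is computed per non-empty set,
#' BH-adjusted across all tested sets; a set is significant at
#' `q < fdr_cutoff`.
#'
#' @param query Character vector of query gene symbols.
#' @param collection A [gene_set_collection()].
#' @param config Unused placeholder for pipeline symmetry (reserved).
#' @param fdr_cutoff Significance cutoff on q. Default 0.05.
#' @return Data frame of class `enrichment_result` with columns `set_id`,
#'   `name`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`, ordered by `q`,
#'   `p`, `set_id`.
#' @export
ora <- function(query, collection, config = NULL, fdr_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(canonicalize_symbols(query))
  dropped <- setdiff(query, collection$universe)
  query <- intersect(query, collection$universe)
  if (!length(query)) {
    stop("query has no genes in the universe; dropped: ",
         paste(dropped, collapse = ", "))
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " query gene(s) outside the ",
            "universe: ", paste(dropped, collapse = ", "))
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- list()
  for (id in names(collection$sets)) {
    s <- collection$sets[[id]]
    members <- intersect(s$members, collection$universe)
    K <- length(members)
    if (K < 1L) next
    k <- length(intersect(query, members))
    rows[[id]] <- data.frame(
      set_id = id, name = s$name, k = k, K = K, n = n, N = N,
      p = hypergeometric_tail(k, K, n, N), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no testable set (all empty within the universe)")
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_cutoff
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
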