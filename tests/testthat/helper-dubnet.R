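# Shared fixtures and independent oracles for the suite.

# Small dependency panel from a scores matrix (lines x genes).
make_dep_panel <- function(scores, lineage = NULL) {
  if (is.null(rownames(scores))) {
    rownames(scores) <- sprintf("CL%04d", seq_len(nrow(scores)))
  }
  if (!is.null(lineage) && is.null(names(lineage))) {
    stopifnot(length(lineage) == nrow(scores))
    names(lineage) <- rownames(scores)
  }
  dependency_panel(scores, lineage)
}

# Independent textbook step-up BH reference (deliberately not p.adjust):
# sort p ascending, q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, unsort.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    q[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force hypergeometric upper tails by enumerating every size-n draw
# from 1:N against the designated set 1:K. Returns tails for k = 0..n.
enum_hyper_tails <- function(N, n, K) {
  if (n == 0L) return(1)
  draws <- utils::combn(N, n)
  overlaps <- if (n == 1L) as.integer(draws <= K) else colSums(draws <= K)
  vapply(0:n, function(k) mean(overlaps >= k), numeric(1))
}

# Vectors with exact sample correlations r against a common reference:
# Gram-Schmidt construction, used to pin co-expression inputs.
make_correlated <- function(r, n, seed = 1) {
  withr::with_seed(seed, {
    std <- function(v) (v - mean(v)) / stats::sd(v)
    x <- std(stats::rnorm(n))
    partners <- vapply(r, function(ri) {
      w <- stats::rnorm(n)
      w <- std(stats::residuals(stats::lm(w ~ x)))
      ri * x + sqrt(1 - ri^2) * w
    }, numeric(n))
    list(x = x, partners = partners)
  })
}

# Naive double-loop Pearson top-k over all partner genes (absolute mode),
# the brute-force oracle for codependency ranking.
naive_top_codep <- function(scores, gene, k) {
  others <- setdiff(colnames(scores), gene)
  res <- data.frame(gene = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  for (g in others) {
    ok <- !is.na(scores[, gene]) & !is.na(scores[, g])
    x <- scores[ok, gene]; y <- scores[ok, g]
    if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    res <- rbind(res, data.frame(gene = g, r = num / den,
                                 stringsAsFactors = FALSE))
  }
  res <- res[order(-abs(res$r), res$gene), ]
  utils::head(res, k)
}
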