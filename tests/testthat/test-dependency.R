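test_that("dependent fraction counts strict threshold crossings", {
  p1 <- make_dep_panel(matrix(c(-1, -1, -1), 3, 1,
                              dimnames = list(NULL, "A")))
  expect_equal(dependent_fraction(p1, "A", -0.5),
               list(fraction = 1.0, n_dependent = 3L, n_tested = 3L))

  p2 <- make_dep_panel(matrix(c(-0.5, -0.4), 2, 1,
                              dimnames = list(NULL, "A")))
  res <- dependent_fraction(p2, "A", -0.5)
  expect_equal(res$fraction, 0.0)
  expect_equal(res$n_dependent, 0L)

  p3 <- make_dep_panel(matrix(c(-0.6, -0.5, -0.4, NA), 4, 1,
                              dimnames = list(NULL, "A")))
  res3 <- dependent_fraction(p3, "A", -0.5)
  expect_equal(res3$fraction, 1 / 3)
  expect_equal(res3$n_tested, 3L)

  expect_error(dependent_fraction(p3, "B", -0.5), "not in panel")
  p4 <- make_dep_panel(matrix(NA_real_, 2, 1, dimnames = list(NULL, "A")))
  expect_error(dependent_fraction(p4, "A", -0.5), "non-missing")
})

test_that("dependent fraction is invariant under row permutation", {
  set.seed(1)
  m <- matrix(rnorm(40, -0.4, 0.3), 20, 2,
              dimnames = list(sprintf("L%02d", 1:20), c("A", "B")))
  p <- make_dep_panel(m)
  pp <- make_dep_panel(m[sample(nrow(m)), ])
  expect_equal(dependent_fraction(p, "A", -0.5),
               dependent_fraction(pp, "A", -0.5))
})

test_that("essentiality categories follow the first-match rule order", {
  mk <- function(frac, n) {
    x <- rep(-0.1, n)
    x[seq_len(round(frac * n))] <- -1
    make_dep_panel(matrix(x, n, 1, dimnames = list(NULL, "A")))
  }
  expect_equal(summarize_essentiality(mk(0.95, 100), "A")$category, "pan")
  expect_equal(summarize_essentiality(mk(0.31, 100), "A")$category, "strong")
  expect_equal(summarize_essentiality(mk(0.10, 100), "A")$category, "partial")
  # 3 dependent lines out of 700: below the 1% (7-line) bar, above the
  # 3-line rare bar
  x <- rep(-0.1, 700); x[1:3] <- -1
  p <- make_dep_panel(matrix(x, 700, 1, dimnames = list(NULL, "A")))
  expect_equal(summarize_essentiality(p, "A")$category, "rare")
  x2 <- rep(-0.1, 700); x2[1:2] <- -1
  p2 <- make_dep_panel(matrix(x2, 700, 1, dimnames = list(NULL, "A")))
  expect_equal(summarize_essentiality(p2, "A")$category, "none")
  expect_equal(nrow(summarize_essentiality(p, character())), 0L)
})

test_that("lineage contrast matches the hand-computed Welch formula", {
  in_grp <- c(-1.0, -0.8)
  out_grp <- c(-0.2, -0.4)
  scores <- matrix(c(in_grp, out_grp), 4, 1, dimnames = list(NULL, "G"))
  p <- make_dep_panel(scores, c("HN", "HN", "Other", "Other"))
  res <- lineage_contrast(p, "G", "HN",
                          analysis_config(min_lineage_size = 2))
  expect_equal(res$diff, mean(out_grp) - mean(in_grp))
  # Welch by hand
  se <- sqrt(var(in_grp) / 2 + var(out_grp) / 2)
  t_hand <- (mean(out_grp) - mean(in_grp)) / se
  df_hand <- se^4 / ((var(in_grp) / 2)^2 / 1 + (var(out_grp) / 2)^2 / 1)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
})

test_that("identically drawn groups give a near-zero contrast", {
  set.seed(42)
  n <- 200
  scores <- matrix(rnorm(n, -0.4, 0.2), n, 1, dimnames = list(NULL, "G"))
  p <- make_dep_panel(scores, rep(c("A", "B"), each = n / 2))
  res <- lineage_contrast(p, "G", "A")
  expect_lt(abs(res$diff), 0.1)
  expect_gt(res$p, 0.01)
})

test_that("lineage scan applies one BH family, sorts, and reports skips", {
  set.seed(8)
  n <- 60
  scores <- matrix(rnorm(n * 3, -0.3, 0.3), n, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
  p <- make_dep_panel(scores, rep(c("L1", "L2", "L3"), each = n / 3))
  res <- scan_lineages(p, c("A", "B", "C"))
  expect_equal(nrow(res), 9L)
  expect_true(all(res$q >= res$p))
  expect_equal(sort(res$q), sort(p.adjust(res$p, method = "BH")))
  expect_false(is.unsorted(res$q))
  # q is monotone in the p-order
  expect_false(is.unsorted(res$q[order(res$p)]))

  # all in-groups below the minimum size: empty result, complete skip report
  small <- make_dep_panel(scores[1:6, , drop = FALSE],
                          rep(c("L1", "L2"), 3))
  out <- scan_lineages(small, c("A", "B"))
  expect_equal(nrow(out), 0L)
  skipped <- attr(out, "skipped")
  expect_equal(nrow(skipped), 4L)
  expect_true(all(skipped$reason == "in_group_too_small"))
})

test_that("codependency ranking handles identity, sign, and mode", {
  set.seed(3)
  x <- rnorm(30, -0.5, 0.4)
  scores <- cbind(Q = x, IDENT = x, NEG = -x,
                  NOISE = rnorm(30, -0.5, 0.4))
  p <- make_dep_panel(scores)
  prof <- codependency_profile(p, "Q")
  expect_equal(prof$partners$r[prof$partners$gene == "IDENT"], 1.0)
  expect_equal(prof$partners$r[prof$partners$gene == "NEG"], -1.0)
  # absolute mode: IDENT before NEG only by lexicographic tie-break
  expect_equal(prof$partners$gene[1:2], c("IDENT", "NEG"))
  prof_pos <- codependency_profile(
    p, "Q", analysis_config(top_k_mode = "positive"))
  expect_equal(prof_pos$partners$gene[1], "IDENT")
  expect_equal(prof_pos$partners$gene[nrow(prof_pos$partners)], "NEG")
})

test_that("codependency r matches the textbook formula on a toy panel", {
  x <- c(-1.2, -0.8, -0.3, -0.9, -0.1)
  y <- c(-1.0, -0.7, -0.5, -1.1, -0.2)
  p <- make_dep_panel(cbind(Q = x, P = y))
  prof <- codependency_profile(p, "Q",
                               analysis_config(min_codep_overlap = 3))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(prof$partners$r, r_hand, tolerance = 1e-12)
  expect_equal(prof$partners$n, 5L)
})

test_that("constant queries error and constant partners are omitted", {
  scores <- cbind(Q = c(1, 2, 3, 4), FLAT = c(1, 1, 1, 1))
  p <- make_dep_panel(scores)
  expect_error(codependency_profile(make_dep_panel(
    cbind(Q = rep(1, 4), X = 1:4)), "Q"), "constant")
  expect_error(
    expect_message(
      codependency_profile(p, "Q", analysis_config(min_codep_overlap = 3)),
      "zero-variance"
    ),
    "no partner"
  )
})

test_that("absolute top-k equals the naive double-loop oracle", {
  set.seed(12)
  n_genes <- 30
  scores <- matrix(rnorm(50 * n_genes, -0.4, 0.5), 50, n_genes,
                   dimnames = list(NULL, sprintf("G%02d", 1:n_genes)))
  scores[sample(length(scores), 100)] <- NA
  p <- make_dep_panel(scores)
  for (q in c("G01", "G15", "G30")) {
    prof <- codependency_profile(p, q)
    mine <- top_codependents(prof, 7)
    ref <- naive_top_codep(scores, q, 7)
    expect_equal(mine$gene, ref$gene)
    expect_equal(mine$r, ref$r, tolerance = 1e-12)
  }
})

test_that("top_codependents truncates and breaks ties lexicographically", {
  prof <- structure(list(
    query = "Q",
    partners = data.frame(gene = c("A", "B", "C"), r = c(0.5, 0.5, 0.4),
                          n = c(20L, 20L, 20L), stringsAsFactors = FALSE),
    omitted = character()
  ), class = "codependency_profile")
  expect_equal(nrow(top_codependents(prof, 7)), 3L)
  expect_equal(top_codependents(prof, 2)$gene, c("A", "B"))
  # tie ordering is established at profile construction
  set.seed(2)
  x <- rnorm(20)
  p <- make_dep_panel(cbind(Q = x, B = x, A = x))
  prof2 <- codependency_profile(p, "Q")
  expect_equal(prof2$partners$gene, c("A", "B"))
})

test_that("dependency-abundance correlation and cohort medians work", {
  set.seed(6)
  lines <- sprintf("ACH-%06d", 1:40)
  x <- rnorm(40, -0.5, 0.3)
  dep <- dependency_panel(matrix(x, 40, 1, dimnames = list(lines, "A")))
  ab <- abundance_panel(matrix(2 * x + 1, 1, 40,
                               dimnames = list("A", lines)))
  res <- dependency_abundance_correlation(dep, ab, "A")
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_equal(res$n, 40L)

  # closed-form p at n = 5
  x5 <- c(-1, -0.5, 0.1, 0.4, 0.9)
  y5 <- c(-0.8, -0.6, 0.3, 0.1, 1.2)
  dep5 <- dependency_panel(matrix(x5, 5, 1,
                                  dimnames = list(lines[1:5], "A")))
  ab5 <- abundance_panel(matrix(y5, 1, 5,
                                dimnames = list("A", lines[1:5])))
  res5 <- dependency_abundance_correlation(
    dep5, ab5, "A", analysis_config(min_codep_overlap = 3))
  r <- cor(x5, y5)
  t <- r * sqrt(3 / (1 - r^2))
  expect_equal(res5$p, 2 * pt(-abs(t), 3), tolerance = 1e-12)

  # insufficient overlap is a reason-coded skip, not an exception
  ab_na <- abundance_panel(matrix(c(y5[1:2], NA, NA, NA), 1, 5,
                                  dimnames = list("A", lines[1:5])))
  res_skip <- dependency_abundance_correlation(dep5, ab_na, "A")
  expect_equal(res_skip$status, "insufficient_overlap")
  expect_true(is.na(res_skip$r))

  summ <- dependency_abundance_summary(dep, ab, "A")
  expect_equal(summ$median_r, 1.0, tolerance = 1e-12)
})

test_that("Pearson correlation is invariant to positive affine rescaling", {
  set.seed(10)
  x <- rnorm(25); y <- rnorm(25)
  p1 <- make_dep_panel(cbind(Q = x, P = y))
  p2 <- make_dep_panel(cbind(Q = 3 * x - 2, P = 0.5 * y + 7))
  cfg <- analysis_config(min_codep_overlap = 5)
  expect_equal(codependency_profile(p1, "Q", cfg)$partners$r,
               codependency_profile(p2, "Q", cfg)$partners$r,
               tolerance = 1e-12)
})
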