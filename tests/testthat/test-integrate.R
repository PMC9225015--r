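# Small hand-built streams shared by the integration tests.
toy_streams <- function() {
  list(
    codep = data.frame(query = c("Q1", "Q1", "Q2"),
                       partner = c("A", "B", "C"),
                       r = c(0.8, -0.4, 0.6), stringsAsFactors = FALSE),
    sim = data.frame(query = "Q1", partner = "A", stringsAsFactors = FALSE),
    coexpr = data.frame(query = c("Q1", "Q2"), partner = c("A", "D"),
                        stringsAsFactors = FALSE),
    iset = interaction_set(c("Q1", "Q2"), c("A", "C"), "ppi"),
    tested = data.frame(query = c("Q1", "Q1"), partner = c("A", "B"),
                        stringsAsFactors = FALSE)
  )
}

test_that("evidence counts always equal the sum of the four flags", {
  s <- toy_streams()
  ev <- evidence_table(s$codep, s$sim, s$coexpr, s$iset,
                       similarity_tested = s$tested)
  expect_true(all(ev$evidence_count ==
                    ev$codependency + ev$similarity + ev$coexpression +
                    ev$interaction))
  a <- ev[ev$query == "Q1" & ev$partner == "A", ]
  expect_equal(a$evidence_count, 4L)
  b <- ev[ev$query == "Q1" & ev$partner == "B", ]
  expect_equal(b$evidence_count, 1L)
  expect_equal(b$sim_status, "not_similar")
  d <- ev[ev$query == "Q2" & ev$partner == "D", ]
  expect_equal(d$sim_status, "not_tested")
  expect_equal(a$codep_r, 0.8)
  expect_true(is.na(d$codep_r))
})

test_that("exhaustive mode emits zero-count pairs and sorts per query", {
  s <- toy_streams()
  genes <- c("Q1", "Q2", "A", "B", "C", "D", "E")
  ev <- evidence_table(s$codep, s$sim, s$coexpr, s$iset,
                       similarity_tested = s$tested,
                       exhaustive = TRUE, panel_genes = genes)
  expect_equal(nrow(ev), 2L * (length(genes) - 1L))
  e <- ev[ev$query == "Q1" & ev$partner == "E", ]
  expect_equal(e$evidence_count, 0L)
  for (q in c("Q1", "Q2")) {
    sub <- ev[ev$query == q, ]
    expect_false(is.unsorted(-sub$evidence_count))
  }
})

test_that("partners outside the panel namespace warn but are retained", {
  s <- toy_streams()
  expect_warning(
    ev <- evidence_table(s$codep, s$sim, s$coexpr, s$iset,
                         panel_genes = c("Q1", "Q2", "A", "B")),
    "namespace"
  )
  expect_true(all(c("C", "D") %in% ev$partner[!ev$in_panel]))
})

test_that("the ligase network is anchored on co-dependency", {
  s <- toy_streams()
  ev <- evidence_table(s$codep, s$sim, s$coexpr, s$iset,
                       similarity_tested = s$tested)
  net <- ligase_network(ev, c("A", "C", "D"))
  # co-dependent transferases retained with their edge-class flags
  expect_setequal(paste(net$dub, net$partner), c("Q1 A", "Q2 C"))
  expect_true(net$interaction[net$dub == "Q1"])
  # D is coexpression-only: excluded despite being a transferase
  expect_false("D" %in% net$partner)
  # removing the transferase genes empties the network
  expect_equal(nrow(ligase_network(ev, "ZZZ")), 0L)
  expect_error(ligase_network(ev, character()), "empty")
  # network edges are a subset of codependency-flagged evidence pairs
  expect_true(all(paste(net$dub, net$partner) %in%
                    paste(ev$query, ev$partner)[ev$codependency]))
})

test_that("dub summaries are projections of the stream outputs", {
  s <- toy_streams()
  ev <- evidence_table(s$codep, s$sim, s$coexpr, s$iset,
                       similarity_tested = s$tested)
  ess <- data.frame(gene = c("Q1", "Q2", "Q3"),
                    fraction = c(0.95, 0.2, 0.001),
                    n_dependent = c(95L, 20L, 1L),
                    n_tested = c(100L, 100L, 700L),
                    category = c("pan", "partial", "none"),
                    stringsAsFactors = FALSE)
  enr <- data.frame(set_id = c("GOOD", "BAD"), name = c("good", "bad"),
                    k = c(2L, 0L), K = c(4L, 5L), n = 2L, N = 50L,
                    p = c(0.001, 1), q = c(0.002, 1),
                    significant = c(TRUE, FALSE), stringsAsFactors = FALSE)
  su <- dub_summary("Q1", ess, s$codep, list(Q1 = enr), ev)
  expect_equal(su$category, "pan")
  expect_equal(su$top_go_id, "GOOD")
  expect_equal(su$top_go_q, 0.002)
  expect_equal(su$n_evidence_partners, sum(ev$query == "Q1"))
  expect_equal(su$max_evidence, 4L)

  # below the q cutoff nothing is reported
  enr2 <- enr; enr2$q <- c(0.2, 1)
  su2 <- dub_summary("Q1", ess, s$codep, list(Q1 = enr2), ev)
  expect_equal(su2$top_go_id, "none")

  # a gene never profiled for co-dependency carries the explicit marker
  su3 <- dub_summary("Q3", ess, s$codep, list(), ev)
  expect_equal(su3$codep_status, "not analyzed for co-dependency")
  expect_equal(su3$top_go_id, "none")
  expect_error(dub_summary("NOPE", ess, s$codep, list(), ev),
               "missing from the dependency stream")
})

test_that("the file pipeline runs end to end on a simulated bundle", {
  b <- simulate_panel(sim_config(seed = 33L))
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(b, dir)
  res <- suppressMessages(run_pipeline(
    paths[c("dependency", "sample_info", "abundance", "gmt", "ppi", "tau")],
    queries = b$truth$query_genes,
    out_dir = file.path(dir, "out")
  ))
  for (f in c("evidence.tsv", "dub_summary.tsv", "ligase_network.tsv",
              "lineage_scan.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(dir, "out", f)))
  }
  expect_true(all(res$evidence$evidence_count ==
                    res$evidence$codependency + res$evidence$similarity +
                    res$evidence$coexpression + res$evidence$interaction))
  expect_setequal(res$summary$gene, b$truth$query_genes)
  # summaries are projections of the independently queried streams
  ess <- summarize_essentiality(b$dependency, b$truth$query_genes)
  expect_equal(res$summary$fraction,
               ess$fraction[match(res$summary$gene, ess$gene)])
})

test_that("unreadable inputs abort with the failing stage named", {
  b <- simulate_panel(sim_config(n_genes = 25L, n_lines = 40L,
                                 complexes = c(4L, 3L), seed = 44L))
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(b, dir)
  p <- paths[c("dependency", "sample_info", "abundance", "gmt", "ppi",
               "tau")]
  p$abundance <- file.path(dir, "missing.csv")
  expect_error(
    suppressWarnings(suppressMessages(
      run_pipeline(p, b$truth$query_genes,
                   out_dir = file.path(dir, "out")))),
    "read_abundance"
  )
  expect_error(run_pipeline(p[-1], b$truth$query_genes,
                            out_dir = file.path(dir, "out")),
               "missing input paths")
})
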