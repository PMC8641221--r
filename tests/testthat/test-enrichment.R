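test_that("analysis sets merge universes, dedupe symbols, and resolve directions", {
  tr <- toy_diff_table(c("A", "B", "C"), c(TRUE, TRUE, FALSE),
                       c("up", "up", NA), layer = "transcript")
  single <- build_analysis_set(tr)
  expect_setequal(single$universe, c("A", "B", "C"))
  expect_setequal(single$differential, c("A", "B"))

  pr <- toy_diff_table(c("B", "D"), c(TRUE, TRUE), c("down", "up"),
                       layer = "protein")
  both <- build_analysis_set(list(tr, pr))
  expect_setequal(both$universe, c("A", "B", "C", "D"))   # B collapses
  expect_equal(unname(both$direction["B"]), "down")        # protein wins
  expect_equal(both$conflicts, "B")

  t2 <- toy_diff_table(sprintf("x%d", 1:100), rep(TRUE, 100),
                       rep("up", 100))
  p2 <- toy_diff_table(sprintf("y%d", 1:50), rep(TRUE, 50),
                       rep("up", 50), layer = "protein")
  expect_length(build_analysis_set(list(t2, p2))$universe, 150)
})

test_that("connection restriction keeps exactly pairwise-incident differential molecules", {
  kb <- toy_kb()
  expect_setequal(restrict_to_connected(c("A", "B"), kb), c("A", "B"))
  # E's only differential-to-differential path needs C; C alone links to E
  expect_setequal(restrict_to_connected(c("C", "E"), kb), c("C", "E"))
  # differential molecule whose edges all point at non-differential ones
  expect_length(restrict_to_connected("A", kb), 0)
  empty_kb <- knowledge_base(list(P1 = "A"), NULL)
  expect_length(restrict_to_connected(c("A", "B"), empty_kb), 0)
})

test_that("right-tailed Fisher matches direct summation and its edge cases", {
  expect_equal(fisher_right_tail(0, 3, 4, 10), 1)
  expect_equal(fisher_right_tail(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  # denominator effect: same overlap in a doubled universe+list is weaker
  expect_gt(fisher_right_tail(2, 3, 8, 20), fisher_right_tail(2, 3, 4, 10))
  expect_error(fisher_right_tail(5, 3, 4, 10), "inconsistent")
  expect_error(fisher_right_tail(2, 3, 11, 10), "inconsistent")

  set.seed(61)
  for (i in 1:200) {
    N <- sample(5:50, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fisher_right_tail(k, K, n, N),
                 hyper_right_tail_sum(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("enrichment assembles components, skips empty pathways, sorts by p", {
  kb <- toy_kb()
  tr <- toy_diff_table(c("A", "B", "C", "D", "G", "H", "Z1", "Z2"),
                       c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                       c("up", "up", NA, NA, NA, NA, "up", NA))
  aset <- build_analysis_set(tr)
  e <- suppressMessages(enrich(aset, kb))
  # a set whose universe misses a pathway entirely reports the skip
  met <- toy_diff_table("MET001", TRUE, "down", layer = "metabolite")
  expect_message(enrich(build_analysis_set(met), kb), "skipped")
  # P3 members MET001 absent; G,H present -> tested; P1 has A,B connected
  expect_true(all(diff(e$p_value) >= 0))
  p1 <- e[e$pathway == "P1", ]
  expect_equal(p1$K, 4)  # A,B,C,D in universe
  expect_equal(p1$k, 2)  # A,B differential and connected via A-B edge
  expect_equal(p1$n, 3)
  expect_equal(p1$N, 8)
  members <- attr(e, "members")
  expect_setequal(members$P1$molecule, c("A", "B"))
})

test_that("a one-table analysis set enriches identically to the table itself", {
  kb <- toy_kb()
  tr <- toy_diff_table(c("A", "B", "C", "E"), c(TRUE, TRUE, TRUE, FALSE),
                       c("up", "up", "down", NA))
  e1 <- suppressMessages(enrich(build_analysis_set(tr), kb))
  e2 <- suppressMessages(enrich(build_analysis_set(list(tr)), kb))
  expect_equal(as.data.frame(e1), as.data.frame(e2))
})

test_that("differential set equal to the universe gives p = 1 everywhere", {
  kb <- toy_kb()
  ids <- c("A", "B", "C", "D", "E", "F")
  tr <- toy_diff_table(ids, rep(TRUE, 6), rep("up", 6))
  e <- suppressMessages(enrich(build_analysis_set(tr), kb))
  expect_true(all(e$p_value == 1))
})

test_that("growing the combined list with pathway-unmapped molecules weakens every pathway", {
  # the integration mechanism: a further layer contributes analysis-ready
  # molecules; when none of them connects into a pathway, that pathway's
  # p-value can only rise
  kb <- toy_kb()
  tr <- toy_diff_table(c("A", "B", "C", "D", "E", "F"),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       c("up", "up", "down", NA, NA, NA))
  base <- suppressMessages(enrich(build_analysis_set(tr), kb))
  extra <- toy_diff_table(sprintf("unmapped%d", 1:30), rep(TRUE, 30),
                          rep("up", 30), layer = "protein")
  combined <- suppressMessages(enrich(build_analysis_set(list(tr, extra)),
                                      kb))
  idx <- match(base$pathway, combined$pathway)
  expect_true(all(combined$p_value[idx] >= base$p_value - 1e-12))
})

test_that("pathway-scoped connection restriction is available and tighter", {
  kb <- toy_kb()
  # C-E edge exists but E is outside P1; under pathway scope C has no
  # in-pathway differential partner
  tr <- toy_diff_table(c("A", "C", "E", "F"), c(FALSE, TRUE, TRUE, FALSE),
                       c(NA, "down", "down", NA))
  g <- suppressMessages(enrich(build_analysis_set(tr), kb,
                               connection_scope = "global"))
  p <- suppressMessages(enrich(build_analysis_set(tr), kb,
                               connection_scope = "pathway"))
  expect_equal(g[g$pathway == "P1", "k"], 1)  # C via global C-E link
  expect_equal(p[p$pathway == "P1", "k"], 0)
  expect_true(all(p$k <= g$k[match(p$pathway, g$pathway)]))
})

test_that("combination comparison keeps absent pathways and rejects label collisions", {
  kb <- toy_kb()
  tr <- toy_diff_table(c("A", "B", "C", "G"), c(TRUE, TRUE, FALSE, FALSE),
                       c("up", "up", NA, NA))
  met <- toy_diff_table("MET001", TRUE, "down", layer = "metabolite")
  e1 <- suppressMessages(enrich(build_analysis_set(tr), kb))
  e2 <- suppressMessages(enrich(build_analysis_set(met), kb))
  cmp <- compare_combinations(list(genes = e1, metabolites = e2))
  expect_equal(nrow(cmp), 2 * length(union(e1$pathway, e2$pathway)))
  # P1 is untestable for the metabolite-only set but keeps a row
  expect_true(is.na(cmp$p_value[cmp$label == "metabolites" &
                                cmp$pathway == "P1"]))
  expect_error(compare_combinations(list(x = e1, x = e2)), "collision")

  plot_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(plot_file)
  plot(cmp)
  grDevices::dev.off()
  expect_gt(file.size(plot_file), 0)
})
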