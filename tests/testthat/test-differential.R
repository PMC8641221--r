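test_that("zero-count filtering removes exactly the all-zero features", {
  groups <- two_group(5)
  m <- rbind(allzero = rep(0L, 10),
             oneread = c(1L, rep(0L, 9)),
             busy = rpois(10, 50))
  colnames(m) <- names(groups)
  lay <- omics_layer(m, "transcript", groups)
  kept <- filter_transcripts(lay)
  expect_setequal(rownames(kept$values), c("oneread", "busy"))

  empty <- layer_subset(lay, character())
  expect_equal(nrow(filter_transcripts(empty)$values), 0)
})

test_that("TMM factors behave under symmetry, scaling, and match edgeR", {
  groups <- two_group(2)
  m <- matrix(rep(rpois(50, 30), 4), ncol = 4,
              dimnames = list(sprintf("g%d", 1:50), names(groups)))
  f <- tmm_normalize(omics_layer(m, "transcript", groups))$factors
  expect_equal(unname(f), rep(1, 4))  # identical samples

  set.seed(1)
  a <- rpois(200, 40)
  m2 <- cbind(a, 2L * a, a, 2L * a)
  dimnames(m2) <- list(sprintf("g%d", 1:200), names(groups))
  norm <- tmm_normalize(omics_layer(m2, "transcript", groups))$layer$values
  expect_lt(max(abs(norm[, 1] - norm[, 2])), 1e-9)  # pure depth difference

  set.seed(7)
  m3 <- matrix(rnbinom(200 * 6, mu = exp(rnorm(1200, 5, 1)), size = 5),
               200, 6, dimnames = list(sprintf("g%d", 1:200),
                                       names(two_group(3))))
  lay3 <- omics_layer(m3, "transcript", two_group(3))
  f3 <- tmm_normalize(lay3)$factors
  expect_lt(abs(exp(mean(log(f3))) - 1), 1e-9)  # geometric mean 1
  # independent implementation of the same published procedure
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m3))$samples$norm.factors
  expect_lt(max(abs(unname(f3) - f_ref)), 1e-8)

  m4 <- m3; m4[, 2] <- 0L
  expect_error(tmm_normalize(omics_layer(m4, "transcript", two_group(3))),
               "all-zero sample")
})

test_that("equal-variance t-tests agree between raw-data and summary forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ttest_equal_var(x, x)$t, 0)
  expect_equal(ttest_equal_var(x, x)$p, 1)

  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2))
    t1 <- ttest_equal_var(a, b)
    t2 <- ttest_from_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_equal(t1$t, t2$t, tolerance = 1e-12)
    expect_equal(t1$p, t2$p, tolerance = 1e-12)
    ref <- stats::t.test(b, a, var.equal = TRUE)
    expect_equal(t1$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(t1$p, ref$p.value, tolerance = 1e-10)
  }

  # constant vectors: undefined result is flagged, not thrown
  z <- ttest_equal_var(c(2, 2, 2), c(2, 2, 2))
  expect_true(is.na(z$t) && is.na(z$p))
})

test_that("t p-value matches direct numerical integration of the t density", {
  r <- ttest_equal_var(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  tail_mass <- stats::integrate(function(u) stats::dt(u, df = 8),
                                lower = abs(r$t), upper = Inf,
                                rel.tol = 1e-12)$value
  expect_equal(r$p, 2 * tail_mass, tolerance = 1e-10)
})

test_that("clinical group summaries reproduce the recorded p-values", {
  f <- system.file("extdata", "clinical_summary.tsv",
                   package = "integromics")
  tab <- read.delim(f)
  res <- ttest_from_summary(tab$control_mean, tab$control_sd, tab$control_n,
                            tab$treatment_mean, tab$treatment_sd,
                            tab$treatment_n)
  key <- c("total_cholesterol", "alt", "alp", "ggtp", "ast", "glucose")
  idx <- match(key, tab$measure)
  expect_equal(round(res$p[idx], 3), tab$printed_p[idx])
})

test_that("protein presence filter implements both retention branches", {
  groups <- two_group(5)
  mk <- function(oc, ot) {  # observation counts per group
    v <- c(ifelse(seq_len(5) <= oc, 2.0, NA), ifelse(seq_len(5) <= ot, 3.0, NA))
    v
  }
  m <- rbind(testable = mk(3, 4), exclusive = mk(0, 5), dropped = mk(2, 5),
             full = mk(5, 5))
  colnames(m) <- names(groups)
  fp <- filter_proteins_presence(omics_layer(m, "protein", groups))
  expect_setequal(names(fp$exclusivity), c("testable", "exclusive", "full"))
  expect_equal(unname(fp$exclusivity[c("testable", "full")]),
               c("none", "none"))
  expect_equal(unname(fp$exclusivity["exclusive"]), "exclusive_treatment")

  expect_error(filter_proteins_presence(
    omics_layer(m[, c(1, 2, 6, 7)], "protein", groups[c(1, 2, 6, 7)])),
    ">= 3")
})

test_that("sequential imputation is identity on complete data and never touches observed cells", {
  groups <- two_group(5)
  set.seed(21)
  m <- matrix(rnorm(40 * 10, 14, 1), 40, 10,
              dimnames = list(sprintf("p%d", 1:40), names(groups)))
  lay <- omics_layer(exp(m), "protein", groups)
  loglay <- log_transform(lay)
  expect_equal(impute_sequential(loglay)$values, loglay$values)

  m2 <- m
  mask <- matrix(runif(length(m2)) < 0.08, nrow(m2))
  # cap at 2 missing per group to satisfy the bound
  for (g in list(1:5, 6:10))
    for (i in seq_len(nrow(m2))) {
      w <- which(mask[i, g]); if (length(w) > 2) mask[i, g[w[-(1:2)]]] <- FALSE
    }
  m2[mask] <- NA
  lay2 <- lay; lay2$values <- m2
  done <- impute_sequential(lay2)
  expect_false(anyNA(done$values))
  expect_equal(done$values[!mask], m2[!mask])
})

test_that("imputation degenerates to the group mean when predictors are flat", {
  groups <- two_group(5)
  m <- rbind(target = c(1, 2, NA, 4, 3, rep(4, 5)),
             flat1 = rep(5, 10), flat2 = rep(7, 10))
  colnames(m) <- names(groups)
  lay <- omics_layer(m, "protein", groups)
  done <- impute_sequential(lay)
  expect_equal(done$values["target", 3], mean(c(1, 2, 4, 3)),
               tolerance = 1e-8)
})

test_that("imputation violating the missingness bound names the feature", {
  groups <- two_group(5)
  m <- matrix(3, 4, 10, dimnames = list(sprintf("p%d", 1:4), names(groups)))
  m["p2", 1:3] <- NA
  expect_error(impute_sequential(omics_layer(m, "protein", groups)), "p2")
})

test_that("regression imputation beats group-mean imputation on correlated data", {
  # ground-truth oracle: mask cells of a known complete matrix and compare
  # recovered values; features share a per-sample latent factor
  set.seed(31)
  groups <- two_group(5)
  f <- rnorm(10)
  truth <- outer(rnorm(50, 1, 0.3), f) + matrix(rnorm(500, 0, 0.3), 50)
  truth <- truth + 14
  dimnames(truth) <- list(sprintf("p%d", 1:50), names(groups))
  mask <- matrix(FALSE, 50, 10, dimnames = dimnames(truth))
  for (g in list(1:5, 6:10))
    for (i in 1:50)
      if (runif(1) < 0.4) mask[i, sample(g, sample(1:2, 1))] <- TRUE
  x <- truth; x[mask] <- NA
  lay <- omics_layer(exp(x), "protein", groups)
  seq_done <- impute_sequential(log_transform(lay))$values
  mean_done <- x
  for (g in list(1:5, 6:10)) {
    gm <- rowMeans(x[, g], na.rm = TRUE)
    for (j in g) mean_done[is.na(x[, j]), j] <- gm[is.na(x[, j])]
  }
  err_seq <- mean(abs(seq_done[mask] - truth[mask]))
  err_mean <- mean(abs(mean_done[mask] - truth[mask]))
  expect_lt(err_seq, err_mean)
})

test_that("log transform maps 1 to 0, e to 1, keeps NA, rejects non-positive", {
  groups <- two_group(2)
  m <- matrix(c(1, exp(1), NA, 2, 2, 2, 2, 2), 2, 4,
              dimnames = list(c("a", "b"), names(groups)))
  out <- log_transform(omics_layer(m, "protein", groups))
  expect_equal(out$values["a", 1], 0)
  expect_equal(out$values["b", 1], 1)
  expect_true(is.na(out$values["a", 2]))
  m[1, 1] <- 0
  expect_error(log_transform(omics_layer(m, "protein", groups)), "positive")
})

test_that("one-component VIP satisfies its algebraic identities and ranks signal over noise", {
  groups <- two_group(5)
  one <- matrix(c(rnorm(5, 0), rnorm(5, 3)), 1, 10,
                dimnames = list("only", names(groups)))
  expect_equal(unname(pls_vip(omics_layer(abs(one) + 10, "metabolite",
                                          groups))), 1)

  set.seed(41)
  m <- matrix(abs(rnorm(20 * 10, 10, 2)), 20, 10,
              dimnames = list(sprintf("f%d", 1:20), names(groups)))
  v <- pls_vip(omics_layer(m, "metabolite", groups))
  expect_equal(mean(v^2), 1, tolerance = 1e-9)

  big <- two_group(100)
  sig <- c(rnorm(100, 10), rnorm(100, 14))
  noise <- rnorm(200, 12)
  m2 <- rbind(signal = sig, noise = noise)
  colnames(m2) <- names(big)
  v2 <- pls_vip(omics_layer(abs(m2), "metabolite", big))
  expect_gt(v2[["signal"]], 1)
  expect_lt(v2[["noise"]], 1)

  m3 <- rbind(m, flat = rep(3, 10))
  expect_warning(v3 <- pls_vip(omics_layer(m3, "metabolite", groups)),
                 "zero-variance")
  expect_equal(unname(v3["flat"]), 0)
})

test_that("VIP matches an independent PLS-DA implementation", {
  set.seed(43)
  groups <- two_group(5)
  m <- matrix(abs(rnorm(30 * 10, 10, 2)), 30, 10,
              dimnames = list(sprintf("f%d", 1:30), names(groups)))
  v1 <- pls_vip(omics_layer(m, "metabolite", groups))
  fit <- mixOmics::plsda(t(m), factor(unname(groups)), ncomp = 1,
                         scale = TRUE)
  v2 <- mixOmics::vip(fit)[, 1]
  expect_equal(unname(v1), unname(v2[names(v1)]), tolerance = 1e-8)
})

test_that("metabolite selection is the strict joint VIP/p rule", {
  sel <- select_metabolites(c("a", "b", "c"), vip = c(1.2, 0.9, 1.2),
                            p = c(0.01, 0.001, 0.06), ratio = c(2, 2, 2))
  expect_equal(sel, c(TRUE, FALSE, FALSE))
})

test_that("run_layer marks group-exclusive proteins differential without a test", {
  groups <- two_group(5)
  set.seed(51)
  m <- matrix(exp(rnorm(200, 14, 0.3)), 20, 10,
              dimnames = list(sprintf("p%d", 1:20), names(groups)))
  m["p7", 1:5] <- NA  # control missing -> treatment-exclusive
  tab <- run_layer(omics_layer(m, "protein", groups))
  row <- tab[tab$id == "p7", ]
  expect_equal(row$direction, "exclusive_treatment")
  expect_true(row$differential)
  expect_equal(row$ratio, Inf)
  expect_true(is.na(row$p))
  expect_true(all(tab$differential <= tab$passed_quality))
})

test_that("planted count effects are detected with high power at n=5", {
  # power oracle: repeated small simulations with a strong planted effect
  hits <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s, n_transcripts = 200L, n_proteins = 50L,
                      n_metabolites = 30L, n_mirnas = 20L, n_pathways = 4L,
                      pathway_size_range = c(10L, 15L),
                      planted_pathways = data.frame(
                        pathway = "PW01", effect_size = 2,
                        affected_fraction = 1),
                      n_planted_regulators = 0L, n_planted_mirnas = 0L)
    kb <- make_knowledge_base(cfg)
    lay <- simulate_layers(cfg, kb)$transcript
    truth <- attr(kb, "truth")
    planted <- intersect(names(truth$lfc)[truth$lfc != 0],
                         rownames(lay$values))
    tab <- run_layer(lay)
    mean(tab$differential[match(planted, tab$id)])
  }, 0)
  expect_gt(mean(hits), 0.8)
})

test_that("the imputed protein chain is anti-conservative under missingness", {
  # deterministic imputation shrinks within-group variance, so the
  # unadjusted t-test chain over-rejects on null data with missing cells --
  # a documented limitation of impute-then-test at n=5
  cfg <- null_config(seed = 2, n_transcripts = 800L, n_proteins = 800L,
                     n_metabolites = 30L, n_mirnas = 20L)
  kb <- make_knowledge_base(cfg)
  layers <- simulate_layers(cfg, kb)
  tab <- run_layer(layers$protein)
  rate <- mean(tab$p[!is.na(tab$p)] < 0.05)
  expect_gt(rate, 0.05)
})

test_that("duplicate protein ids are summed with missing-aware semantics", {
  m <- matrix(c(1, 2, NA, 4, NA, NA), 3, 2,
              dimnames = list(c("A", "A", "B"), c("s1", "s2")))
  out <- sum_duplicate_ids(m)
  expect_equal(out["A", ], c(s1 = 3, s2 = 4))
  expect_true(all(is.na(out["B", ])))
})
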