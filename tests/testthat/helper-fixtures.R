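# Shared in-code fixtures: a hand-wired toy knowledge base and layers small
# enough to reason about by eye, plus a scaled-down simulation config used
# where a full-size study would be wasteful.

two_group <- function(n = 5) {
  stats::setNames(rep(c("control", "treatment"), each = n),
                  c(sprintf("CON%d", seq_len(n)), sprintf("HFR%d", seq_len(n))))
}

toy_kb <- function() {
  pathways <- list(P1 = c("A", "B", "C", "D"),
                   P2 = c("C", "D", "E", "F"),
                   P3 = c("MET001", "G", "H"))
  edges <- data.frame(
    source = c("A", "B", "C", "TF01", "TF01", "TF01", "TF02", "TF02"),
    target = c("B", "C", "E", "A",    "B",    "C",    "E",    "F"),
    sign = c(1L, 1L, -1L, 1L, 1L, -1L, 1L, 1L),
    relation = c(rep("interacts", 3), rep("regulates", 5)),
    tissue_evidence = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  mt <- data.frame(
    mirna = c("miR-001", "miR-001", "miR-002", "miR-003"),
    target = c("A", "B", "C", "E"),
    evidence = c("validated", "high_predicted", "validated", "low_predicted"),
    stringsAsFactors = FALSE)
  knowledge_base(pathways, edges, mt)
}

# a differential table assembled directly (bypasses run_layer) for tests that
# need exact control over statuses and directions
toy_diff_table <- function(ids, differential, direction, layer = "transcript",
                           passed = rep(TRUE, length(ids)), alpha = 0.05) {
  df <- data.frame(id = ids, layer = layer,
                   mean_control = 1, mean_treatment = 1, ratio = 1,
                   direction = direction, t = NA_real_,
                   p = ifelse(differential, 0.01, 0.5), vip = NA_real_,
                   passed_quality = passed,
                   differential = differential & passed,
                   stringsAsFactors = FALSE)
  structure(df, class = c("differential_table", "data.frame"),
            layer_kind = layer, alpha = alpha)
}

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_transcripts = 400L, n_proteins = 150L,
             n_metabolites = 80L, n_mirnas = 60L, n_pathways = 12L,
             pathway_size_range = c(8L, 15L), n_regulators = 5L,
             targets_per_regulator = 10L, n_planted_mirnas = 6L, ...)
}

null_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             planted_pathways = data.frame(pathway = character(),
                                           effect_size = numeric(),
                                           affected_fraction = numeric()),
             n_planted_regulators = 0L, n_planted_mirnas = 0L, ...)
}

# direct hypergeometric right-tail by explicit summation (log-scale terms),
# kept independent of fisher_right_tail's phyper route
hyper_right_tail_sum <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  terms <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}
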