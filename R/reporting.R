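# Cross-omics set comparisons, trait overlap, and the end-to-end driver.
# The layer-combination schedule is fixed: each single layer, then
# transcript+protein, then transcript+protein+metabolite; miRNAs are merged
# last by inverse-expression pairing without re-testing.

dir_sign_num <- function(d)
  ifelse(d %in% c("up", "exclusive_treatment"), 1L,
         ifelse(d %in% c("down", "exclusive_control"), -1L, NA_integer_))

#' Venn-style comparison of two differential tables
#'
#' Splits the shared symbol space into common / A-only / B-only, either on
#' molecules passing quality filters (`mode = "expressed"`) or on
#' differential molecules (`mode = "differential"`). Common molecules are
#' annotated concordant or discordant by the sign of their abundance ratios.
#'
#' @param table_a,table_b `differential_table`s keyed by shared symbols.
#' @param mode `"expressed"` or `"differential"`.
#' @return list of class `venn_compare`: `common` (data frame with
#'   `concordant` flag), `only_a`, `only_b`, and the two labels.
#' @export
venn_compare <- function(table_a, table_b,
                         mode = c("expressed", "differential")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table_a, "differential_table"),
            inherits(table_b, "differential_table"))
  pick <- function(tb) if (mode == "expressed") tb$id[tb$passed_quality]
                       else tb$id[tb$differential]
  a <- pick(table_a); b <- pick(table_b)
  common <- intersect(a, b)
  da <- dir_sign_num(table_a$direction[match(common, table_a$id)])
  db <- dir_sign_num(table_b$direction[match(common, table_b$id)])
  structure(list(
    common = data.frame(id = common, direction_a = da, direction_b = db,
                        concordant = !is.na(da) & !is.na(db) & da == db,
                        stringsAsFactors = FALSE),
    only_a = setdiff(a, b), only_b = setdiff(b, a),
    labels = c(attr(table_a, "layer_kind"), attr(table_b, "layer_kind")),
    mode = mode), class = "venn_compare")
}

#' @export
print.venn_compare <- function(x, ...) {
  cat(sprintf("<venn_compare: %s vs %s, %s> common %d (%d concordant), only-%s %d, only-%s %d\n",
              x$labels[1], x$labels[2], x$mode, nrow(x$common),
              sum(x$common$concordant), x$labels[1], length(x$only_a),
              x$labels[2], length(x$only_b)))
  invisible(x)
}

#' Overlap differential molecules with GWAS trait associations
#'
#' One output row per gene found both differential and trait-associated,
#' with its traits and variants aggregated. With
#' `scope = "enriched_only"`, the gene must additionally appear among the
#' counted molecules of a significant pathway or the differential direct
#' targets of a network with significant overlap, and those sets are
#' listed.
#'
#' @param diff_ids character vector of differential molecule ids (genes,
#'   proteins, miRNAs share the symbol space).
#' @param traits a `trait_table`.
#' @param scope `"all"` or `"enriched_only"`.
#' @param enrichment an `enrichment` result; required for
#'   `"enriched_only"`.
#' @param calls an `activation_calls` result; optional extra sets for
#'   `"enriched_only"`.
#' @return data frame (gene, traits, variants, sets) of class
#'   `gwas_overlap`.
#' @export
gwas_overlap <- function(diff_ids, traits, scope = c("all", "enriched_only"),
                         enrichment = NULL, calls = NULL) {
  scope <- match.arg(scope)
  hits <- traits[traits$gene %in% diff_ids, , drop = FALSE]
  sets_of <- NULL
  if (scope == "enriched_only") {
    if (is.null(enrichment))
      stop("scope = 'enriched_only' needs an enrichment result")
    members <- attr(enrichment, "members")
    sig <- enrichment$pathway[enrichment$significant]
    sets_of <- list()
    for (pw in sig)
      for (mol in members[[pw]]$molecule)
        sets_of[[mol]] <- c(sets_of[[mol]], pw)
    if (!is.null(calls)) {
      tg <- attr(calls, "targets")
      for (r in calls$regulator[calls$p_value < attr(calls, "alpha")])
        for (mol in tg[[r]])
          sets_of[[mol]] <- c(sets_of[[mol]], paste0(r, " network"))
    }
    hits <- hits[hits$gene %in% names(sets_of), , drop = FALSE]
  }
  genes <- unique(hits$gene)
  out <- data.frame(
    gene = genes,
    traits = vapply(genes, function(g)
      paste(sort(unique(hits$trait[hits$gene == g])), collapse = "; "), ""),
    variants = vapply(genes, function(g)
      paste(sort(unique(hits$variant[hits$gene == g])), collapse = "; "), ""),
    sets = if (is.null(sets_of)) rep(NA_character_, length(genes)) else
      vapply(genes, function(g)
        paste(sort(unique(sets_of[[g]])), collapse = "; "), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gwas_overlap", "data.frame"), scope = scope)
}

#' Run the full synthetic-study pipeline
#'
#' Generates (or accepts) a knowledge base and four layers, runs per-layer
#' differential abundance, builds the fixed schedule of analysis sets
#' (transcript, protein, metabolite, transcript+protein,
#' transcript+protein+metabolite), enriches and calls regulator networks on
#' each, pairs miRNAs by inverse expression against the fully combined set,
#' merges pairs into the combined results, compares combinations, and
#' overlaps differential molecules with the trait table. Deterministic
#' given the config seed.
#'
#' @param config a `sim_config`.
#' @param alpha unadjusted per-feature significance threshold.
#' @param kb,layers,traits optional pre-built inputs (defaults are
#'   generated from `config`).
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return a `run_report`: list with the config, differential tables,
#'   enrichments and activation calls per combination, the comparison
#'   table, inverse pairs, merged miRNA annotations, the venn comparison,
#'   trait overlaps, per-layer counts, and the package version.
#' @export
run_pipeline <- function(config, alpha = 0.05, kb = NULL, layers = NULL,
                         traits = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(kb)) kb <- make_knowledge_base(config)
  if (is.null(layers)) layers <- simulate_layers(config, kb)
  if (is.null(traits)) traits <- make_trait_table(config, kb)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    r
  }
  diffs <- stage("differential", lapply(layers, run_layer, alpha = alpha))
  sets <- stage("analysis sets", list(
    transcript = build_analysis_set(diffs$transcript),
    protein = build_analysis_set(diffs$protein),
    metabolite = build_analysis_set(diffs$metabolite),
    `transcript+protein` =
      build_analysis_set(diffs[c("transcript", "protein")]),
    `transcript+protein+metabolite` =
      build_analysis_set(diffs[c("transcript", "protein", "metabolite")])))
  enrichments <- stage("enrichment",
                       lapply(sets, enrich, kb = kb, alpha = alpha))
  calls <- stage("networks", lapply(sets, call_networks, kb = kb,
                                    alpha = alpha))
  comparison <- stage("comparison", compare_combinations(enrichments))
  combined <- sets$`transcript+protein+metabolite`
  pairs <- stage("miRNA pairing",
                 find_inverse_pairs(diffs$mirna, combined, kb))
  merged <- stage("miRNA merge",
                  merge_pairs(pairs,
                              enrichments$`transcript+protein+metabolite`,
                              calls$`transcript+protein+metabolite`))
  venn <- stage("venn", venn_compare(diffs$transcript, diffs$protein,
                                     mode = "differential"))
  gwas <- stage("trait overlap", list(
    all = gwas_overlap(unique(c(combined$differential,
                                diffs$mirna$id[diffs$mirna$differential])),
                       traits, scope = "all"),
    enriched_only = gwas_overlap(
      combined$differential, traits, scope = "enriched_only",
      enrichment = enrichments$`transcript+protein+metabolite`,
      calls = calls$`transcript+protein+metabolite`)))
  layer_counts <- data.frame(
    layer = names(diffs),
    passed_quality = vapply(diffs, function(d) sum(d$passed_quality), 0L),
    differential = vapply(diffs, function(d) sum(d$differential), 0L),
    stringsAsFactors = FALSE)
  rownames(layer_counts) <- NULL
  report <- structure(list(
    config = config, seed = config$seed, alpha = alpha,
    version = as.character(utils::packageVersion("integromics")),
    diff_tables = diffs, analysis_sets = sets, enrichments = enrichments,
    calls = calls, comparison = comparison, pairs = pairs, merged = merged,
    venn = venn, gwas = gwas, layer_counts = layer_counts),
    class = "run_report")
  audit_report(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Self-consistency audit of a run report
#'
#' Recounts every summary number in the report from its attached tables
#' (per-layer counts, enrichment overlap bounds, pair counts, merge
#' attachment counts) and errors on the first mismatch. Called
#' automatically by [run_pipeline()].
#'
#' @param report a `run_report`.
#' @return `TRUE`, invisibly.
#' @export
audit_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  chk <- function(ok, what) if (!ok) stop("report audit failed: ", what)
  for (i in seq_len(nrow(report$layer_counts))) {
    d <- report$diff_tables[[report$layer_counts$layer[i]]]
    chk(report$layer_counts$passed_quality[i] == sum(d$passed_quality),
        "passed_quality recount")
    chk(report$layer_counts$differential[i] == sum(d$differential),
        "differential recount")
    chk(all(d$differential <= d$passed_quality), "differential without quality")
  }
  for (nm in names(report$enrichments)) {
    e <- report$enrichments[[nm]]
    aset <- report$analysis_sets[[nm]]
    chk(all(e$k <= pmin(e$K, e$n)), "overlap exceeds margins")
    chk(all(e$N == length(aset$universe)), "universe size recount")
    chk(all(e$n == length(aset$differential)), "differential size recount")
    members <- attr(e, "members")
    chk(all(vapply(e$pathway, function(p) nrow(members[[p]]), 0L) == e$k),
        "member list vs k recount")
  }
  s <- pair_count_summary(report$pairs)
  chk(s[["pairs"]] == nrow(report$pairs), "pair recount")
  chk(s[["mirnas"]] == length(unique(report$pairs$mirna)), "miRNA recount")
  invisible(TRUE)
}

#' Write all report tables as TSV
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) {
    utils::write.table(as.data.frame(df), file.path(out_dir, f),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    file.path(out_dir, f)
  }
  paths <- c(
    vapply(names(report$diff_tables), function(nm)
      wt(report$diff_tables[[nm]], paste0("diff_", nm, ".tsv")), ""),
    vapply(names(report$enrichments), function(nm)
      wt(report$enrichments[[nm]],
         paste0("enrichment_", gsub("[+]", "_", nm), ".tsv")), ""),
    vapply(names(report$calls), function(nm)
      wt(report$calls[[nm]], paste0("networks_", gsub("[+]", "_", nm),
                                    ".tsv")), ""),
    wt(report$comparison, "comparison.tsv"),
    wt(report$pairs, "inverse_pairs.tsv"),
    wt(report$merged$counts, "mirna_merge_counts.tsv"),
    wt(report$gwas$all, "gwas_overlap_all.tsv"),
    wt(report$gwas$enriched_only, "gwas_overlap_enriched.tsv"),
    wt(report$layer_counts, "layer_counts.tsv"))
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> integromics %s, seed %d, alpha %g\n",
              x$version, x$seed, x$alpha))
  cat("layers:\n")
  print(x$layer_counts, row.names = FALSE)
  cat("significant pathways per combination:\n")
  for (nm in names(x$enrichments))
    cat(sprintf("  %-32s %d of %d\n", nm, sum(x$enrichments[[nm]]$significant),
                nrow(x$enrichments[[nm]])))
  calls <- x$calls$`transcript+protein+metabolite`
  cat(sprintf("network calls (combined): %d activated, %d inhibited\n",
              sum(calls$state == "activated"),
              sum(calls$state == "inhibited")))
  s <- pair_count_summary(x$pairs)
  cat(sprintf("inverse pairs: %d pairs over %d miRNAs and %d targets\n",
              s[["pairs"]], s[["mirnas"]], s[["targets"]]))
  invisible(x)
}

#' @export
summary.run_report <- function(object, ...) {
  print(object)
  cat("\ntop combined pathways:\n")
  print(utils::head(as.data.frame(
    object$enrichments$`transcript+protein+metabolite`), 5),
    row.names = FALSE)
  cat("\nregulator calls (combined):\n")
  print(as.data.frame(object$calls$`transcript+protein+metabolite`),
        row.names = FALSE)
  invisible(object)
}
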