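# Inverse-expression miRNA-target pairing. A pair is a differential miRNA
# and a differential gene/protein target with strictly opposite directions,
# connected by an experimentally validated or highly predicted targeting
# edge; pairs are then merged into already-enriched pathways and networks
# without re-testing (the pairing adds molecules, not statistics).

#' Find inverse-expression miRNA-target pairs
#'
#' Emits every (miRNA, target) edge where the miRNA is differential, the
#' target is differential in the analysis set with a resolved (non-conflict)
#' direction, the two directions are strictly opposite, and the edge
#' evidence is `validated` or `high_predicted`. Deduplicated on
#' (miRNA, target).
#'
#' @param mirna_table the miRNA `differential_table`.
#' @param aset an `analysis_set` over the gene/protein (and metabolite)
#'   layers supplying target directions and layer provenance.
#' @param kb a `knowledge_base` with `mirna_targets` edges.
#' @return an `inverse_pairs` data frame: mirna, target, target_layers,
#'   mirna_direction, target_direction, evidence.
#' @export
find_inverse_pairs <- function(mirna_table, aset, kb) {
  stopifnot(inherits(mirna_table, "differential_table"),
            inherits(aset, "analysis_set"))
  mt <- if (inherits(kb, "knowledge_base")) kb$mirna_targets else kb
  empty <- data.frame(mirna = character(), target = character(),
                      target_layers = character(),
                      mirna_direction = character(),
                      target_direction = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  mdir <- stats::setNames(mirna_table$direction[mirna_table$differential],
                          mirna_table$id[mirna_table$differential])
  usable_targets <- setdiff(aset$differential, aset$conflicts)
  keep <- mt$evidence %in% c("validated", "high_predicted") &
    mt$mirna %in% names(mdir) & mt$target %in% usable_targets
  mt <- mt[keep, , drop = FALSE]
  mt <- mt[!duplicated(paste(mt$mirna, mt$target, sep = "\r")), ,
           drop = FALSE]
  if (!nrow(mt)) return(structure(empty, class = c("inverse_pairs",
                                                   "data.frame")))
  tdir <- aset$direction[mt$target]
  inv <- mdir[mt$mirna] != tdir
  mt <- mt[inv, , drop = FALSE]
  out <- data.frame(
    mirna = mt$mirna, target = mt$target,
    target_layers = vapply(aset$diff_layers[mt$target],
                           function(l) paste(sort(unique(l)),
                                             collapse = "+"), ""),
    mirna_direction = unname(mdir[mt$mirna]),
    target_direction = unname(aset$direction[mt$target]),
    evidence = mt$evidence, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("inverse_pairs", "data.frame"))
}

#' @export
print.inverse_pairs <- function(x, ...) {
  s <- pair_count_summary(x)
  cat(sprintf("<inverse_pairs> %d pairs over %d miRNAs and %d targets\n",
              s[["pairs"]], s[["mirnas"]], s[["targets"]]))
  NextMethod()
}

#' Distinct pair / miRNA / target counts
#' @param pairs an `inverse_pairs` data frame.
#' @return named integer vector `pairs`, `mirnas`, `targets`.
#' @export
pair_count_summary <- function(pairs) {
  c(pairs = nrow(pairs),
    mirnas = length(unique(pairs$mirna)),
    targets = length(unique(pairs$target)))
}

#' Merge inverse pairs into enriched pathways and networks
#'
#' Attaches each pair to every significant pathway whose counted molecules
#' include its target, and to every called (or significant-overlap) network
#' whose differential direct targets include it. A miRNA targeting members
#' of several sets is attached to each. P-values are not recomputed: the
#' pairing layer annotates, it does not test. Pairs matching no significant
#' set are listed under `unassigned`.
#'
#' @param pairs an `inverse_pairs` table.
#' @param enrichment an `enrichment` result (with member lists).
#' @param calls an `activation_calls` result (with target lists), optional.
#' @return list of class `mirna_merge`: `pathway_pairs`, `network_pairs`,
#'   `unassigned`, and `counts` (per set: molecules with and without
#'   miRNAs).
#' @export
merge_pairs <- function(pairs, enrichment, calls = NULL) {
  stopifnot(inherits(pairs, "inverse_pairs"),
            inherits(enrichment, "enrichment"))
  members <- attr(enrichment, "members")
  sig_pw <- enrichment$pathway[enrichment$significant]
  pw_rows <- list(); counts <- list(); assigned <- logical(nrow(pairs))
  for (pw in sig_pw) {
    mem <- members[[pw]]$molecule
    hit <- pairs$target %in% mem
    assigned <- assigned | hit
    if (any(hit))
      pw_rows[[pw]] <- cbind(set = pw, set_type = "pathway",
                             pairs[hit, , drop = FALSE])
    counts[[pw]] <- data.frame(
      set = pw, set_type = "pathway", n_molecules = length(mem),
      n_with_mirna = length(mem) + length(unique(pairs$mirna[hit])),
      stringsAsFactors = FALSE)
  }
  nw_rows <- list()
  if (!is.null(calls)) {
    stopifnot(inherits(calls, "activation_calls"))
    targets <- attr(calls, "targets")
    sig_nw <- calls$regulator[calls$p_value < attr(calls, "alpha")]
    for (r in sig_nw) {
      tg <- targets[[r]]
      hit <- pairs$target %in% tg
      assigned <- assigned | hit
      if (any(hit))
        nw_rows[[r]] <- cbind(set = r, set_type = "network",
                              pairs[hit, , drop = FALSE])
      counts[[paste0("nw_", r)]] <- data.frame(
        set = r, set_type = "network", n_molecules = length(tg),
        n_with_mirna = length(tg) + length(unique(pairs$mirna[hit])),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, template) {
    out <- do.call(rbind, lst)
    if (is.null(out)) template else { rownames(out) <- NULL; out }
  }
  empty_assign <- cbind(set = character(), set_type = character(),
                        pairs[0, , drop = FALSE])
  structure(list(
    pathway_pairs = bind(pw_rows, empty_assign),
    network_pairs = bind(nw_rows, empty_assign),
    unassigned = { u <- pairs[!assigned, , drop = FALSE]
                   rownames(u) <- NULL; u },
    counts = bind(counts, data.frame(set = character(),
                                     set_type = character(),
                                     n_molecules = integer(),
                                     n_with_mirna = integer()))),
    class = "mirna_merge")
}

#' @export
print.mirna_merge <- function(x, ...) {
  cat(sprintf("<mirna_merge> %d pathway attachments, %d network attachments, %d unassigned pairs\n",
              nrow(x$pathway_pairs), nrow(x$network_pairs),
              nrow(x$unassigned)))
  invisible(x)
}
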