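# Upstream-regulator network analysis: overlap significance of a
# regulator's direct targets with the differential set, plus a
# sign-consistency activation score over the signed edges. A regulator
# itself need not be measured, let alone differential, to be called --
# regulator activity is often post-translational.

#' Keep only tissue-evidenced edges
#'
#' Regulator-network analysis requires previous experimental validation of
#' direct connections in the tissue of interest (liver); edges without the
#' evidence flag are dropped and regulators left without outgoing edges are
#' removed from the candidate list.
#'
#' @param kb a `knowledge_base`.
#' @return the filtered `knowledge_base`.
#' @export
tissue_filter <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  edges <- kb$edges[kb$edges$tissue_evidence, , drop = FALSE]
  keep_reg <- kb$regulators[kb$regulators %in% edges$source]
  knowledge_base(kb$pathways, edges, kb$mirna_targets, regulators = keep_reg)
}

#' Sign-consistency activation z-score
#'
#' For a regulator with signed edges to differential targets,
#' `z = sum(edge_sign * target_direction_sign) / sqrt(m)` over the `m`
#' differential targets with a resolved direction: an activating edge to an
#' up-regulated target (or inhibiting edge to a down-regulated one) is
#' consistent with activation. `|z| <= sqrt(m)` always; all-consistent
#' targets give exactly `sqrt(m)`.
#'
#' @param edge_sign integer vector of +1/-1 edge signs, one per
#'   direction-resolved differential target.
#' @param target_dir character vector, `"up"` or `"down"`, aligned with
#'   `edge_sign`.
#' @return the z-score, or `NA` when there is no usable target.
#' @export
activation_z <- function(edge_sign, target_dir) {
  stopifnot(length(edge_sign) == length(target_dir))
  m <- length(edge_sign)
  if (m == 0) return(NA_real_)
  dsign <- ifelse(target_dir == "up", 1, -1)
  sum(edge_sign * dsign) / sqrt(m)
}

#' Call regulator networks against an analysis set
#'
#' Per candidate regulator: overlap significance of its direct targets with
#' the differential set by [fisher_right_tail()] (`k` = differential direct
#' targets, `K` = direct targets in the universe, `n` = differential set
#' size, `N` = universe size), activation z by [activation_z()] over the
#' direction-resolved differential targets (cross-layer direction conflicts
#' are excluded from z but still counted in the overlap), and the state
#' rule: activated iff `z >= z_min` and `p < alpha`; inhibited iff
#' `z <= -z_min` and `p < alpha`; otherwise no call. Regulators with no
#' target in the universe are omitted.
#'
#' @param aset an `analysis_set`.
#' @param kb a `knowledge_base`.
#' @param alpha overlap significance threshold.
#' @param z_min activation threshold on |z| (conventional default 2).
#' @param tissue apply [tissue_filter()] first (default TRUE).
#' @return an `activation_calls` data frame (regulator, K, k, m_z, p_value,
#'   z, state) sorted by p, with per-edge contribution tables in
#'   `attr(, "edges")` and differential-target lists in
#'   `attr(, "targets")`.
#' @export
call_networks <- function(aset, kb, alpha = 0.05, z_min = 2, tissue = TRUE) {
  stopifnot(inherits(aset, "analysis_set"), inherits(kb, "knowledge_base"))
  if (tissue) kb <- tissue_filter(kb)
  edges <- kb$edges
  rows <- list(); contrib <- list(); targets <- list()
  N <- length(aset$universe); n <- length(aset$differential)
  for (r in kb$regulators) {
    e <- edges[edges$source == r, , drop = FALSE]
    e <- e[!duplicated(e$target), , drop = FALSE]
    K_ids <- intersect(e$target, aset$universe)
    if (!length(K_ids)) next
    k_ids <- intersect(K_ids, aset$differential)
    p <- fisher_right_tail(length(k_ids), length(K_ids), n, N)
    usable <- setdiff(k_ids, aset$conflicts)
    eu <- e[e$target %in% usable, , drop = FALSE]
    z <- activation_z(eu$sign, aset$direction[eu$target])
    state <- "none"
    if (!is.na(z) && p < alpha) {
      if (z >= z_min) state <- "activated"
      else if (z <= -z_min) state <- "inhibited"
    }
    rows[[r]] <- data.frame(regulator = r, K = length(K_ids),
                            k = length(k_ids), m_z = nrow(eu),
                            p_value = p, z = z, state = state,
                            stringsAsFactors = FALSE)
    consistency <- eu$sign * ifelse(aset$direction[eu$target] == "up", 1, -1)
    contrib[[r]] <- data.frame(target = eu$target, sign = eu$sign,
                               direction = unname(aset$direction[eu$target]),
                               consistent = consistency > 0,
                               stringsAsFactors = FALSE)
    targets[[r]] <- k_ids
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(regulator = character(), K = integer(), k = integer(),
                      m_z = integer(), p_value = numeric(), z = numeric(),
                      state = character())
  res <- res[order(res$p_value, res$regulator), ]
  rownames(res) <- NULL
  structure(res, class = c("activation_calls", "data.frame"),
            label = aset$label, alpha = alpha, z_min = z_min,
            edges = contrib, targets = targets)
}

#' @export
print.activation_calls <- function(x, ...) {
  cat(sprintf("<activation_calls: %s> %d regulators tested, %d activated, %d inhibited (alpha=%g, |z|>=%g)\n",
              attr(x, "label"), nrow(x), sum(x$state == "activated"),
              sum(x$state == "inhibited"), attr(x, "alpha"),
              attr(x, "z_min")))
  NextMethod()
}
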