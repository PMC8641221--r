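# Over-representation analysis across single and combined omics layers.
# The combined ("integrated") analyses change both the analysis-ready list
# (differential molecules) and the reference set (all molecules passing
# quality filters), which is what moves pathway p-values on integration.

#' Combine differential tables into an analysis set
#'
#' Builds the harmonized universe (reference set) and differential set for
#' one layer combination. Gene-level ids shared between transcript and
#' protein layers collapse to one molecule. Directions are resolved
#' molecule-wise with protein direction taking precedence over transcript;
#' molecules whose layers disagree are recorded in `conflicts` (their
#' resolved direction is the protein one, but sign-consistency scoring
#' treats them as direction-undefined).
#'
#' @param tables a `differential_table` or list of them (miRNA tables are
#'   handled by the pairing module, not here).
#' @param label human-readable label for the layer combination, e.g.
#'   `"transcript+protein"`; defaults to the joined layer kinds.
#' @return an object of class `analysis_set`: list with `label`, `universe`,
#'   `differential`, `direction` (named character `up`/`down`), `conflicts`,
#'   `diff_layers` (named list molecule -> layers differential in),
#'   `layers`.
#' @export
build_analysis_set <- function(tables, label = NULL) {
  if (inherits(tables, "differential_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "differential_table")))
  kinds <- vapply(tables, attr, "", "layer_kind")
  if (is.null(label)) label <- paste(kinds, collapse = "+")
  # precedence order for direction resolution: later wins on conflict
  precedence <- c("mirna", "metabolite", "transcript", "protein")
  tables <- tables[order(match(kinds, precedence))]
  kinds <- kinds[order(match(kinds, precedence))]
  universe <- character(); differential <- character()
  direction <- character(); conflicts <- character()
  diff_layers <- list()
  dir_sign <- function(d) ifelse(d %in% c("up", "exclusive_treatment"),
                                 "up", "down")
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    universe <- union(universe, tb$id[tb$passed_quality])
    d_ids <- tb$id[tb$differential]
    differential <- union(differential, d_ids)
    dirs <- stats::setNames(dir_sign(tb$direction[tb$differential]), d_ids)
    for (id in d_ids) {
      diff_layers[[id]] <- c(diff_layers[[id]], kinds[i])
      if (id %in% names(direction) && direction[[id]] != dirs[[id]])
        conflicts <- union(conflicts, id)
      direction[id] <- dirs[[id]]
    }
  }
  structure(list(label = label, universe = universe,
                 differential = differential, direction = direction,
                 conflicts = conflicts, diff_layers = diff_layers,
                 layers = unique(kinds)),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("<analysis_set: %s> universe %d, differential %d, conflicts %d\n",
              x$label, length(x$universe), length(x$differential),
              length(x$conflicts)))
  invisible(x)
}

#' Restrict a differential set to directly connected molecules
#'
#' Keeps exactly the differential molecules incident (in either direction)
#' to at least one knowledge-base edge whose other endpoint is also
#' differential; this is the "direct connections based on experimental
#' evidence among differentially abundant molecules" requirement.
#'
#' @param differential character vector of differential molecule ids.
#' @param kb a `knowledge_base` (or a data frame of edges).
#' @param within optional character vector; when given, only edges with both
#'   endpoints inside `within` count (pathway-scoped connection rule).
#' @return the connected subset of `differential`.
#' @export
restrict_to_connected <- function(differential, kb, within = NULL) {
  edges <- if (inherits(kb, "knowledge_base")) kb$edges else kb
  if (!nrow(edges) || !length(differential)) return(character())
  s <- edges$source; t <- edges$target
  ok <- s %in% differential & t %in% differential
  if (!is.null(within)) ok <- ok & s %in% within & t %in% within
  intersect(differential, unique(c(s[ok], t[ok])))
}

#' Right-tailed Fisher (hypergeometric) p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` pathway molecules when `n` differential molecules are drawn
#' without replacement from a universe of `N` molecules of which `K` belong
#' to the pathway. Computed on the log-gamma scale via [stats::phyper()];
#' `k = 0` gives exactly 1. Vectorized.
#'
#' @param k overlap count(s), `0 <= k <= min(K, n)`.
#' @param K pathway molecules in the universe.
#' @param n differential molecules (analysis-ready list size).
#' @param N universe (reference set) size.
#' @return p-value(s) in (0, 1].
#' @export
fisher_right_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 1) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation for one analysis set
#'
#' For every pathway with at least one member in the universe, assembles the
#' Fisher components: `K` = pathway members in the universe, `k` =
#' differential, connection-passing members, `n` = differential set size,
#' `N` = universe size, and the right-tail p-value. The overlap `k` is
#' counted after [restrict_to_connected()].
#'
#' @param aset an `analysis_set`.
#' @param kb a `knowledge_base` supplying edges (and default pathways).
#' @param pathways named list of pathway member sets; defaults to
#'   `kb$pathways`.
#' @param alpha reported significance threshold (results level).
#' @param strict stricter threshold also reported (methods level).
#' @param connection_scope `"global"` (connections anywhere in the
#'   differential set, the default reading) or `"pathway"` (both endpoints
#'   must lie in the pathway).
#' @return an `enrichment` object: data frame (pathway, K, k, n, N,
#'   p_value, significant, significant_strict) sorted by p, with counted
#'   member lists and layer provenance in `attr(, "members")` and skipped
#'   (K = 0) pathways in `attr(, "skipped")`.
#' @export
enrich <- function(aset, kb, pathways = NULL, alpha = 0.05, strict = 0.01,
                   connection_scope = c("global", "pathway")) {
  stopifnot(inherits(aset, "analysis_set"))
  connection_scope <- match.arg(connection_scope)
  if (is.null(pathways)) pathways <- kb$pathways
  N <- length(aset$universe)
  n <- length(aset$differential)
  dc_global <- if (connection_scope == "global")
    restrict_to_connected(aset$differential, kb) else NULL
  rows <- vector("list", length(pathways))
  members <- list()
  skipped <- character()
  for (i in seq_along(pathways)) {
    pid <- names(pathways)[i]
    mem_u <- intersect(pathways[[i]], aset$universe)
    if (!length(mem_u)) { skipped <- c(skipped, pid); next }
    dc <- if (connection_scope == "global") dc_global
          else restrict_to_connected(aset$differential, kb,
                                     within = pathways[[i]])
    hit <- intersect(mem_u, dc)
    p <- fisher_right_tail(length(hit), length(mem_u), n, N)
    rows[[i]] <- data.frame(pathway = pid, K = length(mem_u),
                            k = length(hit), n = n, N = N, p_value = p,
                            stringsAsFactors = FALSE)
    members[[pid]] <- data.frame(
      molecule = hit,
      layers = vapply(aset$diff_layers[hit],
                      function(l) paste(sort(unique(l)), collapse = "+"), ""),
      direction = unname(aset$direction[hit]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("skipped ", length(skipped),
            " pathway(s) with no members in the universe")
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(pathway = character(), K = integer(), k = integer(),
                      n = integer(), N = integer(), p_value = numeric())
  res$significant <- res$p_value < alpha
  res$significant_strict <- res$p_value < strict
  res <- res[order(res$p_value, res$pathway), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment", "data.frame"),
            label = aset$label, alpha = alpha, strict = strict,
            members = members, skipped = skipped)
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("<enrichment: %s> %d pathways tested, %d significant (p<%g), %d strict (p<%g)\n",
              attr(x, "label"), nrow(x), sum(x$significant),
              attr(x, "alpha"), sum(x$significant_strict),
              attr(x, "strict")))
  NextMethod()
}

#' Compare enrichment across layer combinations
#'
#' Assembles a long-format table (pathway, label, p, k) across labeled
#' result sets over the same pathway collection, suitable for the dot-plot
#' view of how integration moves each pathway's p-value. Pathways absent
#' from one result set keep a row with missing values rather than being
#' dropped.
#'
#' @param results named list of `enrichment` objects (names = labels); an
#'   unnamed list uses each result's own label. Duplicate labels are an
#'   error.
#' @return an `enrichment_comparison` data frame with columns `pathway`,
#'   `label`, `p_value`, `k`.
#' @export
compare_combinations <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "enrichment")))
  labels <- names(results)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(results, attr, "", "label")
  if (anyDuplicated(labels))
    stop("label collision: ", paste(labels[duplicated(labels)],
                                    collapse = ", "))
  all_pw <- unique(unlist(lapply(results, function(r) r$pathway)))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    idx <- match(all_pw, r$pathway)
    data.frame(pathway = all_pw, label = labels[i],
               p_value = r$p_value[idx], k = r$k[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("enrichment_comparison", "data.frame"),
            labels = labels)
}

#' Dot-plot of pathway p-values across layer combinations
#'
#' One row per pathway, one color per layer combination, dot size scaled by
#' the overlap count; the x-axis is -log10(p) with the significance
#' threshold drawn as a dashed line.
#'
#' @param x an `enrichment_comparison`.
#' @param alpha reference threshold line.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.enrichment_comparison <- function(x, alpha = 0.05, ...) {
  labels <- attr(x, "labels")
  pw <- rev(unique(x$pathway))
  cols <- grDevices::hcl.colors(max(3, length(labels)), "Dark 3")
  y <- match(x$pathway, pw)
  lp <- -log10(pmax(x$p_value, 1e-300))
  op <- graphics::par(mar = c(5, 10, 2, 8), xpd = FALSE)
  on.exit(graphics::par(op))
  graphics::plot(lp, y, yaxt = "n", ylab = "",
                 xlab = expression(-log[10](p)),
                 pch = 19, col = cols[match(x$label, labels)],
                 cex = 0.6 + sqrt(pmax(x$k, 0)) / 3, ...)
  graphics::axis(2, at = seq_along(pw), labels = pw, las = 2, cex.axis = 0.7)
  graphics::abline(v = -log10(alpha), lty = 2, col = "grey40")
  graphics::par(xpd = TRUE)
  graphics::legend("topright", inset = c(-0.35, 0), legend = labels,
                   col = cols[seq_along(labels)], pch = 19, cex = 0.7,
                   bty = "n")
  invisible(x)
}
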