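LAYER_KINDS <- c("transcript", "protein", "metabolite", "mirna")
GROUP_LEVELS <- c("control", "treatment")
EVIDENCE_LEVELS <- c("validated", "high_predicted", "low_predicted")

#' Construct an omics layer
#'
#' Bundles one layer's feature-by-sample abundance matrix with its group
#' labels and layer kind. Count layers (transcript, miRNA) must hold
#' non-negative integers with no missing values; intensity layers (protein,
#' metabolite) may contain `NA` for "not identified", which is distinct from
#' a measured zero and drives the proteomics presence filter.
#'
#' @param values numeric matrix, features in rows (rownames = molecule ids,
#'   gene symbols for gene-level layers, metabolite names otherwise),
#'   samples in columns (colnames = sample ids).
#' @param layer_kind one of `"transcript"`, `"protein"`, `"metabolite"`,
#'   `"mirna"`.
#' @param groups named character vector mapping every sample id to
#'   `"control"` or `"treatment"`; both groups must be non-empty.
#' @return an object of class `omics_layer`: a list with elements `values`,
#'   `layer_kind`, `groups`.
#' @export
omics_layer <- function(values, layer_kind, groups) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique sample column names")
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("feature ids (rownames) must be present and unique within a layer")
  missing_group <- setdiff(colnames(values), names(groups))
  if (length(missing_group))
    stop("sample(s) absent from group map: ",
         paste(missing_group, collapse = ", "))
  groups <- groups[colnames(values)]
  if (!all(groups %in% GROUP_LEVELS))
    stop("groups must be 'control' or 'treatment'")
  if (!all(GROUP_LEVELS %in% groups))
    stop("both groups must be non-empty")
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  if (layer_kind %in% c("transcript", "mirna")) {
    if (anyNA(values))
      stop("missing values are not allowed in a count layer (", layer_kind, ")")
    if (any(values != round(values)))
      stop("count layer values must be integers")
  }
  structure(list(values = values, layer_kind = layer_kind, groups = groups),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<omics_layer: %s> %d features x %d samples (%d control, %d treatment)%s\n",
              x$layer_kind, nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "treatment"),
              if (n_miss) sprintf(", %d missing cells", n_miss) else ""))
  invisible(x)
}

#' Subset an omics layer by feature
#' @param layer an `omics_layer`.
#' @param ids character vector of feature ids to keep (order preserved).
#' @return an `omics_layer` restricted to `ids`.
#' @keywords internal
layer_subset <- function(layer, ids) {
  out <- layer
  out$values <- layer$values[ids, , drop = FALSE]
  out
}

#' Construct a knowledge base
#'
#' The knowledge base stands in for a curated molecular-interaction resource:
#' pathway membership sets, signed regulator-to-target edges flagged with
#' tissue-level experimental evidence (here: liver), and miRNA-to-target
#' edges graded by evidence level.
#'
#' @param pathways named list of character vectors (pathway id -> member
#'   molecule ids). Members are deduplicated; empty sets are an error.
#' @param edges data frame with columns `source`, `target`, `sign` (+1/-1),
#'   `relation` (`"regulates"` or `"interacts"`), `tissue_evidence` (logical).
#' @param mirna_targets data frame with columns `mirna`, `target`,
#'   `evidence` (one of `"validated"`, `"high_predicted"`, `"low_predicted"`).
#' @param regulators character vector of molecule ids treated as network
#'   regulators; defaults to the unique sources of `regulates` edges, which
#'   makes the "every regulator has an outgoing edge" invariant structural.
#' @return an object of class `knowledge_base`.
#' @export
knowledge_base <- function(pathways, edges, mirna_targets = NULL,
                           regulators = NULL) {
  if (length(pathways)) {
    if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
      stop("pathways must be uniquely named")
    pathways <- lapply(pathways, function(m) unique(as.character(m)))
    empty <- names(pathways)[vapply(pathways, length, 1L) == 0L]
    if (length(empty))
      stop("empty pathway set(s): ", paste(empty, collapse = ", "))
  } else pathways <- structure(list(), names = character())
  edges <- validate_edges(edges)
  if (is.null(mirna_targets))
    mirna_targets <- data.frame(mirna = character(), target = character(),
                                evidence = character(),
                                stringsAsFactors = FALSE)
  if (!all(c("mirna", "target", "evidence") %in% names(mirna_targets)))
    stop("mirna_targets needs columns mirna, target, evidence")
  if (!all(mirna_targets$evidence %in% EVIDENCE_LEVELS))
    stop("mirna_targets evidence must be one of: ",
         paste(EVIDENCE_LEVELS, collapse = ", "))
  if (is.null(regulators))
    regulators <- unique(edges$source[edges$relation == "regulates"])
  out_deg <- table(factor(edges$source, levels = regulators))
  if (length(regulators) && any(out_deg == 0))
    stop("regulator(s) without outgoing edges: ",
         paste(names(out_deg)[out_deg == 0], collapse = ", "))
  structure(list(pathways = pathways, edges = edges,
                 regulators = as.character(regulators),
                 mirna_targets = mirna_targets),
            class = "knowledge_base")
}

validate_edges <- function(edges) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), relation = character(),
                        tissue_evidence = logical(),
                        stringsAsFactors = FALSE)
  need <- c("source", "target", "sign", "relation", "tissue_evidence")
  if (!all(need %in% names(edges)))
    stop("edges need columns: ", paste(need, collapse = ", "))
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop("edge sign must be +1 or -1")
  if (!all(edges$relation %in% c("regulates", "interacts")))
    stop("edge relation must be 'regulates' or 'interacts'")
  if (!is.logical(edges$tissue_evidence) || anyNA(edges$tissue_evidence))
    stop("tissue_evidence must be TRUE/FALSE")
  self <- edges$source == edges$target
  if (any(self))
    stop("self-edge(s) not allowed: ",
         paste(unique(edges$source[self]), collapse = ", "))
  key <- paste(edges$source, edges$target, edges$relation, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate edge(s): ",
         paste(unique(gsub("\r", "->", key[dup])), collapse = ", "))
  edges <- edges[need]
  rownames(edges) <- NULL
  edges
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "<knowledge_base> %d pathways, %d edges (%d liver-evidenced), %d regulators, %d miRNA-target edges\n",
    length(x$pathways), nrow(x$edges), sum(x$edges$tissue_evidence),
    length(x$regulators), nrow(x$mirna_targets)))
  invisible(x)
}

# ---- readers / writers ------------------------------------------------------

#' Read a GMT pathway-set file
#'
#' GMT dialect: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line collapse to a set.
#'
#' @param path file path.
#' @return named list of character vectors (pathway id -> members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- structure(vector("list", length(lines)), names = rep("", length(lines)))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d in '%s': fewer than 3 fields",
                   i, path))
    names(out)[i] <- f[[1]]
    out[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(names(out)))
    stop("duplicate pathway id(s) in ", path)
  out
}

#' Write pathway sets as GMT
#' @param pathways named list of member vectors.
#' @param path output file.
#' @param descriptions optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  desc <- if (is.null(descriptions)) rep("na", length(pathways))
          else descriptions[names(pathways)]
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], desc[i], pathways[[i]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_sign <- function(x) {
  s <- trimws(as.character(x))
  out <- ifelse(s %in% c("+1", "1"), 1L, ifelse(s == "-1", -1L, NA_integer_))
  if (anyNA(out))
    stop("unparseable edge sign(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

parse_bool <- function(x, what) {
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("true", "t", "1"), TRUE,
                ifelse(s %in% c("false", "f", "0"), FALSE, NA))
  if (anyNA(out)) stop("unparseable ", what, " value(s)")
  out
}

#' Read a signed edge table
#'
#' TSV with header `source  target  sign  relation  tissue_evidence`; `sign`
#' accepts `+1`/`1`/`-1`, `tissue_evidence` accepts true/false. Duplicate
#' (source, target, relation) rows are rejected.
#'
#' @param path file path.
#' @return data frame of validated edges.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("source", "target", "sign", "relation", "tissue_evidence")
  if (!identical(names(df), need))
    stop("edge file '", path, "' must have header: ",
         paste(need, collapse = ", "))
  df$sign <- parse_sign(df$sign)
  df$tissue_evidence <- parse_bool(df$tissue_evidence, "tissue_evidence")
  validate_edges(df)
}

#' Write a signed edge table
#' @param edges validated edge data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  out <- edges
  out$sign <- ifelse(edges$sign > 0, "+1", "-1")
  out$tissue_evidence <- ifelse(edges$tissue_evidence, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target table
#' @param path TSV with header `mirna  target  evidence`.
#' @return data frame with evidence validated against the allowed levels.
#' @export
read_mirna_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), c("mirna", "target", "evidence")))
    stop("miRNA target file must have header: mirna, target, evidence")
  if (!all(df$evidence %in% EVIDENCE_LEVELS))
    stop("evidence must be one of: ", paste(EVIDENCE_LEVELS, collapse = ", "))
  df
}

#' Write a miRNA-target table
#' @param mirna_targets data frame (mirna, target, evidence).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_targets <- function(mirna_targets, path) {
  utils::write.table(mirna_targets[, c("mirna", "target", "evidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait-gene association table
#'
#' @param path TSV with header `gene  trait  variant` (GWAS-catalog-style
#'   rows: gene symbol, trait name, variant id). Duplicate triples are
#'   rejected.
#' @return data frame of class `trait_table`.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), c("gene", "trait", "variant")))
    stop("trait file must have header: gene, trait, variant")
  trait_table(df)
}

#' Construct a trait table
#' @param df data frame with columns gene, trait, variant.
#' @return data frame of class `trait_table`.
#' @export
trait_table <- function(df) {
  key <- paste(df$gene, df$trait, df$variant, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, trait, variant) triple(s)")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table
#' @param traits `trait_table` or plain data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(as.data.frame(traits)[, c("gene", "trait", "variant")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample abundance table
#'
#' First column is the feature id, remaining columns are samples. Blank
#' cells become missing values, which only protein and metabolite layers
#' accept; a blank in a count layer is a validation error.
#'
#' @param path delimited file (tab by default).
#' @param layer_kind layer kind, see [omics_layer()].
#' @param groups named character vector sample -> group covering all sample
#'   columns.
#' @param sep field separator.
#' @return an `omics_layer`.
#' @export
read_layer <- function(path, layer_kind, groups, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("layer file needs a feature id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_layer(m, layer_kind, groups)
}

#' Write a feature-by-sample abundance table
#' @param layer an `omics_layer`.
#' @param path output file; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  df <- data.frame(feature_id = rownames(layer$values),
                   layer$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample-group map
#' @param path TSV with header `sample  group`.
#' @return named character vector sample -> group.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), c("sample", "group")))
    stop("group file must have header: sample, group")
  stats::setNames(df$group, df$sample)
}

#' Write a sample-group map
#' @param groups named character vector sample -> group.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(
    data.frame(sample = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
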