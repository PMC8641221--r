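# Per-layer quality filtering, normalization, imputation and differential
# testing. All layers end in an unadjusted two-sided equal-variance t-test at
# alpha = 0.05; metabolites additionally require VIP > 1 from a
# one-component PLS fit, and group-exclusive proteins are carried as
# differential without a test.

#' Drop features with zero counts in every sample
#'
#' @param layer a transcript or miRNA `omics_layer`.
#' @return the layer restricted to features with at least one nonzero count;
#'   a single read anywhere retains the feature.
#' @export
filter_transcripts <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  if (!layer$layer_kind %in% c("transcript", "mirna"))
    stop("filter_transcripts expects a count layer")
  keep <- rowSums(layer$values) > 0
  layer_subset(layer, rownames(layer$values)[keep])
}

# Scaling factor of one sample against the reference: doubly trimmed
# (log-ratio and absolute-intensity trims), precision-weighted mean of
# log2 ratios of library-size-scaled counts.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' procedure: the reference sample is the one whose library-size-scaled
#' upper-quartile count is closest to the mean of upper quartiles; each
#' sample's factor is a doubly trimmed (30\% on log-ratios, 5\% on average
#' log intensity), precision-weighted mean of log2 ratios against the
#' reference; factors are centered to geometric mean 1. Normalized values
#' are counts per million of the factor-adjusted library size.
#'
#' @param layer a count `omics_layer` with at least two samples.
#' @param trim_m two-sided trim fraction on log-ratios (M values).
#' @param trim_a two-sided trim fraction on average log intensities.
#' @return list with `layer` (CPM-scale `omics_layer`) and `factors`
#'   (named numeric, geometric mean 1).
#' @export
tmm_normalize <- function(layer, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  xp <- x[rowSums(x > 0) > 0, , drop = FALSE]
  f75 <- apply(xp, 2, stats::quantile, probs = 0.75) / lib
  ref <- if (stats::median(f75) < 1e-20) which.max(colSums(sqrt(xp)))
         else which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(xp)), function(i)
    tmm_pair_factor(xp[, i], xp[, ref], lib[i], lib[ref], trim_m, trim_a), 0)
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(x)
  cpm <- sweep(x, 2, lib * factors, "/") * 1e6
  out <- layer
  out$values <- cpm
  out$layer_kind <- layer$layer_kind  # stays a count layer conceptually
  # CPM values are no longer integers; bypass the constructor check
  list(layer = out, factors = factors)
}

#' Two-sample equal-variance t-test
#'
#' Pooled-variance two-sided t-test with `n1 + n2 - 2` degrees of freedom.
#' A zero pooled variance yields `NA` statistics (flagged, not an error).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
ttest_equal_var <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  ttest_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
}

#' Equal-variance t-test from group summaries
#'
#' Same pooled-variance test as [ttest_equal_var()] computed from printed
#' group means, SDs and sizes, e.g. a clinical summary table. Vectorized
#' over measures. The sign convention is group 2 minus group 1.
#'
#' @param mean1,sd1,n1 summary of group 1 (e.g. control); `sd >= 0`,
#'   `n >= 2`.
#' @param mean2,sd2,n2 summary of group 2 (e.g. treatment).
#' @return list with `t`, `p`, `df` (each vectorized).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0)) stop("sd must be >= 0")
  if (any(c(n1, n2) < 2)) stop("n must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (mean2 - mean1) / se, NA_real_)
  p <- ifelse(is.na(t), NA_real_,
              ifelse(t == 0, 1, 2 * stats::pt(-abs(t), df)))
  list(t = t, p = p, df = df)
}

#' Presence filtering of a protein layer
#'
#' Retains proteins observed (non-missing) in at least `ceiling(0.6 * n)`
#' samples of each group (3 of 5 in the reference design) as testable, and
#' proteins observed in every sample of exactly one group and none of the
#' other as group-exclusive. Everything else is dropped from downstream
#' analysis.
#'
#' @param layer a protein `omics_layer`.
#' @return list with `layer` (retained features, exclusives included) and
#'   `exclusivity` (named character: `"none"`, `"exclusive_treatment"`,
#'   `"exclusive_control"`).
#' @export
filter_proteins_presence <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  obs <- !is.na(layer$values)
  ctl <- layer$groups == "control"; trt <- layer$groups == "treatment"
  n_ctl <- sum(ctl); n_trt <- sum(trt)
  if (min(n_ctl, n_trt) < 3) stop("presence filter needs group sizes >= 3")
  oc <- rowSums(obs[, ctl, drop = FALSE])
  ot <- rowSums(obs[, trt, drop = FALSE])
  thr_c <- ceiling(0.6 * n_ctl); thr_t <- ceiling(0.6 * n_trt)
  testable <- oc >= thr_c & ot >= thr_t
  excl_t <- ot == n_trt & oc == 0
  excl_c <- oc == n_ctl & ot == 0
  keep <- testable | excl_t | excl_c
  ids <- rownames(layer$values)
  lab <- stats::setNames(rep("none", sum(keep)), ids[keep])
  lab[ids[excl_t]] <- "exclusive_treatment"
  lab[ids[excl_c]] <- "exclusive_control"
  list(layer = layer_subset(layer, names(lab)), exclusivity = lab)
}

#' Natural-log transform of an intensity layer
#' @param layer protein or metabolite `omics_layer` with strictly positive
#'   observed values; missing cells are preserved.
#' @return the log-scale layer.
#' @export
log_transform <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  if (any(layer$values <= 0, na.rm = TRUE))
    stop("log transform requires strictly positive observed values")
  out <- layer
  out$values <- log(layer$values)
  out
}

# Minimum-norm least-squares prediction: fit response b on design A at the
# observed samples, predict at A_new. Collinear/overparameterized designs
# (features >> samples) resolve to the pseudoinverse solution.
ls_predict <- function(A, b, A_new) {
  coef <- MASS::ginv(A) %*% b
  drop(A_new %*% coef)
}

#' Sequential regression imputation of missing intensities
#'
#' Fills missing log-intensities within each experimental group
#' independently: features are ordered by increasing missingness, missing
#' cells are initialized at the feature's group mean, then each incomplete
#' feature is iteratively regressed (minimum-norm least squares with
#' intercept) on all other features and its missing cells updated, until the
#' largest absolute change is below `tol` or `max_iter` sweeps. Observed
#' cells are never altered. Group-exclusive proteins must be removed first;
#' a feature may miss at most `n_group - 3` values per group.
#'
#' @param layer a log-scale protein `omics_layer` (or any intensity layer).
#' @param tol convergence tolerance on the largest absolute update.
#' @param max_iter sweep cap.
#' @return the completed `omics_layer`.
#' @export
impute_sequential <- function(layer, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  for (g in GROUP_LEVELS) {
    cols <- which(layer$groups == g)
    ng <- length(cols)
    miss <- rowSums(is.na(x[, cols, drop = FALSE]))
    bad <- miss > max(ng - 3, 0)
    if (any(bad))
      stop("feature(s) exceed the missingness bound (> n-3 missing) in ",
           g, ": ", paste(rownames(x)[bad][seq_len(min(5, sum(bad)))],
                          collapse = ", "))
    x[, cols] <- impute_group(x[, cols, drop = FALSE], tol, max_iter)
  }
  out <- layer
  out$values <- x
  out
}

impute_group <- function(xg, tol, max_iter) {
  miss <- is.na(xg)
  if (!any(miss)) return(xg)
  inc <- which(rowSums(miss) > 0)
  inc <- inc[order(rowSums(miss)[inc])]  # least missing first
  gm <- rowMeans(xg, na.rm = TRUE)
  for (j in inc) xg[j, miss[j, ]] <- gm[j]
  if (nrow(xg) < 2) return(xg)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in inc) {
      obs_s <- !miss[j, ]
      mis_s <- miss[j, ]
      preds <- xg[-j, , drop = FALSE]
      A <- cbind(1, t(preds[, obs_s, drop = FALSE]))
      A_new <- cbind(1, t(preds[, mis_s, drop = FALSE]))
      new_vals <- ls_predict(A, xg[j, obs_s], A_new)
      delta <- max(delta, max(abs(new_vals - xg[j, mis_s])))
      xg[j, mis_s] <- new_vals
    }
    if (delta < tol) break
  }
  xg
}

#' Per-feature VIP from a one-component PLS fit
#'
#' Fits a single-component projection to latent structures of the autoscaled
#' feature matrix against the centered group indicator and returns variable
#' importance in projection scores. With one component the VIP reduces to
#' `sqrt(P) * |w_j| / ||w||` where `w` is the X-weight vector, so the mean
#' squared VIP over (non-degenerate) features is identically 1. Features
#' with zero variance get VIP 0 with a warning.
#'
#' @param layer a complete (no missing) `omics_layer`.
#' @return named numeric vector of VIP scores.
#' @export
pls_vip <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  if (anyNA(x)) stop("pls_vip requires a complete matrix")
  y <- ifelse(layer$groups == "treatment", 1, -1)
  y <- y - mean(y)
  sds <- apply(x, 1, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning("zero-variance feature(s) get VIP 0: ",
            paste(rownames(x)[degenerate][seq_len(min(5, sum(degenerate)))],
                  collapse = ", "))
  xs <- (x - rowMeans(x)) / ifelse(degenerate, 1, sds)
  w <- drop(xs %*% y)           # X-weights up to scale: cov(feature, y)
  w[degenerate] <- 0
  nrm <- sqrt(sum(w^2))
  p_eff <- sum(!degenerate)
  vip <- if (nrm == 0) rep(0, length(w)) else sqrt(p_eff) * abs(w) / nrm
  names(vip) <- rownames(x)
  vip
}

#' Median-normalize and log2-transform a metabolite layer
#'
#' Optional internal-standard division (per sample) followed by per-sample
#' median normalization and log2 transformation, the standard pre-treatment
#' for ratio-scaled MS intensities.
#'
#' @param layer a metabolite `omics_layer` with positive values.
#' @param internal_standard optional feature id used to divide each sample
#'   before median normalization; the standard itself is dropped.
#' @return the normalized, log2-scale layer.
#' @export
normalize_metabolites <- function(layer, internal_standard = NULL) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  if (any(x <= 0, na.rm = TRUE))
    stop("metabolite normalization requires positive intensities")
  if (!is.null(internal_standard)) {
    if (!internal_standard %in% rownames(x))
      stop("internal standard '", internal_standard, "' not in layer")
    x <- sweep(x, 2, x[internal_standard, ], "/")
    x <- x[setdiff(rownames(x), internal_standard), , drop = FALSE]
  }
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- sweep(x, 2, med / mean(med), "/")
  out <- layer
  out$values <- log2(x)
  out
}

#' Select differential metabolites by the joint VIP / p-value rule
#'
#' A metabolite is differential iff `VIP > 1` and `p < alpha` (both strict).
#'
#' @param ids feature ids.
#' @param vip VIP scores aligned with `ids`.
#' @param p unadjusted two-sided p-values aligned with `ids`.
#' @param ratio treatment/control abundance ratios aligned with `ids`.
#' @param alpha significance threshold.
#' @return logical vector: differential status.
#' @export
select_metabolites <- function(ids, vip, p, ratio, alpha = 0.05) {
  stopifnot(length(ids) == length(vip), length(ids) == length(p))
  !is.na(p) & vip > 1 & p < alpha
}

new_differential_table <- function(df, layer_kind, alpha) {
  rownames(df) <- NULL
  structure(df, class = c("differential_table", "data.frame"),
            layer_kind = layer_kind, alpha = alpha)
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("<differential_table: %s> %d features, %d passed quality, %d differential (alpha=%g)\n",
              attr(x, "layer_kind"), nrow(x), sum(x$passed_quality),
              sum(x$differential), attr(x, "alpha")))
  NextMethod()
}

row_ttests <- function(values, groups) {
  ctl <- groups == "control"; trt <- groups == "treatment"
  m1 <- rowMeans(values[, ctl, drop = FALSE])
  m2 <- rowMeans(values[, trt, drop = FALSE])
  s1 <- apply(values[, ctl, drop = FALSE], 1, stats::sd)
  s2 <- apply(values[, trt, drop = FALSE], 1, stats::sd)
  tt <- ttest_from_summary(m1, s1, sum(ctl), m2, s2, sum(trt))
  list(mean_control = m1, mean_treatment = m2, t = tt$t, p = tt$p)
}

#' Run the layer-appropriate differential-abundance chain
#'
#' Dispatches on layer kind:
#' \itemize{
#'   \item transcript / miRNA: drop all-zero features, TMM-normalize to CPM,
#'     equal-variance t-test per feature;
#'   \item protein: presence filter (testable + group-exclusive), natural
#'     log, per-group sequential imputation, t-test; exclusives are marked
#'     differential with direction `exclusive_*`, ratio `+Inf`/`-Inf`, and
#'     no statistic;
#'   \item metabolite: optional median/log2 normalization, t-test plus
#'     one-component PLS VIP; differential iff `p < alpha` and `VIP > 1`.
#' }
#'
#' @param layer an `omics_layer`.
#' @param alpha unadjusted significance threshold.
#' @param normalize logical; TMM for count layers, median/log2 for
#'   metabolites. Disable for data already on a comparable scale.
#' @param adjust `"none"` (default, mirrors the unadjusted design) or
#'   `"BH"` for Benjamini-Hochberg; when `"BH"`, the differential flag uses
#'   the adjusted p-values.
#' @return a `differential_table` with one row per input feature: id, layer,
#'   group means (post-normalization scale), treatment/control ratio,
#'   direction (`up`, `down`, `exclusive_treatment`, `exclusive_control`),
#'   t, p, vip (metabolites), passed_quality, differential.
#' @export
run_layer <- function(layer, alpha = 0.05, normalize = TRUE,
                      adjust = c("none", "BH")) {
  stopifnot(inherits(layer, "omics_layer"))
  adjust <- match.arg(adjust)
  switch(layer$layer_kind,
    transcript = ,
    mirna = run_count_layer(layer, alpha, normalize, adjust),
    protein = run_protein_layer(layer, alpha, adjust),
    metabolite = run_metabolite_layer(layer, alpha, normalize, adjust))
}

finalize_diff <- function(df, alpha, adjust, extra_gate = NULL) {
  p_eff <- df$p
  if (adjust == "BH") p_eff <- stats::p.adjust(df$p, method = "BH")
  diff <- !is.na(p_eff) & p_eff < alpha & df$passed_quality
  if (!is.null(extra_gate)) diff <- diff & extra_gate
  df$differential <- diff
  df
}

run_count_layer <- function(layer, alpha, normalize, adjust) {
  kept <- filter_transcripts(layer)
  vals <- if (normalize && nrow(kept$values) > 0)
    tmm_normalize(kept)$layer$values else kept$values
  all_ids <- rownames(layer$values)
  passed <- all_ids %in% rownames(vals)
  res <- if (nrow(vals)) row_ttests(vals, kept$groups) else
    list(mean_control = numeric(), mean_treatment = numeric(),
         t = numeric(), p = numeric())
  df <- data.frame(id = all_ids, layer = layer$layer_kind,
                   mean_control = NA_real_, mean_treatment = NA_real_,
                   ratio = NA_real_, direction = NA_character_,
                   t = NA_real_, p = NA_real_, vip = NA_real_,
                   passed_quality = passed, differential = FALSE,
                   stringsAsFactors = FALSE)
  idx <- match(rownames(vals), all_ids)
  df$mean_control[idx] <- res$mean_control
  df$mean_treatment[idx] <- res$mean_treatment
  df$ratio[idx] <- res$mean_treatment / res$mean_control
  df$direction[idx] <- ifelse(df$ratio[idx] >= 1, "up", "down")
  df$t[idx] <- res$t
  df$p[idx] <- res$p
  df <- finalize_diff(df, alpha, adjust)
  new_differential_table(df, layer$layer_kind, alpha)
}

run_protein_layer <- function(layer, alpha, adjust) {
  fp <- filter_proteins_presence(layer)
  lab <- fp$exclusivity
  testable_ids <- names(lab)[lab == "none"]
  all_ids <- rownames(layer$values)
  df <- data.frame(id = all_ids, layer = "protein",
                   mean_control = NA_real_, mean_treatment = NA_real_,
                   ratio = NA_real_, direction = NA_character_,
                   t = NA_real_, p = NA_real_, vip = NA_real_,
                   passed_quality = all_ids %in% names(lab),
                   differential = FALSE, stringsAsFactors = FALSE)
  if (length(testable_ids)) {
    sub <- impute_sequential(log_transform(layer_subset(fp$layer,
                                                        testable_ids)))
    res <- row_ttests(sub$values, sub$groups)
    idx <- match(testable_ids, all_ids)
    df$mean_control[idx] <- res$mean_control
    df$mean_treatment[idx] <- res$mean_treatment
    df$ratio[idx] <- exp(res$mean_treatment - res$mean_control)
    df$direction[idx] <- ifelse(df$ratio[idx] >= 1, "up", "down")
    df$t[idx] <- res$t
    df$p[idx] <- res$p
  }
  df <- finalize_diff(df, alpha, adjust)
  excl <- names(lab)[lab != "none"]
  if (length(excl)) {
    idx <- match(excl, all_ids)
    df$direction[idx] <- lab[excl]
    df$ratio[idx] <- ifelse(lab[excl] == "exclusive_treatment", Inf, -Inf)
    df$differential[idx] <- TRUE
  }
  new_differential_table(df, "protein", alpha)
}

run_metabolite_layer <- function(layer, alpha, normalize, adjust) {
  work <- layer
  if (normalize) work <- normalize_metabolites(layer)
  if (anyNA(work$values))
    stop("metabolite testing requires a complete matrix")
  res <- row_ttests(work$values, work$groups)
  vip <- suppressWarnings(pls_vip(work))
  ids <- rownames(work$values)
  ratio <- if (normalize) 2^(res$mean_treatment - res$mean_control)
           else res$mean_treatment / res$mean_control
  df <- data.frame(id = ids, layer = "metabolite",
                   mean_control = res$mean_control,
                   mean_treatment = res$mean_treatment,
                   ratio = ratio,
                   direction = ifelse(ratio >= 1, "up", "down"),
                   t = res$t, p = res$p, vip = unname(vip),
                   passed_quality = TRUE, differential = FALSE,
                   stringsAsFactors = FALSE)
  df <- finalize_diff(df, alpha, adjust,
                      extra_gate = select_metabolites(ids, vip, df$p,
                                                      ratio, alpha))
  new_differential_table(df, "metabolite", alpha)
}

#' Sum duplicate feature ids in a layer
#'
#' Helper for intensity tables where one molecule appears multiple times
#' (e.g. peptide groups mapped to the same gene symbol): rows sharing an id
#' are summed, treating missing as missing only when all occurrences are
#' missing.
#'
#' @param values numeric matrix with (possibly duplicated) rownames.
#' @return matrix with unique rownames.
#' @export
sum_duplicate_ids <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  u <- unique(ids)
  out <- matrix(NA_real_, length(u), ncol(values),
                dimnames = list(u, colnames(values)))
  for (id in u) {
    rows <- values[ids == id, , drop = FALSE]
    s <- colSums(rows, na.rm = TRUE)
    s[colSums(!is.na(rows)) == 0] <- NA_real_
    out[id, ] <- s
  }
  out
}
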