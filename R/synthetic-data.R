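# Synthetic multi-omics study generator. Emulates the statistical structure
# the analysis assumes -- a two-group (n=5 vs n=5) design over four layers,
# negative-binomial count layers around lognormal baselines, lognormal MS
# intensities with missingness and group-exclusive proteins, planted
# pathway-concentrated effects, signed regulator programs, and inverse
# miRNA-target relationships -- so every downstream stage is testable
# without any external download.

sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 2048L + k

#' Simulation configuration
#'
#' All knobs of the synthetic study. Defaults encode the reference design:
#' five animals per group, count layers with moderate negative-binomial
#' dispersion, three planted pathways at a log2 fold change of 2 affecting
#' 80\% of members, two planted regulators (one activated, one inhibited),
#' group-exclusive proteins, and a block of planted miRNAs mostly inverse
#' to their targets.
#'
#' @param seed integer master seed; every layer derives its own sub-seed
#'   from it.
#' @param n_per_group animals per diet group.
#' @param n_transcripts,n_proteins,n_metabolites,n_mirnas layer sizes;
#'   proteins are the first `n_proteins` gene symbols, sharing ids with the
#'   transcript layer.
#' @param n_pathways number of pathway sets.
#' @param pathway_size_range integer pair, inclusive member-count range.
#' @param metabolite_fraction expected fraction of pathway members drawn
#'   from the metabolite universe.
#' @param pathway_edge_density probability that a within-pathway molecule
#'   pair gets an `interacts` edge.
#' @param n_regulators,targets_per_regulator regulator count and direct
#'   targets per regulator.
#' @param n_planted_regulators leading regulators given a coherent signed
#'   target program (activation signs alternate +1, -1, ...).
#' @param regulator_effect absolute log2 fold change applied to planted
#'   regulator targets.
#' @param planted_pathways data frame with columns `pathway`, `effect_size`
#'   (log2 fold change) and `affected_fraction`.
#' @param n_exclusive_proteins proteins present in every sample of one
#'   group and absent from all of the other (split evenly between groups).
#' @param protein_missing_rate missing-at-random cell probability for the
#'   protein layer.
#' @param n_planted_mirnas,targets_per_mirna planted miRNA block and its
#'   per-miRNA target count (targets drawn from planted, affected genes).
#' @param mirna_inverse_fraction fraction of planted miRNAs shifted
#'   opposite to their targets' planted direction.
#' @param mirna_effect absolute log2 fold change of planted miRNAs.
#' @param count_dispersion negative-binomial dispersion of count layers.
#' @param baseline_log_mean,baseline_log_sd lognormal baseline of count
#'   means.
#' @param intensity_log_mean,intensity_log_sd lognormal baseline of
#'   protein/metabolite intensities.
#' @param intensity_noise_sd per-cell log-scale noise of intensity layers.
#' @param depth_range library-depth multiplier range across samples (count
#'   layers).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 5L,
                       n_transcripts = 2000L,
                       n_proteins = 800L,
                       n_metabolites = 300L,
                       n_mirnas = 150L,
                       n_pathways = 25L,
                       pathway_size_range = c(10L, 30L),
                       metabolite_fraction = 0.15,
                       pathway_edge_density = 0.25,
                       n_regulators = 8L,
                       targets_per_regulator = 12L,
                       n_planted_regulators = 2L,
                       regulator_effect = 2,
                       planted_pathways = data.frame(
                         pathway = c("PW01", "PW02", "PW03"),
                         effect_size = 2,
                         affected_fraction = 0.8,
                         stringsAsFactors = FALSE),
                       n_exclusive_proteins = 4L,
                       protein_missing_rate = 0.10,
                       n_planted_mirnas = 10L,
                       targets_per_mirna = 5L,
                       mirna_inverse_fraction = 0.8,
                       mirna_effect = 1.5,
                       count_dispersion = 0.1,
                       baseline_log_mean = 5,
                       baseline_log_sd = 1,
                       intensity_log_mean = 14,
                       intensity_log_sd = 1,
                       intensity_noise_sd = 0.25,
                       depth_range = c(0.7, 1.3)) {
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              n_transcripts = as.integer(n_transcripts),
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              n_mirnas = as.integer(n_mirnas),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              metabolite_fraction = metabolite_fraction,
              pathway_edge_density = pathway_edge_density,
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              n_planted_regulators = as.integer(n_planted_regulators),
              regulator_effect = regulator_effect,
              planted_pathways = as.data.frame(planted_pathways),
              n_exclusive_proteins = as.integer(n_exclusive_proteins),
              protein_missing_rate = protein_missing_rate,
              n_planted_mirnas = as.integer(n_planted_mirnas),
              targets_per_mirna = as.integer(targets_per_mirna),
              mirna_inverse_fraction = mirna_inverse_fraction,
              mirna_effect = mirna_effect,
              count_dispersion = count_dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              intensity_log_mean = intensity_log_mean,
              intensity_log_sd = intensity_log_sd,
              intensity_noise_sd = intensity_noise_sd,
              depth_range = depth_range)
  counts <- c("n_per_group", "n_transcripts", "n_proteins", "n_metabolites",
              "n_mirnas", "n_pathways", "n_regulators",
              "targets_per_regulator")
  for (f in counts) if (cfg[[f]] < 1L) stop(f, " must be >= 1")
  for (f in c("n_planted_regulators", "n_exclusive_proteins",
              "n_planted_mirnas", "targets_per_mirna"))
    if (cfg[[f]] < 0L) stop(f, " must be >= 0")
  probs <- c("metabolite_fraction", "pathway_edge_density",
             "protein_missing_rate", "mirna_inverse_fraction")
  for (f in probs) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must be a probability in [0, 1]")
  if (!all(is.finite(cfg$planted_pathways$effect_size)) ||
      !all(is.finite(c(cfg$regulator_effect, cfg$mirna_effect))))
    stop("effect sizes must be finite")
  if (any(cfg$planted_pathways$affected_fraction < 0 |
          cfg$planted_pathways$affected_fraction > 1))
    stop("affected_fraction must be in [0, 1]")
  if (cfg$count_dispersion <= 0) stop("count_dispersion must be positive")
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 1L)
    stop("pathway_size_range must be an increasing positive pair")
  if (cfg$pathway_size_range[2] > cfg$n_transcripts + cfg$n_metabolites)
    stop("universe too small for requested pathway sizes")
  if (cfg$n_proteins > cfg$n_transcripts)
    stop("n_proteins cannot exceed n_transcripts (proteins share gene symbols)")
  if (cfg$n_planted_regulators > cfg$n_regulators)
    stop("n_planted_regulators cannot exceed n_regulators")
  if (cfg$n_planted_mirnas > cfg$n_mirnas)
    stop("n_planted_mirnas cannot exceed n_mirnas")
  bad_pw <- setdiff(cfg$planted_pathways$pathway, pathway_ids(cfg))
  if (length(bad_pw))
    stop("planted pathway id(s) outside PW01..: ",
         paste(bad_pw, collapse = ", "))
  structure(cfg, class = "sim_config")
}

pathway_ids <- function(cfg) sprintf("PW%02d", seq_len(cfg$n_pathways))
gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_transcripts))
metabolite_ids <- function(cfg) sprintf("MET%03d", seq_len(cfg$n_metabolites))
mirna_ids <- function(cfg) sprintf("miR-%03d", seq_len(cfg$n_mirnas))
regulator_ids <- function(cfg) sprintf("TF%02d", seq_len(cfg$n_regulators))

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, %d+%d design; %d transcripts / %d proteins / %d metabolites / %d miRNAs; %d pathways (%d planted), %d regulators (%d planted)\n",
              x$seed, x$n_per_group, x$n_per_group, x$n_transcripts,
              x$n_proteins, x$n_metabolites, x$n_mirnas, x$n_pathways,
              nrow(x$planted_pathways), x$n_regulators,
              x$n_planted_regulators))
  invisible(x)
}

#' Generate the synthetic knowledge base
#'
#' Draws pathway sets over the gene + metabolite universe with sizes in the
#' configured range, within-pathway `interacts` edges, signed
#' regulator-to-target `regulates` edges (planted regulators get a coherent
#' program over affected genes outside the pathways; roughly 90\% of
#' regulator edges carry tissue evidence), and miRNA-target edges with
#' graded evidence. The planted ground truth (per-molecule log2 fold
#' changes, regulator activation signs, miRNA directions) is attached as
#' `attr(kb, "truth")` and consumed by [simulate_layers()]. Deterministic
#' given the config seed.
#'
#' @param config a `sim_config`.
#' @return a `knowledge_base` with a `truth` attribute.
#' @export
make_knowledge_base <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  genes <- gene_ids(config); mets <- metabolite_ids(config)
  mirnas <- mirna_ids(config); regs <- regulator_ids(config)

  sizes <- sample(seq(config$pathway_size_range[1],
                      config$pathway_size_range[2]),
                  config$n_pathways, replace = TRUE)
  pathways <- stats::setNames(vector("list", config$n_pathways),
                              pathway_ids(config))
  for (i in seq_len(config$n_pathways)) {
    n_met <- min(stats::rbinom(1, sizes[i], config$metabolite_fraction),
                 length(mets))
    pathways[[i]] <- c(sample(genes, sizes[i] - n_met),
                       if (n_met) sample(mets, n_met))
  }

  pp <- config$planted_pathways
  affected <- stats::setNames(vector("list", nrow(pp)), pp$pathway)
  lfc <- numeric(0)
  for (i in seq_len(nrow(pp))) {
    mem <- pathways[[pp$pathway[i]]]
    aff <- sample(mem, round(pp$affected_fraction[i] * length(mem)))
    affected[[pp$pathway[i]]] <- aff
    lfc[aff] <- pp$effect_size[i]
  }

  edge_rows <- list()
  for (i in seq_len(config$n_pathways)) {
    mem <- sort(pathways[[i]])
    if (length(mem) < 2) next
    prs <- utils::combn(mem, 2)
    pick <- stats::runif(ncol(prs)) < config$pathway_edge_density
    if (!any(pick)) pick[sample(ncol(prs), 1)] <- TRUE  # keep pathway wired
    edge_rows[[i]] <- data.frame(
      source = prs[1, pick], target = prs[2, pick],
      sign = sample(c(1L, -1L), sum(pick), replace = TRUE),
      relation = "interacts",
      tissue_evidence = stats::runif(sum(pick)) < 0.7,
      stringsAsFactors = FALSE)
  }
  interacts <- do.call(rbind, edge_rows)
  if (!is.null(interacts))
    interacts <- interacts[!duplicated(paste(interacts$source,
                                             interacts$target)), ]

  pathway_genes <- unique(unlist(pathways))
  free_genes <- setdiff(genes, pathway_genes)
  reg_rows <- list()
  reg_activation <- stats::setNames(integer(0), character(0))
  planted_regs <- regs[seq_len(config$n_planted_regulators)]
  reg_pool <- free_genes
  for (j in seq_along(regs)) {
    r <- regs[j]
    if (r %in% planted_regs) {
      a <- if (j %% 2L == 1L) 1L else -1L  # alternate activated/inhibited
      reg_activation[r] <- a
      tg <- sample(reg_pool, min(config$targets_per_regulator,
                                 length(reg_pool)))
      reg_pool <- setdiff(reg_pool, tg)  # planted programs never share genes
      sg <- sample(c(1L, -1L), length(tg), replace = TRUE, prob = c(.7, .3))
      lfc[tg] <- a * sg * config$regulator_effect
    } else {
      tg <- sample(genes, min(config$targets_per_regulator, length(genes)))
      sg <- sample(c(1L, -1L), length(tg), replace = TRUE, prob = c(.7, .3))
    }
    reg_rows[[r]] <- data.frame(
      source = r, target = tg, sign = sg, relation = "regulates",
      tissue_evidence = stats::runif(length(tg)) < 0.9,
      stringsAsFactors = FALSE)
  }
  edges <- rbind(interacts, do.call(rbind, reg_rows))

  aff_genes <- intersect(unique(unlist(affected)), genes)
  planted_mirs <- mirnas[seq_len(config$n_planted_mirnas)]
  n_inv <- round(config$mirna_inverse_fraction * length(planted_mirs))
  inverse_mirs <- planted_mirs[seq_len(n_inv)]
  mir_rows <- list()
  mirna_lfc <- stats::setNames(numeric(0), character(0))
  for (m in mirnas) {
    planted <- m %in% planted_mirs
    pool <- if (planted && length(aff_genes)) aff_genes else genes
    tg <- sample(pool, min(config$targets_per_mirna, length(pool)))
    ev <- if (planted)
      sample(c("validated", "high_predicted", "low_predicted"), length(tg),
             replace = TRUE, prob = c(.45, .45, .10))
    else
      sample(EVIDENCE_LEVELS, length(tg), replace = TRUE)
    mir_rows[[m]] <- data.frame(mirna = m, target = tg, evidence = ev,
                                stringsAsFactors = FALSE)
    if (planted) {
      # affected targets are planted up; inverse miRNAs go down
      mirna_lfc[m] <- if (m %in% inverse_mirs) -config$mirna_effect
                      else config$mirna_effect
    }
  }
  mirna_targets <- do.call(rbind, mir_rows)
  rownames(mirna_targets) <- NULL

  kb <- knowledge_base(pathways, edges, mirna_targets, regulators = regs)
  attr(kb, "truth") <- list(
    lfc = lfc, mirna_lfc = mirna_lfc, affected = affected,
    regulator_activation = reg_activation,
    planted_mirnas = planted_mirs, inverse_mirnas = inverse_mirs)
  kb
}

#' Simulate the four omics layers
#'
#' Transcript and miRNA counts are negative-binomial around lognormal
#' baselines with sample-specific library depths; protein and metabolite
#' intensities are lognormal. Molecules carrying a planted log2 fold change
#' (pathway members, regulator targets, planted miRNAs) have their
#' treatment-group mean shifted accordingly. Protein cells are masked
#' missing-at-random at the configured rate, and the configured number of
#' group-exclusive proteins is present in every sample of one group and
#' absent from all of the other. Deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @param kb the matching knowledge base from [make_knowledge_base()]
#'   (supplies the planted truth).
#' @return named list of `omics_layer`: `transcript`, `protein`,
#'   `metabolite`, `mirna`.
#' @export
simulate_layers <- function(config, kb) {
  stopifnot(inherits(config, "sim_config"))
  truth <- attr(kb, "truth")
  if (is.null(truth))
    stop("kb carries no planted truth; generate it with make_knowledge_base()")
  set.seed(sub_seed(config$seed, 2L))
  n <- config$n_per_group
  samples <- c(sprintf("CON%d", seq_len(n)), sprintf("HFR%d", seq_len(n)))
  groups <- stats::setNames(rep(c("control", "treatment"), each = n), samples)
  is_trt <- groups == "treatment"

  lfc_of <- function(ids, table) {
    out <- stats::setNames(numeric(length(ids)), ids)
    hit <- intersect(ids, names(table))
    out[hit] <- table[hit]
    out
  }

  nb_layer <- function(ids, kind, lfc_table) {
    lfc <- lfc_of(ids, lfc_table)
    base <- exp(stats::rnorm(length(ids), config$baseline_log_mean,
                             config$baseline_log_sd))
    depth <- stats::runif(length(samples), config$depth_range[1],
                          config$depth_range[2])
    mu <- outer(base, depth) * 2^(outer(lfc, as.numeric(is_trt)))
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$count_dispersion),
                  nrow = length(ids),
                  dimnames = list(ids, samples))
    omics_layer(cnt, kind, groups)
  }

  ln_matrix <- function(ids, lfc_table) {
    lfc <- lfc_of(ids, lfc_table)
    mu <- stats::rnorm(length(ids), config$intensity_log_mean,
                       config$intensity_log_sd)
    noise <- matrix(stats::rnorm(length(ids) * length(samples), 0,
                                 config$intensity_noise_sd),
                    nrow = length(ids))
    m <- exp(mu + outer(lfc * log(2), as.numeric(is_trt)) + noise)
    dimnames(m) <- list(ids, samples)
    m
  }

  transcript <- nb_layer(gene_ids(config), "transcript", truth$lfc)
  mirna <- nb_layer(mirna_ids(config), "mirna", truth$mirna_lfc)

  prot_ids <- gene_ids(config)[seq_len(config$n_proteins)]
  pv <- pv_complete <- ln_matrix(prot_ids, truth$lfc)
  if (config$protein_missing_rate > 0) {
    mask <- matrix(stats::runif(length(pv)) < config$protein_missing_rate,
                   nrow = nrow(pv))
    pv[mask] <- NA_real_
  }
  if (config$n_exclusive_proteins > 0) {
    unplanted <- setdiff(prot_ids, names(truth$lfc)[truth$lfc != 0])
    n_ex <- min(config$n_exclusive_proteins, length(unplanted))
    ex <- sample(unplanted, n_ex)
    half <- ceiling(n_ex / 2)
    trt_only <- ex[seq_len(half)]
    pv[trt_only, is_trt] <- pv_complete[trt_only, is_trt]
    pv[trt_only, !is_trt] <- NA_real_
    if (n_ex > half) {
      ctl_only <- ex[(half + 1):n_ex]
      pv[ctl_only, !is_trt] <- pv_complete[ctl_only, !is_trt]
      pv[ctl_only, is_trt] <- NA_real_
    }
  }
  protein <- omics_layer(pv, "protein", groups)

  metabolite <- omics_layer(ln_matrix(metabolite_ids(config), truth$lfc),
                            "metabolite", groups)

  list(transcript = transcript, protein = protein, metabolite = metabolite,
       mirna = mirna)
}

#' Generate a synthetic trait-gene association table
#'
#' Draws a GWAS-catalog-style table over the configured gene universe,
#' biased so that roughly a third of rows hit planted (affected) genes and
#' the rest background genes; traits come from a fixed metabolic-liver
#' vocabulary and variants are synthetic rs ids.
#'
#' @param config a `sim_config`.
#' @param kb knowledge base with planted truth.
#' @param n_rows number of association rows.
#' @return a `trait_table`.
#' @export
make_trait_table <- function(config, kb, n_rows = 60L) {
  stopifnot(inherits(config, "sim_config"))
  truth <- attr(kb, "truth")
  set.seed(sub_seed(config$seed, 3L))
  vocab <- c("non-alcoholic fatty liver disease", "body mass index",
             "type II diabetes", "triglycerides", "total cholesterol",
             "LDL cholesterol", "insulin resistance", "fat body mass",
             "alkaline phosphatase", "aspartate aminotransferase")
  planted <- intersect(names(truth$lfc)[truth$lfc != 0], gene_ids(config))
  n_pl <- min(round(n_rows / 3), length(planted))
  g <- c(sample(planted, n_pl),
         sample(gene_ids(config), n_rows - n_pl, replace = TRUE))
  df <- unique(data.frame(
    gene = g,
    trait = sample(vocab, n_rows, replace = TRUE),
    variant = sprintf("rs%07d", sample.int(9999999L, n_rows)),
    stringsAsFactors = FALSE))
  trait_table(df)
}

#' Write a complete fixture set to disk
#'
#' Emits the four layer tables, the group map, the knowledge base
#' (pathways as GMT, edges and miRNA targets as TSV), a synthetic trait
#' table, and the configuration as YAML -- exactly the formats the package
#' readers consume. Re-running with the same config is byte-identical.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory, created recursively if needed.
#' @return character vector of written file paths (the manifest),
#'   invisibly.
#' @export
write_fixture_set <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  kb <- make_knowledge_base(config)
  layers <- simulate_layers(config, kb)
  traits <- make_trait_table(config, kb)
  p <- function(f) file.path(out_dir, f)
  manifest <- c(
    write_layer(layers$transcript, p("transcripts.tsv")),
    write_layer(layers$protein, p("proteins.tsv")),
    write_layer(layers$metabolite, p("metabolites.tsv")),
    write_layer(layers$mirna, p("mirnas.tsv")),
    write_groups(layers$transcript$groups, p("groups.tsv")),
    write_gmt(kb$pathways, p("pathways.gmt")),
    write_edges(kb$edges, p("edges.tsv")),
    write_mirna_targets(kb$mirna_targets, p("mirna_targets.tsv")),
    write_traits(traits, p("traits.tsv")),
    { cfg <- unclass(config)
      cfg$planted_pathways <- lapply(seq_len(nrow(config$planted_pathways)),
                                     function(i)
                                       as.list(config$planted_pathways[i, ]))
      yaml::write_yaml(cfg, p("config.yml"))
      p("config.yml") })
  invisible(manifest)
}

#' Read a simulation configuration from YAML
#' @param path file written by [write_fixture_set()] (or hand-authored).
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$planted_pathways <- do.call(rbind, lapply(cfg$planted_pathways,
                                                as.data.frame))
  do.call(sim_config, cfg)
}
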