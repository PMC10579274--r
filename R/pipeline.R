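#' Configuration for an end-to-end qSIP pipeline run
#'
#' Assembles the run configuration: input paths (or simulator settings when
#' inputs are simulated), stage toggles, stage parameters and the master
#' seed from which every stage seed is derived deterministically.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage seeds are `seed * 1000 + stage offset`.
#' @param stages named logical vector toggling `qsip`, `diversity`,
#'   `partition`, `classify`, `phylosignal`, `network`; the simulate stage
#'   runs whenever no `fractions` input path is given.
#' @param fractions,features,tree optional input paths (fraction table,
#'   genome-feature table, newick tree). When omitted, the corresponding
#'   input is simulated.
#' @param sim named list of overrides passed to [sim_config()].
#' @param n_boot,ci_level bootstrap settings for the AFE stage.
#' @param n_perm permutations for phylogenetic-signal tests and ANOSIM.
#' @param n_classes correlogram distance classes.
#' @param rho_min,p_max,min_prevalence network thresholds.
#' @param identity_min 16S identity threshold for genome matching (percent).
#' @param positive `"median"` or `"ci"`: what counts as a labeled taxon.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("qsip_run_"), seed = 1,
                            stages = c(qsip = TRUE, diversity = TRUE,
                                       partition = TRUE, classify = TRUE,
                                       phylosignal = TRUE, network = TRUE),
                            fractions = NULL, features = NULL, tree = NULL,
                            sim = list(),
                            n_boot = 1000, ci_level = 0.90, n_perm = 999,
                            n_classes = 8, rho_min = 0.7, p_max = 0.01,
                            min_prevalence = 0.10, identity_min = 95,
                            positive = "median") {
  all_stages <- c("qsip", "diversity", "partition", "classify",
                  "phylosignal", "network")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  if ((st[["partition"]] || st[["classify"]] || st[["phylosignal"]]) &&
      !st[["qsip"]])
    stop("partition, classify and phylosignal stages require the qsip stage")
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = st,
                 fractions = fractions, features = features, tree = tree,
                 sim = sim, n_boot = n_boot, ci_level = ci_level,
                 n_perm = n_perm, n_classes = n_classes, rho_min = rho_min,
                 p_max = p_max, min_prevalence = min_prevalence,
                 identity_min = identity_min,
                 positive = match.arg(positive, c("median", "ci"))),
            class = "pipeline_config")
}

.stage_seed <- function(master, offset) as.integer(master) * 1000L + offset

#' Run the qSIP analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' inputs), per-substrate AFE estimation, diversity and group statistics,
#' resource-partitioning test, utilizer classification, phylogenetic signal,
#' co-occurrence network — writing stage tables under `config$out_dir` and a
#' machine-readable JSON report. Identical configurations produce identical
#' reports.
#'
#' @param config a [pipeline_config()] object (or a path to a YAML file of
#'   arguments for it).
#' @return the run report (nested list), invisibly.
#' @examples
#' cfg <- pipeline_config(out_dir = tempfile(), seed = 3,
#'                        sim = list(n_taxa = 20, reads_per_fraction = 2000),
#'                        n_boot = 100, n_perm = 99)
#' rep <- run_qsip_pipeline(cfg)
#' names(rep)
#' @export
run_qsip_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    seed = config$seed, n_boot = config$n_boot, ci_level = config$ci_level,
    n_perm = config$n_perm, rho_min = config$rho_min, p_max = config$p_max,
    min_prevalence = config$min_prevalence,
    identity_min = config$identity_min, positive = config$positive))

  ## --- inputs: load or simulate ------------------------------------------
  truth <- NULL
  if (is.null(config$fractions)) {
    sim_args <- utils::modifyList(list(seed = .stage_seed(config$seed, 1L)),
                                  config$sim)
    sim <- simulate_experiment(do.call(sim_config, sim_args))
    fractions <- sim$fractions
    truth <- sim$truth
    write_fraction_table(fractions, file.path(config$out_dir, "fractions.tsv"))
    write_truth_table(truth, file.path(config$out_dir, "truth.tsv"))
    report$simulate <- list(n_taxa = nrow(truth),
                            n_tubes = length(unique(fractions$tube)),
                            n_emergent_true = sum(truth$emergent))
  } else {
    if (!file.exists(config$fractions))
      stop("missing input: ", config$fractions)
    fractions <- read_fraction_table(config$fractions)
  }
  taxa <- .fraction_taxa(fractions)

  features <- if (!is.null(config$features)) {
    if (!file.exists(config$features)) stop("missing input: ", config$features)
    read_genome_features(config$features)
  } else if (!is.null(truth)) {
    f <- simulate_genome_features(truth, seed = .stage_seed(config$seed, 2L))
    utils::write.table(f, file.path(config$out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f
  } else NULL

  tree <- if (!is.null(config$tree)) {
    if (!file.exists(config$tree)) stop("missing input: ", config$tree)
    ape::read.tree(config$tree)
  } else {
    set.seed(.stage_seed(config$seed, 3L))
    tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
    ape::write.tree(tr, file.path(config$out_dir, "tree.nwk"))
    tr
  }

  ## --- qsip: per-substrate AFE -------------------------------------------
  afe <- NULL
  if (config$stages[["qsip"]]) {
    afe <- do.call(rbind, lapply(c("acetate", "aspartate"), function(s) {
      qsip_afe(fractions, s, n_boot = config$n_boot,
               ci_level = config$ci_level,
               seed = .stage_seed(config$seed, 4L))
    }))
    write_afe_table(afe, file.path(config$out_dir, "afe.tsv"))
    labeled <- .is_labeled(afe, config$positive)
    report$qsip <- list(
      n_scored = sum(afe$status == "scored") / 2,
      n_emergent = nrow(detect_emergent_taxa(fractions)),
      labeled_acetate = sum(labeled & afe$substrate == "acetate"),
      labeled_aspartate = sum(labeled & afe$substrate == "aspartate"))
  }

  ## --- diversity ----------------------------------------------------------
  ta <- tube_abundance(fractions)
  if (config$stages[["diversity"]]) {
    ab <- ta$abundance
    alpha <- data.frame(
      tube = rownames(ab), treatment = ta$meta$treatment,
      chao1 = apply(round(sweep(ab, 1, rowSums(ab), "/") * 1e5), 1, chao1),
      shannon = apply(ab, 1, shannon),
      pielou = apply(ab, 1, pielou), stringsAsFactors = FALSE)
    utils::write.table(alpha, file.path(config$out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d <- bray_curtis(ab)
    ord <- pcoa(d, k = 2)
    # ANOSIM needs replicated groups: drop treatments with a single tube
    cnt <- table(ta$meta$treatment)
    rep_tubes <- ta$meta$treatment %in% names(cnt)[cnt >= 2]
    an <- anosim_test(bray_curtis(ab[rep_tubes, , drop = FALSE]),
                      ta$meta$treatment[rep_tubes], n_perm = config$n_perm,
                      seed = .stage_seed(config$seed, 5L))
    kw <- kruskal_wallis(split(rowSums(ab), ta$meta$treatment))
    report$diversity <- list(
      mean_shannon = mean(alpha$shannon),
      anosim_R = an$R, anosim_p = an$p,
      kruskal_H = kw$H, kruskal_p = kw$p,
      pcoa_axis1_var = ord$variance_explained[1])
  }

  ## --- partition: Venn counts + chi-square --------------------------------
  if (config$stages[["partition"]]) {
    ace <- afe[afe$substrate == "acetate", ]
    asp <- afe[afe$substrate == "aspartate", ]
    common <- intersect(ace$taxon[ace$status == "scored"],
                        asp$taxon[asp$status == "scored"])
    lab_ace <- ace$taxon[.is_labeled(ace, config$positive)]
    lab_asp <- asp$taxon[.is_labeled(asp, config$positive)]
    n_a <- length(intersect(lab_asp, common))
    n_b <- length(intersect(lab_ace, common))
    n_both <- length(intersect(intersect(lab_ace, lab_asp), common))
    pt <- partition_test(length(common), n_a, n_b, n_both)
    report$partition <- list(n_total = length(common),
                             labeled_aspartate = n_a, labeled_acetate = n_b,
                             labeled_both = n_both,
                             chi2 = pt$chi2, p = pt$p)
  }

  ## --- classify ------------------------------------------------------------
  if (config$stages[["classify"]] && !is.null(features)) {
    calls <- classify_utilizers(afe, features,
                                identity_min = config$identity_min,
                                positive = config$positive)
    utils::write.table(calls, file.path(config$out_dir, "utilizer_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$classify <- lapply(split(calls$class, calls$substrate),
                              function(cl) as.list(table(cl)))
  }

  ## --- phylosignal ----------------------------------------------------------
  if (config$stages[["phylosignal"]]) {
    asp <- afe[afe$substrate == "aspartate" & afe$status == "scored", ]
    trait <- stats::setNames(asp$afe_median, asp$taxon)
    trait <- trait[names(trait) %in% tree$tip.label]
    if (length(trait) >= 4 && stats::sd(trait) > 0) {
      sub <- ape::keep.tip(tree, names(trait))
      mi <- morans_i(trait, moran_weights(sub), n_perm = config$n_perm,
                     seed = .stage_seed(config$seed, 6L))
      cm <- abouheif_cmean(trait, sub, n_perm = config$n_perm,
                           seed = .stage_seed(config$seed, 7L))
      cg <- phylo_correlogram(trait, sub, n_classes = config$n_classes,
                              n_perm = config$n_perm,
                              seed = .stage_seed(config$seed, 8L))
      utils::write.table(cg, file.path(config$out_dir, "correlogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$phylosignal <- list(
        n_tips = length(trait),
        moran_I = mi$observed, moran_p = mi$p,
        cmean = cm$observed, cmean_p = cm$p)
    } else {
      report$phylosignal <- list(n_tips = length(trait),
                                 note = "too few scored tips for signal tests")
    }
  }

  ## --- network ---------------------------------------------------------------
  if (config$stages[["network"]]) {
    net <- co_occurrence_network(ta$abundance,
                                 min_prevalence = config$min_prevalence,
                                 rho_min = config$rho_min,
                                 p_max = config$p_max,
                                 seed = .stage_seed(config$seed, 9L))
    if (nrow(net$edges) > 0)
      utils::write.table(net$edges, file.path(config$out_dir, "edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    report$network <- list(
      n_nodes = if (is.null(net$metrics)) 0L else net$metrics$n_nodes,
      n_edges = nrow(net$edges),
      modularity = net$modularity,
      n_modules = length(unique(net$nodes$module)),
      average_degree = if (is.null(net$metrics)) NA else
        net$metrics$average_degree,
      average_path_length = if (is.null(net$metrics)) NA else
        net$metrics$average_path_length,
      clustering_coefficient = if (is.null(net$metrics)) NA else
        net$metrics$clustering_coefficient)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(report)
}

# labeled taxon = scored with positive evidence per the configured rule
.is_labeled <- function(afe, positive) {
  scored <- afe$status == "scored"
  if (positive == "median") scored & !is.na(afe$afe_median) & afe$afe_median > 0
  else scored & !is.na(afe$ci_low) & afe$ci_low > 0
}
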