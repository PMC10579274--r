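#' Configuration for a synthetic qSIP experiment
#'
#' Bundles and validates every knob of the forward simulator. The default
#' design mirrors the incubation layout of a hot-spring sediment qSIP study:
#' \eqn{^{13}}C-acetate (n = 3), \eqn{^{13}}C-aspartate (n = 4),
#' natural-abundance acetate (n = 4), a single no-substrate control, and four
#' unincubated (initial) samples, with 13--15 density fractions per tube.
#'
#' @param n_taxa number of taxa (ASVs) in the community.
#' @param seed integer seed governing every random draw of the simulation.
#' @param gc_range range of genomic GC contents, a pair of fractions inside
#'   `[0.25, 0.75]`.
#' @param labeled_fraction probability that a taxon assimilates a given
#'   substrate (drawn independently per substrate).
#' @param afe_values pool of true atom-fraction-excess values assigned to
#'   assimilating taxa; all must stay below the full-labeling bound
#'   `1 - nat_abund_13C`.
#' @param abundance_lognormal `c(meanlog, sdlog)` of the per-taxon tube-level
#'   abundance distribution (16S copies per g sediment).
#' @param n_fractions_range inclusive range of fractions per tube; the count
#'   is drawn uniformly per tube so downstream code must handle ragged tables.
#' @param density_grid min/max buoyant density of the gradient (g/mL).
#' @param within_taxon_density_sd spread of one taxon's DNA around its mean
#'   buoyant density (g/mL).
#' @param reads_per_fraction amplicon reads sequenced per fraction; `Inf`
#'   replaces multinomial sampling with exact expected proportions.
#' @param qpcr_cv coefficient of variation of the multiplicative lognormal
#'   qPCR noise on per-fraction total copies; 0 disables the noise.
#' @param replicates named integer vector of tubes per treatment; names must
#'   be among `13C-acetate`, `13C-aspartate`, `nat-acetate`, `control`,
#'   `initial`.
#' @param emergent_taxa number of taxa absent from every unlabeled and
#'   initial tube but present (and labeled) in isotope-amended tubes.
#' @param calibration a [gradient_calibration()] object used by the forward
#'   density model.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 200,
                       seed = 1,
                       gc_range = c(0.35, 0.65),
                       labeled_fraction = 0.3,
                       afe_values = c(0, 0.05, 0.2, 0.5),
                       abundance_lognormal = c(meanlog = 14, sdlog = 2),
                       n_fractions_range = c(13L, 15L),
                       density_grid = c(1.60, 1.78),
                       within_taxon_density_sd = 0.008,
                       reads_per_fraction = 50000,
                       qpcr_cv = 0.1,
                       replicates = c(`13C-acetate` = 3L, `13C-aspartate` = 4L,
                                      `nat-acetate` = 4L, control = 1L,
                                      initial = 4L),
                       emergent_taxa = 5L,
                       calibration = gradient_calibration()) {
  cal <- .as_calibration(calibration)
  stopifnot(
    length(n_taxa) == 1, n_taxa >= 2,
    length(seed) == 1, is.finite(seed),
    length(gc_range) == 2, gc_range[1] < gc_range[2],
    gc_range[1] >= 0.25, gc_range[2] <= 0.75,
    length(labeled_fraction) == 1, labeled_fraction >= 0, labeled_fraction <= 1,
    length(afe_values) >= 1, all(afe_values >= 0),
    length(abundance_lognormal) == 2, abundance_lognormal[2] >= 0,
    length(n_fractions_range) == 2,
    n_fractions_range[1] >= 13, n_fractions_range[2] <= 15,
    n_fractions_range[1] <= n_fractions_range[2],
    length(density_grid) == 2, density_grid[1] < density_grid[2],
    within_taxon_density_sd >= 0,
    length(reads_per_fraction) == 1, reads_per_fraction > 0,
    qpcr_cv >= 0,
    length(replicates) >= 1, all(replicates >= 1),
    emergent_taxa >= 0, emergent_taxa < n_taxa
  )
  if (any(afe_values >= 1 - cal$nat_abund_13C))
    stop("afe_values must all be below the full-labeling bound 1 - nat_abund_13C")
  known <- c("13C-acetate", "13C-aspartate", "nat-acetate", "control", "initial")
  if (!all(names(replicates) %in% known))
    stop("replicate names must be among: ", paste(known, collapse = ", "))
  labeled <- intersect(names(replicates), c("13C-acetate", "13C-aspartate"))
  unlabeled <- intersect(names(replicates), c("nat-acetate", "control", "initial"))
  if (length(labeled) == 0 || length(unlabeled) == 0)
    stop("need at least one labeled and one unlabeled treatment")
  # the grid must cover the heaviest attainable taxon density plus its spread
  w_max <- taxon_mean_density(gc_range[2], max(afe_values), cal)
  w_min <- taxon_mean_density(gc_range[1], 0, cal)
  if (w_max + 3 * within_taxon_density_sd > density_grid[2] ||
      w_min - 3 * within_taxon_density_sd < density_grid[1])
    stop("density_grid does not cover the simulated taxon densities (+/- 3 sd)")
  structure(
    list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
         gc_range = gc_range, labeled_fraction = labeled_fraction,
         afe_values = afe_values, abundance_lognormal = abundance_lognormal,
         n_fractions_range = as.integer(n_fractions_range),
         density_grid = density_grid,
         within_taxon_density_sd = within_taxon_density_sd,
         reads_per_fraction = reads_per_fraction, qpcr_cv = qpcr_cv,
         replicates = replicates, emergent_taxa = as.integer(emergent_taxa),
         calibration = cal),
    class = "sim_config"
  )
}

#' Forward-simulate a qSIP density-gradient experiment
#'
#' Generates a complete experiment with known ground truth: a community of
#' taxa with GC content, per-substrate true AFE and tube-level abundance;
#' per-tube density fractions on an equal-width grid; each taxon's DNA mass
#' spread across fractions by Normal CDF differences around its
#' treatment-dependent mean density (mass outside the grid is truncated and
#' renormalized); per-fraction relative abundances as multinomial read draws;
#' and per-fraction qPCR totals with multiplicative lognormal noise.
#' Emergent taxa carry zero abundance in every unlabeled and initial tube.
#'
#' All randomness derives from `config$seed`: the same config reproduces the
#' output exactly.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `qsip_simulation` with elements
#'   \describe{
#'     \item{fractions}{data frame, one row per tube x fraction: `tube`,
#'       `treatment`, `fraction`, `density`, `total_copies`, then one relative
#'       abundance column per taxon.}
#'     \item{truth}{data frame `taxon`, `gc_true`, `afe_acetate`,
#'       `afe_aspartate`, `abundance`, `emergent`.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulate_experiment(sim_config(n_taxa = 20, seed = 42,
#'                                       reads_per_fraction = 2000))
#' head(sim$truth)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cal <- cfg$calibration
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  taxa <- sprintf("ASV%04d", seq_len(n))

  gc <- stats::runif(n, cfg$gc_range[1], cfg$gc_range[2])
  pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
  draw_afe <- function() {
    hit <- stats::runif(n) < cfg$labeled_fraction
    ifelse(hit, pick(cfg$afe_values, n), 0)
  }
  afe_ace <- draw_afe()
  afe_asp <- draw_afe()
  abundance <- stats::rlnorm(n, cfg$abundance_lognormal[1],
                             cfg$abundance_lognormal[2])
  emergent <- rep(FALSE, n)
  if (cfg$emergent_taxa > 0) {
    idx <- sample.int(n, cfg$emergent_taxa)
    emergent[idx] <- TRUE
    # emergent taxa appear only after labeling; give them a positive AFE so
    # the labeled signal that reveals them is physically motivated
    pos_vals <- cfg$afe_values[cfg$afe_values > 0]
    if (length(pos_vals) > 0) {
      afe_ace[idx] <- pick(pos_vals, length(idx))
      afe_asp[idx] <- pick(pos_vals, length(idx))
    }
  }

  treatments <- rep(names(cfg$replicates), cfg$replicates)
  tubes <- sprintf("tube%02d", seq_along(treatments))

  sdlog_q <- if (cfg$qpcr_cv > 0) sqrt(log(1 + cfg$qpcr_cv^2)) else 0
  rows <- vector("list", length(tubes))
  for (t in seq_along(tubes)) {
    treat <- treatments[t]
    afe_t <- switch(treat,
                    `13C-acetate` = afe_ace,
                    `13C-aspartate` = afe_asp,
                    rep(0, n))
    present <- abundance
    if (!treat %in% c("13C-acetate", "13C-aspartate"))
      present[emergent] <- 0
    nf <- if (cfg$n_fractions_range[1] == cfg$n_fractions_range[2])
      cfg$n_fractions_range[1]
    else
      sample(seq(cfg$n_fractions_range[1], cfg$n_fractions_range[2]), 1)
    bounds <- seq(cfg$density_grid[1], cfg$density_grid[2], length.out = nf + 1)
    mids <- (bounds[-1] + bounds[-(nf + 1)]) / 2
    mu <- taxon_mean_density(gc, afe_t, cal)
    # fraction x taxon matrix of bin masses (Normal CDF differences,
    # truncated to the grid and renormalized)
    if (cfg$within_taxon_density_sd > 0) {
      cdf <- outer(bounds, mu, function(b, m)
        stats::pnorm(b, mean = m, sd = cfg$within_taxon_density_sd))
      share <- cdf[-1, , drop = FALSE] - cdf[-(nf + 1), , drop = FALSE]
      tot <- colSums(share)
      tot[tot == 0] <- 1
      share <- sweep(share, 2, tot, "/")
    } else {
      # degenerate spread: all mass in the bin containing the mean density
      bin <- pmin(pmax(findInterval(mu, bounds, all.inside = TRUE), 1), nf)
      share <- matrix(0, nf, n)
      share[cbind(bin, seq_len(n))] <- 1
    }
    copies <- sweep(share, 2, present, "*")     # fraction x taxon, copies/g
    true_total <- rowSums(copies)
    obs_total <- if (sdlog_q > 0)
      true_total * stats::rlnorm(nf, -sdlog_q^2 / 2, sdlog_q)
    else
      true_total
    rel <- matrix(0, nf, n)
    for (k in seq_len(nf)) {
      if (true_total[k] <= 0) next
      pr <- copies[k, ] / true_total[k]
      if (is.finite(cfg$reads_per_fraction)) {
        cnt <- stats::rmultinom(1, size = cfg$reads_per_fraction, prob = pr)
        rel[k, ] <- cnt[, 1] / cfg$reads_per_fraction
      } else {
        rel[k, ] <- pr
      }
    }
    colnames(rel) <- taxa
    rows[[t]] <- data.frame(tube = tubes[t], treatment = treat,
                            fraction = seq_len(nf), density = mids,
                            total_copies = obs_total, rel,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  fractions <- do.call(rbind, rows)
  rownames(fractions) <- NULL
  truth <- data.frame(taxon = taxa, gc_true = gc, afe_acetate = afe_ace,
                      afe_aspartate = afe_asp, abundance = abundance,
                      emergent = emergent, stringsAsFactors = FALSE)
  structure(list(fractions = fractions, truth = truth, config = cfg),
            class = "qsip_simulation")
}

#' @export
print.qsip_simulation <- function(x, ...) {
  cat(sprintf("qSIP simulation: %d taxa, %d tubes, %d fraction rows\n",
              nrow(x$truth), length(unique(x$fractions$tube)),
              nrow(x$fractions)))
  cat("treatments:", paste(sprintf("%s (n=%d)", names(x$config$replicates),
                                   x$config$replicates), collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic genome-feature table matched to a simulated community
#'
#' Generates per-taxon genome features (transporter and pathway presence
#' flags, MAG quality, 16S identity, source spring) consistent with the
#' simulated truth: taxa with a positive true AFE for a substrate usually
#' receive the genomic machinery to assimilate it, while a configurable
#' minority lack it and will be called cross-feeders downstream. This is
#' synthetic plumbing for end-to-end runs, not a model of real annotation.
#'
#' @param truth the `truth` data frame of a [simulate_experiment()] result.
#' @param seed integer seed.
#' @param cross_feeder_rate probability that an assimilating taxon lacks the
#'   genomic machinery (making it a cross-feeder).
#' @param genome_rate probability that a taxon has a matched genome at all.
#' @return data frame with one row per taxon that has a matched genome.
#' @export
simulate_genome_features <- function(truth, seed = 1, cross_feeder_rate = 0.2,
                                     genome_rate = 0.75) {
  stopifnot(is.data.frame(truth), all(c("taxon", "afe_acetate",
                                        "afe_aspartate") %in% names(truth)))
  set.seed(seed)
  n <- nrow(truth)
  has_genome <- stats::runif(n) < genome_rate
  springs <- c("Gongxiaoshe", "Jinze", "Rehai", "other")
  asp_user <- truth$afe_aspartate > 0
  ace_user <- truth$afe_acetate > 0
  asp_machinery <- asp_user & stats::runif(n) >= cross_feeder_rate
  ace_machinery <- ace_user & stats::runif(n) >= cross_feeder_rate
  flag <- function(base, p_bg = 0.1) base | stats::runif(n) < p_bg
  feats <- data.frame(
    taxon = truth$taxon,
    genome = sprintf("MAG%04d", seq_len(n)),
    source_spring = sample(springs, n, replace = TRUE,
                           prob = c(0.2, 0.35, 0.35, 0.1)),
    identity_16S = round(stats::runif(n, 95.5, 100), 2),
    completeness = round(stats::runif(n, 0.7, 1), 3),
    contamination = round(stats::runif(n, 0, 0.08), 3),
    size_obs = round(stats::runif(n, 1.2e6, 4e6)),
    gltI = flag(asp_machinery),
    peb1A = flag(rep(FALSE, n), 0.05),
    aapJ = flag(rep(FALSE, n), 0.05),
    abc_pa_s = flag(asp_machinery, 0.15),
    gltP = flag(rep(FALSE, n), 0.05),
    gltT = flag(rep(FALSE, n), 0.05),
    gltTK = flag(rep(FALSE, n), 0.02),
    gltPh = flag(rep(FALSE, n), 0.02),
    ybeC = flag(rep(FALSE, n), 0.02),
    actP = flag(ace_machinery & stats::runif(n) < 0.5, 0.05),
    atcase = flag(asp_machinery, 0.2),
    ack_pta = flag(ace_machinery, 0.15),
    acs = flag(ace_machinery & stats::runif(n) < 0.5, 0.1),
    doubling_time_h = round(stats::rlnorm(n, log(6), 0.6), 2),
    stringsAsFactors = FALSE
  )
  feats[has_genome, , drop = FALSE]
}

#' Read / write fraction-level observation tables
#'
#' The on-disk format is UTF-8 tab-separated text with a header: columns
#' `tube`, `treatment`, `fraction`, `density`, `total_copies` followed by one
#' relative-abundance column per taxon.
#'
#' @param fractions a fraction table as produced by [simulate_experiment()].
#' @param path file path.
#' @return `read_fraction_table()` returns the data frame;
#'   `write_fraction_table()` returns `path` invisibly.
#' @export
write_fraction_table <- function(fractions, path) {
  .check_fraction_table(fractions)
  utils::write.table(fractions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_table
#' @export
read_fraction_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .check_fraction_table(df)
  df
}

.fraction_core_cols <- c("tube", "treatment", "fraction", "density",
                         "total_copies")

.check_fraction_table <- function(df) {
  if (!is.data.frame(df) || !all(.fraction_core_cols %in% names(df)))
    stop("fraction table must contain columns: ",
         paste(.fraction_core_cols, collapse = ", "))
  taxa <- setdiff(names(df), .fraction_core_cols)
  if (length(taxa) == 0) stop("fraction table has no taxon columns")
  rel <- as.matrix(df[, taxa, drop = FALSE])
  if (any(rel < 0) || any(rel > 1))
    stop("relative abundances must lie in [0, 1]")
  if (any(rowSums(rel) > 1 + 1e-6))
    stop("per-fraction relative abundances must sum to <= 1")
  if (any(df$total_copies < 0)) stop("total_copies must be nonnegative")
  invisible(df)
}

.fraction_taxa <- function(df) setdiff(names(df), .fraction_core_cols)

#' Write the simulator's ground-truth table
#'
#' Tab-separated text with header
#' `taxon gc_true afe_acetate afe_aspartate abundance emergent`.
#'
#' @param truth the `truth` element of a [simulate_experiment()] result.
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
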