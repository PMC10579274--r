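#' Weighted average density of one taxon in one tube
#'
#' The copy-number-weighted mean buoyant density (WAD) across the gradient
#' fractions of a single tube: \eqn{\sum_k x_k y_k / \sum_k y_k} with
#' \eqn{y_k = p_k f_k} (relative abundance times total copies). Returns `NA`
#' when the taxon carries zero copies in every fraction of the tube; the
#' caller aggregates absent tubes rather than erroring.
#'
#' @param density per-fraction buoyant densities (g/mL).
#' @param copies per-fraction taxon copy numbers (same length).
#' @return WAD in g/mL, or `NA_real_` if the taxon is absent from the tube.
#' @examples
#' weighted_average_density(c(1.70, 1.71, 1.72), c(100, 300, 100))  # 1.71
#' @export
weighted_average_density <- function(density, copies) {
  stopifnot(length(density) == length(copies), all(copies >= 0))
  tot <- sum(copies)
  if (tot == 0) return(NA_real_)
  sum(density * copies) / tot
}

# Per tube x taxon WAD matrix from a fraction table. Rows: tubes; cols: taxa.
# NA marks taxa absent from a tube.
.wad_matrix <- function(fractions) {
  taxa <- .fraction_taxa(fractions)
  tubes <- unique(fractions$tube)
  out <- matrix(NA_real_, length(tubes), length(taxa),
                dimnames = list(tubes, taxa))
  for (tb in tubes) {
    sub <- fractions[fractions$tube == tb, , drop = FALSE]
    y <- as.matrix(sub[, taxa, drop = FALSE]) * sub$total_copies
    tot <- colSums(y)
    wad <- colSums(y * sub$density) / tot
    wad[tot == 0] <- NA_real_
    out[tb, ] <- wad
  }
  out
}

#' Per-tube weighted average densities for all taxa
#'
#' @param fractions a fraction table (see [read_fraction_table()] for the
#'   format).
#' @return a list with `wad` (tube x taxon matrix of WADs, `NA` where a taxon
#'   is absent from a tube) and `treatment` (named character vector, one
#'   treatment label per tube).
#' @export
wad_table <- function(fractions) {
  .check_fraction_table(fractions)
  w <- .wad_matrix(fractions)
  tr <- fractions$treatment[match(rownames(w), fractions$tube)]
  names(tr) <- rownames(w)
  list(wad = w, treatment = tr)
}

# treatment labels entering the unlabeled pool for an AFE comparison
.unlabeled_treatments <- function(include_initial = FALSE) {
  out <- c("nat-acetate", "control")
  if (include_initial) out <- c(out, "initial")
  out
}

.labeled_treatment <- function(substrate) {
  substrate <- match.arg(substrate, c("acetate", "aspartate"))
  paste0("13C-", substrate)
}

#' Detect emergent taxa
#'
#' Emergent taxa appear only after isotope labeling: zero copies in every
#' unlabeled and initial tube, nonzero copies in at least one labeled tube of
#' the substrate. They carry no pre-labeling density information, so no AFE
#' can be computed for them; they are flagged instead.
#'
#' @inheritParams wad_table
#' @param substrate `"acetate"`, `"aspartate"`, or `"both"` (default): which
#'   labeled treatments to scan.
#' @return data frame with columns `taxon` and `substrate`.
#' @export
detect_emergent_taxa <- function(fractions, substrate = "both") {
  .check_fraction_table(fractions)
  substrate <- match.arg(substrate, c("both", "acetate", "aspartate"))
  subs <- if (substrate == "both") c("acetate", "aspartate") else substrate
  taxa <- .fraction_taxa(fractions)
  copies <- as.matrix(fractions[, taxa, drop = FALSE]) * fractions$total_copies
  unl <- fractions$treatment %in% c("nat-acetate", "control", "initial")
  absent_unlabeled <- colSums(copies[unl, , drop = FALSE]) == 0
  res <- list()
  for (s in subs) {
    lab <- fractions$treatment == .labeled_treatment(s)
    present_lab <- colSums(copies[lab, , drop = FALSE]) > 0
    hit <- taxa[absent_unlabeled & present_lab]
    if (length(hit) > 0)
      res[[s]] <- data.frame(taxon = hit, substrate = s,
                             stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(taxon = character(), substrate = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bootstrap AFE for one taxon from per-tube densities
#'
#' Point estimate from the treatment-mean WADs; uncertainty by resampling
#' tubes with replacement independently within the labeled and unlabeled
#' groups, recomputing AFE per iterate, and taking the median and percentile
#' interval. With a single tube in a group the interval is degenerate in that
#' group's dimension and a warning is emitted.
#'
#' @param wads_light per-tube WADs in unlabeled tubes (g/mL).
#' @param wads_lab per-tube WADs in labeled tubes (g/mL).
#' @param n_boot number of bootstrap iterates (>= 1).
#' @param ci_level two-sided percentile interval level (default 0.90).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the result is reproducible in isolation.
#' @inheritParams taxon_mean_density
#' @return a list: `w_light`, `w_lab`, `gc_est`, `afe_point`, `afe_median`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_tubes_light`, `n_tubes_lab`.
#' @export
afe_with_bootstrap <- function(wads_light, wads_lab, n_boot = 1000,
                               ci_level = 0.90, seed = NULL,
                               calibration = gradient_calibration()) {
  cal <- .as_calibration(calibration)
  wads_light <- wads_light[!is.na(wads_light)]
  wads_lab <- wads_lab[!is.na(wads_lab)]
  if (length(wads_light) < 1 || length(wads_lab) < 1)
    stop("need at least one labeled and one unlabeled tube WAD")
  if (n_boot < 1) stop("n_boot must be >= 1")
  stopifnot(ci_level > 0, ci_level < 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(wads_light) == 1)
    warning("only one unlabeled tube: confidence interval is degenerate in the unlabeled dimension")
  res <- .afe_boot_core(wads_light, wads_lab, n_boot, ci_level, cal)
  res
}

# shared by afe_with_bootstrap() and qsip_afe(); assumes RNG state is set
.afe_boot_core <- function(wl, wb, n_boot, ci_level, cal) {
  w_light <- mean(wl)
  w_lab <- mean(wb)
  gc_pt <- .gc_from_density(w_light, cal)
  afe_point <- .afe_from_densities(w_light, w_lab, gc_pt, cal)
  nl <- length(wl)
  nb <- length(wb)
  bl <- matrix(wl[sample.int(nl, n_boot * nl, replace = TRUE)], n_boot, nl)
  bb <- matrix(wb[sample.int(nb, n_boot * nb, replace = TRUE)], n_boot, nb)
  wl_star <- rowMeans(bl)
  wb_star <- rowMeans(bb)
  afe_star <- .afe_from_densities(wl_star, wb_star,
                                  .gc_from_density(wl_star, cal), cal)
  alpha <- (1 - ci_level) / 2
  qs <- stats::quantile(afe_star, c(alpha, 1 - alpha), names = FALSE)
  list(w_light = w_light, w_lab = w_lab, gc_est = gc_pt,
       afe_point = afe_point, afe_median = stats::median(afe_star),
       ci_low = qs[1], ci_high = qs[2], n_boot = as.integer(n_boot),
       n_tubes_light = nl, n_tubes_lab = nb)
}

#' Per-taxon atom fraction excess for one substrate
#'
#' The main qSIP estimator: computes per-tube weighted average densities,
#' partitions tubes into the labeled treatment (`13C-<substrate>`) and the
#' combined unlabeled pool (natural-abundance acetate plus the no-substrate
#' control; optionally the initial samples), and converts the density shift
#' of each taxon into \eqn{^{13}}C atom fraction excess with tube-level
#' bootstrap uncertainty.
#'
#' A taxon contributes a WAD for a tube only where it has nonzero copies;
#' tubes without the taxon are dropped from that treatment's mean. Taxa with
#' fewer than `min_tubes` informative tubes in either group are reported with
#' status `"unscored"`; taxa absent from all unlabeled and initial tubes but
#' present after labeling are status `"emergent"` and carry no AFE.
#'
#' @inheritParams wad_table
#' @param substrate `"acetate"` or `"aspartate"`.
#' @param n_boot bootstrap iterates (default 1000).
#' @param ci_level percentile CI level (default 0.90).
#' @param seed integer seed; one call to `set.seed()` governs the whole
#'   bootstrap so results are reproducible.
#' @param include_initial include the unincubated (initial) tubes in the
#'   unlabeled pool (default `FALSE`: time-zero chemistry differs).
#' @param min_tubes minimum informative tubes per group to score a taxon
#'   (default 2).
#' @inheritParams taxon_mean_density
#' @return data frame, one row per taxon: `taxon`, `substrate`, `W_light`,
#'   `W_lab`, `gc_est`, `afe_point`, `afe_median`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_tubes_light`, `n_tubes_lab`, `emergent`, `status`
#'   (`"scored"`, `"unscored"`, `"emergent"`, or `"absent"`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_taxa = 15, seed = 7,
#'                                       reads_per_fraction = 5000,
#'                                       emergent_taxa = 1))
#' afe <- qsip_afe(sim$fractions, "aspartate", n_boot = 200, seed = 1)
#' head(afe[, c("taxon", "afe_median", "ci_low", "ci_high", "status")])
#' @export
qsip_afe <- function(fractions, substrate, n_boot = 1000, ci_level = 0.90,
                     seed = 1, include_initial = FALSE, min_tubes = 2,
                     calibration = gradient_calibration()) {
  .check_fraction_table(fractions)
  cal <- .as_calibration(calibration)
  substrate <- match.arg(substrate, c("acetate", "aspartate"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  wt <- wad_table(fractions)
  lab_tubes <- names(wt$treatment)[wt$treatment == .labeled_treatment(substrate)]
  unl_tubes <- names(wt$treatment)[wt$treatment %in%
                                     .unlabeled_treatments(include_initial)]
  if (length(lab_tubes) == 0 || length(unl_tubes) == 0)
    stop("fraction table lacks labeled or unlabeled tubes for ", substrate)
  emergent_tab <- detect_emergent_taxa(fractions, substrate)
  emergent_set <- emergent_tab$taxon
  taxa <- colnames(wt$wad)

  set.seed(seed)
  out <- vector("list", length(taxa))
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    wl <- wt$wad[unl_tubes, tx]
    wb <- wt$wad[lab_tubes, tx]
    wl <- wl[!is.na(wl)]
    wb <- wb[!is.na(wb)]
    base <- data.frame(taxon = tx, substrate = substrate, W_light = NA_real_,
                       W_lab = NA_real_, gc_est = NA_real_,
                       afe_point = NA_real_, afe_median = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       n_boot = NA_integer_, n_tubes_light = length(wl),
                       n_tubes_lab = length(wb), emergent = tx %in% emergent_set,
                       status = "unscored", stringsAsFactors = FALSE)
    if (tx %in% emergent_set) {
      base$status <- "emergent"
    } else if (length(wl) == 0 && length(wb) == 0) {
      base$status <- "absent"
    } else if (length(wl) >= min_tubes && length(wb) >= min_tubes) {
      r <- .afe_boot_core(wl, wb, n_boot, ci_level, cal)
      base$W_light <- r$w_light
      base$W_lab <- r$w_lab
      base$gc_est <- r$gc_est
      base$afe_point <- r$afe_point
      base$afe_median <- r$afe_median
      base$ci_low <- r$ci_low
      base$ci_high <- r$ci_high
      base$n_boot <- r$n_boot
      base$status <- "scored"
    }
    out[[i]] <- base
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an AFE result table
#'
#' Tab-separated text with the columns of [qsip_afe()]'s output.
#'
#' @param afe data frame from [qsip_afe()].
#' @param path file path.
#' @export
write_afe_table <- function(afe, path) {
  utils::write.table(afe, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
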