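#' Convert relative abundances to absolute copies
#'
#' Multiplies each sample's relative abundances by its total 16S copy number
#' from qPCR, the standard absolute-abundance normalization in quantitative
#' microbial ecology.
#'
#' @param rel_abund samples x taxa matrix (or data frame) of relative
#'   abundances; each row must sum to at most `1 + 1e-6`.
#' @param qpcr_totals per-sample total copies (length = number of rows).
#' @return samples x taxa matrix of absolute copies, same dimnames.
#' @export
absolute_abundance <- function(rel_abund, qpcr_totals) {
  m <- as.matrix(rel_abund)
  if (any(m < 0) || any(qpcr_totals < 0))
    stop("relative abundances and qPCR totals must be nonnegative")
  if (nrow(m) != length(qpcr_totals))
    stop("one qPCR total per sample is required")
  if (any(rowSums(m) > 1 + 1e-6))
    stop("per-sample relative abundances must sum to <= 1")
  m * qpcr_totals
}

#' Tube-level absolute abundance from a fraction table
#'
#' Aggregates fraction-level observations to one absolute abundance per tube
#' and taxon: \eqn{\sum_k p_{ik} f_k} over the tube's fractions (relative
#' abundance times qPCR total copies).
#'
#' @inheritParams wad_table
#' @return list with `abundance` (tubes x taxa matrix of copies per g) and
#'   `meta` (data frame `tube`, `treatment`).
#' @export
tube_abundance <- function(fractions) {
  .check_fraction_table(fractions)
  taxa <- .fraction_taxa(fractions)
  tubes <- unique(fractions$tube)
  ab <- matrix(0, length(tubes), length(taxa),
               dimnames = list(tubes, taxa))
  for (tb in tubes) {
    sub <- fractions[fractions$tube == tb, , drop = FALSE]
    ab[tb, ] <- colSums(as.matrix(sub[, taxa, drop = FALSE]) * sub$total_copies)
  }
  meta <- data.frame(tube = tubes,
                     treatment = fractions$treatment[match(tubes, fractions$tube)],
                     stringsAsFactors = FALSE)
  list(abundance = ab, meta = meta)
}

#' Log2 change in abundance with +1 zero handling
#'
#' `log2((after + 1)/(before + 1))`: the offset is applied to all values (not
#' only zeros) for continuity, and the result approaches `log2(after/before)`
#' for large counts.
#'
#' @param before,after nonnegative abundances (vectorized).
#' @return log2 fold change.
#' @export
log2_change <- function(before, after) {
  if (any(before < 0) || any(after < 0))
    stop("abundances must be nonnegative")
  log2((after + 1) / (before + 1))
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: \eqn{S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))} where
#' \eqn{F_1} and \eqn{F_2} are the numbers of singletons and doubletons.
#'
#' @param counts nonnegative integer counts per taxon.
#' @return estimated richness.
#' @examples
#' chao1(c(1, 1, 2, 5, 9))  # 5.5
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0 || all(counts == 0))
    stop("empty community: diversity undefined")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (nats)
#'
#' \eqn{H = -\sum p \ln p} with \eqn{0 \ln 0 := 0}. Counts are accepted and
#' normalized to proportions.
#'
#' @param x proportions (summing to 1) or counts.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(x) {
  if (length(x) == 0 || all(x == 0)) stop("empty community: diversity undefined")
  if (any(x < 0)) stop("abundances must be nonnegative")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Pielou's evenness
#'
#' \eqn{J = H / \ln S_{obs}}, with \eqn{J := 1} for a single-taxon community.
#'
#' @inheritParams shannon
#' @return evenness in `[0, 1]`.
#' @export
pielou <- function(x) {
  s_obs <- sum(x > 0)
  if (s_obs == 0) stop("empty community: diversity undefined")
  if (s_obs == 1) return(1)
  shannon(x) / log(s_obs)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u, v) = \sum |u - v| / \sum (u + v)} over taxa, for every pair of
#' samples.
#'
#' @param abundance samples x taxa matrix of (absolute or relative)
#'   abundances.
#' @return an object of class `dist`.
#' @export
bray_curtis <- function(abundance) {
  m <- as.matrix(abundance)
  if (nrow(m) < 2) stop("need at least two samples")
  if (any(rowSums(m) == 0)) stop("all-zero sample: distance undefined")
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (eigendecomposition of the double-centered
#' squared-distance matrix). Negative eigenvalues are reported, not
#' corrected; variance explained is computed over positive eigenvalues only.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k number of coordinate axes to return (default: all informative).
#' @return list with `points` (samples x k), `eig` (all eigenvalues) and
#'   `variance_explained` (per returned axis, positive eigenvalues only).
#' @export
pcoa <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (is.null(k)) k <- n - 1
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  ve <- fit$eig[seq_len(ncol(fit$points))] / sum(pos)
  ve[ve < 0] <- NA_real_
  list(points = fit$points, eig = fit$eig, variance_explained = ve)
}

#' ANOSIM test of group separation
#'
#' Analysis of similarities on a distance matrix:
#' \eqn{R = (\bar r_{between} - \bar r_{within}) / (n(n-1)/4)} with a
#' permutation p-value over group labels. Deterministic given `seed`.
#'
#' @param d a `dist` object or distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `R`, `p` and `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Kruskal-Wallis rank-sum test
#'
#' Classic H statistic with mid-rank tie correction and a chi-square
#' reference distribution on k - 1 degrees of freedom.
#'
#' @param groups a list of numeric vectors, one per group.
#' @return list with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("invalid grouping: empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 2) stop("need at least two observations")
  if (length(unique(x)) == 1)
    stop("all observations identical: H undefined after tie correction")
  g <- factor(rep(seq_along(groups), sizes))
  fit <- stats::kruskal.test(x, g)
  list(H = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Chi-square test of resource partitioning
#'
#' Builds the 2x2 labeling table from Venn counts — taxa labeled by substrate
#' A, by substrate B, by both, out of a total pool — and tests independence
#' of the two labels. Cells: both, A-only, B-only, neither. The default is
#' Pearson's chi-square test of independence without continuity correction
#' (df = 1); `variant = "gof"` instead runs a goodness-of-fit test of the
#' four observed cells against their expected proportions under independence
#' (df = 3).
#'
#' @param n_total total number of taxa considered.
#' @param n_a,n_b numbers labeled by substrate A and B.
#' @param n_both number labeled by both.
#' @param variant `"independence"` (default) or `"gof"`.
#' @return list with `chi2`, `p`, `df` and `table` (the 2x2 matrix).
#' @examples
#' partition_test(492, 58, 34, 26)  # chi2 ~ 147, p << 0.001
#' @export
partition_test <- function(n_total, n_a, n_b, n_both,
                           variant = c("independence", "gof")) {
  variant <- match.arg(variant)
  if (n_both > min(n_a, n_b))
    stop("inconsistent counts: n_both exceeds a margin")
  cells <- c(both = n_both, a_only = n_a - n_both, b_only = n_b - n_both,
             neither = n_total - n_a - n_b + n_both)
  if (any(cells < 0)) stop("inconsistent counts: negative derived cell")
  tab <- matrix(cells, 2, 2, byrow = TRUE,
                dimnames = list(a = c("yes", "no"), b = c("yes", "no")))
  if (variant == "independence") {
    fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  } else {
    exp_p <- outer(rowSums(tab), colSums(tab)) / n_total^2
    fit <- suppressWarnings(stats::chisq.test(as.vector(tab),
                                              p = as.vector(exp_p)))
  }
  list(chi2 = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), table = tab)
}
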