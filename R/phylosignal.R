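#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return symmetric matrix with zero diagonal, tips as dimnames.
#' @export
patristic_matrix <- function(tree) {
  .check_tree(tree)
  ape::cophenetic.phylo(tree)
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("invalid tree: missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("invalid tree: negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("invalid tree: duplicated tip labels")
  invisible(tree)
}

#' Inverse patristic-distance weights for Moran's I
#'
#' \eqn{w_{ij} = 1/d_{ij}} for distinct tips, zero diagonal. Zero patristic
#' distance between distinct tips is an error (the inverse is undefined);
#' row standardization happens inside [morans_i()].
#'
#' @inheritParams patristic_matrix
#' @return a weight matrix with tips as dimnames.
#' @export
moran_weights <- function(tree) {
  d <- patristic_matrix(tree)
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("zero patristic distance between distinct tips: inverse-distance weights undefined")
  w <- 1 / d
  diag(w) <- 0
  w
}

# align a named trait vector with a weight matrix / tree tip order
.align_trait <- function(trait, labels) {
  if (!is.null(names(trait)) && !is.null(labels)) {
    missing <- setdiff(labels, names(trait))
    if (length(missing) > 0)
      stop("trait values missing for: ", paste(utils::head(missing, 5),
                                               collapse = ", "))
    trait <- trait[labels]
  }
  trait
}

# permutation engine shared by morans_i / abouheif_cmean / correlogram.
# w must already be row-standardized (or intentionally raw); S0 = sum(w).
.moran_perm <- function(z, w, n_perm, alternative) {
  n <- length(z)
  s0 <- sum(w)
  denom <- sum(z^2)
  i_obs <- (n / s0) * sum(z * (w %*% z)) / denom
  zp <- replicate(n_perm, sample(z))
  i_perm <- (n / s0) * colSums(zp * (w %*% zp)) / denom
  p_greater <- (1 + sum(i_perm >= i_obs)) / (1 + n_perm)
  p_less <- (1 + sum(i_perm <= i_obs)) / (1 + n_perm)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  list(observed = i_obs, p = p, permuted = i_perm)
}

.row_standardize <- function(w) {
  rs <- rowSums(w)
  pos <- rs > 0
  w[pos, ] <- w[pos, , drop = FALSE] / rs[pos]
  w
}

#' Moran's I with a permutation test
#'
#' Spatial/phylogenetic autocorrelation of a tip trait:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the centered trait. Weights are row-standardized before use
#' (rows with no positive entry are left at zero). The permutation test
#' shuffles the trait over tips; the default alternative is `"greater"`
#' (phylogenetic signal is positive autocorrelation). The analytic null
#' expectation is \eqn{E[I] = -1/(n-1)}.
#'
#' @param trait numeric trait, one value per tip; names (if present) are
#'   matched against the weight matrix dimnames.
#' @param weights nonnegative weight matrix with zero diagonal; e.g.
#'   [moran_weights()] for inverse patristic distances.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param row_standardize divide each row by its sum before use (default
#'   `TRUE`).
#' @return an object of class `signal_result`: `statistic`, `observed`, `p`,
#'   `n_perm`, `expected` (\eqn{-1/(n-1)}), `alternative`, and the vector of
#'   `permuted` statistics.
#' @export
morans_i <- function(trait, weights, n_perm = 999, seed = 1,
                     alternative = c("greater", "less", "two.sided"),
                     row_standardize = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  trait <- .align_trait(trait, rownames(weights))
  n <- length(trait)
  if (n != nrow(weights)) stop("trait length must match the weight matrix")
  if (n < 4) stop("need at least 4 tips")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (any(diag(weights) != 0)) stop("weight matrix must have zero diagonal")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (stats::sd(trait) == 0) stop("constant trait: Moran's I undefined")
  w <- if (row_standardize) .row_standardize(weights) else weights
  z <- trait - mean(trait)
  set.seed(seed)
  res <- .moran_perm(z, w, n_perm, alternative)
  structure(list(statistic = "MoranI", observed = res$observed, p = res$p,
                 n_perm = as.integer(n_perm), expected = -1 / (n - 1),
                 alternative = alternative, permuted = res$permuted),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (null expectation %.4f), permutation p = %.4g (%s, %d perms)\n",
              x$statistic, x$observed, x$expected, x$p, x$alternative,
              x$n_perm))
  invisible(x)
}

#' Abouheif proximity matrix
#'
#' Topology-only tip proximities: for tips i and j,
#' \eqn{a_{ij} = 1 / \prod \mathrm{dd}(v)} over the internal nodes \eqn{v} on
#' the path between them (the most recent common ancestor counted once),
#' where dd is the number of direct descendants of the node. Branch lengths
#' play no role. Diagonal is zero.
#'
#' @inheritParams patristic_matrix
#' @return symmetric proximity matrix with tips as dimnames.
#' @export
abouheif_proximity <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("invalid tree: duplicated tip labels")
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  dd <- tabulate(tree$edge[, 1], nbins = n_nodes)
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ancestors <- lapply(seq_len(n), function(i) {
    path <- integer(0)
    v <- i
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
  a <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    ai <- ancestors[[i]]
    for (j in seq((i + 1), n)) {
      aj <- ancestors[[j]]
      mrca <- ai[match(TRUE, ai %in% aj)]
      nodes <- c(ai[seq_len(match(mrca, ai))],
                 aj[seq_len(match(mrca, aj) - 1)])
      a[i, j] <- a[j, i] <- 1 / prod(dd[nodes])
    }
  }
  a
}

#' Abouheif's Cmean with a permutation test
#'
#' Moran's I computed with the Abouheif proximity matrix
#' ([abouheif_proximity()]), row-normalized. Because the proximities depend
#' only on node degrees along tip-to-tip paths, the statistic is invariant to
#' any rescaling of branch lengths.
#'
#' @inheritParams morans_i
#' @param tree a rooted `phylo` object.
#' @return a `signal_result` with statistic name `"AbouheifCmean"`.
#' @export
abouheif_cmean <- function(trait, tree, n_perm = 999, seed = 1,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- abouheif_proximity(tree)
  res <- morans_i(trait, a, n_perm = n_perm, seed = seed,
                  alternative = alternative, row_standardize = TRUE)
  res$statistic <- "AbouheifCmean"
  res
}

#' Phylogenetic correlogram
#'
#' Moran's I per patristic-distance class: pairwise distances are binned into
#' `n_classes` equal-count classes, and within each class Moran's I is
#' computed with binary weights (1 when the pair falls in the class) and a
#' seeded permutation p-value. Classes containing no pair are skipped with a
#' warning. A decreasing profile of I with class midpoint is the signature of
#' a phylogenetic gradient: trait similarity concentrated at short
#' phylogenetic distances.
#'
#' @inheritParams abouheif_cmean
#' @param n_classes number of distance classes (>= 2; default 8).
#' @return data frame, ordered by class midpoint: `class`, `d_low`, `d_high`,
#'   `midpoint` (mean pair distance in the class), `n_pairs`, `moran_i`, `p`.
#' @export
phylo_correlogram <- function(trait, tree, n_classes = 8, n_perm = 999,
                              seed = 1,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_classes < 2) stop("n_classes must be >= 2")
  d <- patristic_matrix(tree)
  trait <- .align_trait(trait, rownames(d))
  if (length(trait) != nrow(d)) stop("trait length must match the tree")
  pd <- d[upper.tri(d)]
  breaks <- unique(stats::quantile(pd, probs = seq(0, 1,
                                                   length.out = n_classes + 1),
                                   names = FALSE))
  if (length(breaks) < 3) {
    # few distinct distances (e.g. small symmetric trees): split between
    # the unique values instead of at collapsed quantiles
    u <- sort(unique(pd))
    if (length(u) < 2)
      stop("too few distinct pair distances to form classes")
    breaks <- c(u[1], (u[-1] + u[-length(u)]) / 2, u[length(u)])
  }
  breaks[1] <- breaks[1] - 1e-12
  out <- list()
  for (k in seq_len(length(breaks) - 1)) {
    w <- (d > breaks[k] & d <= breaks[k + 1]) * 1
    diag(w) <- 0
    n_pairs <- sum(w) / 2
    if (n_pairs == 0) {
      warning(sprintf("distance class %d contains no pairs; skipped", k))
      next
    }
    res <- morans_i(trait, w, n_perm = n_perm, seed = seed + k,
                    alternative = alternative, row_standardize = TRUE)
    out[[length(out) + 1]] <- data.frame(
      class = k, d_low = max(breaks[k], 0), d_high = breaks[k + 1],
      midpoint = mean(d[w == 1]), n_pairs = n_pairs,
      moran_i = res$observed, p = res$p)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$midpoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}
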