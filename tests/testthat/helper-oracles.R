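# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# all permutations of a vector (used for exact enumeration on small n)
all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Pearson chi-square on a contingency table, by the textbook formula
hand_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# brute-force shortest paths via Floyd-Warshall on an adjacency matrix
hand_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- min(d[i, j], d[i, k] + d[k, j])
  d
}

# brute-force local clustering coefficient per node
hand_local_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(NaN)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  })
}

# Moran's I by direct double summation (row-standardized weights)
hand_moran <- function(x, w) {
  n <- length(x)
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  unname((n / sum(w)) * num / sum(z^2))
}

# planted-correlation abundance table: `blocks` groups of `per_block` taxa
# driven by shared latent factors plus Gaussian noise
planted_correlation_table <- function(n_samples = 15, blocks = 4,
                                      per_block = 6, noise_sd = 0.3,
                                      seed = 1) {
  set.seed(seed)
  bl <- rep(seq_len(blocks), each = per_block)
  lat <- matrix(rnorm(n_samples * blocks), n_samples, blocks)
  x <- lat[, bl] + matrix(rnorm(n_samples * length(bl), sd = noise_sd),
                          n_samples, length(bl))
  ab <- exp(x)
  colnames(ab) <- sprintf("taxon%02d", seq_along(bl))
  list(abundance = ab, blocks = bl,
       true_pairs = {
         pairs <- character(0)
         for (b in seq_len(blocks)) {
           ix <- which(bl == b)
           for (i in ix) for (j in ix) if (i < j)
             pairs <- c(pairs, paste(colnames(ab)[i], colnames(ab)[j]))
         }
         pairs
       })
}

# row standardization, re-derived independently of the package internals
.row_std_for_test <- function(w) {
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  w
}

# balanced 64-tip unit-branch tree used for power experiments
balanced_tree64 <- function() {
  tr <- ape::stree(64, "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
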