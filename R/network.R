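#' Prevalence filter for network construction
#'
#' Keeps taxa with nonzero abundance in strictly more than `min_prevalence`
#' of the samples (e.g. present in 2 of 15 samples passes a 10% threshold,
#' 1 of 15 does not).
#'
#' @param abundance samples x taxa abundance matrix.
#' @param min_prevalence fraction of samples in (0, 1); `0` keeps every
#'   taxon with at least one occurrence.
#' @return the filtered abundance matrix (possibly with zero columns, in
#'   which case an empty-network warning is emitted).
#' @export
prevalence_filter <- function(abundance, min_prevalence = 0.10) {
  m <- as.matrix(abundance)
  if (min_prevalence < 0 || min_prevalence >= 1)
    stop("min_prevalence must lie in [0, 1)")
  prev <- colMeans(m > 0)
  keep <- prev > min_prevalence
  if (!any(keep)) warning("no taxon passes the prevalence filter: empty network")
  m[, keep, drop = FALSE]
}

# two-sided p for Spearman's rho via the t approximation
.spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  exact1 <- !is.na(rho) & abs(rho) >= 1
  p[exact1] <- 0
  ok <- !is.na(rho) & abs(rho) < 1
  tstat <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Spearman correlation edges
#'
#' Pairwise Spearman rank correlations (mid-ranks for ties) between taxa
#' across samples, with two-sided p-values from the t approximation. Pairs
#' with `rho > rho_min` (or `|rho| > rho_min` when `use_abs = TRUE`) and
#' `p < p_max` are retained as edges. Constant taxa have undefined
#' correlations; their pairs are skipped with a warning.
#'
#' @param abundance samples x taxa abundance matrix (>= 4 samples).
#' @param rho_min correlation threshold (default 0.7, strict inequality).
#' @param p_max significance threshold (default 0.01, strict inequality).
#' @param use_abs admit strong negative correlations too (default `FALSE`:
#'   only positive co-occurrence).
#' @param p_adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, i.e. raw p-values).
#' @return data frame of edges: `source`, `target`, `rho`, `p`.
#' @export
spearman_edges <- function(abundance, rho_min = 0.7, p_max = 0.01,
                           use_abs = FALSE, p_adjust = "none") {
  m <- as.matrix(abundance)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 samples")
  if (ncol(m) < 2)
    return(data.frame(source = character(), target = character(),
                      rho = numeric(), p = numeric()))
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant taxa skipped (undefined correlation): ",
            paste(utils::head(colnames(m)[const], 5), collapse = ", "))
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  p <- .spearman_p(r, n)
  p <- stats::p.adjust(p, method = p_adjust)
  strength <- if (use_abs) abs(r) else r
  keep <- !is.na(r) & strength > rho_min & p < p_max
  data.frame(source = colnames(m)[idx[keep, 1]],
             target = colnames(m)[idx[keep, 2]],
             rho = r[keep], p = p[keep], stringsAsFactors = FALSE)
}

.edges_to_graph <- function(edges, nodes = NULL) {
  igraph::graph_from_data_frame(edges[, c("source", "target")],
                                directed = FALSE, vertices = nodes)
}

#' Module detection by greedy modularity maximization
#'
#' Louvain community detection on the unweighted co-occurrence graph at
#' resolution 1, with Newman modularity of the returned partition.
#' Deterministic for a given seed.
#'
#' @param edges edge data frame (`source`, `target`, ...) or an igraph
#'   object.
#' @param seed integer seed (tie-breaking in the greedy sweep).
#' @return list with `membership` (named integer vector), `modularity`
#'   (Newman Q) and `n_modules`. An empty graph yields an empty partition
#'   with `modularity = NA`.
#' @export
detect_modules <- function(edges, seed = 1) {
  g <- if (inherits(edges, "igraph")) edges else {
    if (nrow(edges) == 0)
      return(list(membership = integer(0), modularity = NA_real_,
                  n_modules = 0L))
    .edges_to_graph(edges)
  }
  if (igraph::ecount(g) == 0)
    return(list(membership = integer(0), modularity = NA_real_,
                n_modules = 0L))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  mem <- igraph::membership(cl)
  list(membership = structure(as.integer(mem), names = names(mem)),
       modularity = igraph::modularity(g, mem),
       n_modules = length(unique(mem)))
}

#' Network topology metrics
#'
#' Average degree (`2E/N` over all nodes), average shortest-path length over
#' connected pairs within the largest connected component (`NA` when that
#' component has fewer than two nodes), and the clustering coefficient as
#' the mean local clustering over nodes of degree >= 2 (`NA` when no node
#' qualifies).
#'
#' @param graph an igraph object or an edge data frame (`source`, `target`).
#' @return list with `n_nodes`, `n_edges`, `average_degree`,
#'   `average_path_length`, `clustering_coefficient`.
#' @export
topology_metrics <- function(graph) {
  g <- if (inherits(graph, "igraph")) graph else .edges_to_graph(graph)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n < 1) stop("need at least one node")
  comps <- igraph::components(g)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == big))
  apl <- if (igraph::vcount(sub) < 2) NA_real_ else
    igraph::mean_distance(sub, directed = FALSE)
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc <- if (any(deg >= 2)) mean(loc[deg >= 2]) else NA_real_
  list(n_nodes = n, n_edges = e, average_degree = 2 * e / n,
       average_path_length = apl, clustering_coefficient = cc)
}

#' Build a co-occurrence network from an abundance table
#'
#' End-to-end network stage: prevalence filter, Spearman edges, Louvain
#' modules, and topology metrics.
#'
#' @inheritParams spearman_edges
#' @param min_prevalence prevalence threshold (default 0.10).
#' @param seed integer seed for module detection.
#' @return list of class `co_network`: `nodes` (data frame `taxon`, `degree`,
#'   `module`), `edges` (with `module_source`, `module_target` appended),
#'   `modularity`, `metrics`.
#' @export
co_occurrence_network <- function(abundance, min_prevalence = 0.10,
                                  rho_min = 0.7, p_max = 0.01, seed = 1,
                                  use_abs = FALSE, p_adjust = "none") {
  m <- prevalence_filter(abundance, min_prevalence)
  edges <- spearman_edges(m, rho_min = rho_min, p_max = p_max,
                          use_abs = use_abs, p_adjust = p_adjust)
  if (nrow(edges) == 0) {
    return(structure(list(nodes = data.frame(taxon = character(),
                                             degree = integer(),
                                             module = integer()),
                          edges = edges, modularity = NA_real_,
                          metrics = NULL),
                     class = "co_network"))
  }
  g <- .edges_to_graph(edges)
  mods <- detect_modules(g, seed = seed)
  deg <- igraph::degree(g)
  nodes <- data.frame(taxon = names(deg), degree = as.integer(deg),
                      module = mods$membership[names(deg)],
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges$module_source <- mods$membership[edges$source]
  edges$module_target <- mods$membership[edges$target]
  structure(list(nodes = nodes, edges = edges,
                 modularity = mods$modularity,
                 metrics = topology_metrics(g)),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges, %d modules (Q = %.3f)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$module)), x$modularity))
  if (!is.null(x$metrics))
    cat(sprintf("  avg degree %.3f | avg path length %.3f | clustering %.3f\n",
                x$metrics$average_degree, x$metrics$average_path_length,
                x$metrics$clustering_coefficient))
  invisible(x)
}
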