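#' Metric computation configuration
#'
#' @param tortuosity_sample_pairs Number of distinct same-component node
#'   pairs sampled for average tortuosity (default 100, to manage computation
#'   time on large skeletons). If fewer valid pairs exist, all are used.
#' @param rng_seed Integer seed controlling the pair sampling; required so
#'   records are reproducible.
#' @param weighted_paths Use Euclidean edge weights for shortest paths
#'   (efficiency, betweenness, tortuosity). `FALSE` switches to hop counts.
#' @return A list of class `"metric_config"`.
#' @export
metric_config <- function(tortuosity_sample_pairs = 100L,
                          rng_seed = 1L,
                          weighted_paths = TRUE) {
  stopifnot(tortuosity_sample_pairs >= 1, is.numeric(rng_seed))
  structure(list(tortuosity_sample_pairs = as.integer(tortuosity_sample_pairs),
                 rng_seed = as.integer(rng_seed),
                 weighted_paths = isTRUE(weighted_paths)),
            class = "metric_config")
}

path_weights <- function(g, cfg) {
  if (cfg$weighted_paths && igraph::ecount(g) > 0) igraph::E(g)$weight else NA
}

check_graph <- function(g, min_nodes = 1L) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n < min_nodes)
    stop("graph has ", n, " nodes; at least ", min_nodes, " required")
  n
}

#' Average node degree
#'
#' Mean number of direct connections per node, `(1/|V|) sum deg(v)`;
#' identically `2 |E| / |V|`.
#'
#' @param g Skeleton graph from [build_graph()].
#' @return Numeric scalar.
#' @export
average_degree <- function(g) {
  check_graph(g, 1L)
  mean(igraph::degree(g))
}

#' Average clustering coefficient
#'
#' Watts-Strogatz local clustering `C_v = 2 T_v / (k_v (k_v - 1))` (`T_v` =
#' triangles through `v`; `C_v = 0` when `k_v < 2`), averaged over all nodes.
#' Triangle counting is unweighted.
#'
#' @inheritParams average_degree
#' @return Numeric scalar in `[0, 1]`.
#' @export
average_clustering <- function(g) {
  n <- check_graph(g, 1L)
  if (igraph::ecount(g) == 0) return(0)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Global efficiency
#'
#' Average inverse shortest-path length over all ordered node pairs,
#' `E_global = (1/(|V|(|V|-1))) sum_{i != j} 1/d_ij`. Pairs in different
#' components contribute 0 (the `1/Inf` convention), so fragmented early
#' networks are handled without special casing. Paths are weighted by the
#' Euclidean edge weights unless `cfg$weighted_paths` is `FALSE`.
#'
#' @inheritParams average_degree
#' @param cfg A [metric_config()].
#' @return Numeric scalar `>= 0`.
#' @export
global_efficiency <- function(g, cfg = metric_config()) {
  check_graph(g, 2L)
  igraph::global_efficiency(g, weights = path_weights(g, cfg), directed = FALSE)
}

#' Average betweenness centrality
#'
#' `BC(v) = sum_{s != v != t} sigma_st(v) / sigma_st` with weighted shortest
#' paths, normalized by `(|V|-1)(|V|-2)/2` (undirected convention) so values
#' are comparable across images of different size, then averaged over nodes.
#' Graphs with fewer than 3 nodes return 0 (no interior positions exist).
#'
#' @inheritParams global_efficiency
#' @return Numeric scalar `>= 0`.
#' @export
average_betweenness <- function(g, cfg = metric_config()) {
  n <- check_graph(g, 1L)
  if (n < 3) return(0)
  mean(igraph::betweenness(g, weights = path_weights(g, cfg),
                           normalized = TRUE))
}

# All same-component unordered pairs, or a seeded uniform sample of n_pairs
# of them. Returns 2-column matrix of vertex ids (possibly 0 rows).
sample_component_pairs <- function(g, n_pairs, rng_seed) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  npair_comp <- sizes * (sizes - 1) / 2
  total <- sum(npair_comp)
  if (total == 0) return(matrix(integer(0), 0, 2))
  members <- split(seq_len(igraph::vcount(g)), comp$membership)
  if (total <= n_pairs) {
    out <- do.call(rbind, lapply(members, function(v) {
      if (length(v) < 2) return(NULL)
      t(utils::combn(v, 2))
    }))
    return(out)
  }
  withr::with_seed(rng_seed, {
    chosen <- matrix(0L, 0, 2)
    seen <- character(0)
    while (nrow(chosen) < n_pairs) {
      k <- n_pairs - nrow(chosen)
      ci <- sample.int(length(sizes), k, replace = TRUE,
                       prob = npair_comp / total)
      for (cc in ci) {
        v <- members[[cc]]
        pr <- sort(v[sample.int(length(v), 2)])
        key <- paste0(pr[1], "_", pr[2])
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          chosen <- rbind(chosen, pr)
        }
      }
    }
    chosen
  })
}

#' Average tortuosity
#'
#' Tortuosity of a node pair is `T_ij = L_ij / D_ij`: along-network shortest
#' path length over straight-line Euclidean distance between the two pixels
#' (always `>= 1`). The average is taken over up to
#' `cfg$tortuosity_sample_pairs` distinct unordered pairs drawn uniformly at
#' random (seeded by `cfg$rng_seed`) from pairs lying in the same connected
#' component; if fewer valid pairs exist, all are used, making the result the
#' exact all-pairs mean.
#'
#' @inheritParams global_efficiency
#' @param pairs Optional 2-column matrix of vertex ids overriding the random
#'   sample (used for targeted checks).
#' @return Numeric scalar `>= 1`.
#' @export
average_tortuosity <- function(g, cfg = metric_config(), pairs = NULL) {
  check_graph(g, 2L)
  if (is.null(pairs))
    pairs <- sample_component_pairs(g, cfg$tortuosity_sample_pairs,
                                    cfg$rng_seed)
  if (nrow(pairs) == 0)
    stop("no connected node pair exists: graph is fully fragmented")
  w <- path_weights(g, cfg)
  rows <- igraph::V(g)$row; cols <- igraph::V(g)$col
  tij <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    L <- igraph::distances(g, v = a, to = b, weights = w)[1, 1]
    D <- sqrt((rows[a] - rows[b])^2 + (cols[a] - cols[b])^2)
    L / D
  }, numeric(1))
  mean(tij)
}

#' Connected-component statistics and connectivity index
#'
#' The connectivity index is the size of the largest connected component
#' divided by the total node count, `N_largest / N_total`: 1 for a fully
#' integrated network, small values for fragmented ones.
#'
#' @inheritParams average_degree
#' @return List with `n_components`, `largest_component_size`,
#'   `connectivity_index`.
#' @export
component_stats <- function(g) {
  n <- check_graph(g, 1L)
  comp <- igraph::components(g)
  largest <- max(comp$csize)
  list(n_components = as.integer(comp$no),
       largest_component_size = as.integer(largest),
       connectivity_index = largest / n)
}

#' Network density
#'
#' Realized fraction of possible undirected edges, `ND = 2E / (N(N-1))`.
#'
#' @inheritParams average_degree
#' @return Numeric scalar in `[0, 1]`.
#' @export
network_density <- function(g) {
  check_graph(g, 2L)
  igraph::edge_density(g)
}

#' Compute all eleven network metrics of a skeleton graph
#'
#' Populates the full metric record: node and edge counts, average degree,
#' average clustering coefficient, global efficiency, average betweenness
#' centrality, average tortuosity, number of connected components, largest
#' component size, connectivity index, and network density. Metrics that are
#' undefined on degenerate graphs (efficiency and density need 2 nodes;
#' tortuosity needs a connected pair) are reported as `NA` with a warning,
#' never silently as 0.
#'
#' @inheritParams global_efficiency
#' @return A list of class `"graph_metrics"`; see [as.data.frame.graph_metrics()].
#' @export
#' @examples
#' g <- build_graph(toy_skeletons()$line3)
#' compute_all_metrics(g, metric_config(rng_seed = 7))
compute_all_metrics <- function(g, cfg = metric_config()) {
  n <- check_graph(g, 1L)
  cs <- component_stats(g)
  tort <- if (max(igraph::components(g)$csize) >= 2)
    average_tortuosity(g, cfg)
  else {
    warning("no connected node pair: tortuosity undefined (NA)")
    NA_real_
  }
  eff <- if (n >= 2) global_efficiency(g, cfg) else {
    warning("singleton graph: efficiency undefined (NA)"); NA_real_
  }
  dens <- if (n >= 2) network_density(g) else {
    warning("singleton graph: density undefined (NA)"); NA_real_
  }
  structure(list(
    n_nodes = as.integer(n),
    n_edges = as.integer(igraph::ecount(g)),
    avg_degree = average_degree(g),
    avg_clustering = average_clustering(g),
    global_efficiency = eff,
    avg_betweenness = average_betweenness(g, cfg),
    avg_tortuosity = tort,
    n_components = cs$n_components,
    largest_component_size = cs$largest_component_size,
    connectivity_index = cs$connectivity_index,
    network_density = dens
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat("Skeleton-graph metrics\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Coerce a metric record to a one-row data frame
#'
#' @param x A `"graph_metrics"` record.
#' @param ... Unused.
#' @export
as.data.frame.graph_metrics <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Names of the eleven network metric columns
#' @return Character vector.
#' @export
metric_names <- function() {
  c("n_nodes", "n_edges", "avg_degree", "avg_clustering",
    "global_efficiency", "avg_betweenness", "avg_tortuosity",
    "n_components", "largest_component_size", "connectivity_index",
    "network_density")
}
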