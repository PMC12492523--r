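# Independent brute-force oracles used to validate the graph-metric
# implementations. These deliberately avoid igraph's analysis routines:
# distances come from Floyd-Warshall, clustering from direct triangle
# enumeration over the adjacency matrix, and betweenness from exhaustive
# enumeration of all shortest paths.

PATH_TOL <- 1e-9

oracle_edgelist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  list(el = el, w = w)
}

# All-pairs shortest-path distances by Floyd-Warshall.
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  eo <- oracle_edgelist(g)
  for (k in seq_len(nrow(eo$el))) {
    i <- eo$el[k, 1]; j <- eo$el[k, 2]
    d[i, j] <- d[j, i] <- min(d[i, j], eo$w[k])
  }
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# Global efficiency from the Floyd-Warshall distances (ordered pairs,
# disconnected pairs contribute 0).
oracle_efficiency <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  d <- oracle_distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Average Watts-Strogatz clustering by enumerating neighbor pairs.
oracle_clustering <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  n <- nrow(a)
  cv <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(a[nb, nb]) / 2
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(cv)
}

# Average normalized betweenness by exhaustive shortest-path enumeration:
# for every pair (s, t), depth-first enumeration of all paths of total
# weight d_st (pruned by the Floyd-Warshall distance bound), crediting
# interior nodes sigma_st(v) / sigma_st.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(0)
  d <- oracle_distances(g)
  adj <- lapply(seq_len(n), function(v) {
    inc <- igraph::incident(g, v)
    ends <- igraph::ends(g, inc, names = FALSE)
    nb <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    cbind(nb = nb, w = igraph::E(g)$weight[as.integer(inc)])
  })
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    interior_counts <- numeric(n)
    sigma <- 0
    stack <- list(list(v = s, len = 0, path = s))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (fr$v == t) {
        if (abs(fr$len - d[s, t]) <= PATH_TOL) {
          sigma <- sigma + 1
          inner <- setdiff(fr$path, c(s, t))
          interior_counts[inner] <- interior_counts[inner] + 1
        }
        next
      }
      a <- adj[[fr$v]]
      for (r in seq_len(nrow(a))) {
        nb <- a[r, "nb"]; w <- a[r, "w"]
        if (nb %in% fr$path) next
        len2 <- fr$len + w
        if (len2 + d[nb, t] > d[s, t] + PATH_TOL) next
        stack[[length(stack) + 1]] <-
          list(v = nb, len = len2, path = c(fr$path, nb))
      }
    }
    bc <- bc + interior_counts / sigma
  }
  mean(bc * 2 / ((n - 1) * (n - 2)))
}

# Random sparse weighted graph for oracle comparisons. Integer weights keep
# shortest-path ties exact in floating point for both routes.
random_weighted_graph <- function(n, p = 0.3, weights = c(1, 2)) {
  g <- igraph::sample_gnp(n, p)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- sample(weights, igraph::ecount(g), replace = TRUE)
  g
}

# Brute-force pairwise-distance graph construction: an edge for every pixel
# pair at Euclidean distance <= sqrt(2) (+ tolerance). Returns a canonical
# sorted edge key set and weights.
oracle_pixel_graph <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  keys <- character(0); wts <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (dd <= sqrt(2) + 1e-9) {
        keys <- c(keys, paste0(i, "_", j))
        wts <- c(wts, dd)
      }
    }
  }
  ord <- order(keys)
  list(keys = keys[ord], weights = wts[ord], n = n)
}

canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(list(keys = character(0), weights = numeric(0)))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  keys <- paste0(a, "_", b)
  ord <- order(keys)
  list(keys = keys[ord], weights = igraph::E(g)$weight[ord])
}

random_mask <- function(h = 12, w = 12, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}
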