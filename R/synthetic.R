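#' Synthetic tube-formation image configuration
#'
#' Parameters of the ground-truth-known generator that emulates the polygonal
#' capillary-like meshes endothelial cells form on basement-membrane matrix:
#' dark tubes on a bright background (brightfield appearance), with tunable
#' branching density (`n_seeds`), tube caliber, fragmentation (emulating
#' early-timepoint disconnected networks) and small dark noise specks (all
#' strictly smaller than 64 px, so the preprocessing cleanup removes them).
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_seeds Number of mesh generator points; small values give sparse,
#'   large values dense morphologies.
#' @param tube_width Tube caliber in pixels.
#' @param noise_level Approximate fraction of image area covered by dark
#'   specks of side 2-7 px (each < 64 px in area), in `[0, 1)`.
#' @param fragmentation Fraction of mesh edges randomly deleted, in `[0, 1]`.
#' @param rng_seed Integer seed; the output is fully determined by the
#'   configuration.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(image_size = c(384L, 384L),
                             n_seeds = 25L,
                             tube_width = 5L,
                             noise_level = 0,
                             fragmentation = 0,
                             rng_seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            n_seeds >= 2, tube_width >= 1,
            noise_level >= 0, noise_level < 1,
            fragmentation >= 0, fragmentation <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_seeds = as.integer(n_seeds),
                 tube_width = as.integer(tube_width),
                 noise_level = as.numeric(noise_level),
                 fragmentation = as.numeric(fragmentation),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Preset synthetic configurations
#'
#' The two presets mirror the two seeding-density morphologies of the assay:
#' `"sparse"` (few generator points, partially fragmented — the sparse /
#' early-timepoint phenotype) and `"dense"` (many points, fully connected
#' mesh — the dense / mature phenotype). They differ only in `n_seeds` and
#' `fragmentation`.
#'
#' @param preset `"sparse"` or `"dense"`.
#' @param rng_seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `"synthetic_config"`.
#' @export
synthetic_preset <- function(preset = c("sparse", "dense"), rng_seed = 1L,
                             ...) {
  preset <- match.arg(preset)
  args <- if (preset == "sparse")
    list(n_seeds = 10L, fragmentation = 0.25)
  else
    list(n_seeds = 40L, fragmentation = 0)
  defaults <- c(args, list(noise_level = 0.001, rng_seed = rng_seed))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(synthetic_config, defaults)
}

# Rejection-sample n points (row, col) with pairwise separation >= min_sep,
# inside a margin. Falls back to accepting closer points if the field is
# crowded; never returns fewer than n.
place_seeds <- function(h, w, n, min_sep = 24, margin = 16L) {
  pts <- matrix(0, 0, 2)
  tries <- 0L
  sep <- min_sep
  while (nrow(pts) < n) {
    cand <- c(sample(seq(margin, h - margin), 1),
              sample(seq(margin, w - margin), 1))
    ok <- nrow(pts) == 0 ||
      min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= sep
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
    if (tries %% 2000L == 0L) sep <- sep * 0.8  # crowded field: relax
  }
  pts
}

# Symmetrized k-nearest-neighbor edge list over seed points, augmented with
# the shortest inter-component links until the mesh is one component.
mesh_edges <- function(pts, k = 3L) {
  n <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts))
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:min(n, k + 1L)]
    for (j in nb) edges <- rbind(edges, sort(c(i, j)))
  }
  edges <- unique(edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  while (comp$no > 1) {
    main <- which(comp$membership == comp$membership[1])
    other <- which(comp$membership != comp$membership[1])
    sub <- dmat[main, other, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    e <- sort(c(main[ij[1]], other[ij[2]]))
    edges <- rbind(edges, e)
    g <- igraph::add_edges(g, e)
    comp <- igraph::components(g)
  }
  edges
}

# Paint all pixels within radius of the segment a-b into logical mask m.
stamp_segment <- function(m, a, b, radius) {
  h <- nrow(m); w <- ncol(m)
  r0 <- max(1L, floor(min(a[1], b[1]) - radius))
  r1 <- min(h, ceiling(max(a[1], b[1]) + radius))
  c0 <- max(1L, floor(min(a[2], b[2]) - radius))
  c1 <- min(w, ceiling(max(a[2], b[2]) + radius))
  rr <- r0:r1; cc <- c0:c1
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else ((pr - a[1]) * vx + (pc - a[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (pr - (a[1] + t * vx))^2 + (pc - (a[2] + t * vy))^2
  m[r0:r1, c0:c1] <- m[r0:r1, c0:c1, drop = FALSE] | (d2 <= radius^2)
  m
}

#' Generate a synthetic tube-formation image with exact ground truth
#'
#' Scatters `n_seeds` points, connects each to its 3 nearest neighbors (plus
#' the minimal links needed to make the mesh one component), deletes a
#' `fragmentation` fraction of edges, and rasterizes the surviving edges as
#' dark tubes of width `tube_width` on a bright background. Dark noise
#' specks (side 2-7 px) cover approximately `noise_level` of the image area;
#' they appear in the image only, never in the ground-truth mask. The whole
#' construction is a deterministic function of the configuration.
#'
#' @param cfg A [synthetic_config()] or [synthetic_preset()].
#' @return List with `image` (grayscale matrix in `[0, 1]`), `truth`
#'   (logical ground-truth tube mask), `seeds` (point coordinates), and
#'   `config`.
#' @export
#' @examples
#' syn <- generate_mesh_image(synthetic_config(image_size = c(128, 128),
#'                                             n_seeds = 8, rng_seed = 3))
#' range(syn$image); sum(syn$truth) > 0
generate_mesh_image <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  withr::with_seed(cfg$rng_seed, {
    pts <- place_seeds(h, w, cfg$n_seeds)
    edges <- mesh_edges(pts)
    if (cfg$fragmentation > 0 && nrow(edges) > 0) {
      ndrop <- round(cfg$fragmentation * nrow(edges))
      if (ndrop > 0)
        edges <- edges[-sample.int(nrow(edges), ndrop), , drop = FALSE]
    }
    radius <- cfg$tube_width / 2
    truth <- matrix(FALSE, h, w)
    if (nrow(edges) > 0)
      for (i in seq_len(nrow(edges)))
        truth <- stamp_segment(truth, pts[edges[i, 1], ], pts[edges[i, 2], ],
                               radius)
    img <- matrix(0.85, h, w)
    img[truth] <- 0.30
    if (cfg$noise_level > 0) {
      n_specks <- max(1L, round(cfg$noise_level * h * w / 20))
      for (i in seq_len(n_specks)) {
        s <- sample(2:7, 1)
        r0 <- sample(seq_len(h - s), 1); c0 <- sample(seq_len(w - s), 1)
        img[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- 0.30
      }
    }
  })
  list(image = img, truth = truth, seeds = pts, config = cfg)
}

#' Named toy skeleton fixtures
#'
#' Small hand-constructed skeletons whose metric records are known exactly:
#' \describe{
#'   \item{line3}{Horizontal 3-pixel line. 3 nodes, 2 unit edges, average
#'     degree 4/3, clustering 0, efficiency 5/6, average betweenness 1/3,
#'     tortuosity 1, one component, density 2/3.}
#'   \item{line9}{Horizontal 9-pixel line (tortuosity 1 on every pair).}
#'   \item{l_triangle}{Pixels (0,0), (0,1), (1,1): a 3-cycle with weights
#'     \{1, 1, sqrt(2)\}; clustering 1, density 1, tortuosity 1.}
#'   \item{ring}{Diamond ring `|dr| + |dc| = 5`: one component, every node
#'     degree 2, no triangles.}
#'   \item{cross}{Plus sign; the center pixel has degree 4 and diagonal
#'     shortcuts between adjacent arms form triangles.}
#'   \item{two_component}{A 3-pixel and a distant 5-pixel line: 2 components,
#'     connectivity index 5/8.}
#'   \item{isolated}{Pixels with no two 8-adjacent: edgeless graph.}
#' }
#'
#' @return Named list of logical matrices.
#' @export
toy_skeletons <- function() {
  mk <- function(h, w, cells) {
    m <- matrix(FALSE, h, w)
    m[cells] <- TRUE
    m
  }
  line3 <- mk(3, 5, cbind(2, 2:4))
  line9 <- mk(3, 11, cbind(2, 2:10))
  l_triangle <- mk(4, 4, rbind(c(2, 2), c(2, 3), c(3, 3)))
  R <- 5L
  ring_cells <- which(outer(abs(seq_len(13) - 7), abs(seq_len(13) - 7), "+")
                      == R, arr.ind = TRUE)
  ring <- mk(13, 13, ring_cells)
  cross <- mk(9, 9, rbind(cbind(5, 2:8), cbind(2:8, 5)))
  two_component <- mk(5, 15, rbind(cbind(2, 2:4), cbind(4, 9:13)))
  isolated <- mk(7, 7, rbind(c(1, 1), c(1, 4), c(1, 7), c(4, 1), c(4, 4),
                             c(4, 7), c(7, 1), c(7, 7)))
  list(line3 = line3, line9 = line9, l_triangle = l_triangle, ring = ring,
       cross = cross, two_component = two_component, isolated = isolated)
}

#' Write a synthetic image, its ground truth and metadata to disk
#'
#' @param syn Result of [generate_mesh_image()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the paths written (image PNG, truth PNG, config JSON).
#' @export
write_synthetic_image <- function(syn, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  truth_path <- file.path(dir, paste0(name, "_truth.png"))
  meta_path <- file.path(dir, paste0(name, ".json"))
  EBImage::writeImage(EBImage::Image(t(syn$image)), img_path)
  EBImage::writeImage(EBImage::Image(t(syn$truth * 1)), truth_path)
  jsonlite::write_json(unclass(syn$config), meta_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(image = img_path, truth = truth_path, metadata = meta_path))
}
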