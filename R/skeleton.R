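# Zhang-Suen binary thinning, vectorized over the whole image per
# sub-iteration. Foreground is TRUE; the result is a 1-pixel-wide,
# 8-connected, topology-preserving centerline.

# Shifted copy of logical matrix m by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

thin_subiteration <- function(img, pass) {
  # neighbor order p2..p9 clockwise starting north
  p2 <- shift_mask(img, -1L,  0L); p3 <- shift_mask(img, -1L,  1L)
  p4 <- shift_mask(img,  0L,  1L); p5 <- shift_mask(img,  1L,  1L)
  p6 <- shift_mask(img,  1L,  0L); p7 <- shift_mask(img,  1L, -1L)
  p8 <- shift_mask(img,  0L, -1L); p9 <- shift_mask(img, -1L, -1L)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  cond <- if (pass == 1L) (!(p2 & p4 & p6)) & (!(p4 & p6 & p8))
          else            (!(p2 & p4 & p8)) & (!(p2 & p6 & p8))
  del <- img & b >= 2 & b <= 6 & a == 1 & cond
  img & !del
}

#' Skeletonize a binary mask
#'
#' Iterative morphological thinning (Zhang-Suen) reducing each 8-connected
#' foreground object to a 1-pixel-wide centerline while preserving its
#' topology. One-pixel-wide structures are fixed points. A guard restores a
#' single representative pixel for any source component that parallel
#' deletion would otherwise erase completely (this can happen for tiny
#' compact blobs), so the skeleton always has the same number of 8-connected
#' components as the input mask.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return Logical matrix of the same shape; a subset of `mask`.
#' @export
#' @examples
#' bar <- matrix(FALSE, 7, 11); bar[3:5, 2:10] <- TRUE
#' sum(skeletonize(bar)) < sum(bar)
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  img <- mask
  attributes(img) <- list(dim = dim(mask))
  if (!any(img)) return(img)
  repeat {
    before <- img
    img <- thin_subiteration(img, 1L)
    img <- thin_subiteration(img, 2L)
    if (identical(img, before)) break
  }
  # component-preservation guard
  src <- label_components(mask)
  if (length(src$sizes)) {
    surviving <- unique(src$labels[img])
    lost <- setdiff(seq_along(src$sizes), surviving)
    for (lb in lost) {
      cells <- which(src$labels == lb, arr.ind = TRUE)
      ctr <- colMeans(cells)
      d2 <- (cells[, 1] - ctr[1])^2 + (cells[, 2] - ctr[2])^2
      pick <- cells[which.min(d2), , drop = FALSE]
      img[pick[1, 1], pick[1, 2]] <- TRUE
    }
  }
  img
}

#' Build the weighted pixel graph of a skeleton
#'
#' Every skeleton pixel becomes one node; an undirected edge joins every pair
#' of 8-adjacent skeleton pixels (equivalently, pairs whose Euclidean pixel
#' distance is at most sqrt(2)), weighted by that Euclidean distance: 1 for
#' axial neighbors, sqrt(2) for diagonal neighbors. Node pixel coordinates
#' are kept as vertex attributes `row` and `col` (0-based, image convention:
#' row increases downward) plus plotting aliases `x = col`, `y = row`.
#'
#' @param skeleton Logical skeleton matrix (typically from [skeletonize()],
#'   but any binary mask is accepted).
#' @return An [igraph][igraph::igraph-package] undirected graph with edge
#'   attribute `weight` and the vertex attributes above. Empty skeletons give
#'   an empty graph.
#' @export
#' @examples
#' sk <- matrix(FALSE, 3, 5); sk[2, 2:4] <- TRUE
#' g <- build_graph(sk)
#' igraph::vcount(g); igraph::ecount(g)
build_graph <- function(skeleton) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton))
  pe <- pixel_edges(skeleton)
  g <- igraph::make_empty_graph(pe$n, directed = FALSE)
  if (length(pe$from)) {
    g <- igraph::add_edges(g, rbind(pe$from, pe$to))
    igraph::E(g)$weight <- pe$weight
  }
  if (pe$n > 0) {
    coords <- which(skeleton, arr.ind = TRUE)  # column-major, matches ids
    igraph::V(g)$row <- as.integer(coords[, 1] - 1L)
    igraph::V(g)$col <- as.integer(coords[, 2] - 1L)
    igraph::V(g)$x <- igraph::V(g)$col
    igraph::V(g)$y <- igraph::V(g)$row
  }
  attr(g, "image_shape") <- dim(skeleton)
  g
}

#' Node pixel coordinates of a skeleton graph
#'
#' @param g Graph from [build_graph()].
#' @return Data frame with 0-based `row` and `col` columns, one row per node.
#' @export
node_coords <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0)
    return(data.frame(row = integer(0), col = integer(0)))
  data.frame(row = igraph::V(g)$row, col = igraph::V(g)$col)
}
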