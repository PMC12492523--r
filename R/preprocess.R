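#' Preprocessing configuration
#'
#' Bundles the parameters of the mask-extraction pipeline. Defaults follow the
#' standard tube-formation workflow: Gaussian smoothing at sigma = 1 pixel,
#' Otsu thresholding, and removal of 8-connected components smaller than 64
#' pixels.
#'
#' @param gaussian_sigma Standard deviation (pixels) of the Gaussian smoothing
#'   kernel. `0` disables smoothing.
#' @param min_object_size Components with strictly fewer pixels than this are
#'   removed; components of exactly this size are kept.
#' @param invert_foreground Foreground polarity. `NA` (default) picks the side
#'   of the Otsu threshold occupying the smaller pixel fraction — tubules
#'   cover a minority of the field in these assays. `TRUE` forces the dark
#'   (below-threshold) side, `FALSE` the bright side.
#' @return A list of class `"preprocess_config"`.
#' @export
#' @examples
#' preprocess_config(gaussian_sigma = 2)
preprocess_config <- function(gaussian_sigma = 1.0,
                              min_object_size = 64L,
                              invert_foreground = NA) {
  stopifnot(is.numeric(gaussian_sigma), length(gaussian_sigma) == 1,
            gaussian_sigma >= 0,
            is.numeric(min_object_size), length(min_object_size) == 1,
            min_object_size >= 0)
  structure(list(gaussian_sigma = as.numeric(gaussian_sigma),
                 min_object_size = as.integer(min_object_size),
                 invert_foreground = invert_foreground),
            class = "preprocess_config")
}

#' Read an image file as a grayscale intensity matrix
#'
#' Reads JPEG, PNG or TIFF (8/16-bit grayscale or 8-bit RGB) via
#' [EBImage::readImage()] and converts to a single-channel matrix in `[0, 1]`.
#'
#' @param path Path to an image file.
#' @return Numeric matrix (rows x cols) of intensities in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores (x = col, y = row); transpose to row-major matrix
  if (length(dim(dat)) == 2) {
    gray <- t(dat)
  } else if (length(dim(dat)) == 3 && dim(dat)[3] %in% c(3L, 4L)) {
    arr <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3))
    gray <- to_grayscale(arr)
  } else {
    stop("unsupported channel count in ", path, ": ",
         paste(dim(dat), collapse = "x"))
  }
  gray <- clamp01(gray)
  gray
}

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Convert an image to grayscale
#'
#' Single-channel input is returned unchanged. RGB input (rows x cols x 3) is
#' combined with the ITU-R BT.709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B); the standard used is recorded in the
#' `"luma"` attribute of the result.
#'
#' @param image Numeric matrix (already grayscale) or rows x cols x 3 array.
#' @return Numeric matrix; RGB inputs carry `attr(, "luma") == "BT.709"`.
#' @export
#' @examples
#' rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 1   # pure red
#' to_grayscale(rgb)[1, 1]                        # 0.2126
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] == 1L) return(image[, , 1])
  if (length(d) == 3 && d[3] == 3L) {
    w <- c(0.2126, 0.7152, 0.0722)
    gray <- w[1] * image[, , 1] + w[2] * image[, , 2] + w[3] * image[, , 3]
    attr(gray, "luma") <- "BT.709"
    return(gray)
  }
  stop("unsupported channel count: expected 1 or 3 channels, got dims ",
       paste(d, collapse = "x"))
}

# Symmetric (half-sample) boundary reflection of 1-based indices onto 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  m[m < 0] <- m[m < 0] + 2L * n
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with a discrete kernel truncated at radius
#' `ceiling(4 * sigma)` and renormalized to sum 1. Boundaries use symmetric
#' reflection, so a constant image is reproduced exactly (including borders).
#'
#' @param gray Numeric intensity matrix.
#' @param sigma Kernel standard deviation in pixels; `0` returns the input
#'   unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(gray, sigma = 1.0) {
  stopifnot(is.matrix(gray))
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(gray)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) {
      idx <- reflect_index(seq_len(n) + o, n)
      w <- k[o + r + 1L]
      if (along_rows) out <- out + w * m[idx, , drop = FALSE]
      else out <- out + w * m[, idx, drop = FALSE]
    }
    out
  }
  smooth_axis(smooth_axis(gray, TRUE), FALSE)
}

#' The discrete Gaussian kernel used by [gaussian_smooth()]
#'
#' Exposed so the smoothing response can be verified against direct
#' convolution.
#'
#' @param sigma Kernel standard deviation (> 0).
#' @return Numeric vector of length `2 * ceiling(4 * sigma) + 1`, summing to 1.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Otsu binarization
#'
#' Thresholds a grayscale image at the intensity maximizing between-class
#' variance over a 256-bin histogram ([EBImage::otsu()]), then chooses the
#' foreground side. By default the side with the smaller pixel fraction is
#' taken as foreground (tubules are a minority of the field); override with
#' `invert_foreground`.
#'
#' @param gray Numeric matrix with values in `[0, 1]`.
#' @param invert_foreground `NA` = minority side, `TRUE` = dark side,
#'   `FALSE` = bright side.
#' @return List with `mask` (logical matrix) and `threshold` (numeric). A
#'   constant image yields an all-`FALSE` mask, `threshold = NA`, and a
#'   warning (rather than an error, to keep batch runs alive).
#' @export
binarize_otsu <- function(gray, invert_foreground = NA) {
  stopifnot(is.matrix(gray))
  if (length(unique(as.vector(gray))) < 2) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                threshold = NA_real_))
  }
  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1), levels = 256)
  dark <- gray <= thr
  take_dark <- if (is.na(invert_foreground)) mean(dark) <= 0.5 else
    isTRUE(invert_foreground)
  mask <- if (take_dark) dark else !dark
  list(mask = mask, threshold = as.numeric(thr))
}

# Linear indices -> pixel-adjacency edge list over TRUE cells of `mask`,
# scanning only the half-neighborhood {E, S, SE, SW} so each 8-adjacent pair
# appears exactly once. Returns from/to (1..n over foreground pixels in
# column-major order) and weight (1 axial, sqrt(2) diagonal).
pixel_edges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  n <- sum(mask)
  ids <- matrix(0L, h, w)
  ids[mask] <- seq_len(n)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a)) next
    from <- c(from, ids[r1, c1, drop = FALSE][a])
    to <- c(to, ids[r1 + dr, c1 + dc, drop = FALSE][a])
    wt <- c(wt, rep(if (dr != 0L && dc != 0L) sqrt(2) else 1, sum(a)))
  }
  list(from = from, to = to, weight = wt, n = n)
}

# 8-connected component labels of a logical mask. Returns an integer matrix
# (0 = background) plus component sizes.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  n <- sum(mask)
  lab <- matrix(0L, h, w)
  if (n == 0L) return(list(labels = lab, sizes = integer(0)))
  pe <- pixel_edges(mask)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pe$from))
    g <- igraph::add_edges(g, rbind(pe$from, pe$to))
  comp <- igraph::components(g)
  lab[mask] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}

#' Remove small connected components
#'
#' Drops every 8-connected foreground component with strictly fewer than
#' `min_size` pixels; components of exactly `min_size` pixels are kept.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum surviving component size in pixels.
#' @return Logical matrix of the same shape.
#' @export
remove_small_objects <- function(mask, min_size = 64L) {
  stopifnot(is.matrix(mask), is.logical(mask), min_size >= 0)
  if (min_size <= 1L || !any(mask)) return(mask)
  lc <- label_components(mask)
  keep <- which(lc$sizes >= min_size)
  matrix(lc$labels %in% keep, nrow(mask), ncol(mask))
}

#' Full preprocessing pipeline: image to binary tubule mask
#'
#' Runs grayscale conversion, Gaussian smoothing, Otsu binarization and
#' small-object removal, in that order.
#'
#' @param image Grayscale matrix, rows x cols x 3 RGB array, or a file path.
#' @param config A [preprocess_config()].
#' @return Logical mask matrix with attributes `"threshold"` (Otsu threshold)
#'   and `"foreground"` (`"dark"` or `"bright"`).
#' @export
#' @examples
#' syn <- generate_mesh_image(synthetic_config(image_size = c(96, 96),
#'                                             n_seeds = 5, rng_seed = 1))
#' mask <- preprocess_image(syn$image, preprocess_config())
#' mean(mask)
preprocess_image <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (is.character(image)) image <- read_gray_image(image)
  gray <- tryCatch(to_grayscale(image),
                   error = function(e) stop("[grayscale] ", conditionMessage(e)))
  sm <- tryCatch(gaussian_smooth(gray, config$gaussian_sigma),
                 error = function(e) stop("[smooth] ", conditionMessage(e)))
  bo <- tryCatch(binarize_otsu(sm, config$invert_foreground),
                 error = function(e) stop("[otsu] ", conditionMessage(e)))
  mask <- remove_small_objects(bo$mask, config$min_object_size)
  attr(mask, "threshold") <- bo$threshold
  attr(mask, "foreground") <-
    if (is.na(bo$threshold)) NA_character_
    else if (isTRUE(all.equal(mask_polarity(bo$mask, sm, bo$threshold), "dark")))
      "dark" else "bright"
  mask
}

mask_polarity <- function(mask, gray, thr) {
  if (!any(mask)) return("dark")
  if (mean(gray[mask]) <= thr) "dark" else "bright"
}
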