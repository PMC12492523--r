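#' Analyze one tube-formation image end to end
#'
#' Runs the full pipeline — preprocessing to a binary tubule mask,
#' skeletonization, pixel-graph construction, the eleven network metrics,
#' radial zone analysis and the five heterogeneity metrics — and returns a
#' self-describing record that can be re-run from its own parameters.
#'
#' @param image File path, grayscale matrix, or rows x cols x 3 array.
#' @param image_id Identifier stored in the record (defaults to the file
#'   name, or `"image"` for in-memory input).
#' @param preprocess A [preprocess_config()].
#' @param metrics A [metric_config()].
#' @param delta_r,n_zones Radial zone parameters (defaults 50 px, 6 zones).
#' @param keep_images Keep the grayscale image and skeleton in the record
#'   (needed for [plot_analysis()]).
#' @return A list of class `"analysis_record"` with elements `image_id`,
#'   `config`, `metrics`, `zone_profile`, `heterogeneity`, `version`. If the
#'   mask is empty, metric fields are `NA` and a warning is raised.
#' @export
#' @examples
#' syn <- generate_mesh_image(synthetic_preset("dense", rng_seed = 2,
#'                                             image_size = c(160, 160)))
#' rec <- analyze_image(syn$image, image_id = "demo")
#' rec$metrics$connectivity_index
analyze_image <- function(image, image_id = NULL,
                          preprocess = preprocess_config(),
                          metrics = metric_config(),
                          delta_r = 50, n_zones = 6L,
                          keep_images = FALSE) {
  if (is.null(image_id))
    image_id <- if (is.character(image)) basename(image) else "image"
  mask <- preprocess_image(image, preprocess)
  sk <- skeletonize(mask)
  g <- build_graph(sk)
  if (igraph::vcount(g) == 0) {
    warning("empty mask for ", image_id, ": all metrics NA")
    gm <- stats::setNames(as.list(rep(NA_real_, length(metric_names()))),
                          metric_names())
    class(gm) <- "graph_metrics"
    zp <- NULL
    het <- stats::setNames(as.list(rep(NA_real_, 5)), heterogeneity_names())
    class(het) <- "heterogeneity_metrics"
  } else {
    gm <- compute_all_metrics(g, metrics)
    zp <- assign_zones(g, delta_r = delta_r, n_zones = n_zones)
    het <- if (all(zp$densities == 0)) {
      warning("all nodes outside the radial zones for ", image_id)
      h <- stats::setNames(as.list(rep(NA_real_, 5)), heterogeneity_names())
      class(h) <- "heterogeneity_metrics"
      h
    } else heterogeneity(zp)
  }
  rec <- structure(list(
    image_id = image_id,
    config = list(preprocess = unclass(preprocess),
                  metrics = unclass(metrics),
                  radial = list(delta_r = delta_r, n_zones = n_zones)),
    metrics = gm,
    zone_profile = zp,
    heterogeneity = het,
    version = as.character(utils::packageVersion("angionet"))
  ), class = "analysis_record")
  if (keep_images) {
    rec$gray <- if (is.character(image)) read_gray_image(image) else
      to_grayscale(image)
    rec$mask <- mask
    rec$skeleton <- sk
    rec$graph <- g
  }
  rec
}

#' @export
print.analysis_record <- function(x, ...) {
  cat("Analysis record:", x$image_id, "\n")
  print(x$metrics)
  print(x$heterogeneity)
  invisible(x)
}

#' One-row data frame of an analysis record
#'
#' Columns: `image_id`, the eleven network metrics, the five heterogeneity
#' metrics, and `zone_excluded` (nodes beyond the outermost zone).
#'
#' @param x An `"analysis_record"`.
#' @param ... Unused.
#' @export
as.data.frame.analysis_record <- function(x, ...) {
  cbind(data.frame(image_id = x$image_id),
        as.data.frame(x$metrics),
        as.data.frame(x$heterogeneity),
        data.frame(zone_excluded =
                     if (is.null(x$zone_profile)) NA_integer_
                     else x$zone_profile$n_excluded))
}

#' Analyze a batch of images into a metrics table
#'
#' @param paths Image file paths, or a directory (all JPEG/PNG/TIFF inside,
#'   in filename order — row order is therefore stable).
#' @param ... Passed to [analyze_image()].
#' @param csv Optional path: write the table as CSV.
#' @return Data frame, one row per image. Unreadable images are skipped with
#'   a warning and recorded in the `"skipped"` attribute.
#' @export
analyze_images <- function(paths, ..., csv = NULL) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, "\\.(jpe?g|png|tiff?)$",
                             full.names = TRUE, ignore.case = TRUE))
  skipped <- character(0)
  rows <- list()
  for (p in paths) {
    row <- tryCatch(as.data.frame(analyze_image(p, ...)),
                    error = function(e) {
                      warning("skipping ", p, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(row)) skipped <- c(skipped, p) else rows[[p]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Write an analysis record as JSON
#'
#' @param record An `"analysis_record"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_record_json <- function(record, path) {
  r <- unclass(record)
  r$gray <- r$mask <- r$skeleton <- r$graph <- NULL
  r$metrics <- unclass(r$metrics)
  r$heterogeneity <- unclass(r$heterogeneity)
  if (!is.null(r$zone_profile)) r$zone_profile <- unclass(r$zone_profile)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Standard four-panel figure for one image
#'
#' Writes the standardized visual output: (I) the original image, (II) the
#' skeletonized network, (III) the extracted graph overlaid on the image,
#' and (IV) a 2D scatter plot of node coordinates.
#'
#' @param record An [analyze_image()] record created with
#'   `keep_images = TRUE`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return Invisibly, `path`.
#' @export
plot_analysis <- function(record, path, width = 1600, height = 440) {
  stopifnot(inherits(record, "analysis_record"))
  if (is.null(record$gray))
    stop("record has no stored images; rerun analyze_image(keep_images = TRUE)")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 4), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  show_raster <- function(m, main) {
    graphics::plot(NA, xlim = c(0, ncol(m)), ylim = c(nrow(m), 0),
                   asp = 1, xlab = "", ylab = "", main = main, axes = FALSE)
    graphics::rasterImage(m, 0, nrow(m), ncol(m), 0, interpolate = FALSE)
  }
  show_raster(record$gray, paste0("I. ", record$image_id))
  show_raster(1 - record$skeleton, "II. skeleton")
  show_raster(record$gray, "III. graph overlay")
  g <- record$graph
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    graphics::segments(igraph::V(g)$col[el[, 1]] + 0.5,
                       igraph::V(g)$row[el[, 1]] + 0.5,
                       igraph::V(g)$col[el[, 2]] + 0.5,
                       igraph::V(g)$row[el[, 2]] + 0.5,
                       col = "red", lwd = 1.5)
  }
  nc <- node_coords(g)
  graphics::plot(nc$col, nc$row, pch = 16, cex = 0.3, col = "steelblue",
                 xlim = c(0, ncol(record$gray)),
                 ylim = c(nrow(record$gray), 0), asp = 1,
                 xlab = "x (col)", ylab = "y (row)", main = "IV. node scatter")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file with optional sections `preprocess`
#' (`gaussian_sigma`, `min_object_size`, `invert_foreground`), `metrics`
#' (`tortuosity_sample_pairs`, `rng_seed`, `weighted_paths`) and `radial`
#' (`delta_r`, `n_zones`). Missing keys fall back to the defaults.
#'
#' @param path YAML file path (`NULL` = all defaults).
#' @return List with `preprocess`, `metrics`, `delta_r`, `n_zones`.
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pp <- do.call(preprocess_config, raw$preprocess %||% list())
  mc <- do.call(metric_config, raw$metrics %||% list())
  rz <- raw$radial %||% list()
  list(preprocess = pp, metrics = mc,
       delta_r = rz$delta_r %||% 50, n_zones = as.integer(rz$n_zones %||% 6L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
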