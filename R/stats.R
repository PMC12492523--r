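#' Mann-Whitney U test (two-sided)
#'
#' Wraps [stats::wilcox.test()]. The exact p-value is used when the smaller
#' sample has at most 8 observations and there are no ties (matching the
#' small-n design of tube-formation experiments, n = 6-9 per group);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each with at least 1 observation.
#' @return List with `u` (the U statistic for `x`, i.e. the number of
#'   `(x_i, y_j)` pairs with `x_i > y_j`, ties counting 1/2) and `p`
#'   (two-sided p-value).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1)  # all observations tied: no evidence
    return(list(u = length(x) * length(y) / 2, p = 1, exact = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m)`, in `[-1, 1]`.
#' Magnitude classes use the conventional cut-points, with boundary values
#' falling in the lower class: negligible `|delta| <= 0.147`, small
#' `(0.147, 0.33]`, medium `(0.33, 0.474]`, large `> 0.474`.
#'
#' @inheritParams mann_whitney
#' @return List with `delta` and `magnitude` (factor level as character).
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))   # -5/9, large
cliffs_delta <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  delta <- (gt - lt) / (length(x) * length(y))
  list(delta = delta, magnitude = delta_magnitude(delta))
}

#' Classify a Cliff's delta magnitude
#' @param delta Numeric in `[-1, 1]`.
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
delta_magnitude <- function(delta) {
  a <- abs(delta)
  if (a <= 0.147) "negligible"
  else if (a <= 0.33) "small"
  else if (a <= 0.474) "medium"
  else "large"
}

#' ROC area under the curve for a binary grouping
#'
#' Probability that a randomly chosen positive-group score outranks a
#' randomly chosen negative-group score, ties counted 1/2 — the
#' Mann-Whitney interpretation, so `auc == U / (n m)` with `U` computed on
#' the positive sample. Raw metric values are used directly as predictor
#' scores, with the convention sparse = 0 (negative), dense = 1 (positive).
#' Since discriminability is direction-free (a metric consistently *lower*
#' in the positive group separates just as well), `auc_flipped =
#' max(auc, 1 - auc)` is reported alongside.
#'
#' @param scores Numeric metric values, one per image.
#' @param labels Binary group labels (0/1, logical, or a 2-level factor whose
#'   second level is positive).
#' @return List with `auc` and `auc_flipped`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(unique(labels)) < 2)
    stop("both classes must be present in labels")
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  auc <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  list(auc = auc, auc_flipped = max(auc, 1 - auc))
}

#' Spearman correlation matrix of a metric table
#'
#' Pairwise Spearman rank correlations across metric columns (average ranks
#' for ties), typically restricted to one timepoint or condition. Constant
#' columns have undefined rank correlation; their off-diagonal entries are
#' `NA`, never 0.
#'
#' @param table Data frame of per-image metrics.
#' @param metrics Columns to correlate (default: all numeric columns).
#' @param filter Optional logical vector selecting rows (e.g. one timepoint).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, metrics = NULL, filter = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(filter)) table <- table[filter, , drop = FALSE]
  if (is.null(metrics))
    metrics <- names(table)[vapply(table, is.numeric, logical(1))]
  if (nrow(table) < 3) stop("need at least 3 rows for a correlation matrix")
  m <- as.matrix(table[, metrics, drop = FALSE])
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "everything"))
  diag(rho) <- 1
  rho
}

#' Per-node normalization of scale-dependent metrics
#'
#' Divides the named metric columns by each image's node count to control for
#' scale effects, adding `_per_node`-suffixed columns (originals retained).
#' Metrics that are already per-node averages are divided anyway if named —
#' the choice of columns is the caller's — with a message.
#'
#' @param table Data frame with an `n_nodes` column.
#' @param which Character vector of column names to normalize (may be empty).
#' @return The table with added columns.
#' @export
normalize_per_node <- function(table, which = character(0)) {
  stopifnot(is.data.frame(table), "n_nodes" %in% names(table))
  if (any(table$n_nodes <= 0)) stop("n_nodes must be positive for all rows")
  already_avg <- intersect(which, c("avg_degree", "avg_clustering",
                                    "avg_betweenness", "avg_tortuosity"))
  if (length(already_avg))
    message("normalizing per-node metrics that are already averages: ",
            paste(already_avg, collapse = ", "))
  for (nm in which) {
    if (!nm %in% names(table)) stop("no such metric column: ", nm)
    table[[paste0(nm, "_per_node")]] <- table[[nm]] / table$n_nodes
  }
  table
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Two-group comparison of every metric column
#'
#' For each metric, runs the Mann-Whitney U test, Cliff's delta with
#' magnitude class, and ROC-AUC (group B is the positive class, following
#' the sparse = 0 / dense = 1 convention when `group_b` is the dense
#' condition). Significance stars use *p < 0.05, **p < 0.01, ***p < 0.001.
#' No multiple-testing correction is applied by default (per-metric raw
#' p-values); set `adjust = "BH"` for Benjamini-Hochberg adjusted p-values
#' in an extra column.
#'
#' @param table Data frame of per-image metrics.
#' @param group_col Name of the group label column.
#' @param group_a,group_b The two labels to compare; `group_b` is positive.
#' @param metrics Metric columns (default: all numeric columns except
#'   obvious identifiers).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame, one row per metric: `metric`, `u`, `p`, `stars`,
#'   `cliffs_delta`, `magnitude`, `auc`, `auc_flipped` (+ `p_adj`).
#' @export
compare_groups <- function(table, group_col, group_a, group_b,
                           metrics = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table), group_col %in% names(table))
  labs <- table[[group_col]]
  for (gl in c(group_a, group_b))
    if (!gl %in% labs)
      stop("group '", gl, "' not present; available: ",
           paste(unique(labs), collapse = ", "))
  if (is.null(metrics)) {
    metrics <- names(table)[vapply(table, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("seed", "rng_seed"))
  }
  rows <- lapply(metrics, function(nm) {
    a <- table[[nm]][labs == group_a]
    b <- table[[nm]][labs == group_b]
    if (anyNA(a) || anyNA(b))
      return(data.frame(metric = nm, u = NA_real_, p = NA_real_, stars = "",
                        cliffs_delta = NA_real_, magnitude = NA_character_,
                        auc = NA_real_, auc_flipped = NA_real_))
    mw <- mann_whitney(a, b)
    cd <- cliffs_delta(a, b)
    au <- roc_auc(c(a, b), rep(c(0L, 1L), c(length(a), length(b))))
    data.frame(metric = nm, u = mw$u, p = mw$p,
               stars = significance_stars(mw$p),
               cliffs_delta = cd$delta, magnitude = cd$magnitude,
               auc = au$auc, auc_flipped = au$auc_flipped)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
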