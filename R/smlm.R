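#' Cluster single-molecule localizations with DBSCAN
#'
#' Density-based clustering of 2-D localization coordinates (nm) with
#' standard DBSCAN semantics: a point is a core point when at least
#' `min_pts` points (counting itself) lie within `eps`; clusters grow
#' from core points over density-reachable neighbours; non-core points
#' within `eps` of a core point are border points and are assigned to
#' the first core cluster reaching them in scan order; everything else
#' is noise (label -1). The expansion is deterministic given the input
#' order: points are scanned in row order and seed queues are FIFO with
#' neighbours appended in row order. Neighbour queries use an eps-sized
#' grid, so the result is exact.
#'
#' @param locs Data frame with localization coordinates in columns `x`
#'   and `y` (nm), e.g. from [synth_localizations()] or
#'   [read_localizations()].
#' @param eps Neighbourhood radius (nm, > 0). Default 50.
#' @param min_pts Minimum neighbourhood size including the point itself
#'   (>= 1). Default 10.
#'
#' @return The input as a tibble with an integer `cluster` column
#'   (1, 2, ... in order of discovery; -1 = noise).
#' @export
cluster_localizations <- function(locs, eps = 50, min_pts = 10) {
  stopifnot(eps > 0, min_pts >= 1)
  locs <- tibble::as_tibble(locs)
  n <- nrow(locs)
  if (n == 0) {
    locs$cluster <- integer(0)
    return(locs)
  }
  x <- locs$x; y <- locs$y
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("localization coordinates must be finite", call. = FALSE)
  }
  nb <- grid_neighbours(x, y, eps)
  labels <- rep.int(NA_integer_, n)   # NA = unvisited, -1 = noise
  cluster_id <- 0L
  for (p in seq_len(n)) {
    if (!is.na(labels[p])) next
    if (length(nb[[p]]) < min_pts) {
      labels[p] <- -1L
      next
    }
    cluster_id <- cluster_id + 1L
    labels[p] <- cluster_id
    queue <- setdiff(nb[[p]], p)
    head_i <- 1L
    while (head_i <= length(queue)) {
      q <- queue[head_i]
      head_i <- head_i + 1L
      if (!is.na(labels[q]) && labels[q] != -1L) next
      labels[q] <- cluster_id
      if (length(nb[[q]]) >= min_pts) {
        fresh <- nb[[q]][is.na(labels[nb[[q]]]) | labels[nb[[q]]] == -1L]
        queue <- c(queue, fresh)
      }
    }
  }
  locs$cluster <- labels
  locs
}

# Exact fixed-radius neighbour lists (including self) via an eps grid;
# queries are vectorized per occupied cell.
#' @noRd
grid_neighbours <- function(x, y, eps) {
  n <- length(x)
  gx <- floor(x / eps); gy <- floor(y / eps)
  idx_by_cell <- split(seq_len(n), paste(gx, gy, sep = ","))
  eps2 <- eps^2
  out <- vector("list", n)
  for (pts_in in idx_by_cell) {
    cx <- gx[pts_in[1]]; cy <- gy[pts_in[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      js <- idx_by_cell[[paste(cx + dx, cy + dy, sep = ",")]]
      if (!is.null(js)) cand <- c(cand, js)
    }
    d2 <- outer(x[pts_in], x[cand], `-`)^2 + outer(y[pts_in], y[cand], `-`)^2
    for (r in seq_along(pts_in)) {
      out[[pts_in[r]]] <- sort(cand[d2[r, ] <= eps2])
    }
  }
  out
}

#' Morphometrics of one localization cluster
#'
#' Computes the 2x2 gyration tensor (second-moment tensor about the
#' centroid) of a point set and derives the radius of gyration
#' \eqn{R_g = \sqrt{\lambda_1 + \lambda_2}} and the eccentricity
#' \eqn{Ecc = \sqrt{\lambda_1 / \lambda_2}} from its eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2}. Ecc is 1 for isotropic sets and grows
#' with elongation; for collinear points (\eqn{\lambda_2 = 0}) Ecc is
#' reported as `Inf` and flagged. With `ecc_def = "flattening"` the
#' alternative \eqn{\sqrt{1 - \lambda_2/\lambda_1}} is returned instead.
#'
#' @param points Data frame with columns `x`, `y` (nm) and >= 2 rows.
#' @param cluster_id Optional identifier copied into the output.
#' @param ecc_def `"axis_ratio"` (default) or `"flattening"`.
#'
#' @return A one-row tibble with `cluster_id`, `n_locs`, `centroid_x`,
#'   `centroid_y`, `rg`, `ecc`, `lambda1`, `lambda2`, `collinear`.
#' @export
#' @examples
#' cluster_shape(data.frame(x = c(-1, -1, 1, 1), y = c(-1, 1, -1, 1)))
cluster_shape <- function(points, cluster_id = NA_integer_,
                          ecc_def = c("axis_ratio", "flattening")) {
  ecc_def <- match.arg(ecc_def)
  points <- tibble::as_tibble(points)
  n <- nrow(points)
  if (n < 2) stop("cluster shape needs >= 2 points", call. = FALSE)
  cx <- mean(points$x); cy <- mean(points$y)
  dx <- points$x - cx; dy <- points$y - cy
  S <- matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2, 2)
  ev <- eigen(S, symmetric = TRUE)$values
  l1 <- max(ev[1], 0); l2 <- max(ev[2], 0)
  collinear <- l2 <= .Machine$double.eps * max(l1, 1)
  ecc <- if (collinear) {
    if (ecc_def == "axis_ratio") Inf else 1
  } else if (ecc_def == "axis_ratio") sqrt(l1 / l2) else sqrt(1 - l2 / l1)
  tibble::tibble(cluster_id = cluster_id, n_locs = n,
                 centroid_x = cx, centroid_y = cy,
                 rg = sqrt(l1 + l2), ecc = ecc,
                 lambda1 = l1, lambda2 = l2, collinear = collinear)
}

#' Summarize a clustered localization field
#'
#' Per-cluster morphometrics for all non-noise clusters plus field-level
#' counts: number of clusters, clusters per area, and the fraction of
#' unclustered (noise) localizations.
#'
#' @param locs A clustered tibble from [cluster_localizations()] (or any
#'   data frame with `x`, `y` and `cluster` columns, noise = -1).
#' @param field_area Field area in square micrometres; when `NULL` the
#'   density is `NA` but counts are still reported.
#' @param ecc_def Passed to [cluster_shape()].
#'
#' @return A `field_summary` list with elements `clusters` (per-cluster
#'   tibble), `n_clusters`, `clusters_per_area` (per square micrometre),
#'   `noise_fraction`, `n_locs`. Use [glance()] for a one-row tibble.
#' @export
summarize_field <- function(locs, field_area = NULL,
                            ecc_def = c("axis_ratio", "flattening")) {
  ecc_def <- match.arg(ecc_def)
  locs <- tibble::as_tibble(locs)
  if (!"cluster" %in% names(locs)) {
    stop("locs must carry a 'cluster' column; run cluster_localizations() first",
         call. = FALSE)
  }
  keep <- locs$cluster != -1L
  ids <- sort(unique(locs$cluster[keep]))
  clusters <- purrr::map_dfr(ids, function(id) {
    cluster_shape(locs[locs$cluster == id, c("x", "y")], cluster_id = id,
                  ecc_def = ecc_def)
  })
  if (length(ids) == 0) {
    clusters <- cluster_shape(data.frame(x = c(0, 1), y = c(0, 1)))[0, ]
  }
  out <- list(
    clusters = clusters,
    n_clusters = length(ids),
    clusters_per_area = if (is.null(field_area)) NA_real_ else length(ids) / field_area,
    noise_fraction = if (nrow(locs) > 0) mean(!keep) else NA_real_,
    n_locs = nrow(locs),
    field_area = if (is.null(field_area)) NA_real_ else field_area)
  class(out) <- "field_summary"
  out
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("<field_summary> %d clusters, %d localizations, noise fraction %.3f\n",
              x$n_clusters, x$n_locs, x$noise_fraction))
  if (is.finite(x$clusters_per_area)) {
    cat(sprintf("  density %.4f clusters/um^2 over %.1f um^2\n",
                x$clusters_per_area, x$field_area))
  }
  invisible(x)
}

#' Tidy methods for field summaries
#'
#' @param x A `field_summary` from [summarize_field()].
#' @param ... Unused.
#' @return `tidy()` returns the per-cluster morphometrics tibble;
#'   `glance()` a one-row field-level summary with median Rg/Ecc.
#' @method tidy field_summary
#' @export
tidy.field_summary <- function(x, ...) x$clusters

#' @rdname tidy.field_summary
#' @method glance field_summary
#' @export
glance.field_summary <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    clusters_per_area = x$clusters_per_area,
    noise_fraction = x$noise_fraction,
    n_locs = x$n_locs,
    median_rg = stats::median(x$clusters$rg),
    median_ecc = stats::median(x$clusters$ecc[is.finite(x$clusters$ecc)]),
    median_n_locs = stats::median(x$clusters$n_locs))
}

#' Compare two conditions by per-experiment medians
#'
#' Student's unpaired two-sided t-test on per-experiment median values
#' (one median per independent experiment, never pooled localizations),
#' the design used to compare cluster Rg and Ecc between untreated and
#' pyroptotic cells. Groups whose pooled variance is zero are handled in
#' closed form (t = 0, p = 1 for equal means; |t| = Inf, p = 0
#' otherwise).
#'
#' @param medians_a,medians_b Numeric vectors of per-experiment medians
#'   (>= 2 each).
#'
#' @return A one-row tibble with `estimate` (mean A - mean B),
#'   `statistic`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
#' @examples
#' compare_conditions(c(55, 60, 58), c(120, 140, 130))
compare_conditions <- function(medians_a, medians_b) {
  a <- as.numeric(medians_a); b <- as.numeric(medians_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 per-experiment medians per condition: the test is run ",
         "on one median per independent experiment, not pooled localizations",
         call. = FALSE)
  }
  df <- length(a) + length(b) - 2
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (pooled_var <= .Machine$double.eps * max(abs(c(a, b)), 1)^2) {
    diff <- mean(a) - mean(b)
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    return(tibble::tibble(estimate = diff, statistic = stat, p_value = p,
                          df = df, n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  tibble::tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}

#' Read a localization table
#'
#' Reads a CSV of single-molecule localizations with a header. Columns
#' `x_nm`, `y_nm`, `frame` and optional `precision_nm` are mapped to
#' `x`, `y`, `frame`, `precision`; alternative dialects can be mapped
#' via `col_map`.
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping output names (`x`, `y`,
#'   `frame`, `precision`) to input column names.
#' @return A tibble with columns `x`, `y` (nm), `frame` and optionally
#'   `precision`.
#' @export
read_localizations <- function(path, col_map = c(x = "x_nm", y = "y_nm",
                                                 frame = "frame",
                                                 precision = "precision_nm")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(.rows = nrow(raw))
  for (nm in c("x", "y", "frame", "precision")) {
    src <- if (nm %in% names(col_map)) col_map[[nm]] else NULL
    if (!is.null(src) && !is.na(src) && src %in% names(raw)) {
      out[[nm]] <- raw[[src]]
    } else if (nm %in% c("x", "y")) {
      stop("column '", src, "' not found in ", path, call. = FALSE)
    }
  }
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    stop("localization coordinates must be finite", call. = FALSE)
  }
  out
}
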