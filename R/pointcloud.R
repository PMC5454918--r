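#' Point-cloud analysis of two-colour localization data
#'
#' ALU-dense regions are found with DBSCAN (density-based spatial
#' clustering of applications with noise): a localization is a
#' "cluster-point" (core point) when at least `min_points` localizations —
#' itself included — lie within `radius_nm`; core points closer than the
#' radius share a cluster, and every non-core point within the radius of a
#' core point joins that core's cluster (border point). Everything else is
#' noise. Cluster centres are the shoelace (Surveyor's-formula) centroids
#' of the convex hull of the member points, and the heterochromatin
#' environment is profiled as point densities in concentric 10-nm annuli
#' around those centres.
#'
#' @name pointcloud
NULL

#' DBSCAN cluster labels for a point cloud
#'
#' @param points data frame with `x_nm`, `y_nm` (e.g. one channel of a
#'   localization table).
#' @param radius_nm neighbourhood radius in nm (default 100).
#' @param min_points minimum number of points within the radius — the point
#'   itself counts — for a core point (default 10).
#' @return integer vector of labels: 0 for noise, 1..K for clusters.
#'   Clusters are numbered by their smallest core-point row index; border
#'   points equidistant from several clusters take the cluster of their
#'   first core neighbour in row order, so labels are deterministic.
#' @export
dbscan_points <- function(points, radius_nm = 100, min_points = 10L) {
  cl_assert(is_scalar_num(radius_nm) && radius_nm > 0, "radius_nm must be > 0")
  cl_assert(min_points >= 1, "min_points must be >= 1")
  x <- points$x_nm; y <- points$y_nm
  n <- length(x)
  labels <- integer(n)
  if (n == 0L) return(labels)
  nb <- cell_neighbors(x, y, radius_nm)
  core <- lengths(nb) >= min_points
  core_idx <- which(core)
  if (length(core_idx) == 0L) return(labels)

  # connected components of core points under distance <= radius
  edges <- vector("list", length(core_idx))
  for (i in seq_along(core_idx)) {
    ci <- core_idx[i]
    js <- nb[[ci]]
    js <- js[js > ci & core[js]]
    if (length(js)) edges[[i]] <- cbind(ci, js)
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(core_idx), directed = FALSE)
  if (!is.null(edges)) {
    local_e <- cbind(match(edges[, 1L], core_idx), match(edges[, 2L], core_idx))
    g <- igraph::add_edges(g, t(local_e))
  }
  comp <- igraph::components(g)$membership
  # number clusters by smallest member core index
  first_idx <- vapply(split(core_idx, comp), min, numeric(1))
  relabel <- integer(length(first_idx))
  relabel[order(first_idx)] <- seq_along(first_idx)
  labels[core_idx] <- relabel[comp]

  # border points: first core neighbour in index order decides
  for (i in which(!core)) {
    cn <- nb[[i]]
    cn <- cn[core[cn]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

#' Convex hull of a point set as a counter-clockwise polygon
#'
#' @param x,y coordinates in nm.
#' @return two-column matrix of hull vertices in counter-clockwise order,
#'   or NULL when fewer than 3 distinct non-collinear points exist.
#' @export
convex_hull_polygon <- function(x, y) {
  if (length(x) < 3L) return(NULL)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(NULL)
  h <- rev(h)  # chull returns clockwise order; flip to counter-clockwise
  cbind(x = x[h], y = y[h])
}

# Signed area of a polygon (counter-clockwise positive).
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

#' Cluster centre by the Surveyor's (shoelace) formula
#'
#' The centre of a cluster is the centroid of the convex hull polygon of
#' its member points, C = 1/(6A) * sum((v_i + v_{i+1}) * cross(v_i,
#' v_{i+1})). Degenerate clusters (fewer than 3 distinct points, or all
#' collinear) fall back to the arithmetic mean.
#'
#' @param x,y member coordinates in nm.
#' @return numeric `(x, y)` centre in nm.
#' @export
cluster_center <- function(x, y) {
  cl_assert(length(x) > 0, "cluster is empty")
  poly <- convex_hull_polygon(x, y)
  if (is.null(poly)) return(c(x = mean(x), y = mean(y)))
  px <- poly[, 1L]; py <- poly[, 2L]
  x2 <- c(px[-1L], px[1L]); y2 <- c(py[-1L], py[1L])
  cross <- px * y2 - x2 * py
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(x = mean(x), y = mean(y)))
  c(x = sum((px + x2) * cross) / (6 * a),
    y = sum((py + y2) * cross) / (6 * a))
}

#' Detect clusters and summarize them
#'
#' Runs [dbscan_points()] and computes, per cluster, the member count, the
#' shoelace centre and the convex hull polygon.
#'
#' @inheritParams dbscan_points
#' @return list with `labels` (per-point integer labels) and `clusters`, a
#'   tibble with `cluster_id`, `n_points`, `center_x_nm`, `center_y_nm` and
#'   a list-column `hull` of counter-clockwise vertex matrices.
#' @export
find_clusters <- function(points, radius_nm = 100, min_points = 10L) {
  labels <- dbscan_points(points, radius_nm, min_points)
  ids <- sort(unique(labels[labels > 0L]))
  n_points <- integer(length(ids))
  cx <- numeric(length(ids)); cy <- numeric(length(ids))
  hulls <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- labels == ids[i]
    ctr <- cluster_center(points$x_nm[sel], points$y_nm[sel])
    n_points[i] <- sum(sel)
    cx[i] <- ctr[["x"]]; cy[i] <- ctr[["y"]]
    hulls[[i]] <- convex_hull_polygon(points$x_nm[sel], points$y_nm[sel])
  }
  clusters <- tibble::tibble(cluster_id = ids, n_points = n_points,
                             center_x_nm = cx, center_y_nm = cy,
                             hull = hulls)
  list(labels = labels, clusters = clusters)
}

#' Density profile in concentric shells around one centre
#'
#' Shell k (k = 0, 1, ...) covers distances `[k*w, (k+1)*w)` from the
#' centre; its density is the target point count divided by the annulus
#' area pi*((k+1)^2 - k^2)*w^2 in points/nm^2.
#'
#' @param center numeric `(x, y)` in nm.
#' @param targets data frame with `x_nm`, `y_nm` (e.g. the heterochromatin
#'   channel).
#' @param shell_width_nm shell width w in nm (default 10).
#' @param max_radius_nm outermost shell edge in nm (default 1000).
#' @return tibble with `shell_inner_nm`, `shell_outer_nm`, `count`,
#'   `density_per_nm2` and attribute `n_clusters_averaged = 1`.
#' @export
shell_density_profile <- function(center, targets, shell_width_nm = 10,
                                  max_radius_nm = 1000) {
  cl_assert(shell_width_nm > 0, "shell_width_nm must be > 0")
  cl_assert(max_radius_nm >= shell_width_nm,
            "max_radius_nm must be >= shell_width_nm")
  nshell <- floor(max_radius_nm / shell_width_nm)
  d <- sqrt((targets$x_nm - center[[1L]])^2 + (targets$y_nm - center[[2L]])^2)
  d <- d[d < nshell * shell_width_nm]
  counts <- tabulate(floor(d / shell_width_nm) + 1L, nbins = nshell)
  inner <- (seq_len(nshell) - 1L) * shell_width_nm
  outer <- seq_len(nshell) * shell_width_nm
  area <- pi * (outer^2 - inner^2)
  out <- tibble::tibble(shell_inner_nm = inner, shell_outer_nm = outer,
                        count = counts, density_per_nm2 = counts / area)
  attr(out, "n_clusters_averaged") <- 1L
  out
}

#' Mean shell-density profile over many cluster centres
#'
#' Computes [shell_density_profile()] for every centre and averages the
#' per-shell densities arithmetically (`pool = "mean"`), or pools raw
#' counts over all centres before dividing by the summed annulus area
#' (`pool = "pooled"`, equivalent to a count-weighted mean). Mean counts
#' per shell are reported alongside.
#'
#' @param centers data frame with `center_x_nm`, `center_y_nm` (as produced
#'   by [find_clusters()]) or a two-column matrix.
#' @inheritParams shell_density_profile
#' @param pool "mean" (default) or "pooled".
#' @return tibble as for [shell_density_profile()], with attribute
#'   `n_clusters_averaged`.
#' @export
mean_shell_profile <- function(centers, targets, shell_width_nm = 10,
                               max_radius_nm = 1000,
                               pool = c("mean", "pooled")) {
  pool <- match.arg(pool)
  if (is.matrix(centers)) {
    centers <- tibble::tibble(center_x_nm = centers[, 1L],
                              center_y_nm = centers[, 2L])
  }
  ncl <- nrow(centers)
  cl_assert(ncl >= 1, "at least one cluster centre is required")
  nshell <- floor(max_radius_nm / shell_width_nm)
  count_mat <- matrix(0, ncl, nshell)
  dens_mat <- matrix(0, ncl, nshell)
  for (i in seq_len(ncl)) {
    p <- shell_density_profile(c(centers$center_x_nm[i], centers$center_y_nm[i]),
                               targets, shell_width_nm, max_radius_nm)
    count_mat[i, ] <- p$count
    dens_mat[i, ] <- p$density_per_nm2
  }
  inner <- (seq_len(nshell) - 1L) * shell_width_nm
  outer <- seq_len(nshell) * shell_width_nm
  area <- pi * (outer^2 - inner^2)
  dens <- if (pool == "mean") colMeans(dens_mat) else
    colSums(count_mat) / (ncl * area)
  out <- tibble::tibble(shell_inner_nm = inner, shell_outer_nm = outer,
                        count = colMeans(count_mat), density_per_nm2 = dens)
  attr(out, "n_clusters_averaged") <- ncl
  out
}

#' Nearest-neighbour colocalization fraction
#'
#' Fraction of points in `set_a` whose nearest neighbour in `set_b` lies
#' within `threshold_nm`. The measure is asymmetric; call it in both
#' directions to report both.
#'
#' @param set_a,set_b data frames with `x_nm`, `y_nm`.
#' @param threshold_nm colocalization distance threshold in nm (> 0).
#' @return fraction in `[0, 1]`.
#' @export
colocalization_fraction <- function(set_a, set_b, threshold_nm) {
  cl_assert(is_scalar_num(threshold_nm) && threshold_nm > 0,
            "threshold_nm must be > 0")
  cl_assert(nrow(set_b) > 0, "set_b must not be empty")
  na <- nrow(set_a)
  if (na == 0L) return(NaN)
  hit <- logical(na)
  t2 <- threshold_nm^2
  chunk <- max(1L, floor(5e6 / nrow(set_b)))
  for (s in seq(1L, na, by = chunk)) {
    e <- min(na, s + chunk - 1L)
    d2 <- outer(set_a$x_nm[s:e], set_b$x_nm, "-")^2 +
      outer(set_a$y_nm[s:e], set_b$y_nm, "-")^2
    hit[s:e] <- apply(d2 <= t2, 1L, any)
  }
  mean(hit)
}

#' Write a cluster table to CSV
#'
#' Columns: `cluster_id`, `n_points`, `center_x_nm`, `center_y_nm`,
#' `hull_wkt` (the hull polygon as WKT).
#'
#' @param clusters cluster tibble from [find_clusters()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  wkt <- vapply(clusters$hull, function(h) {
    if (is.null(h)) return("POLYGON EMPTY")
    ring <- rbind(h, h[1L, , drop = FALSE])
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.3f %.3f", ring[, 1L], ring[, 2L]), collapse = ", "))
  }, character(1))
  out <- data.frame(cluster_id = clusters$cluster_id,
                    n_points = clusters$n_points,
                    center_x_nm = clusters$center_x_nm,
                    center_y_nm = clusters$center_y_nm,
                    hull_wkt = wkt)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a shell profile to CSV
#'
#' @param profile tibble from [shell_density_profile()] or
#'   [mean_shell_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shell_profile <- function(profile, path) {
  out <- data.frame(shell_inner_nm = profile$shell_inner_nm,
                    shell_outer_nm = profile$shell_outer_nm,
                    mean_count = profile$count,
                    mean_density_per_nm2 = profile$density_per_nm2,
                    n_clusters = attr(profile, "n_clusters_averaged") %||% NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
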