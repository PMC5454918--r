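# Independent reference implementations and fixture builders used across the
# suite. These stay deliberately naive (literal sums, O(n^2) scans, BFS) so
# they are oracles for the optimized package code, not copies of it.

# Literal double-loop evaluation of the moment and precision sums for an ROI.
oracle_moments <- function(qi, origin, nb, pixel_size_nm) {
  Q <- 0
  for (r in seq_len(nrow(qi))) for (c in seq_len(ncol(qi))) Q <- Q + qi[r, c]
  sx <- 0; sy <- 0
  for (r in seq_len(nrow(qi))) {
    for (c in seq_len(ncol(qi))) {
      x <- (origin[["col"]] - 1) + (c - 0.5)
      y <- (origin[["row"]] - 1) + (r - 0.5)
      sx <- sx + qi[r, c] * x
      sy <- sy + qi[r, c] * y
    }
  }
  mux <- sx / Q; muy <- sy / Q
  vx <- 0; vy <- 0; px <- 0; py <- 0
  for (r in seq_len(nrow(qi))) {
    for (c in seq_len(ncol(qi))) {
      x <- (origin[["col"]] - 1) + (c - 0.5)
      y <- (origin[["row"]] - 1) + (r - 0.5)
      vx <- vx + (x - mux)^2 * qi[r, c] / Q
      vy <- vy + (y - muy)^2 * qi[r, c] / Q
      px <- px + ((x - mux) / Q)^2 * (qi[r, c] + nb)
      py <- py + ((y - muy) / Q)^2 * (qi[r, c] + nb)
    }
  }
  list(Q = Q, mux = mux * pixel_size_nm, muy = muy * pixel_size_nm,
       vx = vx * pixel_size_nm^2, vy = vy * pixel_size_nm^2,
       px = sqrt(1 / (12 * Q) + px) * pixel_size_nm,
       py = sqrt(1 / (12 * Q) + py) * pixel_size_nm)
}

random_roi <- function(side = 7L) {
  qi <- matrix(stats::rexp(side^2, rate = 1 / 50), side, side)
  qi[sample(side^2, side)] <- 0  # some empty pixels
  list(origin = c(row = sample(1:50, 1L), col = sample(1:50, 1L)),
       qi = qi, nb = stats::runif(1, 0, 20))
}

# O(n^2) density-reachability DBSCAN: core points found from the full
# distance matrix, clusters grown by BFS over core points in index order,
# border points assigned to the cluster of their first core neighbour.
oracle_dbscan <- function(x, y, radius, min_points) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(cbind(x, y)))
  nbmat <- D <= radius
  core <- rowSums(nbmat) >= min_points  # diagonal TRUE: the point counts itself
  labels <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    k <- k + 1L
    labels[i] <- k
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      nxt <- which(nbmat[j, ] & core & labels == 0L)
      labels[nxt] <- k
      queue <- c(queue, nxt)
    }
  }
  for (i in which(!core)) {
    cn <- which(nbmat[i, ] & core)
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Map cluster ids to 1..K in order of first appearance so two labelings can
# be compared up to relabeling (noise stays 0).
normalize_labels <- function(labels) {
  ids <- unique(labels[labels > 0L])
  out <- labels
  for (i in seq_along(ids)) out[labels == ids[i]] <- i
  out
}

# A mixed clustered + noise point field for DBSCAN equivalence checks.
random_point_field <- function(n, field = 4000) {
  n_blob <- sample(0:6, 1L)
  frac_noise <- stats::runif(1, 0.2, 0.8)
  n_noise <- round(n * frac_noise)
  n_cl <- n - n_noise
  xs <- stats::runif(n_noise, 0, field)
  ys <- stats::runif(n_noise, 0, field)
  if (n_blob > 0L && n_cl > 0L) {
    alloc <- tabulate(sample.int(n_blob, n_cl, replace = TRUE), n_blob)
    cx <- stats::runif(n_blob, 0, field)
    cy <- stats::runif(n_blob, 0, field)
    sg <- stats::runif(n_blob, 20, 120)
    for (b in seq_len(n_blob)) {
      xs <- c(xs, stats::rnorm(alloc[b], cx[b], sg[b]))
      ys <- c(ys, stats::rnorm(alloc[b], cy[b], sg[b]))
    }
  } else if (n_cl > 0L) {
    xs <- c(xs, stats::runif(n_cl, 0, field))
    ys <- c(ys, stats::runif(n_cl, 0, field))
  }
  tibble::tibble(x_nm = xs, y_nm = ys)
}

# Naive sliding-window exact scan (string comparison at every offset).
naive_scan <- function(seq, probe) {
  n <- nchar(seq)
  k <- nchar(probe)
  if (n < k) return(integer(0))
  windows <- substring(seq, 1:(n - k + 1L), k:n)
  which(windows == probe) - 1L  # 0-based
}

# Fraction of planted ON events recovered within 3 * reported precision.
recovery_fraction <- function(truth, locs) {
  rec <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- locs[locs$frame == truth$frame[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- sqrt((cand$x_nm - truth$x_nm[i])^2 + (cand$y_nm - truth$y_nm[i])^2)
    tol <- 3 * pmax(cand$precision_x_nm, cand$precision_y_nm)
    if (any(d <= tol)) rec <- rec + 1L
  }
  rec / nrow(truth)
}

# n points uniform in a disc, as a bare coordinate tibble.
runif_disc_pts <- function(n, radius, cx = 0, cy = 0) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  tibble::tibble(x_nm = cx + r * cos(th), y_nm = cy + r * sin(th))
}

# Small two-channel localization table for I/O and rendering tests.
random_localizations <- function(n, channels = c("alu", "het"), extent = 5000) {
  localization_set(
    frame = sample(0:100, n, replace = TRUE),
    channel = sample(channels, n, replace = TRUE),
    x_nm = stats::runif(n, 0, extent), y_nm = stats::runif(n, 0, extent),
    photons = stats::runif(n, 100, 2000),
    sigma_x_nm = stats::runif(n, 50, 150), sigma_y_nm = stats::runif(n, 50, 150),
    precision_x_nm = stats::runif(n, 5, 20),
    precision_y_nm = stats::runif(n, 5, 20),
    background = stats::runif(n, 0, 20))
}
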