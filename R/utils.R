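# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Validation errors get their own condition class so the CLI can map them to
# exit code 2 while runtime failures map to 1.
cl_stop <- function(..., class = "comboloc_validation_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "comboloc_error")))
}

cl_assert <- function(cond, ...) {
  if (!isTRUE(cond)) cl_stop(...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Fixed-radius neighbour search by cell binning: returns, for each point, the
# integer indices of all points (including itself) within Euclidean distance
# <= radius. Cells have side length = radius so neighbours always lie in the
# 3 x 3 cell block around a point's own cell.
cell_neighbors <- function(x, y, radius) {
  n <- length(x)
  if (n == 0L) return(list())
  cx <- floor(x / radius)
  cy <- floor(y / radius)
  key <- paste(cx, cy, sep = ",")
  cells <- split(seq_len(n), key)
  lookup <- list2env(cells, hash = TRUE, size = length(cells) * 2L)
  out <- vector("list", n)
  r2 <- radius^2
  for (k in names(cells)) {
    idx <- cells[[k]]
    cc <- as.numeric(strsplit(k, ",", fixed = TRUE)[[1L]])
    cand <- integer(0)
    for (dx in -1:1) {
      for (dy in -1:1) {
        v <- lookup[[paste(cc[1L] + dx, cc[2L] + dy, sep = ",")]]
        if (!is.null(v)) cand <- c(cand, v)
      }
    }
    d2 <- outer(x[idx], x[cand], "-")^2 + outer(y[idx], y[cand], "-")^2
    keep <- d2 <= r2
    for (i in seq_along(idx)) out[[idx[i]]] <- cand[keep[i, ]]
  }
  out
}

# Uniform point in a disc of given radius centred at (cx, cy).
runif_disc <- function(n, radius, cx = 0, cy = 0) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Uniform point in an annulus [inner, outer) centred at (cx, cy).
runif_annulus <- function(n, inner, outer, cx = 0, cy = 0) {
  r <- sqrt(stats::runif(n, inner^2, outer^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}
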