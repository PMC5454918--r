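#' Super-resolution rendering of localization data
#'
#' Three standard visualizations of a localization table:
#' * pointillist image — binary map, a pixel is 1 iff at least one
#'   localization falls inside it;
#' * density image — each localization is assigned the number of further
#'   localizations within a fixed radius R; every point with a count > 0
#'   becomes a unit-integral Gaussian of width `gauss_sigma_nm` weighted by
#'   its count, and the image is the discretized sum;
#' * localization image — every point becomes a unit-integral Gaussian
#'   whose per-axis sigma is that point's localization precision.
#'
#' Gaussians are truncated at 4 sigma (mass error < 1e-4). Pixel values are
#' the integral of the summed Gaussians over the pixel, so the sum over all
#' pixels approximates the total weight.
#'
#' @name renderer
NULL

#' Count neighbours within a fixed radius
#'
#' For every localization, the number of *other* localizations within
#' Euclidean distance `radius_nm` (the value assigned to each coordinate
#' before density rendering).
#'
#' @param points localization table (or any data frame with `x_nm`, `y_nm`).
#' @param radius_nm neighbourhood radius R in nm (> 0).
#' @return integer vector of neighbour counts, one per row of `points`.
#' @export
neighbor_counts <- function(points, radius_nm) {
  cl_assert(is_scalar_num(radius_nm) && radius_nm > 0, "radius_nm must be > 0")
  nb <- cell_neighbors(points$x_nm, points$y_nm, radius_nm)
  lengths(nb) - 1L
}

new_rendered_image <- function(pixels, pixel_size_nm, origin, kind) {
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 origin = origin,
                 extent_nm = c(width = ncol(pixels) * pixel_size_nm,
                               height = nrow(pixels) * pixel_size_nm),
                 kind = kind),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image: %s, %d x %d px @ %g nm/px, total = %g>\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              sum(x$pixels)))
  invisible(x)
}

# Shared frame geometry: origin defaults to the lower corner of the point
# cloud minus a margin; an explicit field of view overrides it.
render_frame_geometry <- function(x, y, pixel_size_nm, margin_nm, field_of_view) {
  if (!is.null(field_of_view)) {
    origin <- field_of_view$origin_nm
    wpx <- ceiling(field_of_view$width_nm / pixel_size_nm)
    hpx <- ceiling(field_of_view$height_nm / pixel_size_nm)
  } else {
    origin <- c(min(x) - margin_nm, min(y) - margin_nm)
    wpx <- max(1L, ceiling((max(x) + margin_nm - origin[1]) / pixel_size_nm))
    hpx <- max(1L, ceiling((max(y) + margin_nm - origin[2]) / pixel_size_nm))
  }
  list(origin = origin, wpx = as.integer(wpx), hpx = as.integer(hpx))
}

# Accumulate weighted, truncated, unit-integral Gaussians on a pixel grid.
render_gaussians <- function(x, y, weight, sx, sy, pixel_size_nm, field_of_view) {
  keep <- weight > 0
  x <- x[keep]; y <- y[keep]; weight <- weight[keep]
  sx <- sx[keep]; sy <- sy[keep]
  if (length(x) == 0L) {
    geom <- field_of_view %||% list(origin_nm = c(0, 0), width_nm = pixel_size_nm,
                                    height_nm = pixel_size_nm)
    g <- render_frame_geometry(0, 0, pixel_size_nm, 0, geom)
    return(new_rendered_image(matrix(0, g$hpx, g$wpx), pixel_size_nm, g$origin, "empty"))
  }
  margin <- 4 * max(sx, sy) + pixel_size_nm
  g <- render_frame_geometry(x, y, pixel_size_nm, margin, field_of_view)
  img <- matrix(0, g$hpx, g$wpx)
  xedges <- g$origin[1] + (0:g$wpx) * pixel_size_nm
  yedges <- g$origin[2] + (0:g$hpx) * pixel_size_nm
  for (i in seq_along(x)) {
    c0 <- max(1L, floor((x[i] - 4 * sx[i] - g$origin[1]) / pixel_size_nm) + 1L)
    c1 <- min(g$wpx, ceiling((x[i] + 4 * sx[i] - g$origin[1]) / pixel_size_nm))
    r0 <- max(1L, floor((y[i] - 4 * sy[i] - g$origin[2]) / pixel_size_nm) + 1L)
    r1 <- min(g$hpx, ceiling((y[i] + 4 * sy[i] - g$origin[2]) / pixel_size_nm))
    if (c0 > c1 || r0 > r1) next
    px <- diff(stats::pnorm(xedges[c0:(c1 + 1L)], mean = x[i], sd = sx[i]))
    py <- diff(stats::pnorm(yedges[r0:(r1 + 1L)], mean = y[i], sd = sy[i]))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + weight[i] * (py %o% px)
  }
  new_rendered_image(img, pixel_size_nm, g$origin, "gaussian")
}

#' Render a neighbourhood-density image
#'
#' Every localization with a neighbour count k > 0 within `radius_nm`
#' contributes a unit-integral Gaussian of width `gauss_sigma_nm` scaled by
#' k; isolated points (k = 0) contribute nothing.
#'
#' @param points localization table.
#' @param pixel_size_nm output pixel size in nm (e.g. 10).
#' @param radius_nm neighbourhood radius R in nm (e.g. 1000).
#' @param gauss_sigma_nm Gaussian width in nm (e.g. 50).
#' @param field_of_view optional list `(origin_nm, width_nm, height_nm)`
#'   fixing the output frame; default frames the point cloud.
#' @return a `rendered_image` with `kind = "density"`.
#' @export
render_density_image <- function(points, pixel_size_nm = 10, radius_nm = 1000,
                                 gauss_sigma_nm = 50, field_of_view = NULL) {
  cl_assert(pixel_size_nm > 0 && radius_nm > 0 && gauss_sigma_nm > 0,
            "pixel_size_nm, radius_nm and gauss_sigma_nm must be > 0")
  n <- nrow(points)
  k <- if (n > 0) neighbor_counts(points, radius_nm) else integer(0)
  img <- render_gaussians(points$x_nm, points$y_nm, as.numeric(k),
                          rep(gauss_sigma_nm, n), rep(gauss_sigma_nm, n),
                          pixel_size_nm, field_of_view)
  img$kind <- "density"
  img$params <- list(pixel_size_nm = pixel_size_nm, radius_nm = radius_nm,
                     gauss_sigma_nm = gauss_sigma_nm)
  img
}

#' Render a standard localization image
#'
#' Every localization contributes a unit-integral Gaussian whose per-axis
#' widths are its own localization precisions, so the discrete image
#' integral approximates the number of points.
#'
#' @inheritParams render_density_image
#' @return a `rendered_image` with `kind = "localization"`.
#' @export
render_localization_image <- function(points, pixel_size_nm = 10,
                                      field_of_view = NULL) {
  cl_assert(pixel_size_nm > 0, "pixel_size_nm must be > 0")
  if (nrow(points) > 0) {
    cl_assert(all(points$precision_x_nm > 0) && all(points$precision_y_nm > 0),
              "every localization needs precision_x_nm and precision_y_nm > 0")
  }
  img <- render_gaussians(points$x_nm, points$y_nm, rep(1, nrow(points)),
                          points$precision_x_nm, points$precision_y_nm,
                          pixel_size_nm, field_of_view)
  img$kind <- "localization"
  img$params <- list(pixel_size_nm = pixel_size_nm)
  img
}

#' Render a pointillist (binary) image
#'
#' A pixel is 1 iff at least one localization falls in it; binning is
#' half-open, `floor((coord - origin) / pixel_size)`.
#'
#' @inheritParams render_density_image
#' @return a `rendered_image` with `kind = "pointillist"` and 0/1 pixels.
#' @export
render_pointillist <- function(points, pixel_size_nm = 10, field_of_view = NULL) {
  cl_assert(pixel_size_nm > 0, "pixel_size_nm must be > 0")
  x <- points$x_nm; y <- points$y_nm
  if (length(x) == 0L) {
    g <- render_frame_geometry(0, 0, pixel_size_nm, 0,
                               field_of_view %||% list(origin_nm = c(0, 0),
                                                       width_nm = pixel_size_nm,
                                                       height_nm = pixel_size_nm))
    return(new_rendered_image(matrix(0, g$hpx, g$wpx), pixel_size_nm,
                              g$origin, "pointillist"))
  }
  g <- render_frame_geometry(x, y, pixel_size_nm, pixel_size_nm, field_of_view)
  img <- matrix(0, g$hpx, g$wpx)
  cc <- floor((x - g$origin[1]) / pixel_size_nm) + 1L
  rr <- floor((y - g$origin[2]) / pixel_size_nm) + 1L
  inside <- cc >= 1L & cc <= g$wpx & rr >= 1L & rr <= g$hpx
  img[cbind(rr[inside], cc[inside])] <- 1
  new_rendered_image(img, pixel_size_nm, g$origin, "pointillist")
}

#' Write a rendered image to TIFF with a JSON parameter sidecar
#'
#' Pixel values are scaled to the 16-bit range; the scale factor and render
#' parameters go to `<path>.json`.
#'
#' @param image a `rendered_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rendered_image <- function(image, path) {
  px <- image$pixels
  mx <- max(px)
  scaled <- if (mx > 0) px / mx else px
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  meta <- list(kind = image$kind, pixel_size_nm = image$pixel_size_nm,
               origin_nm = image$origin, extent_nm = as.list(image$extent_nm),
               intensity_scale = mx, params = image$params %||% list())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
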