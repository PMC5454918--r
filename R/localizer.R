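#' Single-molecule localization from raw image stacks
#'
#' In SPDM-type localization microscopy only a few fluorophores blink on in
#' any one frame. Each blink images to a diffraction-limited spot (the PSF).
#' The localizer detects spots frame by frame, cuts a square region of
#' interest (ROI) around each, subtracts twice the background level, and
#' estimates the emitter position by intensity-weighted moments:
#'
#'   Q = sum(q_i),  mu = sum(q_i x_i) / Q,  sigma^2 = sum(q_i (x_i - mu)^2)/Q
#'
#' with the localization precision
#'
#'   d_mu = sqrt( 1/(12 Q) + sum(((x_i - mu)/Q)^2 (q_i + N_B)) )
#'
#' evaluated per axis in pixel units and scaled to nm by the pixel size
#' (N_B is the per-pixel background level before the 2x subtraction).
#'
#' Pixel convention: pixel in (row r, column c), 1-based, has its center at
#' x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size; the origin is the
#' top-left corner of the frame, x runs along columns, y along rows.
#'
#' @name localizer
NULL

#' Estimate the per-frame background level
#'
#' Robust scalar background estimate: the median over all pixel
#' intensities. A single bright emitter occupies a vanishing fraction of
#' pixels and leaves the median unchanged.
#'
#' @param frame numeric matrix of non-negative pixel intensities (counts).
#' @return background level in counts/pixel.
#' @export
estimate_background <- function(frame) {
  cl_assert(is.matrix(frame) && length(frame) > 0, "frame must be a non-empty matrix")
  cl_assert(all(frame >= 0), "frame intensities must be >= 0")
  stats::median(frame)
}

#' Detect candidate fluorophore spots in one frame
#'
#' A pixel qualifies as a spot candidate when it is a local intensity
#' maximum (>= its 8 neighbours), its intensity is at least
#' `threshold_factor` times the background, and a `roi_side` x `roi_side`
#' ROI centred on it fits entirely inside the frame. Twice the background is
#' subtracted from every ROI pixel (negative results clamped to 0). When two
#' candidate peaks are closer than `roi_side` pixels along both axes (their
#' ROIs would overlap) only the brighter is kept.
#'
#' @param frame numeric matrix of pixel intensities.
#' @param background scalar background level (counts/pixel), >= 0.
#' @param roi_side odd integer >= 3, ROI side length in pixels.
#' @param threshold_factor peak acceptance threshold as a multiple of the
#'   background (default 4: a peak must be at least four times the
#'   background).
#' @return list of ROIs; each is a list with `origin` (1-based (row, col) of
#'   the ROI's top-left pixel), `qi` (background-subtracted intensity
#'   matrix) and `nb` (the pre-subtraction background level).
#' @export
detect_spots <- function(frame, background, roi_side = 7L, threshold_factor = 4) {
  cl_assert(is.matrix(frame) && length(frame) > 0, "frame must be a non-empty matrix")
  cl_assert(is_scalar_num(background) && background >= 0, "background must be >= 0")
  roi_side <- as.integer(roi_side)
  cl_assert(roi_side >= 3L && roi_side %% 2L == 1L, "roi_side must be odd and >= 3")
  nr <- nrow(frame); nc <- ncol(frame)
  h <- (roi_side - 1L) %/% 2L
  if (nr < roi_side || nc < roi_side) return(list())

  # local maxima: >= all 8 neighbours (plateaus resolved by the overlap rule)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  ismax <- matrix(TRUE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ismax <- ismax & frame >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    }
  }
  cand <- which(ismax & frame >= threshold_factor * background, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list())
  # ROI must fit inside the frame
  fits <- cand[, 1L] > h & cand[, 1L] <= nr - h & cand[, 2L] > h & cand[, 2L] <= nc - h
  cand <- cand[fits, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  # brighter peaks first; drop any candidate whose ROI would overlap a kept one
  ord <- order(frame[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0L ||
        all(abs(kept[, 1L] - cand[i, 1L]) >= roi_side |
            abs(kept[, 2L] - cand[i, 2L]) >= roi_side)) {
      kept <- rbind(kept, cand[i, ])
    }
  }
  rois <- vector("list", nrow(kept))
  keep <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    r <- unname(kept[i, 1L]); c <- unname(kept[i, 2L])
    qi <- pmax(frame[(r - h):(r + h), (c - h):(c + h)] - 2 * background, 0)
    keep[i] <- sum(qi) > 0
    rois[[i]] <- list(origin = c(row = r - h, col = c - h), qi = qi, nb = background)
  }
  rois[keep]
}

#' Localize one ROI by intensity-weighted moments
#'
#' Computes the photon sum Q, the centre of gravity, the signal standard
#' deviations and the localization precisions from the background-subtracted
#' ROI intensities (see [localizer] for the formulas and the pixel-centre
#' coordinate convention).
#'
#' @param roi an ROI as returned by [detect_spots()].
#' @param pixel_size_nm physical pixel pitch in nm.
#' @return one-row tibble with `x_nm`, `y_nm`, `photons`, `sigma_x_nm`,
#'   `sigma_y_nm`, `precision_x_nm`, `precision_y_nm`, `background`.
#' @export
localize_roi <- function(roi, pixel_size_nm) {
  cl_assert(is_scalar_num(pixel_size_nm) && pixel_size_nm > 0,
            "pixel_size_nm must be > 0")
  qi <- roi$qi
  Q <- sum(qi)
  cl_assert(Q > 0, "ROI has zero total intensity")
  nr <- nrow(qi); nc <- ncol(qi)
  nb <- roi$nb %||% 0
  # pixel-centre coordinates in global pixel units
  xs <- (roi$origin[["col"]] - 1L) + (seq_len(nc) - 0.5)
  ys <- (roi$origin[["row"]] - 1L) + (seq_len(nr) - 0.5)
  wx <- colSums(qi); wy <- rowSums(qi)
  mux <- sum(wx * xs) / Q
  muy <- sum(wy * ys) / Q
  vx <- sum(wx * (xs - mux)^2) / Q
  vy <- sum(wy * (ys - muy)^2) / Q
  # precision: pixelation term + photon/background term, per axis; the sum
  # runs over all ROI pixels with q_i + N_B weights
  dx2 <- matrix((xs - mux)^2, nr, nc, byrow = TRUE)
  dy2 <- matrix((ys - muy)^2, nr, nc, byrow = FALSE)
  px <- sqrt(1 / (12 * Q) + sum(dx2 / Q^2 * (qi + nb)))
  py <- sqrt(1 / (12 * Q) + sum(dy2 / Q^2 * (qi + nb)))
  tibble::tibble(
    x_nm = mux * pixel_size_nm, y_nm = muy * pixel_size_nm,
    photons = Q,
    sigma_x_nm = sqrt(vx) * pixel_size_nm, sigma_y_nm = sqrt(vy) * pixel_size_nm,
    precision_x_nm = px * pixel_size_nm, precision_y_nm = py * pixel_size_nm,
    background = nb
  )
}

#' Localize a whole image stack
#'
#' Runs background estimation, spot detection and moment localization on
#' every frame of a stack and concatenates the results into a localization
#' table. Deterministic for fixed input.
#'
#' @param stack list of numeric matrices (frames), all of the same size.
#' @param channel channel label recorded in every row.
#' @param pixel_size_nm pixel pitch in nm.
#' @param roi_side odd ROI side length in pixels (default 7).
#' @param threshold_factor peak threshold as multiple of background
#'   (default 4).
#' @return localization-table tibble (see [localization_set()]).
#' @export
localize_stack <- function(stack, channel, pixel_size_nm,
                           roi_side = 7L, threshold_factor = 4) {
  cl_assert(is.list(stack) && length(stack) > 0, "stack must be a non-empty list of frames")
  dims <- vapply(stack, dim, integer(2))
  cl_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "all frames must share the same dimensions")
  rows <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    frame <- stack[[f]]
    bg <- estimate_background(frame)
    rois <- detect_spots(frame, bg, roi_side = roi_side,
                         threshold_factor = threshold_factor)
    if (length(rois) == 0L) next
    locs <- do.call(rbind, lapply(rois, localize_roi, pixel_size_nm = pixel_size_nm))
    locs$frame <- f
    rows[[f]] <- locs
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(localization_set())
  }
  out <- do.call(rbind, rows)
  out$channel <- channel
  validate_localization_set(out[loc_columns])
}
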