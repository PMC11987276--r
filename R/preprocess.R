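#' Raw fundus image container
#'
#' Wraps an 8-bit RGB fundus photograph as an `H x W x 3` integer array plus an
#' identifier. Pixel coordinates are 0-based `(row, col)` throughout the
#' package; matrices are indexed `[row, col]`.
#'
#' @param pixels `H x W x 3` numeric array with intensities in `[0, 255]`.
#' @param image_id character identifier.
#' @param pixel_pitch optional pixel pitch (unitless; 1 by default — the
#'   pipeline works in pixel units end to end).
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, image_id = "img", pixel_pitch = 1) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    pq_stop("raw_image requires an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 128 || d[2] < 128)
    pq_stop("image must be at least 128 x 128 px")
  if (min(pixels) < 0 || max(pixels) > 255)
    pq_stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, image_id = image_id, pixel_pitch = pixel_pitch),
            class = "raw_image")
}

#' Read a fundus image from disk
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns a [raw_image] scaled to
#' `[0, 255]`. Grayscale files are replicated across the three channels.
#'
#' @param path file path.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [raw_image].
#' @export
read_fundus_image <- function(path, image_id = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  # EBImage stores (x, y, c); transpose to (row, col, c)
  px <- aperm(a, c(2, 1, 3)) * 255
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  raw_image(px, image_id = image_id)
}

new_working_image <- function(pixels, provenance = list()) {
  structure(pixels, provenance = provenance, class = c("working_image", "matrix"))
}

add_provenance <- function(img, step, params) {
  prov <- c(attr(img, "provenance"), list(list(step = step, params = params)))
  new_working_image(unclass_matrix(img), prov)
}

unclass_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "provenance") <- NULL
  m
}

#' Provenance of a working image
#' @param img a `working_image`.
#' @return List of applied steps with their parameters.
#' @export
provenance <- function(img) attr(img, "provenance")

#' Extract the working channel from a raw image
#'
#' The green channel carries the highest vessel/background contrast in fundus
#' photography and is the default working channel feeding contrast
#' enhancement.
#'
#' @param raw a [raw_image].
#' @param mode one of `"green"`, `"red"`, `"blue"`, `"luminance"`.
#' @return A `working_image`: an `H x W` matrix in `[0, 1]` carrying a
#'   provenance attribute.
#' @export
to_working_channel <- function(raw, mode = c("green", "red", "blue", "luminance")) {
  mode <- match.arg(mode)
  if (!inherits(raw, "raw_image")) pq_stop("expected a raw_image")
  px <- raw$pixels
  m <- switch(mode,
    red = px[, , 1], green = px[, , 2], blue = px[, , 3],
    luminance = 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  new_working_image(m / 255,
                    list(list(step = "to_working_channel",
                              params = list(mode = mode, image_id = raw$image_id))))
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Tile-wise histogram equalisation with a normalised clip limit, the standard
#' first step for enhancing vessel/background contrast in fundus images.
#' Constant images are returned unchanged (there is no contrast to
#' redistribute) with a warning.
#'
#' @param img `working_image` (or plain matrix) in `[0, 1]`.
#' @param clip_limit normalised clip limit in `(0, 1]`; fraction of a tile's
#'   pixels a single histogram bin may hold before clipping.
#' @param tile_grid integer `(rows, cols)` tile layout.
#' @param bins number of histogram bins.
#' @return A `working_image` in `[0, 1]`.
#' @export
clahe_enhance <- function(img, clip_limit = 0.01, tile_grid = c(8, 8), bins = 256) {
  stopifnot(clip_limit > 0, all(tile_grid >= 1))
  m <- unclass_matrix(img)
  if (min(m) < 0 || max(m) > 1) pq_stop("working image must lie in [0, 1]")
  if (diff(range(m)) < .Machine$double.eps) {
    pq_warn("constant image: CLAHE skipped")
    return(add_provenance(img, "clahe_enhance",
                          list(clip_limit = clip_limit, tile_grid = tile_grid,
                               skipped = TRUE)))
  }
  # EBImage works in (x, y); its `limit` is a multiple of the uniform bin
  # count, so a normalised clip limit maps to limit = clip_limit * bins.
  e <- EBImage::clahe(EBImage::Image(t(m)), nx = tile_grid[2], ny = tile_grid[1],
                      bins = bins, limit = clip_limit * bins)
  out <- t(EBImage::imageData(e))
  out <- pmin(pmax(out, 0), 1)
  img <- new_working_image(out, attr(img, "provenance"))
  add_provenance(img, "clahe_enhance",
                 list(clip_limit = clip_limit, tile_grid = tile_grid, bins = bins))
}

# Large-scale background estimate: area-average (block-mean) downsampling to
# the background scale followed by bilinear upsampling. Retains only
# structure larger than ~background_scale * min(H, W); vessels average out.
estimate_background <- function(m, background_scale) {
  h <- nrow(m); w <- ncol(m)
  b <- max(1, round(background_scale * min(h, w) / 4))
  hc <- ceiling(h / b); wc <- ceiling(w / b)
  # replicate-pad to a multiple of the block size, then block means
  ri <- pmin(rep(seq_len(hc), each = b), hc * b)
  pad <- m[pmin(seq_len(hc * b), h), pmin(seq_len(wc * b), w)]
  g1 <- rowsum(pad, rep(seq_len(hc), each = b)) / b
  small <- t(rowsum(t(g1), rep(seq_len(wc), each = b))) / b
  # bilinear upsample with block centers anchored at (i - 0.5) * b
  rc_centers <- (seq_len(hc) - 0.5) * b
  cc_centers <- (seq_len(wc) - 0.5) * b
  interp_axis <- function(mat, centers, n_out) {
    xout <- seq_len(n_out) - 0.5
    apply(mat, 2, function(v) {
      n <- length(v)
      if (n == 1) return(rep(v, n_out))
      y <- approx(centers, v, xout = xout, rule = 2)$y
      # linear extrapolation beyond the outermost block centers
      lo <- xout < centers[1]; hi <- xout > centers[n]
      y[lo] <- v[1] + (v[2] - v[1]) / (centers[2] - centers[1]) *
        (xout[lo] - centers[1])
      y[hi] <- v[n] + (v[n] - v[n - 1]) / (centers[n] - centers[n - 1]) *
        (xout[hi] - centers[n])
      y
    })
  }
  g2 <- interp_axis(small, rc_centers, h)          # h x wc
  t(interp_axis(t(g2), cc_centers, w))             # h x w
}

#' Correct uneven illumination
#'
#' Divides the image by a large-scale smoothed background estimate and
#' renormalises to `[0, 1]`, flattening the slowly varying illumination field
#' (vignetting) typical of contact wide-field fundus cameras while preserving
#' vessel/background contrast.
#'
#' @param img `working_image` in `[0, 1]`.
#' @param background_scale smoothing scale as a fraction of `min(H, W)`,
#'   in `(0, 1]`.
#' @param eps floor applied to the background estimate before division.
#' @return A `working_image` in `[0, 1]`.
#' @export
correct_illumination <- function(img, background_scale = 0.25, eps = 1e-3) {
  stopifnot(background_scale > 0, background_scale <= 1)
  m <- unclass_matrix(img)
  bg <- estimate_background(m, background_scale)
  if (any(bg < eps)) {
    pq_warn("background estimate below eps; clamped")
    bg <- pmax(bg, eps)
  }
  out <- m / bg
  # rescale so the mean intensity is preserved (stable under re-application,
  # unlike max-normalisation which keys on a single extreme pixel)
  if (mean(out) > 0) out <- out * (mean(m) / mean(out))
  out <- pmin(pmax(out, 0), 1)
  img <- new_working_image(out, attr(img, "provenance"))
  add_provenance(img, "correct_illumination",
                 list(background_scale = background_scale, eps = eps))
}

#' Full preprocessing chain
#'
#' Channel extraction, CLAHE, then illumination correction.
#'
#' @param raw a [raw_image].
#' @param mode working channel passed to [to_working_channel()].
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param background_scale illumination-correction scale.
#' @return A `working_image`.
#' @export
preprocess_image <- function(raw, mode = "green", clip_limit = 0.01,
                             tile_grid = c(8, 8), background_scale = 0.25) {
  img <- to_working_channel(raw, mode = mode)
  img <- clahe_enhance(img, clip_limit = clip_limit, tile_grid = tile_grid)
  correct_illumination(img, background_scale = background_scale)
}

#' Write a working image (and its provenance) to disk
#'
#' @param img `working_image`.
#' @param path output PNG path; a `.json` provenance sidecar is written next
#'   to it.
#' @return Invisibly, the PNG path.
#' @export
write_working_image <- function(img, path) {
  m <- unclass_matrix(img)
  EBImage::writeImage(EBImage::Image(t(m)), path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(provenance(img), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
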