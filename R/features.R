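#' Optic-disc annotation
#'
#' @param center numeric `(row, col)` disc center (0-based pixel coords).
#' @param diameter_px disc diameter in pixels.
#' @return `disc_annotation` object.
#' @export
disc_annotation <- function(center, diameter_px) {
  stopifnot(length(center) == 2, diameter_px > 0)
  structure(list(center = as.numeric(center), diameter_px = diameter_px),
            class = "disc_annotation")
}

#' Read disc annotations from CSV
#'
#' Expects columns `image_id, center_row, center_col, diameter_px`.
#'
#' @param path CSV path.
#' @return Named list of [disc_annotation()] keyed by `image_id`.
#' @export
read_disc_annotations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "center_row", "center_col", "diameter_px")
  if (!all(need %in% names(d))) pq_stop("disc CSV must have columns: ",
                                        paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    disc_annotation(c(d$center_row[i], d$center_col[i]), d$diameter_px[i]))
  names(out) <- d$image_id
  out
}

#' The 3DD measurement region
#'
#' The annulus extending three disc diameters away from the optic-disc
#' border: pixels at distance `d` from the disc center with
#' `r_d < d <= r_d + 3 * D` (`r_d = D/2`), clipped to the image. The strict
#' inner inequality excludes the disc border itself. Set
#' `as_disk_from_center = TRUE` for the alternative reading (a disk of radius
#' `3 D` about the center, disc interior still excluded).
#'
#' @param disc a [disc_annotation()].
#' @param image_shape integer `(H, W)`.
#' @param as_disk_from_center use the center-anchored alternative.
#' @return `region_mask` object: list with logical `mask` and `kind`.
#' @export
region_3dd <- function(disc, image_shape, as_disk_from_center = FALSE) {
  H <- image_shape[1]; W <- image_shape[2]
  r_d <- disc$diameter_px / 2
  # pixel centers at 0-based integer coordinates
  dist <- sqrt((matrix(0:(H - 1), H, W) - disc$center[1])^2 +
               (matrix(rep(0:(W - 1), each = H), H, W) - disc$center[2])^2)
  outer_r <- if (as_disk_from_center) 3 * disc$diameter_px
             else r_d + 3 * disc$diameter_px
  mask <- dist > r_d & dist <= outer_r
  if (!any(mask)) pq_stop("3DD region lies entirely outside the image")
  structure(list(mask = mask, kind = "three_dd"), class = "region_mask")
}

#' The vascularized region of the retina
#'
#' The retinal area reached by vessels — the zone bounded (in an infant
#' fundus) by the vascular/avascular ridge. The default takes the filled
#' convex hull of the vessel mask, which matches the star-shaped territory a
#' radial vessel tree spans regardless of how sparse the tree is;
#' `method = "closing"` instead applies a morphological closing (plus hole
#' filling) with a disc element of `closing_scale * min(H, W)` px, which
#' tracks concave territory boundaries but under-covers sparse trees.
#'
#' @param mask binary vessel mask.
#' @param method `"hull"` (default) or `"closing"`.
#' @param closing_scale kernel diameter as a fraction of `min(H, W)` for the
#'   closing method.
#' @return `region_mask` object with `kind = "whole_vascularized"`; always a
#'   superset of the vessel mask.
#' @export
vascularized_region <- function(mask, method = c("hull", "closing"),
                                closing_scale = 0.05) {
  method <- match.arg(method)
  m <- as_binary_matrix(mask)
  if (!any(m)) pq_stop("empty vessel mask")
  if (method == "closing") {
    k <- max(3, 2 * floor(closing_scale * min(dim(m)) / 2) + 1)
    brush <- EBImage::makeBrush(k, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(m)), brush)
    closed <- EBImage::fillHull(closed)
    reg <- t(EBImage::imageData(closed)) > 0 | m > 0
  } else {
    rc <- arrayInd(which(m > 0), dim(m))
    h <- grDevices::chull(rc[, 2], rc[, 1])
    reg <- fill_polygon(rc[h, 1], rc[h, 2], nrow(m), ncol(m)) | m > 0
  }
  structure(list(mask = reg, kind = "whole_vascularized"),
            class = "region_mask")
}

# even-odd scanline fill of a polygon given 1-based vertex (row, col) coords
fill_polygon <- function(vr, vc, H, W) {
  out <- matrix(FALSE, H, W)
  n <- length(vr)
  jj <- c(2:n, 1)
  for (r in seq_len(H)) {
    y1 <- vr; y2 <- vr[jj]
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    t <- (r - y1[cross]) / (y2[cross] - y1[cross])
    xs <- sort(vc[cross] + t * (vc[jj][cross] - vc[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1, ceiling(xs[k])); c2 <- min(W, floor(xs[k + 1]))
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

#' Vessel density within a region
#'
#' Ratio of vessel pixels to the remaining (non-vessel) pixels of the region:
#' `density = N_vessel / (N_region - N_vessel)`; vessels are intersected with
#' the region first.
#'
#' @param vessels binary vessel mask.
#' @param region a `region_mask` or logical matrix.
#' @return Non-negative density.
#' @export
vessel_density <- function(vessels, region) {
  v <- as_binary_matrix(vessels) > 0
  r <- if (inherits(region, "region_mask")) region$mask else region > 0
  stopifnot(all(dim(v) == dim(r)))
  nv <- sum(v & r)
  nr <- sum(r)
  if (nr == nv) pq_stop("region entirely covered by vessels; density undefined")
  nv / (nr - nv)
}

#' Mean of the top percent of curvature magnitudes
#'
#' Mean of the `ceil(percent/100 * N)` largest values of the pooled
#' point-based |curvature| values.
#'
#' @param kappas pooled curvature magnitudes (absolute values are taken).
#' @param percent percentage in (0, 100].
#' @return The trimmed-top mean.
#' @export
top_percent_curvature <- function(kappas, percent = 1) {
  stopifnot(percent > 0, percent <= 100)
  k <- abs(as.numeric(kappas))
  if (!length(k)) pq_stop("empty curvature pool")
  n_top <- ceiling(percent / 100 * length(k))
  mean(sort(k, decreasing = TRUE)[seq_len(n_top)])
}

point_in_region <- function(points, region_mask) {
  ri <- pmin(pmax(round(points[, 1]) + 1, 1), nrow(region_mask))
  ci <- pmin(pmax(round(points[, 2]) + 1, 1), ncol(region_mask))
  region_mask[cbind(ri, ci)]
}

region_stats <- function(graph, mask, region_mask) {
  diam <- numeric(0); kap <- numeric(0)
  taus <- numeric(0); tau_w <- numeric(0)
  for (s in graph$segments) {
    inr <- point_in_region(s$points, region_mask)
    reliable <- isTRUE(s$curvature_reliable)
    if (any(inr)) {
      diam <- c(diam, 2 * s$radius[inr])
      if (reliable) kap <- c(kap, abs(s$kappa[inr]))
    }
    mid <- s$points[ceiling(nrow(s$points) / 2), , drop = FALSE]
    if (reliable && !is.na(s$tau) && point_in_region(mid, region_mask)) {
      taus <- c(taus, s$tau)
      tau_w <- c(tau_w, s$length)
    }
  }
  dens <- vessel_density(mask, region_mask)
  list(max_diameter = if (length(diam)) max(diam) else NA_real_,
       mean_diameter = if (length(diam)) mean(diam) else NA_real_,
       # length-weighted: long segments carry the tortuosity information
       mean_sdc_tortuosity = if (length(taus))
         sum(taus * tau_w) / sum(tau_w) else NA_real_,
       top1pct_curvature = if (length(kap)) top_percent_curvature(kap, 1)
                           else NA_real_,
       vessel_density = dens)
}

#' Compute the 10-feature morphometric vector
#'
#' Five measures (max diameter, mean diameter, mean SDC tortuosity, mean of
#' the top 1% |curvature| values, vessel density) over two regions (the 3DD
#' annulus and the whole vascularized region) give the 10-feature grid. The
#' four regression features are aliased on top of it: `F1` = max diameter in
#' 3DD, `F2` = mean segment SDC tortuosity in 3DD, `F3` = density of the
#' whole vascularized region, `F4` = top-1% |curvature| over the whole image.
#' Per-point statistics use per-point region membership; tortuosity assigns a
#' segment to a region by its midpoint.
#'
#' @param graph `vessel_graph` from [analyze_vessels()].
#' @param mask the binary vessel mask the graph came from.
#' @param disc a [disc_annotation()].
#' @param image_shape integer `(H, W)`.
#' @param strict error (rather than NA) when no segment falls inside the 3DD
#'   region.
#' @return Named numeric vector of length 14 (10 grid features + F1..F4).
#' @export
compute_feature_vector <- function(graph, mask, disc, image_shape,
                                   strict = FALSE) {
  if (!length(graph$segments)) pq_stop("empty vessel graph")
  m <- as_binary_matrix(mask)
  r3 <- region_3dd(disc, image_shape)
  rw <- vascularized_region(m)
  s3 <- region_stats(graph, m, r3$mask)
  sw <- region_stats(graph, m, rw$mask)
  if (strict && any(is.na(unlist(s3))))
    pq_stop("no vessel segments inside the 3DD region")
  f <- c(max_diameter_3dd = s3$max_diameter,
         mean_diameter_3dd = s3$mean_diameter,
         mean_sdc_tortuosity_3dd = s3$mean_sdc_tortuosity,
         top1pct_curvature_3dd = s3$top1pct_curvature,
         vessel_density_3dd = s3$vessel_density,
         max_diameter_whole = sw$max_diameter,
         mean_diameter_whole = sw$mean_diameter,
         mean_sdc_tortuosity_whole = sw$mean_sdc_tortuosity,
         top1pct_curvature_whole = sw$top1pct_curvature,
         vessel_density_whole = sw$vessel_density)
  c(f, F1 = unname(f["max_diameter_3dd"]),
       F2 = unname(f["mean_sdc_tortuosity_3dd"]),
       F3 = unname(f["vessel_density_whole"]),
       F4 = unname(f["top1pct_curvature_whole"]))
}
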