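#' Synthetic fundus phantom specification
#'
#' Parameters of the seeded vascular phantom: sine-perturbed vessels radiating
#' from the optic-disc border, rendered with a decaying width profile onto a
#' vignetted, noisy background. The defaults describe a mildly tortuous
#' posterior fundus at desk scale (640 x 640 px, disc diameter 64 px — the
#' disc-to-image proportion of wide-field posterior imaging).
#'
#' @param image_shape integer `(H, W)`.
#' @param disc a [disc_annotation()]; defaults to an image-centred disc of
#'   diameter 1/10 of the image height.
#' @param n_main_vessels number of primary vessels leaving the disc.
#' @param branch_prob probability that a main vessel spawns a side branch.
#' @param sine_amplitude_px amplitude of the sinusoidal tortuosity (px).
#' @param sine_wavelength_px wavelength of the sinusoidal tortuosity (px).
#' @param base_width_px vessel diameter at the disc border (px).
#' @param width_decay exponential width decay rate per px of arc length.
#' @param vessel_contrast vessel darkening relative to background, in `(0, 1)`.
#' @param vignette_strength strength of the radial illumination falloff.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units).
#' @param theta latent Plus-severity in `[1, 5]` recorded with the truth.
#' @param seed integer seed; the phantom is a deterministic function of spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(640, 640), disc = NULL,
                         n_main_vessels = 6, branch_prob = 0.25,
                         sine_amplitude_px = 1.5, sine_wavelength_px = 80,
                         base_width_px = 4, width_decay = 0.001,
                         vessel_contrast = 0.55, vignette_strength = 0.35,
                         noise_sd = 0.02, theta = 1, seed = 1) {
  if (is.null(disc))
    disc <- disc_annotation(center = image_shape / 2,
                            diameter_px = image_shape[1] / 10)
  stopifnot(sine_amplitude_px >= 0, base_width_px >= 2,
            vessel_contrast > 0, vessel_contrast < 1)
  structure(list(image_shape = image_shape, disc = disc,
                 n_main_vessels = n_main_vessels, branch_prob = branch_prob,
                 sine_amplitude_px = sine_amplitude_px,
                 sine_wavelength_px = sine_wavelength_px,
                 base_width_px = base_width_px, width_decay = width_decay,
                 vessel_contrast = vessel_contrast,
                 vignette_strength = vignette_strength,
                 noise_sd = noise_sd, theta = theta, seed = seed),
            class = "phantom_spec")
}

#' Map a latent severity to phantom parameters
#'
#' Encodes the premise that Plus severity manifests jointly as vascular
#' dilation, tortuosity and density: amplitude, width, vessel count and
#' branching probability all scale affinely with `theta`, anchored at the base
#' spec for `theta = 1`. Coefficients (per unit of severity): amplitude
#' +1.5 px, width +0.8 px, +0.75 main vessels, branch probability +0.15.
#'
#' @param theta latent severity in `[1, 5]`.
#' @param base a [phantom_spec()] describing the `theta = 1` anchor.
#' @return A `phantom_spec` with severity-scaled parameters and `theta` set.
#' @export
severity_to_spec <- function(theta, base = phantom_spec()) {
  stopifnot(theta >= 1, theta <= 5)
  s <- base
  d <- theta - 1
  s$sine_amplitude_px <- base$sine_amplitude_px + 1.5 * d
  s$base_width_px <- base$base_width_px + 0.8 * d
  s$n_main_vessels <- base$n_main_vessels + round(0.75 * d)
  s$branch_prob <- min(0.9, base$branch_prob + 0.15 * d)
  s$theta <- theta
  s
}

# Sample one sine-perturbed radial curve. Returns dense samples (row, col,
# halfwidth) plus analytic-by-quadrature curvature/tortuosity truth.
phantom_curve <- function(center, r_disc, angle, length_px, amplitude,
                          wavelength, phase, width0, width_decay, ds = 0.25) {
  s <- seq(0, length_px, by = ds)
  u <- c(cos(angle), sin(angle))   # radial direction (row, col)
  nrm <- c(-sin(angle), cos(angle))
  off <- amplitude * sin(2 * pi * s / wavelength + phase)
  row <- center[1] + (r_disc + s) * u[1] + off * nrm[1]
  col <- center[2] + (r_disc + s) * u[2] + off * nrm[2]
  hw <- pmax(0.75, width0 * exp(-width_decay * s) / 2)
  truth <- curve_quadrature_truth(row, col)
  list(row = row, col = col, halfwidth = hw, s = s,
       kappa = truth$kappa, arc = truth$arc, tau = truth$tau,
       length = truth$L, width = 2 * hw)
}

# Curvature and squared-derivative-curvature tortuosity of a densely sampled
# curve by direct quadrature (independent of the morphometry estimators).
curve_quadrature_truth <- function(row, col) {
  n <- length(row)
  dx <- gradient_central(row)
  dy <- gradient_central(col)
  ddx <- gradient_central(dx)
  ddy <- gradient_central(dy)
  speed2 <- dx^2 + dy^2
  kappa <- (dx * ddy - dy * ddx) / pmax(speed2^1.5, .Machine$double.eps)
  seg <- sqrt(diff(row)^2 + diff(col)^2)
  arc <- c(0, cumsum(seg))
  L <- arc[n]
  dk <- diff(kappa) / pmax(seg, .Machine$double.eps)
  tau <- sum(dk^2 * seg) / L
  list(kappa = kappa, arc = arc, tau = tau, L = L)
}

gradient_central <- function(x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

#' Generate a synthetic fundus phantom
#'
#' Renders the vessel tree described by a [phantom_spec()] into an RGB image
#' (vessels darkest in the green channel, as in real fundus photographs, with
#' radial vignetting, a bright disc and Gaussian noise) together with the
#' ground truth: exact rendered vessel mask, the generating curves with
#' quadrature curvature/tortuosity, per-curve width profiles, the vascularised
#' stencil, pixel-counted vessel density and the latent severity.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `image` ([raw_image]) and `truth` (list with
#'   `mask`, `curves`, `stencil`, `true_density`, `theta`, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(derive_seed(spec$seed, "phantom"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  ctr <- spec$disc$center
  r_d <- spec$disc$diameter_px / 2
  n <- spec$n_main_vessels
  curves <- list()
  for (i in seq_len(n)) {
    ang <- 2 * pi * (i - 1) / n + runif(1, -0.25, 0.25)
    reach <- border_reach(ctr, ang, H, W) - r_d
    if (reach < 40) next
    len <- 0.9 * reach
    phase <- runif(1, 0, 2 * pi)
    cv <- phantom_curve(ctr, r_d, ang, len, spec$sine_amplitude_px,
                        spec$sine_wavelength_px, phase, spec$base_width_px,
                        spec$width_decay)
    cv$parent <- NA_integer_
    curves[[length(curves) + 1]] <- cv
    if (runif(1) < spec$branch_prob) {
      sb <- runif(1, 0.3, 0.6) * len
      bang <- ang + sample(c(-1, 1), 1) * runif(1, pi / 9, 2 * pi / 9)
      broot <- c(ctr[1] + (r_d + sb) * cos(ang), ctr[2] + (r_d + sb) * sin(ang))
      breach <- border_reach(broot, bang, H, W)
      blen <- min(0.6 * (len - sb), 0.9 * breach)
      if (blen > 40) {
        w_at <- spec$base_width_px * exp(-spec$width_decay * sb) * 0.7
        bcv <- phantom_curve(broot, 0, bang, blen, spec$sine_amplitude_px,
                             spec$sine_wavelength_px, runif(1, 0, 2 * pi),
                             w_at, spec$width_decay)
        bcv$parent <- length(curves)
        curves[[length(curves) + 1]] <- bcv
      }
    }
  }
  if (!length(curves)) pq_stop("no vessel fits inside the image; enlarge it")
  row <- unlist(lapply(curves, `[[`, "row"))
  col <- unlist(lapply(curves, `[[`, "col"))
  hw <- unlist(lapply(curves, `[[`, "halfwidth"))
  cid <- unlist(mapply(function(cv, i) rep(i, length(cv$row)), curves,
                       seq_along(curves), SIMPLIFY = FALSE))
  alpha <- render_tubes_cpp(H, W, row, col, hw, as.integer(cid))
  alpha <- pmin(pmax(alpha, 0), 1)
  mask <- alpha >= 0.5
  # vascularised stencil: disc of the radius actually reached by the tree
  rr <- matrix(seq_len(H) - ctr[1], H, W)
  cc <- matrix(rep(seq_len(W) - ctr[2], each = H), H, W)
  dist_ctr <- sqrt(rr^2 + cc^2)
  reach_r <- max(sqrt((row - ctr[1])^2 + (col - ctr[2])^2)) + 2 * spec$base_width_px
  stencil <- dist_ctr <= reach_r
  nv <- sum(mask & stencil)
  true_density <- nv / (sum(stencil) - nv)
  # image: vignetted background, bright disc, dark vessels, noise
  icent <- c((H + 1) / 2, (W + 1) / 2)
  dmax <- sqrt(sum((spec$image_shape / 2)^2))
  dimg <- sqrt((matrix(seq_len(H), H, W) - icent[1])^2 +
               (matrix(rep(seq_len(W), each = H), H, W) - icent[2])^2)
  vig <- 1 - spec$vignette_strength * (dimg / dmax)^2
  disc_px <- dist_ctr <= r_d
  bg <- 0.70 * vig + 0.18 * disc_px * vig
  g <- bg * (1 - spec$vessel_contrast * alpha)
  r <- pmin(1, 1.12 * bg) * (1 - 0.35 * spec$vessel_contrast * alpha)
  b <- 0.25 * bg * (1 - 0.5 * spec$vessel_contrast * alpha)
  nz <- matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- pmin(pmax(r + nz, 0), 1)
  px[, , 2] <- pmin(pmax(g + nz, 0), 1)
  px[, , 3] <- pmin(pmax(b + nz, 0), 1)
  px <- round(px * 255)
  id <- sprintf("phantom_s%d", spec$seed)
  list(image = raw_image(px, image_id = id),
       truth = list(mask = mask, curves = curves, stencil = stencil,
                    true_density = true_density, theta = spec$theta,
                    spec = spec))
}

# Distance from a point to the image border along a direction (row/col angles).
border_reach <- function(p, ang, H, W) {
  u <- c(cos(ang), sin(ang))
  lim <- Inf
  if (abs(u[1]) > 1e-12)
    lim <- min(lim, max((H - 4 - p[1]) / u[1], (4 - p[1]) / u[1]))
  if (abs(u[2]) > 1e-12)
    lim <- min(lim, max((W - 4 - p[2]) / u[2], (4 - p[2]) / u[2]))
  max(0, lim)
}

#' Simulated expert panel
#'
#' Each expert grades a latent severity through four personal ordinal
#' cut-points (jittered around the canonical 1.5/2.5/3.5/4.5) after adding
#' Gaussian perception noise — the mechanism behind inter-expert variability
#' in categorical Plus grading. Defaults (4 experts, cut-point jitter sd 0.25,
#' noise sd 0.3) give moderate pairwise agreement.
#'
#' @param n_experts number of graders.
#' @param cutpoint_jitter_sd sd of the per-expert cut-point offsets.
#' @param noise_sd per-expert perception noise sd (one value recycled, or one
#'   per expert).
#' @param seed integer seed.
#' @return An object of class `simulated_panel` with per-expert `cut_points`
#'   (4 ascending values in `(1, 5)`) and `noise_sd`.
#' @export
simulated_panel <- function(n_experts = 4, cutpoint_jitter_sd = 0.25,
                            noise_sd = 0.3, seed = 1) {
  set.seed(derive_seed(seed, "panel"))
  noise_sd <- rep_len(noise_sd, n_experts)
  canonical <- c(1.5, 2.5, 3.5, 4.5)
  cps <- lapply(seq_len(n_experts), function(e) {
    cp <- sort(canonical + rnorm(4, 0, cutpoint_jitter_sd))
    cp <- pmin(pmax(cp, 1.05), 4.95)
    cp + cumsum(c(0, diff(cp) < 1e-6)) * 1e-3 # enforce strictly ascending
  })
  structure(list(n_experts = n_experts, cut_points = cps,
                 noise_sd = noise_sd, seed = seed),
            class = "simulated_panel")
}

#' Simulate a multi-expert grade table from latent severities
#'
#' Expert `e` grades image `i` as `1 + #\{cut-points below theta_i + noise\}`,
#' deterministic under the panel seed.
#'
#' @param theta latent severities in `[1, 5]`.
#' @param panel a [simulated_panel()].
#' @param image_ids optional identifiers (default `img_001`, ...).
#' @return A [grade_table()] data frame with one expert column per grader.
#' @export
simulate_grades <- function(theta, panel, image_ids = NULL) {
  stopifnot(inherits(panel, "simulated_panel"))
  set.seed(derive_seed(panel$seed, "grades"))
  n <- length(theta)
  if (is.null(image_ids)) image_ids <- sprintf("img_%03d", seq_len(n))
  g <- sapply(seq_len(panel$n_experts), function(e) {
    perceived <- theta + rnorm(n, 0, panel$noise_sd[e])
    vapply(perceived, function(t) 1L + sum(t > panel$cut_points[[e]]), integer(1))
  })
  g <- matrix(as.integer(g), nrow = n)
  colnames(g) <- sprintf("E%d", seq_len(panel$n_experts))
  grade_table(data.frame(image_id = image_ids, g,
                         check.names = FALSE, stringsAsFactors = FALSE))
}

#' Generate a full synthetic cohort
#'
#' Draws latent severities `theta_i ~ Uniform(1, 5)`, renders one phantom per
#' image, grades the cohort with a simulated panel, and (optionally) writes
#' the bundle to disk in the pipeline's input layout: `images/*.png`,
#' `masks/*.png`, `discs.csv`, `grades.csv`, `truth.json`.
#'
#' @param n number of images.
#' @param panel a [simulated_panel()].
#' @param base_spec the `theta = 1` anchor [phantom_spec()].
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return List with `images`, `truths`, `discs` (data frame), `grades`
#'   ([grade_table]) and `theta`.
#' @export
generate_cohort <- function(n, panel = simulated_panel(), base_spec = phantom_spec(),
                            seed = 1, dir = NULL) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, "cohort"))
  theta <- runif(n, 1, 5)
  ids <- sprintf("img_%03d", seq_len(n))
  images <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- severity_to_spec(theta[i], base_spec)
    sp$seed <- derive_seed(seed, paste0("img", i))
    ph <- generate_phantom(sp)
    ph$image$image_id <- ids[i]
    images[[i]] <- ph$image
    truths[[i]] <- ph$truth
  }
  discs <- data.frame(image_id = ids,
                      center_row = vapply(truths, function(t) t$spec$disc$center[1], 0),
                      center_col = vapply(truths, function(t) t$spec$disc$center[2], 0),
                      diameter_px = vapply(truths, function(t) t$spec$disc$diameter_px, 0))
  grades <- simulate_grades(theta, panel, image_ids = ids)
  out <- list(images = images, truths = truths, discs = discs,
              grades = grades, theta = theta)
  if (!is.null(dir)) write_cohort(out, dir)
  invisible(out)
}

write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$images)) {
    img <- cohort$images[[i]]
    EBImage::writeImage(EBImage::Image(aperm(img$pixels / 255, c(2, 1, 3)),
                                       colormode = "Color"),
                        file.path(dir, "images", paste0(img$image_id, ".png")))
    write_mask_png(cohort$truths[[i]]$mask,
                   file.path(dir, "masks", paste0(img$image_id, ".png")))
  }
  write.csv(cohort$discs, file.path(dir, "discs.csv"), row.names = FALSE)
  write.csv(as.data.frame(cohort$grades), file.path(dir, "grades.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(theta = cohort$theta,
         true_density = vapply(cohort$truths, `[[`, 0, "true_density"),
         image_id = cohort$discs$image_id),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Read a binary mask PNG
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  t(EBImage::imageData(EBImage::readImage(path))) >= 0.5
}
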