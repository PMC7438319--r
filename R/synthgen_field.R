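# Synthetic spinning-disk-style two-channel puncta fields with ground truth.

#' Specification of a synthetic two-channel puncta field
#'
#' Describes a 2D field of view emulating a spinning-disk confocal mosaic
#' tile containing fluorescent postsynaptic puncta in two channels (e.g.
#' PSD95 and SAP102). Puncta are placed as a hard-core Poisson process; a
#' stated fraction of the underlying entities is present in both channels
#' (colocalized). Each punctum is rendered as an anisotropic 2D Gaussian
#' spot whose 10%-of-peak isocontour encloses exactly its ground-truth
#' area, so downstream segmentation has an analytic target.
#'
#' @param field_width,field_height field size in micrometers. The defaults
#'   match a 43.008 um square tile.
#' @param pixel_size pixel pitch in nanometers (default 84).
#' @param density_ch1,density_ch2 puncta per 100 um^2 in each channel.
#'   Defaults are hippocampal CA1 all-layer magnitudes.
#' @param coloc_fraction fraction of entities present in both channels,
#'   in \[0, 1\].
#' @param punctum_area_mu,punctum_area_sigma log-normal parameters of the
#'   true punctum area on the nm^2 scale (area of the 10%-of-peak contour).
#' @param amplitude_range peak amplitude range (uniform draw), intensity
#'   units above background. The source imaging does not constrain spot
#'   intensity, so this is a free parameter.
#' @param background_level,noise_sd constant background level and additive
#'   Gaussian noise standard deviation, intensity units.
#' @param axis_ratio_range range of the spot major/minor axis ratio.
#' @param min_separation hard-core minimum distance between entity centers
#'   in micrometers. Keeps neighboring puncta resolvable, as physical
#'   synapses are, while leaving counts Poisson.
#' @param seed integer seed; generation is bit-reproducible.
#' @return an object of class `puncta_field_spec`.
#' @seealso [make_puncta_field()]
#' @export
puncta_field_spec <- function(field_width = 43.008, field_height = 43.008,
                              pixel_size = 84,
                              density_ch1 = 109.8458, density_ch2 = 105.1894,
                              coloc_fraction = 0.6404,
                              punctum_area_mu = 11.21,
                              punctum_area_sigma = 0.46,
                              amplitude_range = c(800, 4000),
                              background_level = 200, noise_sd = 60,
                              axis_ratio_range = c(1, 2),
                              min_separation = 0.25,
                              seed = 1L) {
  check_number(field_width, "field_width", 0, strict_lower = TRUE)
  check_number(field_height, "field_height", 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_number(density_ch1, "density_ch1", 0)
  check_number(density_ch2, "density_ch2", 0)
  check_number(coloc_fraction, "coloc_fraction", 0, 1)
  check_number(punctum_area_sigma, "punctum_area_sigma", 0)
  check_number(background_level, "background_level", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(min_separation, "min_separation", 0)
  if (length(amplitude_range) != 2L || any(amplitude_range <= 0) ||
      diff(amplitude_range) < 0)
    stopf("`amplitude_range` must be an increasing positive pair")
  if (length(axis_ratio_range) != 2L || any(axis_ratio_range < 1) ||
      diff(axis_ratio_range) < 0)
    stopf("`axis_ratio_range` must be an increasing pair with values >= 1")
  # the entity decomposition must admit the requested colocalization
  lam1 <- density_ch1 / 100; lam2 <- density_ch2 / 100
  lam_both <- coloc_fraction * (lam1 + lam2) / (1 + coloc_fraction)
  if (lam_both > min(lam1, lam2) + 1e-12)
    stopf("coloc_fraction %.3f is infeasible for channel densities %.2f / %.2f",
          coloc_fraction, density_ch1, density_ch2)
  structure(list(
    field_width = field_width, field_height = field_height,
    pixel_size = pixel_size,
    density_ch1 = density_ch1, density_ch2 = density_ch2,
    coloc_fraction = coloc_fraction,
    punctum_area_mu = punctum_area_mu,
    punctum_area_sigma = punctum_area_sigma,
    amplitude_range = as.numeric(amplitude_range),
    background_level = background_level, noise_sd = noise_sd,
    axis_ratio_range = as.numeric(axis_ratio_range),
    min_separation = min_separation,
    seed = check_seed(seed)
  ), class = "puncta_field_spec")
}

#' @export
print.puncta_field_spec <- function(x, ...) {
  cat(sprintf(
    "puncta_field_spec: %.3f x %.3f um @ %g nm/px, d1 = %.2f, d2 = %.2f, c = %.3f, seed %d\n",
    x$field_width, x$field_height, x$pixel_size,
    x$density_ch1, x$density_ch2, x$coloc_fraction, x$seed))
  invisible(x)
}

# contour scale: the 10%-of-peak isocontour of an isotropic Gaussian with
# sd sigma has area 2*pi*log(10)*sigma^2
SPOT_CONTOUR_CONST <- 2 * pi * log(10)

# hard-core uniform placement in [0, w] x [0, h]; returns n x 2 matrix.
# Counts are preserved (positions are resampled on conflict), so the
# marginal count law stays Poisson.
place_hardcore_2d <- function(n, w, h, min_sep, max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2L)
  if (n == 0L) return(pts)
  cell <- max(min_sep, 1e-9)
  nx <- max(1L, ceiling(w / cell)); ny <- max(1L, ceiling(h / cell))
  grid <- vector("list", nx * ny)
  key <- function(p) {
    ix <- min(nx - 1L, floor(p[1] / cell)); iy <- min(ny - 1L, floor(p[2] / cell))
    c(ix, iy)
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
      k <- key(p)
      ok <- TRUE
      for (ix in max(0L, k[1] - 1L):min(nx - 1L, k[1] + 1L)) {
        for (iy in max(0L, k[2] - 1L):min(ny - 1L, k[2] + 1L)) {
          for (q in grid[[ix + nx * iy + 1L]]) {
            if (sum((p - q)^2) < min_sep^2) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (!ok) break
      }
      if (ok) {
        pts[i, ] <- p
        idx <- k[1] + nx * k[2] + 1L
        grid[[idx]] <- c(grid[[idx]], list(p))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("could not place %d objects with min_separation %.3g (field too dense)", n, min_sep)
  }
  pts
}

#' Generate a synthetic two-channel puncta field
#'
#' Draws the per-channel entity counts from the Poisson law implied by the
#' requested densities, places entity centers with a hard-core constraint,
#' renders each punctum as an anisotropic Gaussian spot on a noisy
#' constant background, and returns the image together with a ground-truth
#' table. Entities flagged as colocalized produce a spot in both channels
#' at the same center (up to at most one pixel of jitter), with channel
#' specific area and amplitude.
#'
#' The per-channel spot counts are Poisson with mean `density x area`
#' because the generator decomposes the entity population into
#' channel-1-only, channel-2-only and both-channel Poisson components with
#' rates `lambda1 - lambda_b`, `lambda2 - lambda_b` and
#' `lambda_b = c (lambda1 + lambda2) / (1 + c)`.
#'
#' @param spec a [puncta_field_spec()].
#' @param render if `FALSE`, skip image rendering and return only the
#'   ground truth (fast path for count statistics).
#' @return a list with elements `image` (H x W x 2 numeric array of
#'   16-bit-ranged intensities, or `NULL` when `render = FALSE`), `truth`
#'   (one row per rendered spot: entity id, channel, subpixel center,
#'   true 10%-contour area in nm^2, spot shape parameters, colocalization
#'   flag), `spec`, and the field area in um^2.
#' @export
make_puncta_field <- function(spec, render = TRUE) {
  if (!inherits(spec, "puncta_field_spec"))
    stopf("`spec` must be a puncta_field_spec")
  with_seed(spec$seed, {
    area <- spec$field_width * spec$field_height
    lam1 <- spec$density_ch1 / 100 * area
    lam2 <- spec$density_ch2 / 100 * area
    f <- spec$coloc_fraction
    lam_b <- f * (lam1 + lam2) / (1 + f)
    n_b  <- stats::rpois(1, lam_b)
    n_1  <- stats::rpois(1, lam1 - lam_b)
    n_2  <- stats::rpois(1, lam2 - lam_b)
    n_ent <- n_b + n_1 + n_2

    px_um <- spec$pixel_size / 1000
    W <- max(1L, round(spec$field_width / px_um))
    H <- max(1L, round(spec$field_height / px_um))
    sep_px <- spec$min_separation / px_um
    centers <- place_hardcore_2d(n_ent, W, H, sep_px)  # pixel units, 0-based

    ent_channels <- c(rep(3L, n_b), rep(1L, n_1), rep(2L, n_2))  # 3 = both
    e1 <- which(ent_channels != 2L)  # entities with a channel-1 spot
    e2 <- which(ent_channels != 1L)  # entities with a channel-2 spot
    ent <- c(e1, e2)
    chan <- c(rep(1L, length(e1)), rep(2L, length(e2)))
    ns <- length(ent)
    x <- centers[ent, 1]; y <- centers[ent, 2]
    # colocalized channel-2 spots sit at the shared center with <= 1 px jitter
    jit <- chan == 2L & ent_channels[ent] == 3L
    if (any(jit)) {
      x[jit] <- pmin(pmax(x[jit] + stats::runif(sum(jit), -0.5, 0.5), 0), W)
      y[jit] <- pmin(pmax(y[jit] + stats::runif(sum(jit), -0.5, 0.5), 0), H)
    }
    a <- stats::rlnorm(ns, spec$punctum_area_mu, spec$punctum_area_sigma)
    truth <- data.frame(
      entity_id = ent, channel = chan, x = x, y = y,
      area_nm2 = a,
      sigma_px = sqrt(a / SPOT_CONTOUR_CONST) / spec$pixel_size,
      axis_ratio = stats::runif(ns, spec$axis_ratio_range[1],
                                spec$axis_ratio_range[2]),
      theta = stats::runif(ns, 0, pi),
      amplitude = stats::runif(ns, spec$amplitude_range[1],
                               spec$amplitude_range[2]),
      coloc = ent_channels[ent] == 3L)
    truth <- truth[order(truth$entity_id, truth$channel), , drop = FALSE]
    rownames(truth) <- NULL

    img <- NULL
    if (render) {
      img <- array(0, dim = c(H, W, 2L))
      m1 <- matrix(0, H, W); m2 <- matrix(0, H, W)
      tch <- truth$channel; tx <- truth$x; ty <- truth$y
      tsig <- truth$sigma_px; trat <- truth$axis_ratio
      tth <- truth$theta; tam <- truth$amplitude
      for (r in seq_len(nrow(truth))) {
        p <- spot_patch(H, W, tx[r], ty[r], tsig[r], trat[r], tth[r], tam[r])
        if (is.null(p)) next
        if (tch[r] == 1L)
          m1[p$i0:p$i1, p$j0:p$j1] <- m1[p$i0:p$i1, p$j0:p$j1] + p$vals
        else
          m2[p$i0:p$i1, p$j0:p$j1] <- m2[p$i0:p$i1, p$j0:p$j1] + p$vals
      }
      for (ch in 1:2) {
        noisy <- (if (ch == 1L) m1 else m2) + spec$background_level +
          stats::rnorm(H * W, 0, spec$noise_sd)
        img[, , ch] <- round(pmin(pmax(noisy, 0), 65535))
      }
    }
    list(image = img, truth = truth, spec = spec, field_area = area)
  })
}

# evaluate one anisotropic Gaussian spot over its local window.
# Coordinates: pixel (i, j) has center (x = j - 0.5, y = i - 0.5).
spot_patch <- function(H, W, x, y, sigma, ratio, theta, amplitude) {
  sig_a <- sigma * sqrt(ratio)
  sig_b <- sigma / sqrt(ratio)
  rad <- ceiling(3.5 * sig_a) + 1L
  j0 <- max(1L, floor(x + 0.5) - rad); j1 <- min(W, floor(x + 0.5) + rad)
  i0 <- max(1L, floor(y + 0.5) - rad); i1 <- min(H, floor(y + 0.5) + rad)
  if (j0 > j1 || i0 > i1) return(NULL)
  xs <- (j0:j1) - 0.5 - x
  ys <- (i0:i1) - 0.5 - y
  ct <- cos(theta); st <- sin(theta)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  u <- (ct * X + st * Y) / sig_a
  v <- (-st * X + ct * Y) / sig_b
  list(i0 = i0, i1 = i1, j0 = j0, j1 = j1,
       vals = amplitude * exp(-0.5 * (u^2 + v^2)))
}
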