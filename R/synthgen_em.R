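# Synthetic FIB-SEM-like labeled volumes: synapses as paired curved plates
# (presynaptic density + PSD separated by a narrow cleft), with log-normal
# synaptic apposition surface (SAS) areas and anisotropic voxels.

#' Specification of a synthetic labeled EM volume
#'
#' Describes a 3D volume emulating a FIB-SEM stack in which every synapse
#' has been segmented into a presynaptic component and a postsynaptic
#' density (PSD). Synapses are modelled as paired spherical-cap plates
#' separated by a narrow cleft; the cap midsurface is the synaptic
#' apposition surface (SAS), whose area is drawn log-normally per synapse
#' type. Asymmetric (AS, excitatory) and symmetric (SS, inhibitory)
#' synapses differ by PSD plate thickness, mirroring the prominent-vs-thin
#' PSD that distinguishes them in electron micrographs.
#'
#' @param width,height,depth volume dimensions in micrometers. Defaults
#'   give a 10.24 x 7.68 um field and a depth equivalent to the mean
#'   section count of a FIB-SEM series (276.33 sections of 20 nm).
#' @param voxel voxel pitch in nanometers, `c(x, y, z)`; default
#'   `c(5, 5, 20)` (anisotropic: fine in-plane, coarse across sections).
#' @param as_density,ss_density synapses per um^3 for asymmetric and
#'   symmetric synapses. Defaults are hippocampal CA1 all-layer
#'   magnitudes with a 95.6% AS mixture.
#' @param sas_mu_as,sas_sigma_as,sas_mu_ss,sas_sigma_ss log-normal
#'   parameters of the SAS area on the nm^2 scale, per type.
#' @param psd_thickness_as,psd_thickness_ss,presynaptic_thickness plate
#'   thicknesses in nanometers (default 40, 20 and 15: the prominent AS
#'   PSD vs the thin SS PSD vs the presynaptic density).
#' @param cleft cleft width in nanometers between the apposed plate faces
#'   (default 20, one section thickness).
#' @param dome_ratio plate curvature as cap height / cap base radius
#'   (0 = flat discs; default 0.25 gives gently curved plates).
#' @param min_separation hard-core minimum distance between synapse
#'   centers, micrometers (default 0.3, about one synaptic plate
#'   diameter; kept small so counts stay near-Poisson at realistic
#'   densities).
#' @param seed integer seed.
#' @return object of class `em_volume_spec`.
#' @export
em_volume_spec <- function(width = 10.24, height = 7.68, depth = 5.5266,
                           voxel = c(5, 5, 20),
                           as_density = 2.1307, ss_density = 0.098,
                           sas_mu_as = 10.54, sas_sigma_as = 0.64,
                           sas_mu_ss = 10.70, sas_sigma_ss = 0.69,
                           psd_thickness_as = 40, psd_thickness_ss = 20,
                           presynaptic_thickness = 15,
                           cleft = 20, dome_ratio = 0.25,
                           min_separation = 0.3, seed = 1L) {
  for (nm in c("width", "height", "depth"))
    check_number(get(nm), nm, 0, strict_lower = TRUE)
  if (length(voxel) != 3L || any(voxel <= 0))
    stopf("`voxel` must be three positive sizes (nm)")
  check_number(as_density, "as_density", 0)
  check_number(ss_density, "ss_density", 0)
  check_number(cleft, "cleft", 0)
  check_number(dome_ratio, "dome_ratio", 0, 0.9)
  structure(list(width = width, height = height, depth = depth,
                 voxel = as.numeric(voxel),
                 as_density = as_density, ss_density = ss_density,
                 sas_mu_as = sas_mu_as, sas_sigma_as = sas_sigma_as,
                 sas_mu_ss = sas_mu_ss, sas_sigma_ss = sas_sigma_ss,
                 psd_thickness_as = psd_thickness_as,
                 psd_thickness_ss = psd_thickness_ss,
                 presynaptic_thickness = presynaptic_thickness,
                 cleft = cleft, dome_ratio = dome_ratio,
                 min_separation = min_separation,
                 seed = check_seed(seed)),
            class = "em_volume_spec")
}

#' @export
print.em_volume_spec <- function(x, ...) {
  cat(sprintf(
    "em_volume_spec: %.2f x %.2f x %.2f um (voxel %g x %g x %g nm), AS %.3f + SS %.3f /um^3, seed %d\n",
    x$width, x$height, x$depth, x$voxel[1], x$voxel[2], x$voxel[3],
    x$as_density, x$ss_density, x$seed))
  invisible(x)
}

# cap geometry from SAS area A (nm^2) and dome ratio kappa = h / a:
# A = pi * (a^2 + h^2)  (spherical cap area 2 pi R h), so
# a = sqrt(A / (pi (1 + kappa^2))), h = kappa a, R = (a^2 + h^2) / (2 h).
cap_geometry <- function(area_nm2, kappa) {
  a <- sqrt(area_nm2 / (pi * (1 + kappa^2)))
  h <- kappa * a
  R <- if (h > 0) (a^2 + h^2) / (2 * h) else Inf
  list(a = a, h = h, R = R)
}

# uniform random unit vector
random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

#' Generate a synthetic synapse population (no voxel rendering)
#'
#' Draws per-type Poisson counts, places synapse centers uniformly with a
#' hard-core constraint, samples SAS areas log-normally and orientations
#' isotropically, and returns per-synapse records with full spatial
#' extents (axis-aligned bounding boxes in micrometers). This is the fast
#' path for stereological counting experiments; [make_em_volume()] adds
#' the voxelized label volume.
#'
#' @param spec an [em_volume_spec()].
#' @return data.frame with one row per synapse: `id`, `type` ("AS"/"SS"),
#'   center `cx, cy, cz` (um), unit normal `nx, ny, nz`, `sas_area_nm2`,
#'   cap parameters `cap_a, cap_h` (nm), and bounding box
#'   `xmin..zmax` (um). Volume dimensions are attached as attribute
#'   `volume_dim`.
#' @export
make_em_population <- function(spec) {
  if (!inherits(spec, "em_volume_spec")) stopf("`spec` must be an em_volume_spec")
  with_seed(spec$seed, {
    vol <- spec$width * spec$height * spec$depth
    n_as <- stats::rpois(1, spec$as_density * vol)
    n_ss <- stats::rpois(1, spec$ss_density * vol)
    n <- n_as + n_ss
    centers <- place_hardcore_3d(n, c(spec$width, spec$height, spec$depth),
                                 spec$min_separation)
    types <- c(rep("AS", n_as), rep("SS", n_ss))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      as_type <- types[i] == "AS"
      area <- stats::rlnorm(1,
                            if (as_type) spec$sas_mu_as else spec$sas_mu_ss,
                            if (as_type) spec$sas_sigma_as else spec$sas_sigma_ss)
      g <- cap_geometry(area, spec$dome_ratio)
      nv <- random_unit_vector()
      t_post <- if (as_type) spec$psd_thickness_as else spec$psd_thickness_ss
      # conservative spatial extent: lateral cap radius + plate stack
      ext_nm <- sqrt(g$a^2 + g$h^2) + spec$cleft / 2 +
        max(t_post, spec$presynaptic_thickness) + max(spec$voxel)
      ext <- ext_nm / 1000
      rows[[i]] <- data.frame(
        id = i, type = types[i],
        cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
        nx = nv[1], ny = nv[2], nz = nv[3],
        sas_area_nm2 = area, cap_a = g$a, cap_h = g$h,
        xmin = centers[i, 1] - ext, xmax = centers[i, 1] + ext,
        ymin = centers[i, 2] - ext, ymax = centers[i, 2] + ext,
        zmin = centers[i, 3] - ext, zmax = centers[i, 3] + ext)
    }
    out <- if (n) do.call(rbind, rows) else
      data.frame(id = integer(), type = character(),
                 cx = numeric(), cy = numeric(), cz = numeric(),
                 nx = numeric(), ny = numeric(), nz = numeric(),
                 sas_area_nm2 = numeric(), cap_a = numeric(),
                 cap_h = numeric(),
                 xmin = numeric(), xmax = numeric(), ymin = numeric(),
                 ymax = numeric(), zmin = numeric(), zmax = numeric())
    attr(out, "volume_dim") <- c(spec$width, spec$height, spec$depth)
    attr(out, "spec") <- spec
    out
  })
}

place_hardcore_3d <- function(n, dims, min_sep, max_tries = 200L) {
  pts <- matrix(NA_real_, n, 3L)
  if (n == 0L) return(pts)
  kept <- matrix(numeric(0), 0, 3)
  cell <- max(min_sep, 1e-9)
  nx <- pmax(1L, ceiling(dims / cell))
  grid <- new.env(hash = TRUE, parent = emptyenv())
  gkey <- function(ix) paste(ix, collapse = ",")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3) * dims
      ix <- pmin(nx - 1L, floor(p / cell))
      ok <- TRUE
      for (ax in max(0, ix[1] - 1):min(nx[1] - 1, ix[1] + 1)) {
        for (ay in max(0, ix[2] - 1):min(nx[2] - 1, ix[2] + 1)) {
          for (az in max(0, ix[3] - 1):min(nx[3] - 1, ix[3] + 1)) {
            for (q in grid[[gkey(c(ax, ay, az))]]) {
              if (sum((p - q)^2) < min_sep^2) { ok <- FALSE; break }
            }
            if (!ok) break
          }
          if (!ok) break
        }
        if (!ok) break
      }
      if (ok) {
        pts[i, ] <- p
        k <- gkey(ix)
        grid[[k]] <- c(if (!is.null(grid[[k]])) grid[[k]], list(p))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("could not place %d synapses with min_separation %.3g um (density too high)",
            n, min_sep)
  }
  pts
}

# Render one synapse's pre/post plates into voxel index lists.
# Geometry (nm, volume coordinates): SAS cap apex at the synapse center c,
# sphere center O = c - R * n. Signed radial coordinate s = |p - O| - R;
# post plate occupies s in [cleft/2, cleft/2 + t_post] (the +n side), pre
# plate s in [-cleft/2 - t_pre, -cleft/2], both limited laterally to the
# cap half-angle. A voxel belongs to a plate when its support interval
# along the local radial direction intersects the plate slab, which keeps
# plates thinner than a voxel connected at any orientation; voxels
# eligible for both plates go to the nearer slab.
render_synapse_voxels <- function(rec, spec, dims_vox) {
  vx <- spec$voxel
  cen <- c(rec$cx, rec$cy, rec$cz) * 1000
  nv <- c(rec$nx, rec$ny, rec$nz)
  a <- rec$cap_a; h <- rec$cap_h
  kappa_flat <- h <= 1e-9
  t_post <- if (rec$type == "AS") spec$psd_thickness_as else spec$psd_thickness_ss
  t_pre <- spec$presynaptic_thickness
  half_cleft <- spec$cleft / 2
  ext <- sqrt(a^2 + h^2) + half_cleft + max(t_post, t_pre) + max(vx)

  ix0 <- pmax(1L, floor((cen - ext) / vx) + 1L)
  ix1 <- pmin(dims_vox, ceiling((cen + ext) / vx))
  if (any(ix0 > ix1)) return(list(pre = NULL, post = NULL))
  xs <- (ix0[1]:ix1[1]) * vx[1] - vx[1] / 2
  ys <- (ix0[2]:ix1[2]) * vx[2] - vx[2] / 2
  zs <- (ix0[3]:ix1[3]) * vx[3] - vx[3] / 2
  nxv <- length(xs); nyv <- length(ys); nzv <- length(zs)
  # voxel-center coordinate grids relative to the sphere center
  if (kappa_flat) {
    px <- rep(xs, times = nyv * nzv) - cen[1]
    py <- rep(rep(ys, each = nxv), times = nzv) - cen[2]
    pz <- rep(zs, each = nxv * nyv) - cen[3]
    s <- px * nv[1] + py * nv[2] + pz * nv[3]
    lat2 <- (px - s * nv[1])^2 + (py - s * nv[2])^2 + (pz - s * nv[3])^2
    lateral_ok <- lat2 <= a^2
    ux <- rep(nv[1], length(s)); uy <- rep(nv[2], length(s)); uz <- rep(nv[3], length(s))
  } else {
    R <- (a^2 + h^2) / (2 * h)
    O <- cen - R * nv
    px <- rep(xs, times = nyv * nzv) - O[1]
    py <- rep(rep(ys, each = nxv), times = nzv) - O[2]
    pz <- rep(zs, each = nxv * nyv) - O[3]
    rho <- sqrt(px^2 + py^2 + pz^2)
    rho[rho < 1e-9] <- 1e-9
    s <- rho - R
    cosang <- (px * nv[1] + py * nv[2] + pz * nv[3]) / rho
    lateral_ok <- cosang >= (R - h) / R
    ux <- px / rho; uy <- py / rho; uz <- pz / rho
  }
  delta <- abs(ux) * vx[1] + abs(uy) * vx[2] + abs(uz) * vx[3]
  post_lo <- half_cleft; post_hi <- half_cleft + t_post
  pre_hi <- -half_cleft; pre_lo <- -half_cleft - t_pre
  in_post <- lateral_ok & (s + delta / 2 >= post_lo) & (s - delta / 2 <= post_hi)
  in_pre  <- lateral_ok & (s + delta / 2 >= pre_lo) & (s - delta / 2 <= pre_hi)
  both <- in_post & in_pre
  if (any(both)) {
    nearer_post <- abs(s[both] - (post_lo + post_hi) / 2) <=
      abs(s[both] - (pre_lo + pre_hi) / 2)
    in_pre[both][nearer_post] <- FALSE
    in_post[both][!nearer_post] <- FALSE
  }
  lin_index <- function(sel) {
    k <- which(sel) - 1L
    i <- k %% nxv
    jrest <- k %/% nxv
    j <- jrest %% nyv
    l <- jrest %/% nyv
    cbind(i + ix0[1], j + ix0[2], l + ix0[3])
  }
  list(pre = lin_index(in_pre), post = lin_index(in_post))
}

#' Generate a synthetic labeled EM volume
#'
#' Produces the synapse population of [make_em_population()] and, when
#' `render = TRUE`, a voxelized label volume in which each synapse
#' contributes a presynaptic component (label `2 id - 1`) and a
#' postsynaptic component (label `2 id`). Voxel anisotropy is honored in
#' all geometry; already-claimed voxels are never overwritten, so
#' components of distinct synapses do not merge.
#'
#' @param spec an [em_volume_spec()].
#' @param render render the label volume (`FALSE` returns only ground
#'   truth).
#' @param max_voxels safety cap on the rendered array size.
#' @return list with `volume` (integer array x-by-y-by-z, or `NULL`),
#'   `truth` (the population records), `label_map` (data.frame id,
#'   pre_label, post_label, type), and `spec`.
#' @export
make_em_volume <- function(spec, render = TRUE, max_voxels = 2e8) {
  truth <- make_em_population(spec)
  vol <- NULL
  if (render) {
    dims_vox <- as.integer(round(c(spec$width, spec$height, spec$depth) * 1000 /
                                   spec$voxel))
    if (prod(as.numeric(dims_vox)) > max_voxels)
      stopf("requested volume needs %.3g voxels (> max_voxels = %.3g); reduce the dimensions",
            prod(as.numeric(dims_vox)), max_voxels)
    vol <- array(0L, dim = dims_vox)
    for (i in seq_len(nrow(truth))) {
      vidx <- render_synapse_voxels(truth[i, ], spec, dims_vox)
      for (side in c("pre", "post")) {
        ix <- vidx[[side]]
        if (is.null(ix) || !nrow(ix)) next
        lab <- if (side == "pre") 2L * truth$id[i] - 1L else 2L * truth$id[i]
        cur <- vol[ix]
        free <- cur == 0L
        vol[ix[free, , drop = FALSE]] <- lab
      }
    }
  }
  label_map <- data.frame(id = truth$id, type = truth$type,
                          pre_label = 2L * truth$id - 1L,
                          post_label = 2L * truth$id)
  list(volume = vol, truth = truth, label_map = label_map, spec = spec)
}

#' Render one synapse in isolation
#'
#' Builds minimal pre/post logical masks for a single synapse record in
#' its own local voxel grid. Used to validate type classification and SAS
#' measurement synapse-by-synapse without rendering a full volume.
#'
#' @param rec one-row synapse record from [make_em_population()].
#' @param spec the generating [em_volume_spec()].
#' @return list with logical arrays `pre`, `post` and the voxel size.
#' @export
render_synapse_masks <- function(rec, spec) {
  vx <- spec$voxel
  t_max <- max(spec$psd_thickness_as, spec$presynaptic_thickness,
               spec$psd_thickness_ss)
  ext_nm <- sqrt(rec$cap_a^2 + rec$cap_h^2) + spec$cleft / 2 + t_max +
    2 * max(vx)
  dims_vox <- as.integer(ceiling(2 * ext_nm / vx)) + 2L
  local <- rec
  local$cx <- dims_vox[1] * vx[1] / 2 / 1000
  local$cy <- dims_vox[2] * vx[2] / 2 / 1000
  local$cz <- dims_vox[3] * vx[3] / 2 / 1000
  vidx <- render_synapse_voxels(local, spec, dims_vox)
  pre <- array(FALSE, dims_vox); post <- array(FALSE, dims_vox)
  if (!is.null(vidx$pre) && nrow(vidx$pre)) pre[vidx$pre] <- TRUE
  if (!is.null(vidx$post) && nrow(vidx$post)) post[vidx$post] <- TRUE
  list(pre = pre, post = post, voxel = vx)
}
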