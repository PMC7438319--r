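# Shared fixtures, generated in code. The classifier is trained once per
# test run and reused across files.

test_field_spec <- function(seed, width = 21.504, density_ch1 = 109.8458,
                            density_ch2 = 105.1894, coloc_fraction = 0.6404,
                            ...) {
  puncta_field_spec(field_width = width, field_height = width,
                    density_ch1 = density_ch1, density_ch2 = density_ch2,
                    coloc_fraction = coloc_fraction, seed = seed, ...)
}

.test_classifier_cache <- new.env(parent = emptyenv())

test_classifier <- function() {
  if (is.null(.test_classifier_cache$clf)) {
    .test_classifier_cache$clf <- train_classifier_from_specs(
      list(test_field_spec(seed = 424242L)), seed = 7L)
  }
  .test_classifier_cache$clf
}

# fraction of ground-truth spots of `channel` that have a detection
# within `max_dist` pixels
truth_recall <- function(detections, truth, channel, max_dist = 2) {
  tr <- truth[truth$channel == channel, , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any((detections$x - tr$x[i])^2 + (detections$y - tr$y[i])^2
        <= max_dist^2)
  }, logical(1))
  mean(hit)
}

# -- analytic voxel plate builders (SAS oracles) -------------------------

# flat pre/post slabs apposed across one z-section boundary:
# post occupies z-layers [z0, z0 + nz_post - 1], pre the layers below,
# both nx x ny voxels wide
flat_apposition_masks <- function(nx = 100, ny = 100, nz_post = 2,
                                  nz_pre = 2, gap_layers = 0,
                                  dims = c(nx + 4, ny + 4,
                                           nz_post + nz_pre + gap_layers + 4)) {
  post <- array(FALSE, dims); pre <- array(FALSE, dims)
  z_pre <- 2 + seq_len(nz_pre)
  z_post <- max(z_pre) + gap_layers + seq_len(nz_post)
  pre[2 + seq_len(nx), 2 + seq_len(ny), z_pre] <- TRUE
  post[2 + seq_len(nx), 2 + seq_len(ny), z_post] <- TRUE
  list(pre = pre, post = post)
}

# thick slabs on both sides of an arbitrary plane through the volume
# center, limited to lateral radius `radius_nm`; the apposition surface
# is the disc of area pi * radius^2
tilted_apposition_masks <- function(normal, radius_nm = 250,
                                    thickness_nm = 60, cleft_nm = 10,
                                    voxel = c(5, 5, 20)) {
  normal <- normal / sqrt(sum(normal^2))
  ext <- radius_nm + thickness_nm + cleft_nm + 3 * max(voxel)
  dims <- as.integer(ceiling(2 * ext / voxel))
  cen <- dims * voxel / 2
  xs <- (seq_len(dims[1]) - 0.5) * voxel[1] - cen[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel[2] - cen[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel[3] - cen[3]
  px <- rep(xs, times = dims[2] * dims[3])
  py <- rep(rep(ys, each = dims[1]), times = dims[3])
  pz <- rep(zs, each = dims[1] * dims[2])
  s <- px * normal[1] + py * normal[2] + pz * normal[3]
  lat2 <- px^2 + py^2 + pz^2 - s^2
  lateral <- lat2 <= radius_nm^2
  post <- array(lateral & s >= cleft_nm / 2 &
                  s <= cleft_nm / 2 + thickness_nm, dims)
  pre <- array(lateral & s <= -cleft_nm / 2 &
                 s >= -cleft_nm / 2 - thickness_nm, dims)
  list(pre = pre, post = post, voxel = voxel,
       true_area = pi * radius_nm^2)
}

# spherical-cap apposition: shells of radius R (cap half-angle theta_c)
# around a center; true SAS area = 2 pi R h with h = R (1 - cos theta_c)
cap_apposition_masks <- function(R_nm = 400, theta_deg = 40,
                                 thickness_nm = 60, cleft_nm = 10,
                                 voxel = c(5, 5, 20)) {
  theta <- theta_deg * pi / 180
  ext <- R_nm + thickness_nm + cleft_nm + 3 * max(voxel)
  dims <- as.integer(ceiling(2 * ext / voxel))
  cen <- dims * voxel / 2
  xs <- (seq_len(dims[1]) - 0.5) * voxel[1] - cen[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel[2] - cen[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel[3] - cen[3]
  px <- rep(xs, times = dims[2] * dims[3])
  py <- rep(rep(ys, each = dims[1]), times = dims[3])
  pz <- rep(zs, each = dims[1] * dims[2])
  rho <- sqrt(px^2 + py^2 + pz^2)
  rho[rho < 1e-9] <- 1e-9
  ang_ok <- (pz / rho) >= cos(theta)
  srad <- rho - R_nm
  post <- array(ang_ok & srad >= cleft_nm / 2 &
                  srad <= cleft_nm / 2 + thickness_nm, dims)
  pre <- array(ang_ok & srad <= -cleft_nm / 2 &
                 srad >= -cleft_nm / 2 - thickness_nm, dims)
  list(pre = pre, post = post, voxel = voxel,
       true_area = 2 * pi * R_nm * R_nm * (1 - cos(theta)))
}
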