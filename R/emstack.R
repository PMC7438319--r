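# Stereological synapse counting in 3D volumes: unbiased counting frame
# (brick rule), tissue-shrinkage correction, AS/SS classification and
# synapse density records.

#' Tissue shrinkage correction factors from the linear factor
#'
#' Electron-microscopy processing shrinks tissue; measurements taken on
#' the processed volume must be rescaled. Given the linear factor `f`,
#' the area factor is `f^2` and the volume factor `f^3`.
#'
#' @param linear linear shrinkage factor in (0, 1\].
#' @return object of class `shrinkage_factors`: list with `linear`,
#'   `area`, `volume` (unrounded; round only for presentation).
#' @examples
#' shrinkage_from_linear(0.9508)  # area 0.9040, volume 0.8595 (4 d.p.)
#' @export
shrinkage_from_linear <- function(linear) {
  check_number(linear, "linear", 0, 1, strict_lower = TRUE)
  structure(list(linear = linear, area = linear^2, volume = linear^3),
            class = "shrinkage_factors")
}

#' @export
print.shrinkage_factors <- function(x, ...) {
  cat(sprintf("shrinkage factors: linear %.4f, area %.4f, volume %.4f\n",
              x$linear, x$area, x$volume))
  invisible(x)
}

#' Unbiased 3D counting frame (brick)
#'
#' An axis-aligned brick with three inclusion faces and three exclusion
#' faces (one per axis). Objects intersecting the frame are counted
#' unless they touch an exclusion face, so that in a tiling of frames
#' every object is counted in exactly one frame.
#'
#' @param origin numeric length 3, lower corner in micrometers.
#' @param extent numeric length 3, strictly positive edge lengths (um).
#' @param exclusion which face of each axis is the exclusion face:
#'   `"high"` (default: upper x, y, z faces) or `"low"`, per axis.
#' @return object of class `counting_frame`.
#' @export
counting_frame <- function(origin, extent,
                           exclusion = c("high", "high", "high")) {
  if (length(origin) != 3L || length(extent) != 3L)
    stopf("`origin` and `extent` must have length 3")
  if (any(extent <= 0)) stopf("`extent` must be strictly positive")
  exclusion <- rep_len(exclusion, 3L)
  if (!all(exclusion %in% c("high", "low")))
    stopf("`exclusion` entries must be \"high\" or \"low\"")
  structure(list(origin = as.numeric(origin), extent = as.numeric(extent),
                 exclusion = exclusion,
                 volume = prod(as.numeric(extent))),
            class = "counting_frame")
}

#' @export
print.counting_frame <- function(x, ...) {
  cat(sprintf(
    "counting frame: origin (%.3f, %.3f, %.3f) um, extent (%.3f, %.3f, %.3f) um, volume %.3f um^3, exclusion faces %s\n",
    x$origin[1], x$origin[2], x$origin[3],
    x$extent[1], x$extent[2], x$extent[3], x$volume,
    paste(x$exclusion, collapse = "/")))
  invisible(x)
}

#' Count objects inside an unbiased counting frame
#'
#' Applies the brick rule to object records carrying full spatial extents
#' (bounding boxes): an object is counted iff it intersects the frame and
#' does not touch any exclusion face. With the default high-face
#' exclusion this reduces to "the object's maximal corner lies inside the
#' frame", which associates every object with exactly one frame of a
#' tiling. A centroid-association variant is available for cross-checks.
#'
#' @param records data.frame with columns `xmin, xmax, ymin, ymax, zmin,
#'   zmax` (and `cx, cy, cz` for the centroid rule), micrometers.
#' @param frame a [counting_frame()].
#' @param rule `"extent"` (brick rule on bounding boxes, default) or
#'   `"centroid"`.
#' @param volume_dim optional volume dimensions; if given (or attached to
#'   `records` as attribute `volume_dim`), a frame extending outside the
#'   volume is an error.
#' @return integer vector of counted record ids (rows of `records`).
#' @export
count_in_frame <- function(records, frame, rule = c("extent", "centroid"),
                           volume_dim = NULL) {
  rule <- match.arg(rule)
  if (!inherits(frame, "counting_frame")) stopf("`frame` must be a counting_frame")
  if (is.null(volume_dim)) volume_dim <- attr(records, "volume_dim")
  if (!is.null(volume_dim)) {
    if (any(frame$origin < -1e-9) ||
        any(frame$origin + frame$extent > volume_dim + 1e-9))
      stopf("counting frame extends outside the volume")
  }
  if (!nrow(records)) return(integer(0))
  lo <- frame$origin; hi <- frame$origin + frame$extent
  ok <- rep(TRUE, nrow(records))
  mins <- cbind(records$xmin, records$ymin, records$zmin)
  maxs <- cbind(records$xmax, records$ymax, records$zmax)
  if (rule == "centroid") {
    cen <- cbind(records$cx, records$cy, records$cz)
    for (ax in 1:3) ok <- ok & cen[, ax] >= lo[ax] & cen[, ax] < hi[ax]
  } else {
    for (ax in 1:3) {
      if (frame$exclusion[ax] == "high") {
        # counted iff max corner in [lo, hi): intersects, and does not
        # reach the upper (exclusion) plane
        ok <- ok & maxs[, ax] >= lo[ax] & maxs[, ax] < hi[ax]
      } else {
        ok <- ok & mins[, ax] > lo[ax] & mins[, ax] <= hi[ax]
      }
    }
  }
  which(ok)
}

#' Synapse density record from counts and frame volume
#'
#' Converts per-frame synapse counts to densities, optionally applying
#' the tissue-shrinkage correction. Processed tissue is shrunken relative
#' to the living state, so the corrected (in vivo) volume is the measured
#' volume divided by the volume shrinkage factor, and densities scale
#' down accordingly. Set `volume_is_corrected = TRUE` when the supplied
#' volume has already been corrected.
#'
#' @param n_as,n_ss counts of asymmetric and symmetric synapses.
#' @param frame_volume frame volume in um^3.
#' @param shrinkage optional [shrinkage_from_linear()] factors.
#' @param volume_is_corrected whether `frame_volume` is already
#'   shrinkage-corrected (default `TRUE`; set `FALSE` to have the raw
#'   volume divided by the volume factor).
#' @param sample_id optional identifier.
#' @return one-row data.frame: `sample_id`, `n_AS`, `n_SS`,
#'   `frame_volume` (corrected, um^3), `density_AS`, `density_SS`,
#'   `density_total` (synapses/um^3), `shrinkage_applied`.
#' @export
synapse_density <- function(n_as, n_ss = 0, frame_volume,
                            shrinkage = NULL, volume_is_corrected = TRUE,
                            sample_id = NA_character_) {
  check_number(frame_volume, "frame_volume", 0, strict_lower = TRUE)
  check_number(n_as, "n_as", 0); check_number(n_ss, "n_ss", 0)
  vol <- frame_volume
  applied <- FALSE
  if (!volume_is_corrected) {
    if (is.null(shrinkage))
      stopf("raw volumes require `shrinkage` factors")
    vol <- frame_volume / shrinkage$volume
    applied <- TRUE
  }
  data.frame(sample_id = sample_id, n_AS = n_as, n_SS = n_ss,
             frame_volume = vol,
             density_AS = n_as / vol, density_SS = n_ss / vol,
             density_total = (n_as + n_ss) / vol,
             shrinkage_applied = applied)
}

#' Classify a synapse as asymmetric or symmetric
#'
#' Mirrors the EM criterion that an asymmetric (excitatory) synapse has a
#' dense, prominent PSD much thicker than the faint presynaptic
#' thickening, while a symmetric (inhibitory) synapse has a thin PSD
#' similar to it. The mean plate thicknesses are estimated as component
#' chord counting: voxel columns are taken along the axis most aligned
#' with the SAS normal, the median within-component chord is projected
#' onto the normal, and the voxel support along the normal is subtracted
#' (de-biasing the one-voxel dilation that rasterization imposes on
#' plates thinner than a voxel). Per-column chords cross the plate
#' locally, so plate curvature does not bias the estimate. The synapse
#' is AS iff `post thickness >= ratio_threshold x pre thickness`.
#'
#' @param pre_mask,post_mask logical 3D arrays (same dimensions) of the
#'   presynaptic component and the PSD.
#' @param voxel voxel pitch in nanometers, `c(x, y, z)`.
#' @param ratio_threshold PSD/presynaptic thickness ratio separating AS
#'   from SS (default 1.5).
#' @param max_gap_nm apposition search range in nm (see
#'   [extract_sas()]).
#' @return `"AS"` or `"SS"`, with attributes `post_thickness_nm`,
#'   `pre_thickness_nm` and `ratio`.
#' @export
classify_synapse_type <- function(pre_mask, post_mask, voxel = c(5, 5, 20),
                                  ratio_threshold = 1.5, max_gap_nm = 40) {
  if (!any(pre_mask)) stopf("presynaptic component is empty")
  if (!any(post_mask)) stopf("postsynaptic component is empty")
  sas <- extract_sas(pre_mask, post_mask, voxel, max_gap_nm = max_gap_nm)
  t_post <- plate_thickness(post_mask, sas$normal, voxel)
  t_pre <- plate_thickness(pre_mask, sas$normal, voxel)
  ratio <- t_post / t_pre
  out <- if (ratio >= ratio_threshold) "AS" else "SS"
  attr(out, "post_thickness_nm") <- t_post
  attr(out, "pre_thickness_nm") <- t_pre
  attr(out, "ratio") <- ratio
  out
}

# median chord thickness (nm) of a voxelized plate along `normal`
plate_thickness <- function(mask, normal, voxel) {
  ax <- which.max(abs(normal))
  idx <- which(mask, arr.ind = TRUE)
  other <- setdiff(1:3, ax)
  col_id <- idx[, other[1]] * 1e5 + idx[, other[2]]
  chord <- tabulate(match(col_id, unique(col_id)))
  med <- stats::median(chord)
  delta <- sum(abs(normal) * voxel)
  max(med * voxel[ax] * abs(normal[ax]) - delta, min(voxel) / 2)
}
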