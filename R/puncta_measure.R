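# Punctum segmentation (10%-of-peak rule), morphometry (the six punctum
# descriptors), per-field densities and object-based colocalization.

#' Segment one punctum with the 10%-of-peak rule
#'
#' After background handling (subtraction of the field median, clamped at
#' zero), the segmentation threshold is set to `rel_threshold` (default
#' 10%) of the peak pixel intensity of the punctum, and the mask is the
#' connected component of supra-threshold pixels that contains the peak.
#' The rule is invariant to multiplying the image by any positive scale,
#' so punctum size and shape do not depend on absolute brightness.
#'
#' @param image numeric matrix (one channel).
#' @param peak length-2 numeric, punctum peak position `(x, y)` in
#'   pixel-center coordinates (as returned by [detect_candidates()]).
#' @param background scalar background level to subtract; default is the
#'   field median.
#' @param rel_threshold fraction of the (background-subtracted) peak.
#' @param max_radius maximum mask radius in pixels (window guard).
#' @return an object of class `punctum_mask`: list with `pixels` (n x 2
#'   matrix of row/col indices), `peak_value` (background-subtracted),
#'   `threshold`, and `empty` flag. A peak at or below background yields
#'   an empty mask.
#' @export
segment_punctum <- function(image, peak, background = NULL,
                            rel_threshold = 0.10, max_radius = 30L) {
  if (is.null(background)) background <- stats::median(image)
  H <- nrow(image); W <- ncol(image)
  j <- as.integer(floor(peak[1]) + 1L)  # pixel containing x (pixel j covers [j-1, j))
  i <- as.integer(floor(peak[2]) + 1L)
  j <- min(max(j, 1L), W); i <- min(max(i, 1L), H)
  if (any(!is.finite(peak)))
    stopf("`peak` must be finite coordinates")
  pv <- image[i, j] - background
  if (pv <= 0)
    return(structure(list(pixels = matrix(integer(), 0, 2),
                          peak_value = pv, threshold = NA_real_,
                          empty = TRUE), class = "punctum_mask"))
  thr <- rel_threshold * pv
  # region grow inside an expanding window
  rad <- 8L
  repeat {
    i0 <- max(1L, i - rad); i1 <- min(H, i + rad)
    j0 <- max(1L, j - rad); j1 <- min(W, j + rad)
    win <- pmax(image[i0:i1, j0:j1, drop = FALSE] - background, 0) >= thr
    mask <- grow_from_seed(win, i - i0 + 1L, j - j0 + 1L)
    # grow the window only when the mask is clipped at a window edge
    # that is not already the image border
    clipped <- (any(mask[1, ]) && i0 > 1L) ||
      (any(mask[nrow(mask), ]) && i1 < H) ||
      (any(mask[, 1]) && j0 > 1L) ||
      (any(mask[, ncol(mask)]) && j1 < W)
    if (!clipped || rad >= max_radius) break
    rad <- min(max_radius, rad * 2L)
  }
  px <- which(mask, arr.ind = TRUE)
  px[, 1] <- px[, 1] + i0 - 1L
  px[, 2] <- px[, 2] + j0 - 1L
  colnames(px) <- c("row", "col")
  structure(list(pixels = px, peak_value = pv, threshold = thr,
                 empty = FALSE), class = "punctum_mask")
}

# connected component (8-connectivity) of TRUE pixels containing the seed,
# by iterated masked dilation
grow_from_seed <- function(win, si, sj) {
  if (!win[si, sj]) {
    out <- matrix(FALSE, nrow(win), ncol(win))
    out[si, sj] <- TRUE  # seed itself is supra-threshold by construction
    return(out)
  }
  cur <- matrix(FALSE, nrow(win), ncol(win))
  cur[si, sj] <- TRUE
  repeat {
    dil <- cur
    dil <- dil | shift_logical(cur, 1L, 0L) | shift_logical(cur, -1L, 0L) |
      shift_logical(cur, 0L, 1L) | shift_logical(cur, 0L, -1L) |
      shift_logical(cur, 1L, 1L) | shift_logical(cur, 1L, -1L) |
      shift_logical(cur, -1L, 1L) | shift_logical(cur, -1L, -1L)
    nxt <- dil & win
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# shift with FALSE padding
shift_logical <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- seq_len(nr) + dy; ci <- seq_len(nc) + dx
  ok_r <- ri >= 1L & ri <= nr; ok_c <- ci >= 1L & ci <= nc
  out[which(ok_r), which(ok_c)] <- m[ri[ok_r], ci[ok_c], drop = FALSE]
  out
}

#' Measure the six punctum descriptors
#'
#' Computes, over a segmented mask: mean pixel intensity (raw image
#' units), punctum size (pixel count times physical pixel area, um^2),
#' skewness and kurtosis (standardized third and fourth moments of the
#' within-mask intensities; kurtosis is non-excess, so a Gaussian gives
#' 3), circularity (`4 pi A / P^2` with the perimeter estimated from the
#' traced border-pixel contour, corrected for the half-pixel offset of
#' the center path) and aspect ratio (major/minor axis of the
#' intensity-weighted second-moment ellipse).
#'
#' For a degenerate constant-intensity mask the moment ratios are not
#' defined; skewness is reported as 0 and kurtosis as 3 (the
#' vanishing-noise limits).
#'
#' @param image numeric matrix the mask was segmented from.
#' @param mask a `punctum_mask` from [segment_punctum()].
#' @param pixel_size pixel pitch in nanometers.
#' @param background background level used for intensity weighting
#'   (default: field median).
#' @return one-row data.frame (a punctum record): `x`, `y` (centroid,
#'   pixel units), `n_pixels`, `mean_intensity`, `size` (um^2),
#'   `skewness`, `kurtosis`, `circularity`, `aspect_ratio`.
#' @export
measure_punctum <- function(image, mask, pixel_size = 84,
                            background = NULL) {
  if (!inherits(mask, "punctum_mask")) stopf("`mask` must be a punctum_mask")
  if (mask$empty || nrow(mask$pixels) == 0L)
    stopf("cannot measure an empty mask")
  if (is.null(background)) background <- stats::median(image)
  px <- mask$pixels
  n <- nrow(px)
  vals <- image[px]
  w <- pmax(vals - background, 0)
  if (sum(w) <= 0) w <- rep(1, n)
  cx <- sum(w * (px[, 2] - 0.5)) / sum(w)
  cy <- sum(w * (px[, 1] - 0.5)) / sum(w)

  m <- mean(vals); s <- pop_sd(vals)
  if (s > 0) {
    skew <- mean((vals - m)^3) / s^3
    kurt <- mean((vals - m)^4) / s^4
  } else {
    skew <- 0; kurt <- 3
  }

  if (n == 1L) {
    circ <- 1; ar <- 1
  } else {
    P <- trace_perimeter(px)
    circ <- 4 * pi * n / P^2
    # intensity-weighted covariance, with the pixel's own second moment
    dx <- (px[, 2] - 0.5) - cx; dy <- (px[, 1] - 0.5) - cy
    wn <- w / sum(w)
    cxx <- sum(wn * dx^2) + 1 / 12
    cyy <- sum(wn * dy^2) + 1 / 12
    cxy <- sum(wn * dx * dy)
    tr2 <- (cxx + cyy) / 2
    det_ <- cxx * cyy - cxy^2
    disc <- sqrt(max(tr2^2 - det_, 0))
    l1 <- tr2 + disc; l2 <- max(tr2 - disc, 1e-12)
    ar <- sqrt(l1 / l2)
  }
  data.frame(x = cx, y = cy, n_pixels = n,
             mean_intensity = m,
             size = n * (pixel_size / 1000)^2,
             skewness = skew, kurtosis = kurt,
             circularity = circ, aspect_ratio = ar)
}

# Moore-neighbor boundary tracing; returns the contour length through
# border-pixel centers with the Kulpa staircase correction (0.948),
# plus pi (offset from the center path to the physical outline of a
# convex-ish digitized region).
trace_perimeter <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(pi)
  rmin <- min(px[, 1]); cmin <- min(px[, 2])
  nr <- max(px[, 1]) - rmin + 3L; nc <- max(px[, 2]) - cmin + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1] - rmin + 2L, px[, 2] - cmin + 2L)] <- TRUE
  # start: topmost then leftmost pixel
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # Moore neighborhood, clockwise starting from W
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  lens <- sqrt(rowSums(moves^2))
  cur <- start; backtrack <- 1L  # came "from the west"
  total <- 0
  first_move <- NA_integer_
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (backtrack + k - 1L) %% 8L + 1L
      cand <- cur + moves[d, ]
      if (m[cand[1], cand[2]]) {
        total <- total + lens[d]
        # next backtrack: direction pointing back toward previous pixel,
        # rotated one step clockwise
        backtrack <- (d + 4L - 1L + 1L) %% 8L + 1L
        cur <- cand
        if (is.na(first_move)) first_move <- d
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel reached only via diagonals
    steps <- steps + 1L
    if (all(cur == start) && steps > 1L) break
    if (steps > 8L * n) break  # safety
  }
  0.948 * total + pi
}

#' Puncta density per 100 square micrometers
#'
#' @param records data.frame of punctum records (or anything with rows).
#' @param field_area field area in um^2.
#' @return puncta per 100 um^2.
#' @export
puncta_density <- function(records, field_area) {
  check_number(field_area, "field_area", 0, strict_lower = TRUE)
  100 * nrow(records) / field_area
}

#' Object-based colocalization of two punctum channels
#'
#' Two puncta from different channels are the same synaptic entity when
#' their segmented masks share at least one pixel (default), with ties
#' broken by maximal overlap and then by nearest centroid; pairing is
#' one-to-one. Masks that merely touch (8-neighborhood contact, no
#' shared pixel — which happens for near-diffraction-limit puncta whose
#' masks are one or two pixels) also pair, provided their centroids lie
#' within `contact_max_dist` pixels; the distance gate keeps distinct
#' neighboring puncta apart. Alternatively (`method = "centroid"`),
#' puncta pair when their centroids are within `max_dist_nm`. The
#' colocalization index is `c = n_both / n_entities`, where a paired
#' punctum counts as a single entity, so `c` ranges from 0 (no
#' colocalization) to 1 (all entities in both channels).
#'
#' @param records_ch1,records_ch2 punctum record data.frames carrying a
#'   `mask` list-column (as produced by [detect_puncta()]).
#' @param method `"overlap"` (mask overlap, default) or `"centroid"`.
#' @param max_dist_nm centroid pairing radius for `method = "centroid"`.
#' @param pixel_size pixel pitch in nanometers (centroid method only).
#' @param contact_max_dist centroid gate (pixels) for adjacency-only
#'   contacts in the overlap method.
#' @param max_pair_dist peak-distance gate (pixels) applied to every
#'   candidate pair of the overlap method; overlapping masks whose
#'   detection peaks are farther apart than this are treated as
#'   distinct neighboring puncta whose masks merged, not as one
#'   entity.
#' @return object of class `colocalization_result`: `n_total` (entities),
#'   `n_both`, `c`, and `pairing` (data.frame of paired record indices).
#' @export
colocalization <- function(records_ch1, records_ch2,
                           method = c("overlap", "centroid"),
                           max_dist_nm = 200, pixel_size = 84,
                           contact_max_dist = 2, max_pair_dist = 2.5) {
  method <- match.arg(method)
  n1 <- nrow(records_ch1); n2 <- nrow(records_ch2)
  # detection peaks are robust to mask merging; fall back to centroids
  px1 <- if ("peak_x" %in% names(records_ch1)) records_ch1$peak_x else records_ch1$x
  py1 <- if ("peak_y" %in% names(records_ch1)) records_ch1$peak_y else records_ch1$y
  px2 <- if ("peak_x" %in% names(records_ch2)) records_ch2$peak_x else records_ch2$x
  py2 <- if ("peak_y" %in% names(records_ch2)) records_ch2$peak_y else records_ch2$y
  pi_ <- integer(0); pj_ <- integer(0); pover <- numeric(0); pdist <- numeric(0)
  if (n1 > 0L && n2 > 0L) {
    if (method == "overlap") {
      # pixel key -> ch2 record ids (masks of merged neighbors may share
      # pixels, so a key can map to several records)
      k2 <- unlist(lapply(seq_len(n2), function(j) {
        px <- records_ch2$mask[[j]]$pixels
        px[, 1] * 1e5 + px[, 2]
      }))
      j2 <- rep.int(seq_len(n2),
                    vapply(records_ch2$mask,
                           function(m) nrow(m$pixels), integer(1)))
      lookup <- new.env(hash = TRUE, parent = emptyenv())
      sp <- split(j2, k2)
      for (nm in names(sp)) assign(nm, sp[[nm]], envir = lookup)
      for (i in seq_len(n1)) {
        px <- records_ch1$mask[[i]]$pixels
        base_keys <- px[, 1] * 1e5 + px[, 2]
        hits <- unlist(mget(as.character(base_keys), envir = lookup,
                            ifnotfound = list(NULL)), use.names = FALSE)
        if (length(hits)) {
          tb <- table(hits)
          js <- as.integer(names(tb))
          d <- sqrt((px1[i] - px2[js])^2 + (py1[i] - py2[js])^2)
          keep <- d <= max_pair_dist
          js <- js[keep]; d <- d[keep]; tb <- tb[keep]
          pi_ <- c(pi_, rep.int(i, length(js))); pj_ <- c(pj_, js)
          pover <- c(pover, as.numeric(tb)); pdist <- c(pdist, d)
        } else {
          # adjacency-only contact, gated by centroid proximity
          nb <- outer(base_keys, c(-1e5 - 1, -1e5, -1e5 + 1, -1, 1,
                                   1e5 - 1, 1e5, 1e5 + 1), `+`)
          hits2 <- unlist(mget(as.character(unique(as.vector(nb))),
                               envir = lookup, ifnotfound = list(NULL)),
                          use.names = FALSE)
          if (length(hits2)) {
            js <- unique(hits2)
            d <- sqrt((px1[i] - px2[js])^2 + (py1[i] - py2[js])^2)
            keep <- d <= contact_max_dist
            if (any(keep)) {
              js <- js[keep]; d <- d[keep]
              pi_ <- c(pi_, rep.int(i, length(js))); pj_ <- c(pj_, js)
              pover <- c(pover, rep.int(0.5, length(js)))
              pdist <- c(pdist, d)
            }
          }
        }
      }
    } else {
      maxd <- max_dist_nm / pixel_size
      for (i in seq_len(n1)) {
        d <- sqrt((px1[i] - px2)^2 + (py1[i] - py2)^2)
        js <- which(d <= maxd)
        if (length(js)) {
          pi_ <- c(pi_, rep.int(i, length(js))); pj_ <- c(pj_, js)
          pover <- c(pover, rep.int(0, length(js))); pdist <- c(pdist, d[js])
        }
      }
    }
  }
  # greedy one-to-one assignment by nearest centroid (overlap as the
  # tie-break): in clusters of merged masks, several records can share
  # one connected component, and distance-first assignment keeps each
  # punctum with its own cross-channel partner
  ci <- integer(0); cj <- integer(0)
  if (length(pi_)) {
    ord <- order(pdist, -pover)
    used_i <- logical(n1); used_j <- logical(n2)
    for (k in ord) {
      i <- pi_[k]; j <- pj_[k]
      if (!used_i[i] && !used_j[j]) {
        ci <- c(ci, i); cj <- c(cj, j)
        used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
  }
  chosen <- data.frame(i = ci, j = cj)
  n_both <- nrow(chosen)
  n_total <- n1 + n2 - n_both
  structure(list(n_total = n_total, n_both = n_both,
                 c = if (n_total > 0L) n_both / n_total else 0,
                 pairing = chosen),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("colocalization: %d entities, %d in both channels, c = %.4f\n",
              x$n_total, x$n_both, x$c))
  invisible(x)
}

#' Detect, classify, segment and measure puncta in one channel
#'
#' Full single-channel pipeline: NLD features, low-threshold candidates,
#' classifier filtering, 10%-of-peak segmentation and the six-descriptor
#' morphometry. Accepted candidates whose segmentation is empty (peak at
#' or below background) are dropped; records whose centroids fall within
#' `min_distance` pixels of a stronger record are merged away.
#'
#' @param image numeric matrix (one channel).
#' @param classifier a [train_classifier()] model.
#' @param pixel_size pixel pitch in nanometers.
#' @param low_threshold candidate response threshold.
#' @param prob_threshold classifier acceptance probability.
#' @param min_distance duplicate-suppression radius in pixels.
#' @param scales,orientations NLD parameters.
#' @return data.frame of punctum records with a `mask` list-column.
#' @export
detect_puncta <- function(image, classifier, pixel_size = 84,
                          low_threshold = 0, prob_threshold = 0.5,
                          min_distance = 2,
                          scales = c(1, 2, 3),
                          orientations = c(0, 45, 90, 135)) {
  cand <- detect_candidates(image, low_threshold = low_threshold,
                            min_distance = min_distance,
                            scales = scales, orientations = orientations)
  acc <- classify_candidates(cand, classifier, prob_threshold)
  bg <- stats::median(image)
  recs <- list(); masks <- list()
  for (k in seq_len(nrow(acc))) {
    mk <- segment_punctum(image, c(acc$x[k], acc$y[k]), background = bg)
    if (mk$empty) next
    r <- measure_punctum(image, mk, pixel_size, background = bg)
    r$peak_x <- acc$x[k]; r$peak_y <- acc$y[k]
    r$prob <- acc$prob[k]
    recs[[length(recs) + 1L]] <- r
    masks[[length(masks) + 1L]] <- mk
  }
  if (!length(recs)) {
    out <- data.frame(x = numeric(), y = numeric(), n_pixels = integer(),
                      mean_intensity = numeric(), size = numeric(),
                      skewness = numeric(), kurtosis = numeric(),
                      circularity = numeric(), aspect_ratio = numeric(),
                      peak_x = numeric(), peak_y = numeric(),
                      prob = numeric())
    out$mask <- list()
    return(out)
  }
  out <- do.call(rbind, recs)
  out$mask <- masks
  # duplicate suppression already happened at the candidate-peak level;
  # neighboring puncta whose 10%-of-peak masks merge stay separate
  # records (one per detected peak), which keeps counts honest
  rownames(out) <- NULL
  out
}

#' Analyze a two-channel puncta field
#'
#' Runs [detect_puncta()] on both channels and computes per-channel
#' densities plus the colocalization index.
#'
#' @param image H x W x 2 numeric array.
#' @param classifier a [train_classifier()] model (applied to both
#'   channels).
#' @param field_area field area in um^2.
#' @param pixel_size pixel pitch in nanometers.
#' @param ... further arguments to [detect_puncta()].
#' @return list with `records` (per channel), `density_ch1`,
#'   `density_ch2`, `coloc` (a `colocalization_result`).
#' @export
analyze_field <- function(image, classifier, field_area, pixel_size = 84,
                          ...) {
  if (length(dim(image)) != 3L || dim(image)[3] != 2L)
    stopf("`image` must be an H x W x 2 array")
  r1 <- detect_puncta(image[, , 1], classifier, pixel_size, ...)
  r2 <- detect_puncta(image[, , 2], classifier, pixel_size, ...)
  list(records = list(ch1 = r1, ch2 = r2),
       density_ch1 = puncta_density(r1, field_area),
       density_ch2 = puncta_density(r2, field_area),
       coloc = colocalization(r1, r2))
}
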