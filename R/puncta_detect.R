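# Fluorescent punctum detection: multi-scale/multi-orientation second-order
# nonlocal-derivative features, low-threshold candidate extraction, and a
# supervised classifier separating true puncta from background noise.

#' Second-order nonlocal derivative feature stack
#'
#' Computes, for every pixel, the second-order intensity difference
#' `I(x) - (I(x + s u) + I(x - s u)) / 2` along each orientation `u` at
#' each scale `s` (offsets rounded to whole pixels, reflective border
#' padding). On a bright spot the center-surround contrast is positive at
#' the scale matching the spot radius; on constant or linearly ramping
#' intensity the response vanishes.
#'
#' @param image numeric matrix (one channel).
#' @param scales integer-ish vector of offsets in pixels (all >= 1 and
#'   smaller than the image).
#' @param orientations orientations in degrees.
#' @return numeric array `H x W x (length(scales) * length(orientations))`
#'   with attributes `scales` and `orientations`; slices are ordered
#'   orientation-fastest.
#' @export
nld_features <- function(image, scales = c(1, 2, 3),
                         orientations = c(0, 45, 90, 135)) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("`image` must be a numeric matrix")
  if (length(scales) < 1L || length(orientations) < 1L)
    stopf("need at least one scale and one orientation")
  if (any(scales < 1) || any(scales >= min(dim(image))))
    stopf("scales must be >= 1 and smaller than the image")
  nf <- length(scales) * length(orientations)
  out <- array(0, dim = c(nrow(image), ncol(image), nf))
  k <- 0L
  for (s in scales) {
    for (th in orientations) {
      k <- k + 1L
      dx <- round(s * cos(th * pi / 180))
      dy <- round(s * sin(th * pi / 180))
      if (dx == 0L && dy == 0L) next
      out[, , k] <- image -
        0.5 * (shift_matrix(image, dy, dx) + shift_matrix(image, -dy, -dx))
    }
  }
  attr(out, "scales") <- scales
  attr(out, "orientations") <- orientations
  out
}

#' Aggregate spot response from an NLD feature stack
#'
#' Per scale, takes the minimum over orientations (a blob must contrast
#' with its surround in every direction, which suppresses ridges and
#' edges), then the maximum over scales.
#'
#' @param features array from [nld_features()].
#' @return numeric matrix of per-pixel responses.
#' @export
nld_response <- function(features) {
  scales <- attr(features, "scales")
  orientations <- attr(features, "orientations")
  no <- length(orientations)
  resp <- NULL
  for (si in seq_along(scales)) {
    idx <- (si - 1L) * no + seq_len(no)
    m <- features[, , idx[1]]
    for (j in idx[-1]) m <- pmin(m, features[, , j])
    resp <- if (is.null(resp)) m else pmax(resp, m)
  }
  resp
}

#' Detect candidate puncta at a deliberately low threshold
#'
#' Finds local maxima of the aggregated NLD response above `low_threshold`
#' and returns one row per candidate with its full feature vector. The
#' threshold is intended to be set very low so that essentially no true
#' punctum is missed; a classifier then removes the background-noise
#' candidates. Peaks closer than `min_distance` pixels are merged, keeping
#' the stronger one.
#'
#' @param image numeric matrix (one channel).
#' @param features optional precomputed [nld_features()] stack.
#' @param low_threshold non-negative response threshold.
#' @param min_distance peak merge radius in pixels.
#' @param scales,orientations passed to [nld_features()] when `features`
#'   is not supplied.
#' @return data.frame with columns `x`, `y` (pixel-center coordinates),
#'   `response`, `intensity` (median-subtracted pixel value), and feature
#'   columns `f1..fk`.
#' @export
detect_candidates <- function(image, features = NULL, low_threshold = 0,
                              min_distance = 2,
                              scales = c(1, 2, 3),
                              orientations = c(0, 45, 90, 135)) {
  check_number(low_threshold, "low_threshold", 0)
  if (is.null(features)) features <- nld_features(image, scales, orientations)
  resp <- nld_response(features)
  H <- nrow(resp); W <- ncol(resp)
  # 8-neighborhood local maxima (>= neighbors, > threshold)
  is_max <- resp > low_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & (resp >= shift_matrix(resp, dy, dx))
  }
  idx <- which(is_max)
  if (!length(idx)) return(empty_candidates(dim(features)[3]))
  ii <- ((idx - 1L) %% H) + 1L
  jj <- ((idx - 1L) %/% H) + 1L
  rvals <- resp[idx]
  # greedy suppression of peaks closer than min_distance, stronger first
  ord <- order(rvals, decreasing = TRUE)
  keep <- logical(length(ord))
  occ <- matrix(FALSE, H, W)
  rad <- ceiling(min_distance) - 1L
  for (k in ord) {
    i <- ii[k]; j <- jj[k]
    i0 <- max(1L, i - rad); i1 <- min(H, i + rad)
    j0 <- max(1L, j - rad); j1 <- min(W, j + rad)
    if (!any(occ[i0:i1, j0:j1])) {
      keep[k] <- TRUE
      occ[i, j] <- TRUE
    }
  }
  sel <- which(keep)
  nf <- dim(features)[3]
  fm <- matrix(0, length(sel), nf)
  for (f in seq_len(nf)) fm[, f] <- features[, , f][idx[sel]]
  colnames(fm) <- paste0("f", seq_len(nf))
  med <- stats::median(image)
  out <- data.frame(x = jj[sel] - 0.5, y = ii[sel] - 0.5,
                    response = rvals[sel],
                    intensity = image[idx[sel]] - med)
  cbind(out, as.data.frame(fm))
}

empty_candidates <- function(nf) {
  out <- data.frame(x = numeric(), y = numeric(), response = numeric(),
                    intensity = numeric())
  for (f in seq_len(nf)) out[[paste0("f", f)]] <- numeric()
  out
}

candidate_feature_matrix <- function(candidates) {
  cols <- setdiff(names(candidates), c("x", "y"))
  as.matrix(candidates[, cols, drop = FALSE])
}

#' Label detection candidates against ground truth
#'
#' Marks a candidate as a true punctum when a ground-truth spot center of
#' the requested channel lies within `max_dist` pixels. Used to build
#' training sets for [train_classifier()] from synthetic fields.
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param truth ground-truth table from [make_puncta_field()].
#' @param channel channel id to match against.
#' @param max_dist match radius in pixels.
#' @return logical vector, one element per candidate.
#' @export
label_candidates <- function(candidates, truth, channel = 1L, max_dist = 2) {
  tr <- truth[truth$channel == channel, , drop = FALSE]
  if (!nrow(candidates)) return(logical(0))
  if (!nrow(tr)) return(rep(FALSE, nrow(candidates)))
  # bin truth points so each candidate only checks nearby bins
  cell <- max(max_dist, 1)
  bx <- floor(tr$x / cell); by <- floor(tr$y / cell)
  bins <- split(seq_len(nrow(tr)), paste(bx, by))
  cbx <- floor(candidates$x / cell); cby <- floor(candidates$y / cell)
  out <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    for (ox in -1:1) for (oy in -1:1) {
      js <- bins[[paste(cbx[i] + ox, cby[i] + oy)]]
      if (is.null(js)) next
      d2 <- (tr$x[js] - candidates$x[i])^2 + (tr$y[js] - candidates$y[i])^2
      if (any(d2 <= max_dist^2)) { out[i] <- TRUE; break }
    }
    if (out[i]) next
  }
  out
}

#' Train a punctum/background classifier
#'
#' Fits a random forest on candidate feature vectors with binary labels
#' (`TRUE` = true punctum). The training set must contain both classes.
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param labels logical vector, same length as `nrow(candidates)`.
#' @param seed integer seed making the fit reproducible.
#' @param ntree number of trees.
#' @return an object of class `punctum_classifier`.
#' @export
train_classifier <- function(candidates, labels, seed = 1L, ntree = 100L) {
  if (nrow(candidates) != length(labels))
    stopf("`labels` must have one entry per candidate")
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  if (length(unique(y[!is.na(y)])) < 2L)
    stopf("training set must contain both classes (puncta and background)")
  fm <- candidate_feature_matrix(candidates)
  fit <- with_seed(check_seed(seed),
                   randomForest::randomForest(fm, y, ntree = ntree))
  structure(list(model = fit, features = colnames(fm), seed = seed),
            class = "punctum_classifier")
}

#' Classify candidates into accepted puncta
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param classifier a [train_classifier()] result.
#' @param prob_threshold acceptance threshold on the punctum class
#'   probability.
#' @return the accepted subset of `candidates`, with a `prob` column.
#' @export
classify_candidates <- function(candidates, classifier,
                                prob_threshold = 0.5) {
  if (!inherits(classifier, "punctum_classifier"))
    stopf("`classifier` must be a punctum_classifier")
  if (!nrow(candidates)) {
    out <- candidates; out$prob <- numeric(0); return(out)
  }
  fm <- candidate_feature_matrix(candidates)[, classifier$features,
                                             drop = FALSE]
  p <- stats::predict(classifier$model, fm, type = "prob")[, "TRUE"]
  out <- candidates[p >= prob_threshold, , drop = FALSE]
  out$prob <- p[p >= prob_threshold]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve of classifier scores
#'
#' Rank-statistic (Mann-Whitney) form of the AUC; used to validate
#' punctum/background discrimination on held-out synthetic fields.
#'
#' @param scores numeric scores (higher = more punctum-like).
#' @param labels logical truth.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier scores for a candidate table
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param classifier a [train_classifier()] result.
#' @return numeric vector of punctum-class probabilities.
#' @export
classifier_scores <- function(candidates, classifier) {
  if (!nrow(candidates)) return(numeric(0))
  fm <- candidate_feature_matrix(candidates)[, classifier$features,
                                             drop = FALSE]
  stats::predict(classifier$model, fm, type = "prob")[, "TRUE"]
}
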