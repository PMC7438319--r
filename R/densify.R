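# Density algebra: colocalization-corrected total puncta density,
# 2D-to-3D conversion factors, brain-wide extrapolation and log-normal
# size-distribution fitting.

#' Total puncta density corrected for colocalization
#'
#' Puncta detected in both channels would be double counted by a naive
#' sum. With colocalization index `c` (fraction of entities present in
#' both channels), the total density satisfies
#' `dTotal = dPSD95 + dSAP102 - dColoc` with `dColoc = c * dTotal`,
#' giving `dTotal = (dPSD95 + dSAP102) / (1 + c)`.
#'
#' @param dPSD95,dSAP102 channel densities, puncta/100 um^2 (vectors
#'   allowed).
#' @param c colocalization index in \[0, 1\].
#' @param unit optional unit/section/region identifier(s).
#' @return data.frame (class `puncta_density_record`) with columns
#'   `unit`, `dPSD95`, `dSAP102`, `c`, `dColoc`, `dTotal`.
#' @export
total_density <- function(dPSD95, dSAP102, c, unit = NA_character_) {
  if (any(!is.finite(dPSD95)) || any(dPSD95 < 0) ||
      any(!is.finite(dSAP102)) || any(dSAP102 < 0))
    stopf("densities must be finite and >= 0")
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stopf("colocalization index must lie in [0, 1]")
  dTotal <- (dPSD95 + dSAP102) / (1 + c)
  out <- data.frame(unit = unit, dPSD95 = dPSD95, dSAP102 = dSAP102,
                    c = c, dColoc = c * dTotal, dTotal = dTotal)
  class(out) <- c("puncta_density_record", class(out))
  out
}

#' Conversion factor from 2D puncta density to 3D synapse density
#'
#' The calibrated quotient between the density of excitatory (asymmetric)
#' synapses measured volumetrically (synapses/um^3) and the total density
#' of puncta measured in 2D (puncta/100 um^2).
#'
#' @param as_density asymmetric synapse density, synapses/um^3.
#' @param d_total total puncta density, puncta/100 um^2 (> 0).
#' @param scope label for the factor's scope (layer id or "averaged").
#' @return object of class `conversion_factor`: list with `k` and
#'   `scope`.
#' @examples
#' conversion_factor(1.5958, 106.4372)  # k = 0.0150 (4 d.p.)
#' @export
conversion_factor <- function(as_density, d_total, scope = NA_character_) {
  check_number(as_density, "as_density", 0)
  check_number(d_total, "d_total", 0, strict_lower = TRUE)
  structure(list(k = as_density / d_total, scope = scope),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("conversion factor (%s): %.4f (synapses/um^3) per (puncta/100 um^2)\n",
              ifelse(is.na(x$scope), "unscoped", x$scope), x$k))
  invisible(x)
}

#' Average per-layer conversion factors
#'
#' The default estimator is the mean of the per-layer factors (each
#' computed from that layer's mean densities), matching how a
#' layer-averaged factor is tabulated alongside per-layer rows. A pooled
#' estimator — the quotient of the across-layer mean synapse density and
#' mean total puncta density — is available as an alternative.
#'
#' @param layer_factors list of [conversion_factor()] objects (or a
#'   numeric vector of k values) for `method = "mean"`.
#' @param method `"mean"` (default) or `"pooled"`.
#' @param as_densities,d_totals per-layer densities, required for
#'   `method = "pooled"`.
#' @return a `conversion_factor` with scope `"averaged"`.
#' @export
averaged_conversion_factor <- function(layer_factors = NULL,
                                       method = c("mean", "pooled"),
                                       as_densities = NULL,
                                       d_totals = NULL) {
  method <- match.arg(method)
  if (method == "mean") {
    ks <- vapply(layer_factors,
                 function(f) if (inherits(f, "conversion_factor")) f$k else as.numeric(f),
                 numeric(1))
    if (!length(ks)) stopf("no layer factors supplied")
    structure(list(k = mean(ks), scope = "averaged"),
              class = "conversion_factor")
  } else {
    if (is.null(as_densities) || is.null(d_totals))
      stopf("pooled averaging needs `as_densities` and `d_totals`")
    conversion_factor(mean(as_densities), mean(d_totals), scope = "averaged")
  }
}

#' Extrapolate synapse densities across regions
#'
#' Multiplies each region's total puncta density by a calibrated
#' conversion factor to obtain an estimated volumetric density of
#' synapses expressing at least one of the two markers. Because puncta
#' capture only labeled synapses, the outputs are flagged as minimum
#' estimates. Rows with a missing or invalid `dTotal` yield `NA` with a
#' warning, and the run continues.
#'
#' @param region_table data.frame with columns `region` and either
#'   `dTotal` or (`dPSD95`, `dSAP102`, `c`) from which `dTotal` is
#'   computed.
#' @param k a [conversion_factor()] or a plain number.
#' @return data.frame (class `region_estimate`) with columns `region`,
#'   `dTotal`, `est_density` (synapses/um^3) and `flag`
#'   (`"minimum estimate"`), sorted by `est_density` descending.
#' @export
apply_conversion <- function(region_table, k) {
  if (inherits(k, "conversion_factor")) k <- k$k
  check_number(k, "k", 0)
  if (!"dTotal" %in% names(region_table)) {
    if (!all(c("dPSD95", "dSAP102", "c") %in% names(region_table)))
      stopf("region table needs `dTotal` or (`dPSD95`, `dSAP102`, `c`) columns")
    region_table$dTotal <- (region_table$dPSD95 + region_table$dSAP102) /
      (1 + region_table$c)
  }
  bad <- !is.finite(region_table$dTotal) | region_table$dTotal < 0
  if (any(bad))
    warning(sprintf("%d region(s) had missing/invalid dTotal; estimates set to NA",
                    sum(bad)), call. = FALSE)
  est <- ifelse(bad, NA_real_, k * region_table$dTotal)
  out <- data.frame(region = region_table$region,
                    dTotal = region_table$dTotal,
                    est_density = est,
                    flag = rep_len("minimum estimate", nrow(region_table)))
  out <- out[order(-ifelse(is.na(out$est_density), -Inf, out$est_density)), ]
  rownames(out) <- NULL
  class(out) <- c("region_estimate", class(out))
  out
}

#' Maximum-likelihood log-normal fit of a size sample
#'
#' Synaptic sizes (punctum areas, SAS areas) follow log-normal
#' distributions; the ML estimates on the nm^2 scale are
#' `mu = mean(log x)` and `sigma = ` population standard deviation of
#' `log x`. Goodness of fit is reported descriptively via a one-sample
#' Kolmogorov-Smirnov statistic against the fitted distribution (note
#' that fitting and testing on the same sample makes the p-value
#' approximate).
#'
#' @param samples positive sizes (nm^2), n >= 2, non-degenerate.
#' @return object of class `lognormal_fit`: `mu`, `sigma`, `n`,
#'   `gof_stat`, `gof_p`.
#' @export
fit_lognormal <- function(samples) {
  if (length(samples) < 2L) stopf("need at least two samples")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stopf("all samples must be positive and finite")
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- pop_sd(lx)
  if (sigma <= 0) stopf("degenerate sample: zero variance on the log scale")
  ks <- suppressWarnings(stats::ks.test(samples, stats::plnorm,
                                        meanlog = mu, sdlog = sigma))
  structure(list(mu = mu, sigma = sigma, n = length(samples),
                 gof_stat = unname(ks$statistic), gof_p = ks$p.value),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("log-normal fit: mu = %.4f, sigma = %.4f (n = %d, KS D = %.4f, p = %.3g)\n",
              x$mu, x$sigma, x$n, x$gof_stat, x$gof_p))
  invisible(x)
}

#' Frequency histogram of a size sample
#'
#' Half-open bins `[lo, hi)` of fixed width starting at `origin`; counts
#' sum to the sample size.
#'
#' @param samples numeric sizes.
#' @param bin_width strictly positive bin width.
#' @param origin left edge of the first bin.
#' @return data.frame with columns `lo`, `hi`, `count` (empty input gives
#'   an empty table).
#' @export
size_histogram <- function(samples, bin_width, origin = 0) {
  check_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  if (!length(samples))
    return(data.frame(lo = numeric(), hi = numeric(), count = integer()))
  idx <- floor((samples - origin) / bin_width)
  rng <- range(idx)
  bins <- rng[1]:rng[2]
  counts <- tabulate(idx - rng[1] + 1L, nbins = length(bins))
  data.frame(lo = origin + bins * bin_width,
             hi = origin + (bins + 1) * bin_width,
             count = counts)
}
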