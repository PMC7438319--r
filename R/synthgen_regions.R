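# Synthetic per-region puncta-density tables.

#' Generate a synthetic brain-region puncta density table
#'
#' Emulates the structure of a per-region table of PSD95/SAP102 puncta
#' densities and colocalization indices, as used for brain-wide synapse
#' density extrapolation. In addition to `n_regions` random regions, the
#' table always contains two fixed fixture rows whose total puncta
#' densities are 19.78 and 110.15 puncta/100 um^2 — a low-density
#' thalamic-like region ("ventral-medial-like") and a high-density one
#' ("posterior-complex-like") — so regression tests have stable anchors.
#'
#' @param n_regions number of random regions (>= 1).
#' @param dpsd95_range,dsap102_range ranges of the channel densities
#'   (puncta/100 um^2).
#' @param coloc_range range of the colocalization index.
#' @param seed integer seed.
#' @return data.frame with columns `region`, `dPSD95`, `dSAP102`, `c`.
#' @export
make_region_table <- function(n_regions,
                              dpsd95_range = c(10, 130),
                              dsap102_range = c(10, 130),
                              coloc_range = c(0.3, 0.8),
                              seed = 1L) {
  if (!is.numeric(n_regions) || n_regions < 1)
    stopf("`n_regions` must be >= 1")
  n_regions <- as.integer(n_regions)
  with_seed(check_seed(seed), {
    d1 <- stats::runif(n_regions, dpsd95_range[1], dpsd95_range[2])
    d2 <- stats::runif(n_regions, dsap102_range[1], dsap102_range[2])
    cc <- stats::runif(n_regions, coloc_range[1], coloc_range[2])
    synth <- data.frame(region = sprintf("region-%03d", seq_len(n_regions)),
                        dPSD95 = d1, dSAP102 = d2, c = cc)
    # fixture rows: channel densities chosen so (d1 + d2) / (1 + c) hits
    # the anchor totals exactly
    fixture <- function(name, d_total, c) {
      s <- d_total * (1 + c)
      data.frame(region = name, dPSD95 = s * 0.55, dSAP102 = s * 0.45, c = c)
    }
    rbind(synth,
          fixture("ventral-medial-like", 19.78, 0.5),
          fixture("posterior-complex-like", 110.15, 0.5))
  })
}
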