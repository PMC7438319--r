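# End-to-end orchestration: simulate both microscopes, run detection and
# stereological counting, calibrate the 2D-to-3D conversion factor, and
# extrapolate synapse densities across regions.

#' Configuration for an end-to-end calibration run
#'
#' Describes a three-"layer" synthetic study mirroring the magnitudes of
#' a hippocampal CA1 calibration: per layer, the puncta channel densities
#' and colocalization index (the fluorescence side) and the volumetric
#' AS/SS densities (the EM side). Every stochastic stage derives its seed
#' deterministically from `seed` and the stage name, so a configuration
#' re-runs bit-identically.
#'
#' @param layers list of per-layer settings; each element is a list with
#'   `name`, `density_ch1`, `density_ch2`, `coloc_fraction`,
#'   `as_density`, `ss_density`. Defaults mirror the three CA1 strata
#'   (SLM/SR/SO-like magnitudes).
#' @param field_width,field_height,pixel_size fluorescence field
#'   geometry (um, um, nm).
#' @param n_fields fields per layer.
#' @param em_box EM sampling box per stack, um `c(x, y, z)`.
#' @param n_stacks EM stacks per layer.
#' @param frame_margin inset of the counting frame from the box faces
#'   (um), keeping whole objects inside.
#' @param em_mode `"population"` (count geometric records; fast,
#'   default) or `"voxel"` (render each counted synapse and classify its
#'   type from the voxel masks).
#' @param shrinkage_linear linear shrinkage factor applied to EM
#'   volumes. Synthetic volumes are generated unshrunken, so the default
#'   is 1 (no correction); set 0.9508-style values when emulating
#'   processed tissue.
#' @param noise_sd,amplitude_range imaging noise model passed to
#'   [puncta_field_spec()].
#' @param seed global integer seed.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(layers = NULL,
                               field_width = 43.008, field_height = 43.008,
                               pixel_size = 84, n_fields = 2L,
                               em_box = c(8, 8, 8), n_stacks = 2L,
                               frame_margin = 0.5,
                               em_mode = c("population", "voxel"),
                               shrinkage_linear = 1,
                               noise_sd = 60, amplitude_range = c(800, 4000),
                               seed = 1L) {
  em_mode <- match.arg(em_mode)
  if (is.null(layers)) {
    layers <- list(
      list(name = "SLM-like", density_ch1 = 91.3103, density_ch2 = 77.1788,
           coloc_fraction = 0.5840, as_density = 1.5958, ss_density = 0.13),
      list(name = "SR-like", density_ch1 = 118.4513, density_ch2 = 122.7022,
           coloc_fraction = 0.6633, as_density = 2.3076, ss_density = 0.06),
      list(name = "SO-like", density_ch1 = 119.7759, density_ch2 = 115.6872,
           coloc_fraction = 0.6741, as_density = 2.4887, ss_density = 0.05))
  }
  for (ly in layers) {
    if (!all(c("name", "density_ch1", "density_ch2", "coloc_fraction",
               "as_density") %in% names(ly)))
      stopf("each layer needs name, density_ch1, density_ch2, coloc_fraction, as_density")
  }
  structure(list(layers = layers,
                 field_width = field_width, field_height = field_height,
                 pixel_size = pixel_size, n_fields = as.integer(n_fields),
                 em_box = as.numeric(em_box), n_stacks = as.integer(n_stacks),
                 frame_margin = frame_margin, em_mode = em_mode,
                 shrinkage_linear = shrinkage_linear,
                 noise_sd = noise_sd,
                 amplitude_range = as.numeric(amplitude_range),
                 seed = check_seed(seed)),
            class = "calibration_config")
}

layer_field_spec <- function(config, ly, seed) {
  puncta_field_spec(field_width = config$field_width,
                    field_height = config$field_height,
                    pixel_size = config$pixel_size,
                    density_ch1 = ly$density_ch1,
                    density_ch2 = ly$density_ch2,
                    coloc_fraction = ly$coloc_fraction,
                    noise_sd = config$noise_sd,
                    amplitude_range = config$amplitude_range,
                    seed = seed)
}

#' Train a punctum classifier from synthetic training fields
#'
#' Generates one synthetic field per supplied spec, extracts low-threshold
#' candidates, labels them against the ground truth and fits the punctum
#' classifier on the pooled training set (both channels of every field).
#'
#' @param specs list of [puncta_field_spec()] objects.
#' @param seed integer seed for the classifier fit.
#' @param negatives_ratio cap on the number of background training
#'   candidates, as a multiple of the punctum candidates (the
#'   low-threshold detector yields far more noise maxima than puncta;
#'   capping keeps the fit fast without hurting discrimination).
#' @param ... forwarded to [detect_candidates()].
#' @return a `punctum_classifier`.
#' @export
train_classifier_from_specs <- function(specs, seed = 1L,
                                        negatives_ratio = 3, ...) {
  cands <- list(); labs <- list()
  for (sp in specs) {
    fld <- make_puncta_field(sp)
    for (ch in 1:2) {
      cand <- detect_candidates(fld$image[, , ch], ...)
      cands[[length(cands) + 1L]] <- cand
      labs[[length(labs) + 1L]] <- label_candidates(cand, fld$truth, ch)
    }
  }
  cand <- do.call(rbind, cands)
  lab <- unlist(labs)
  n_pos <- sum(lab)
  neg <- which(!lab)
  if (length(neg) > negatives_ratio * n_pos && n_pos > 0L) {
    keep_neg <- with_seed(derive_seed(seed, "negsub"),
                          sample(neg, negatives_ratio * n_pos))
    sel <- sort(c(which(lab), keep_neg))
    cand <- cand[sel, , drop = FALSE]; lab <- lab[sel]
  }
  train_classifier(cand, lab, seed = seed)
}

#' Run the end-to-end calibration pipeline
#'
#' For every configured layer: simulates fluorescence fields, detects and
#' measures puncta to obtain per-field channel densities and the
#' colocalization index, and combines them into the
#' colocalization-corrected total density; simulates EM-style synapse
#' populations, counts them in unbiased counting frames and converts to
#' volumetric densities; then computes per-layer conversion factors and
#' their average. Ground-truth factors are attached so that recovery can
#' be validated. Re-running the same configuration is bit-identical.
#'
#' @param config a [calibration_config()].
#' @param classifier optional pre-trained `punctum_classifier`; by
#'   default one is trained from a dedicated training field per layer.
#' @return object of class `calibration_report`: `per_field`,
#'   `per_stack`, `layers` (one row per layer with mean densities, c,
#'   dTotal, AS density and k), `averaged_k`, `truth` (per-layer and
#'   averaged ground-truth k), `seed`, `config_hash`, `shrinkage`.
#' @export
run_calibration <- function(config, classifier = NULL) {
  if (!inherits(config, "calibration_config"))
    stopf("`config` must be a calibration_config")
  t0 <- Sys.time()
  if (is.null(classifier)) {
    specs <- lapply(seq_along(config$layers), function(i)
      layer_field_spec(config, config$layers[[i]],
                       derive_seed(config$seed, paste0("train", i))))
    classifier <- train_classifier_from_specs(
      specs, seed = derive_seed(config$seed, "classifier"))
  }
  shr <- shrinkage_from_linear(config$shrinkage_linear)
  field_area <- config$field_width * config$field_height
  per_field <- list(); per_stack <- list(); layer_rows <- list()
  for (li in seq_along(config$layers)) {
    ly <- config$layers[[li]]
    # --- fluorescence side -------------------------------------------
    frows <- list()
    for (fi in seq_len(config$n_fields)) {
      sp <- layer_field_spec(config, ly,
                             derive_seed(config$seed,
                                         sprintf("field-%d-%d", li, fi)))
      fld <- make_puncta_field(sp)
      an <- analyze_field(fld$image, classifier, field_area,
                          config$pixel_size)
      rec <- total_density(an$density_ch1, an$density_ch2, an$coloc$c,
                           unit = sprintf("%s/field%d", ly$name, fi))
      rec$layer <- ly$name
      frows[[fi]] <- rec
    }
    frows <- do.call(rbind, frows)
    per_field[[li]] <- frows
    # --- EM side ------------------------------------------------------
    srows <- list()
    for (si in seq_len(config$n_stacks)) {
      es <- em_volume_spec(width = config$em_box[1],
                           height = config$em_box[2],
                           depth = config$em_box[3],
                           as_density = ly$as_density,
                           ss_density = if (is.null(ly$ss_density)) 0 else ly$ss_density,
                           seed = derive_seed(config$seed,
                                              sprintf("em-%d-%d", li, si)))
      pop <- make_em_population(es)
      m <- config$frame_margin
      frame <- counting_frame(rep(m, 3), config$em_box - 2 * m)
      counted <- count_in_frame(pop, frame)
      if (config$em_mode == "voxel" && length(counted)) {
        types <- vapply(counted, function(id) {
          msk <- render_synapse_masks(pop[id, ], es)
          as.character(classify_synapse_type(msk$pre, msk$post, es$voxel))
        }, character(1))
      } else {
        types <- pop$type[counted]
      }
      sd_rec <- synapse_density(sum(types == "AS"), sum(types == "SS"),
                                frame$volume, shrinkage = shr,
                                volume_is_corrected = config$shrinkage_linear == 1,
                                sample_id = sprintf("%s/stack%d", ly$name, si))
      sd_rec$layer <- ly$name
      srows[[si]] <- sd_rec
    }
    srows <- do.call(rbind, srows)
    per_stack[[li]] <- srows
    # --- layer summary ------------------------------------------------
    d1 <- mean(frows$dPSD95); d2 <- mean(frows$dSAP102)
    cbar <- mean(frows$c); dtot <- mean(frows$dTotal)
    asd <- mean(srows$density_AS)
    k <- if (dtot > 0) asd / dtot else NA_real_
    dtot_true <- (ly$density_ch1 + ly$density_ch2) / (1 + ly$coloc_fraction)
    layer_rows[[li]] <- data.frame(
      layer = ly$name, dPSD95 = d1, dSAP102 = d2, c = cbar, dTotal = dtot,
      density_AS = asd, k = k,
      dTotal_true = dtot_true, as_density_true = ly$as_density,
      k_true = ly$as_density / dtot_true)
  }
  layers <- do.call(rbind, layer_rows)
  ks <- layers$k[is.finite(layers$k)]
  averaged_k <- if (length(ks)) mean(ks) else NA_real_
  cfg_list <- unclass(config)
  structure(list(
    layers = layers,
    per_field = do.call(rbind, per_field),
    per_stack = do.call(rbind, per_stack),
    averaged_k = averaged_k,
    truth = list(k_layers = layers$k_true, averaged_k = mean(layers$k_true)),
    seed = config$seed,
    config_hash = config_hash(cfg_list),
    shrinkage = list(linear = shr$linear, volume = shr$volume,
                     direction = "in-vivo volume = measured volume / volume factor"),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("calibration report\n")
  print(x$layers[, c("layer", "dPSD95", "dSAP102", "c", "dTotal",
                     "density_AS", "k")], digits = 5)
  cat(sprintf("averaged k = %.4f (ground truth %.4f)\n",
              x$averaged_k, x$truth$averaged_k))
  invisible(x)
}

#' Write a calibration report to JSON
#'
#' The payload excludes timestamps, so identical configurations produce
#' byte-identical files; the config hash and the seed provide
#' provenance.
#'
#' @param report a `calibration_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  payload <- list(layers = report$layers,
                  per_field = report$per_field,
                  per_stack = report$per_stack,
                  averaged_k = report$averaged_k,
                  truth = report$truth,
                  seed = report$seed,
                  config_hash = report$config_hash,
                  shrinkage = report$shrinkage)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Brain-wide extrapolation of synapse densities
#'
#' Applies a calibrated conversion factor to a per-region puncta density
#' table and returns the estimates sorted in descending order, flagged
#' as minimum estimates (only marker-expressing synapses are counted).
#'
#' @param region_table data.frame with `region` and `dTotal` (or
#'   `dPSD95`, `dSAP102`, `c`).
#' @param k a [conversion_factor()], a `calibration_report` (its
#'   averaged k is used), or a plain number.
#' @param out optional CSV path; the file carries `# minimum estimate`
#'   and provenance comment lines ahead of the header.
#' @return a `region_estimate` data.frame (see [apply_conversion()]).
#' @export
run_brainwide <- function(region_table, k, out = NULL) {
  if (inherits(k, "calibration_report")) {
    if (!is.finite(k$averaged_k)) stopf("calibration report has no usable k")
    k <- k$averaged_k
  }
  if (inherits(k, "conversion_factor")) k <- k$k
  est <- apply_conversion(region_table, k)
  if (!is.null(out)) {
    con <- file(out, "w")
    writeLines(c("# synapdens region estimates",
                 "# flag: minimum estimate (marker-expressing synapses only)",
                 sprintf("# conversion factor k = %.6g (synapses/um^3 per puncta/100 um^2)", k)),
               con)
    utils::write.csv(est, con, row.names = FALSE)
    close(con)
  }
  est
}
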