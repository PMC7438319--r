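# Synthetic-data generators: validation, ground-truth bookkeeping,
# count laws, determinism.

test_that("puncta field spec validates its inputs", {
  expect_error(puncta_field_spec(density_ch1 = -1), "density_ch1")
  expect_error(puncta_field_spec(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(puncta_field_spec(pixel_size = 0), "pixel_size")
  # full colocalization is impossible with unequal channel densities
  expect_error(puncta_field_spec(density_ch1 = 100, density_ch2 = 50,
                                 coloc_fraction = 1), "infeasible")
  expect_error(make_puncta_field(list()), "puncta_field_spec")
})

test_that("zero-density field is pure background with no ground truth", {
  sp <- test_field_spec(seed = 1L, width = 5.376, density_ch1 = 0,
                        density_ch2 = 0, coloc_fraction = 0)
  fld <- make_puncta_field(sp)
  expect_identical(nrow(fld$truth), 0L)
  expect_equal(mean(fld$image[, , 1]), sp$background_level, tolerance = 0.05)
  expect_equal(sd(fld$image[, , 1]), sp$noise_sd, tolerance = 0.1)
})

test_that("full colocalization puts every entity in both channels", {
  sp <- test_field_spec(seed = 2L, width = 10.752, density_ch1 = 60,
                        density_ch2 = 60, coloc_fraction = 1)
  fld <- make_puncta_field(sp, render = FALSE)
  tab <- table(fld$truth$entity_id)
  expect_true(all(tab == 2L))
  expect_true(all(fld$truth$coloc))
  # colocalized partners sit within one pixel of each other
  ch1 <- fld$truth[fld$truth$channel == 1L, ]
  ch2 <- fld$truth[fld$truth$channel == 2L, ]
  ch2 <- ch2[match(ch1$entity_id, ch2$entity_id), ]
  expect_true(all(abs(ch1$x - ch2$x) <= 1 & abs(ch1$y - ch2$y) <= 1))
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- test_field_spec(seed = 11L, width = 5.376)
  a <- make_puncta_field(sp); b <- make_puncta_field(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  es <- em_volume_spec(width = 2, height = 2, depth = 1, seed = 5L)
  va <- make_em_volume(es); vb <- make_em_volume(es)
  expect_identical(va$volume, vb$volume)
  expect_identical(va$truth, vb$truth)
})

test_that("per-channel puncta counts follow the Poisson mean density x area", {
  # 100 puncta / 100 um^2 on a 43.008 um square field: area 1849.69 um^2,
  # so the expected count per field is 1849.69
  n <- vapply(1:50, function(s) {
    sp <- puncta_field_spec(density_ch1 = 100, density_ch2 = 0,
                            coloc_fraction = 0, seed = s)
    nrow(make_puncta_field(sp, render = FALSE)$truth)
  }, numeric(1))
  expected <- 100 / 100 * 43.008^2
  se <- sqrt(expected / 50)  # Poisson variance = mean
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("empirical colocalization fraction converges to the spec value", {
  f <- 0.5
  frac <- vapply(1:20, function(s) {
    sp <- test_field_spec(seed = s, width = 21.504, density_ch1 = 80,
                          density_ch2 = 80, coloc_fraction = f)
    tr <- make_puncta_field(sp, render = FALSE)$truth
    n_ent <- length(unique(tr$entity_id))
    sum(tr$coloc & tr$channel == 1L) / n_ent
  }, numeric(1))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - f), 3 * se + 1e-6)
})

test_that("em volume spec validates and empty densities give empty output", {
  expect_error(em_volume_spec(as_density = -1), "as_density")
  expect_error(em_volume_spec(width = 0), "width")
  es <- em_volume_spec(width = 1.5, height = 1.5, depth = 1,
                       as_density = 0, ss_density = 0, seed = 1L)
  v <- make_em_volume(es)
  expect_identical(nrow(v$truth), 0L)
  expect_true(all(v$volume == 0L))
})

test_that("ground-truth SAS areas reproduce the log-normal mean", {
  # mean of lognormal(10.54, 0.64) = exp(mu + sigma^2 / 2)
  es <- em_volume_spec(width = 13, height = 13, depth = 14,
                       as_density = 2.2, ss_density = 0, seed = 21L)
  pop <- make_em_population(es)
  expect_gte(nrow(pop), 5000)
  expected <- exp(10.54 + 0.64^2 / 2)
  se <- sd(pop$sas_area_nm2) / sqrt(nrow(pop))
  expect_lt(abs(mean(pop$sas_area_nm2) - expected), 3 * se)
})

test_that("synapse counts follow the Poisson mean density x volume", {
  # 2.5 AS / um^3 in a 500 um^3 box
  n <- vapply(1:20, function(s) {
    es <- em_volume_spec(width = 8, height = 8, depth = 7.8125,
                         as_density = 2.5, ss_density = 0, seed = s)
    nrow(make_em_population(es))
  }, numeric(1))
  se <- sqrt(1250 / 20)
  expect_lt(abs(mean(n) - 1250), 3 * se)
})

test_that("rendered label volumes separate pre and post components per synapse", {
  es <- em_volume_spec(width = 2, height = 2, depth = 1.2,
                       as_density = 2.5, ss_density = 0.5, seed = 9L)
  v <- make_em_volume(es)
  expect_gt(nrow(v$truth), 0)
  labs <- sort(unique(as.vector(v$volume)))
  labs <- labs[labs > 0]
  expect_true(all(labs %in% c(v$label_map$pre_label, v$label_map$post_label)))
  # every synapse rendered both components
  for (id in v$truth$id) {
    expect_true(any(v$volume == 2L * id - 1L))
    expect_true(any(v$volume == 2L * id))
  }
})

test_that("oversized volumes are refused instead of exhausting memory", {
  es <- em_volume_spec(seed = 1L)  # full-size default geometry
  expect_error(make_em_volume(es, max_voxels = 1e6), "max_voxels")
})

test_that("region tables carry the fixed fixture rows", {
  tb <- make_region_table(5, seed = 3L)
  expect_identical(nrow(tb), 7L)
  expect_true(all(c("region", "dPSD95", "dSAP102", "c") %in% names(tb)))
  dtot <- (tb$dPSD95 + tb$dSAP102) / (1 + tb$c)
  vm <- which(tb$region == "ventral-medial-like")
  pc <- which(tb$region == "posterior-complex-like")
  expect_equal(dtot[vm], 19.78, tolerance = 1e-9)
  expect_equal(dtot[pc], 110.15, tolerance = 1e-9)
  expect_error(make_region_table(0), "n_regions")
  expect_identical(make_region_table(3, seed = 8), make_region_table(3, seed = 8))
})
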