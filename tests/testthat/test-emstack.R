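# Stereological counting, shrinkage algebra, AS/SS classification and
# SAS area measurement.

test_that("shrinkage factors are the linear factor's powers", {
  s <- shrinkage_from_linear(0.9508)
  expect_equal(round(s$area, 4), 0.9040)
  expect_equal(round(s$volume, 4), 0.8595)
  s1 <- shrinkage_from_linear(1)
  expect_identical(c(s1$linear, s1$area, s1$volume), c(1, 1, 1))
  s9 <- shrinkage_from_linear(0.9)
  expect_equal(c(s9$area, s9$volume), c(0.81, 0.729))
  expect_error(shrinkage_from_linear(0), "linear")
  expect_error(shrinkage_from_linear(1.1), "linear")
})

test_that("counting frames validate geometry and face designations", {
  expect_error(counting_frame(c(0, 0, 0), c(1, 0, 1)), "positive")
  expect_error(counting_frame(c(0, 0), c(1, 1, 1)), "length 3")
  expect_error(counting_frame(c(0, 0, 0), c(1, 1, 1),
                              exclusion = c("mid", "high", "high")),
               "exclusion")
  fr <- counting_frame(c(1, 1, 1), c(2, 3, 4))
  expect_equal(fr$volume, 24)
})

test_that("brick rule counts interior objects and drops exclusion-face hits", {
  fr <- counting_frame(c(1, 1, 1), c(2, 2, 2))
  rec <- function(lo, hi) data.frame(xmin = lo[1], ymin = lo[2], zmin = lo[3],
                                     xmax = hi[1], ymax = hi[2], zmax = hi[3])
  inside <- rec(c(1.2, 1.2, 1.2), c(1.8, 1.8, 1.8))
  crossing_high <- rec(c(2.5, 1.5, 1.5), c(3.5, 1.8, 1.8))
  crossing_low <- rec(c(0.5, 1.5, 1.5), c(1.5, 1.8, 1.8))
  outside <- rec(c(5, 5, 5), c(6, 6, 6))
  recs <- rbind(inside, crossing_high, crossing_low, outside)
  counted <- count_in_frame(recs, fr)
  # inside: counted; crossing the high (exclusion) face: dropped;
  # crossing the low (inclusion) face: counted; far away: dropped
  expect_identical(counted, c(1L, 3L))
  expect_error(count_in_frame(recs, fr, volume_dim = c(2, 2, 2)),
               "outside the volume")
})

test_that("a tiling of frames counts every object exactly once", {
  es <- em_volume_spec(width = 6, height = 6, depth = 6,
                       as_density = 2.4, ss_density = 0.1, seed = 33L)
  pop <- make_em_population(es)
  # exhaustive oracle: the brick rule with high-face exclusion counts an
  # object in the unique tile holding its max corner
  tile <- 2
  total <- 0L
  for (ix in 0:2) for (iy in 0:2) for (iz in 0:2) {
    fr <- counting_frame(c(ix, iy, iz) * tile, rep(tile, 3))
    total <- total + length(count_in_frame(pop, fr))
  }
  oracle <- sum(pop$xmax < 6 & pop$ymax < 6 & pop$zmax < 6 &
                  pop$xmax >= 0 & pop$ymax >= 0 & pop$zmax >= 0)
  expect_identical(total, oracle)
})

test_that("synapse densities divide counts by the (corrected) frame volume", {
  d <- synapse_density(1000, 0, 500)
  expect_identical(d$density_AS, 2)
  # pooled magnitudes: 10,460 synapses in 4,905.07 um^3 of counting frames
  d2 <- synapse_density(10460, 0, 4905.07)
  expect_equal(round(d2$density_AS, 4), 2.1325)
  # raw volumes are corrected by dividing by the volume factor
  shr <- shrinkage_from_linear(0.9508)
  d3 <- synapse_density(100, 10, 100, shrinkage = shr,
                        volume_is_corrected = FALSE)
  expect_equal(d3$frame_volume, 100 / shr$volume)
  expect_equal(d3$density_total, 110 * shr$volume / 100)
  expect_equal(d3$density_total, d3$density_AS + d3$density_SS)
  expect_error(synapse_density(10, 0, 0), "frame_volume")
  expect_error(synapse_density(10, 0, 100, volume_is_corrected = FALSE),
               "shrinkage")
})

test_that("volumetric density is recovered from counting frames", {
  # estimate from an interior counting frame vs the realized
  # ground-truth density of the generated population
  diffs <- vapply(1:20, function(s) {
    es <- em_volume_spec(width = 6, height = 6, depth = 6,
                         as_density = 2.31, ss_density = 0, seed = 100 + s)
    pop <- make_em_population(es)
    fr <- counting_frame(c(0.5, 0.5, 0.5), c(5, 5, 5))
    length(count_in_frame(pop, fr)) / fr$volume - nrow(pop) / 216
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("plate thickness contrast separates AS from SS", {
  es <- em_volume_spec(seed = 1L)
  base <- data.frame(id = 1L, type = "AS", cx = 0, cy = 0, cz = 0,
                     nx = 0, ny = 0, nz = 1,
                     sas_area_nm2 = 50000)
  g <- cap_geometry(50000, es$dome_ratio)
  base$cap_a <- g$a; base$cap_h <- g$h
  # prominent 40 nm PSD vs 15 nm presynaptic plate -> asymmetric
  m_as <- render_synapse_masks(base, es)
  expect_identical(as.character(classify_synapse_type(m_as$pre, m_as$post,
                                                      es$voxel)), "AS")
  # thin 20 nm PSD (SS geometry) -> symmetric
  base_ss <- base; base_ss$type <- "SS"
  m_ss <- render_synapse_masks(base_ss, es)
  expect_identical(as.character(classify_synapse_type(m_ss$pre, m_ss$post,
                                                      es$voxel)), "SS")
  # tilted orientations classify the same way
  for (nv in list(c(1, 0, 0), c(1, 1, 1) / sqrt(3), c(0.3, 0.1, 0.95))) {
    b <- base; b$nx <- nv[1]; b$ny <- nv[2]; b$nz <- nv[3] / sqrt(sum(nv^2))
    nn <- nv / sqrt(sum(nv^2)); b$nx <- nn[1]; b$ny <- nn[2]; b$nz <- nn[3]
    m <- render_synapse_masks(b, es)
    expect_identical(as.character(classify_synapse_type(m$pre, m$post,
                                                        es$voxel)), "AS")
  }
  # missing components are an error
  empty <- array(FALSE, dim(m_as$post))
  expect_error(classify_synapse_type(empty, m_as$post, es$voxel), "empty")
  expect_error(classify_synapse_type(m_as$pre, empty, es$voxel), "empty")
})

test_that("SAS area is exact for flat axis-aligned appositions", {
  # 100 x 100 apposed xy faces at 5 nm pitch: 100 * 100 * 25 nm^2
  m <- flat_apposition_masks(nx = 100, ny = 100)
  s <- extract_sas(m$pre, m$post, voxel = c(5, 5, 20))
  expect_equal(s$area_nm2, 250000)
  expect_equal(abs(s$normal[3]), 1)
  # translation invariance
  m2 <- flat_apposition_masks(nx = 100, ny = 100, dims = c(120, 130, 15))
  s2 <- extract_sas(m2$pre, m2$post, voxel = c(5, 5, 20))
  expect_equal(s2$area_nm2, s$area_nm2)
})

test_that("SAS area tracks analytic areas for tilted planes and caps", {
  # plane tilted 30 degrees from the xy plane
  m <- tilted_apposition_masks(normal = c(sin(pi / 6), 0, cos(pi / 6)))
  s <- extract_sas(m$pre, m$post, m$voxel)
  expect_lt(abs(s$area_nm2 - m$true_area) / m$true_area, 0.10)
  # a steeper plane, tilted about both axes
  m3 <- tilted_apposition_masks(normal = c(0.5, 0.4, 0.76))
  s3 <- extract_sas(m3$pre, m3$post, m3$voxel)
  expect_lt(abs(s3$area_nm2 - m3$true_area) / m3$true_area, 0.10)
  # spherical cap: area 2 pi R h
  mc <- cap_apposition_masks(R_nm = 400, theta_deg = 40)
  sc <- extract_sas(mc$pre, mc$post, mc$voxel)
  expect_lt(abs(sc$area_nm2 - mc$true_area) / mc$true_area, 0.10)
})

test_that("SAS extraction fails cleanly without apposed faces", {
  m <- flat_apposition_masks(nx = 20, ny = 20, gap_layers = 5)
  expect_error(extract_sas(m$pre, m$post, voxel = c(5, 5, 20)),
               "no apposed")
  empty <- array(FALSE, dim(m$pre))
  expect_error(extract_sas(empty, m$post, c(5, 5, 20)), "non-empty")
})

test_that("measured SAS areas reproduce the generating log-normal", {
  es <- em_volume_spec(width = 4, height = 4, depth = 3.5,
                       as_density = 2.2, ss_density = 0, seed = 61L)
  pop <- make_em_population(es)
  areas <- vapply(seq_len(nrow(pop)), function(i) {
    msk <- render_synapse_masks(pop[i, ], es)
    extract_sas(msk$pre, msk$post, msk$voxel)$area_nm2
  }, numeric(1))
  fit <- fit_lognormal(areas)
  se_mu <- es$sas_sigma_as / sqrt(length(areas))
  expect_lt(abs(fit$mu - es$sas_mu_as), 3 * se_mu + 0.05)
  expect_lt(abs(fit$sigma - es$sas_sigma_as), 0.08)
})

test_that("classified AS fraction matches the synthesis mixture", {
  es <- em_volume_spec(width = 14.2, height = 14.2, depth = 14.2,
                       as_density = 1.9, ss_density = 1.9 * 0.044 / 0.956,
                       seed = 77L)
  pop <- make_em_population(es)
  expect_gte(nrow(pop), 5000)
  types <- vapply(seq_len(nrow(pop)), function(i) {
    msk <- render_synapse_masks(pop[i, ], es)
    as.character(classify_synapse_type(msk$pre, msk$post, msk$voxel))
  }, character(1))
  mix_true <- 0.956
  expect_lt(abs(mean(types == "AS") - mix_true), 0.02)
})
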