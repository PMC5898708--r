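test_that("default geometry partitions into exactly 46 place groups", {
  grp <- build_grouping(cochlea_geometry())
  expect_identical(nrow(grp), 46L)
  # non-overlapping cover of [0, 35] mm
  expect_equal(grp$lo[1], 0)
  expect_equal(grp$hi[46], 35)
  expect_equal(grp$lo[-1], grp$hi[-46], tolerance = 1e-12)
  # interior electrode groups are midpoint-bounded: 0.75 mm wide
  elec <- which(!is.na(grp$electrode))
  expect_identical(length(elec), 22L)
  expect_equal(grp$hi[elec] - grp$lo[elec], rep(0.75, 22), tolerance = 1e-12)
  # 12 beyond-array groups each side; terminal groups absorb the residual
  expect_identical(sum(is.na(grp$electrode) & grp$hi <= grp$lo[elec[1]] + 1e-9), 12L)
  expect_equal(grp$hi[1] - grp$lo[1], 1.0, tolerance = 1e-12)
  expect_equal(grp$hi[46] - grp$lo[46], 1.0, tolerance = 1e-12)
  # a geometry that cannot give 46 groups errors with the computed count
  expect_error(build_grouping(cochlea_geometry(pitch_mm = 1)), "groups")
})

test_that("empty rasters give an all-zero internal representation", {
  grp <- build_grouping(cochlea_geometry(n_fibers = 20))
  raster <- structure(
    list(spikes = rep(list(numeric(0)), 20),
         fiber_pos = cochlea_geometry(n_fibers = 20)$fiber_pos,
         duration = 0.1),
    class = "spike_raster"
  )
  ir <- integrate_spikes(raster, grp, ir_params())
  expect_identical(dim(ir), c(46L, 50L))
  expect_true(all(ir == 0))
})

test_that("a single spike relaxes with the integrator time constant", {
  g <- cochlea_geometry(n_fibers = 46)
  grp <- build_grouping(g)
  fg <- attr(grp, "fiber_group")
  raster <- structure(
    list(spikes = c(list(0.0205), rep(list(numeric(0)), 45)),
         fiber_pos = g$fiber_pos, duration = 0.2),
    class = "spike_raster"
  )
  pars <- ir_params(masking_strength = 0, gain = 1)
  ir <- integrate_spikes(raster, grp, pars)
  row <- fg[1]
  expect_true(all(ir[-row, ] == 0)) # response confined to the spike's group
  y <- ir[row, ]
  k <- which(y > 0)[1]
  beta <- exp(-2 / pars$integration_tau_ms)
  # impulse response of the leaky integrator: geometric decay
  expect_equal(y[k + 1:5] / y[k], beta^(1:5), tolerance = 1e-9)
})

test_that("forward masking suppresses the second of two close bursts", {
  g <- cochlea_geometry(n_fibers = 46)
  grp <- build_grouping(g)
  # 40 ms apart: the 10 ms integrator has relaxed (residual < 2%), but the
  # 100 ms masker trace is still at ~2/3 strength
  burst <- function(t0) t0 + seq(0, 0.004, by = 0.001)
  raster <- structure(
    list(spikes = c(list(c(burst(0.02), burst(0.06))),
                    rep(list(numeric(0)), 45)),
         fiber_pos = g$fiber_pos, duration = 0.12),
    class = "spike_raster"
  )
  row <- attr(grp, "fiber_group")[1]
  ir_on <- integrate_spikes(raster, grp, ir_params(masking_strength = 0.5))
  ir_off <- integrate_spikes(raster, grp, ir_params(masking_strength = 0))
  frames1 <- 10:18; frames2 <- 30:38
  peak1_on <- max(ir_on[row, frames1]); peak2_on <- max(ir_on[row, frames2])
  peak1_off <- max(ir_off[row, frames1]); peak2_off <- max(ir_off[row, frames2])
  expect_equal(peak2_off / peak1_off, 1, tolerance = 0.03) # without masking
  expect_lt(peak2_on, peak1_on)                            # with masking
  # masking attenuates the second response more than the first
  expect_lt(peak2_on / peak2_off, peak1_on / peak1_off)
})

test_that("internal noise is multiplicative, unbiased and independent", {
  ir <- matrix(10, 2, 2)
  expect_identical(apply_internal_noise(ir, 0, seed = 1), ir)
  draws <- vapply(1:10000, function(s) {
    apply_internal_noise(ir, 0.19, seed = s)[1, 1]
  }, numeric(1))
  expect_equal(mean(draws), 10, tolerance = 3 * 10 * 0.19 / sqrt(10000) / 10)
  expect_equal(sd(draws), 1.9, tolerance = 0.05 * 1.9)
  # independence across adjacent bins: correlation of multipliers ~ 0
  big <- matrix(1, 400, 250)
  noisy <- apply_internal_noise(big, 0.19, seed = 7)
  r_adj <- cor(as.numeric(noisy[-1, ]), as.numeric(noisy[-400, ]))
  expect_lt(abs(r_adj), 0.02)
  expect_error(apply_internal_noise(ir, -0.1), "sigma")
  # no clipping: negative bins pass through
  tiny <- matrix(0.1, 1, 1000)
  noisy2 <- apply_internal_noise(tiny * 100, 0.3, seed = 2)
  expect_true(any(noisy2 < 0) || min(noisy2) < 30) # heavy left tail retained
})

test_that("internal representations round-trip through delimited text", {
  g <- cochlea_geometry(n_fibers = 46)
  grp <- build_grouping(g)
  raster <- structure(
    list(spikes = c(list(c(0.01, 0.02)), rep(list(numeric(0)), 45)),
         fiber_pos = g$fiber_pos, duration = 0.05),
    class = "spike_raster"
  )
  ir <- integrate_spikes(raster, grp, ir_params(gain = 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ir(ir, path)
  back <- read_ir(path)
  expect_equal(unclass(back), unclass(ir), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(attr(back, "frame_rate"), 500)
  expect_identical(length(attr(back, "group_edges")), 47L)
})

test_that("gain calibration pins the 99th percentile at 50", {
  set.seed(5)
  irs <- lapply(1:5, function(i) matrix(rexp(46 * 100, rate = 0.5), 46))
  gain <- calibrate_gain(irs)
  vals <- unlist(lapply(irs, function(m) m * gain))
  expect_equal(quantile(vals, 0.99, names = FALSE), 50, tolerance = 1e-9)
  expect_identical(gain, calibrate_gain(irs)) # deterministic
  expect_error(calibrate_gain(matrix(0, 46, 10)), "silent")
})

test_that("pipeline calibration hits the amplitude contract, level-dependent", {
  corp <- tiny_corpus()
  cfg <- ci_config("desk")
  gain <- calibrate_pipeline_gain(corp, cfg, seed = 1, min_duration_s = 4)
  cfg$gain <- gain
  sent <- corpus_sentences(corp, 6, seed = 3)
  irs <- lapply(seq_len(6), function(i) {
    frontend_ir(sent$signal[[i]], cfg, seed = i)
  })
  q99 <- quantile(unlist(irs), 0.99, names = FALSE)
  expect_gt(q99, 40)
  expect_lt(q99, 60)
  # doubling the input level lowers the calibrated gain
  corp2 <- corp
  corp2$utterances$signal <- lapply(corp$utterances$signal, function(s) 2 * s)
  gain2 <- calibrate_pipeline_gain(corp2, ci_config("desk"), seed = 1,
                                   min_duration_s = 4)
  expect_lt(gain2, gain)
})
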