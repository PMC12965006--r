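test_that("filament generation is seeded, contained and evenly sampled", {
  fil <- make_filaments(3, fov_nm = 5000, seed = 42)
  expect_identical(fil, make_filaments(3, fov_nm = 5000, seed = 42))
  expect_equal(length(unique(fil$structure_id)), 3)
  expect_true(all(fil$x_nm > 0 & fil$x_nm < 5000 &
                    fil$y_nm > 0 & fil$y_nm < 5000))
  # arc-length spacing close to the requested sampling
  one <- fil[fil$structure_id == 1, ]
  steps <- sqrt(diff(one$x_nm)^2 + diff(one$y_nm)^2)
  expect_lt(abs(median(steps) - 5) / 5, 0.05)
})

test_that("blob generation is seeded, contained and radius-controlled", {
  blb <- make_blobs(5, radius_range_nm = c(100, 250), fov_nm = 5000, seed = 1)
  expect_identical(blb, make_blobs(5, radius_range_nm = c(100, 250),
                                   fov_nm = 5000, seed = 1))
  expect_true(all(blb$x_nm > 0 & blb$x_nm < 5000))
  expect_true(all(blb$radius_nm >= 100 & blb$radius_nm <= 250))
  # shell points sit on their ellipse: within the radius from the center
  for (i in unique(blb$structure_id)) {
    b <- blb[blb$structure_id == i, ]
    d <- sqrt((b$x_nm - mean(b$x_nm))^2 + (b$y_nm - mean(b$y_nm))^2)
    expect_lte(max(d), b$radius_nm[1] + 1)
  }
  # radius draw matches the uniform oracle over many structures
  set.seed(2)
  many <- make_blobs(200, radius_range_nm = c(100, 250), fov_nm = 20000,
                     seed = 3)
  radii <- tapply(many$radius_nm, many$structure_id, function(r) r[1])
  expect_lt(abs(mean(radii) - 175), 10)
})

test_that("blink sampling respects sparsity, budgets and structure geometry", {
  fil <- make_straight_filament(fov_nm = 3000, length_nm = 2000)
  ev <- sample_blinks(fil, frames = 2000, mean_signal = 5000,
                      mean_background = 10000, linker_jitter_nm = 5,
                      sparsity = 2, seed = 9, photon_cv = 0.3)
  expect_identical(ev, sample_blinks(fil, frames = 2000, mean_signal = 5000,
                                     mean_background = 10000,
                                     linker_jitter_nm = 5, sparsity = 2,
                                     seed = 9, photon_cv = 0.3))
  # counting oracle: events/frame ~ Poisson(2)
  n_per_frame <- tabulate(ev$frame, nbins = 2000)
  expect_lt(abs(mean(n_per_frame) - 2), 3 * sqrt(2 / 2000))
  # photon budget: lognormal with the requested mean
  expect_lt(abs(mean(ev$n_signal) - 5000) / 5000, 0.03)
  expect_true(all(ev$n_background == 10000))
  # every event stays within linker + filament radius of the structure line
  dev <- abs(ev$y_nm - 1500)
  expect_lte(max(dev), 12.5 + 5 * 5)
  expect_gt(sd(dev), 5)   # the radial offset actually spreads the labels
  # dye composition inherited exactly
  expect_true(all(ev$dye == "AF647"))
  expect_error(sample_blinks(fil[0, ], frames = 10, sparsity = 1),
               "no structures")
})

test_that("blink photon budgets can be fixed for sweep-style runs", {
  fil <- make_straight_filament()
  ev <- sample_blinks(fil, frames = 300, mean_signal = 3000, sparsity = 1,
                      seed = 5, photon_cv = 0)
  expect_true(all(ev$n_signal == 3000))
})
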