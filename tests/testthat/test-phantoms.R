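test_that("fluorescence fields honour the empty case and determinism", {
  spec0 <- fluor_phantom_spec(n_cells = 0, noise_sd = 5, poisson_noise = FALSE,
                              field_size = c(64, 64), seed = 1)
  f0 <- make_fluor_field(spec0)
  expect_equal(nrow(f0$truth), 0)
  expect_lt(abs(mean(f0$red) - spec0$background), 3)
  expect_lt(sd(f0$red), 3 * spec0$noise_sd)

  spec <- fluor_phantom_spec(n_cells = 6, seed = 9, field_size = c(256, 256))
  f1 <- make_fluor_field(spec)
  f2 <- make_fluor_field(spec)
  expect_identical(f1$green, f2$green)
  expect_identical(f1$red, f2$red)
  expect_identical(f1$truth, f2$truth)
  expect_true(all(f1$red >= 0 & f1$red <= spec$saturation))
})

test_that("fluorescence truth respects the phenotype mix and separation", {
  spec <- fluor_phantom_spec(n_cells = 10, phenotype_mix = 0.5, seed = 3)
  f <- make_fluor_field(spec)
  expect_equal(nrow(f$truth), 10)
  expect_equal(sum(f$truth$phenotype == "fused"), 5)
  expect_true(all(f$truth$n_vesicles[f$truth$phenotype == "partial"] >= 2))
  d <- as.matrix(dist(f$truth[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 2 * mean(spec$cell_radius_range))
  expect_error(make_fluor_field(fluor_phantom_spec(n_cells = 200,
                                                   field_size = c(256, 256))),
               "separation")
})

test_that("tomography phantom masks are mutually consistent", {
  spec <- tomo_phantom_spec(seed = 11, noise_sd = 0)
  ph <- make_tomo_phantom(spec)
  expect_true(all(ph$masks$droplet <= ph$masks$cell))
  expect_true(all(ph$masks$vacuole <= ph$masks$cell))
  # an inside droplet's own sphere is contained in the vacuole mask
  for (i in which(ph$truth$inside)) {
    tr <- ph$truth[i, ]
    dmask <- yeastvac:::sphere_mask(spec$volume_size, c(tr$z, tr$y, tr$x), tr$radius)
    expect_equal(dmask & ph$masks$vacuole, dmask)
  }
  # gray ordering holds in the noise-free rendering
  lv <- spec$absorption_levels
  vol <- ph$volume$voxels
  expect_equal(max(vol), unname(lv["droplet"]))
  expect_equal(min(vol), unname(lv["background"]))
  expect_true(all(vol[ph$masks$droplet] == lv["droplet"]))

  # same seed -> identical volume
  ph2 <- make_tomo_phantom(spec)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
})

test_that("inside fraction 0 places no droplet center in a vacuole", {
  ph <- make_tomo_phantom(tomo_phantom_spec(droplets_inside_fraction = 0,
                                            seed = 21))
  expect_gt(nrow(ph$truth), 0)
  expect_false(any(ph$truth$inside))
})

test_that("voxelized spheres match the analytic volume", {
  sp <- yeastvac:::sphere_mask(c(44, 44, 44), c(22, 22, 22), 10)
  expect_lt(abs(sum(sp) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("absorption ordering is validated", {
  expect_error(tomo_phantom_spec(absorption_levels = c(droplet = 0.3,
                                                       membrane = 0.65,
                                                       cytosol = 0.35,
                                                       lumen = 0.12,
                                                       background = 0.05)),
               "ordering")
})
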