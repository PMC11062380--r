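sphere3 <- function(d, ctr, r) yeastvac:::sphere_mask(d, ctr, r)

mesh_of_sphere <- function(r, pad = 4, voxel = 19.6, smooth = 0,
                           center_off = c(0, 0, 0)) {
  n <- 2 * (r + pad)
  ctr <- rep(r + pad, 3) + center_off
  lab <- array(as.integer(sphere3(c(n, n, n), ctr, r)), c(n, n, n))
  labels_to_meshes(lab, voxel, smooth_iters = smooth)[[1]]
}

test_that("isosurface meshes are watertight with one mesh per label", {
  m <- mesh_of_sphere(8)
  # closed surface: every edge shared by exactly two faces
  e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))

  d <- c(30, 30, 30)
  lab <- array(0L, d)
  lab[sphere3(d, c(9, 9, 9), 5)] <- 1L
  lab[sphere3(d, c(21, 21, 21), 6)] <- 2L
  meshes <- labels_to_meshes(lab, 19.6, smooth_iters = 0)
  expect_length(meshes, 2)
  expect_equal(vapply(meshes, function(x) x$id, numeric(1)), c(1, 2))
})

test_that("mesh volume matches the analytic sphere within 2 percent", {
  m <- mesh_of_sphere(20)
  analytic <- 4 / 3 * pi * (20 * 19.6 / 1000)^3
  expect_lt(abs(mesh_volume(m) - analytic) / analytic, 0.02)

  # translation invariance and cubic scaling
  m2 <- m; m2$vertices <- m2$vertices + 5
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-9)
  m3 <- m; m3$vertices <- m3$vertices * 2
  expect_equal(mesh_volume(m3), 8 * mesh_volume(m), tolerance = 1e-9)
})

test_that("smoothing at default settings preserves volume within 5 percent", {
  m0 <- mesh_of_sphere(12, smooth = 0)
  ms <- smooth_mesh(m0, iterations = 10, relax = 0.5)
  expect_lt(abs(mesh_volume(ms) - mesh_volume(m0)) / mesh_volume(m0), 0.05)
})

test_that("centers of mass match the voxel-mean oracle and equivariance", {
  d <- c(30, 30, 30)
  ball <- sphere3(d, c(14, 15, 16), 7)
  m <- labels_to_meshes(array(as.integer(ball), d), 19.6, smooth_iters = 0)[[1]]
  com_mesh <- center_of_mass(m) / (19.6 / 1000)
  com_vox <- center_of_mass(ball)
  expect_lt(max(abs(com_mesh - com_vox)), 1)
  expect_lt(max(abs(com_vox - c(14, 15, 16))), 0.1)
  m2 <- m; m2$vertices <- sweep(m2$vertices, 2, c(1, 2, 3), `+`)
  expect_equal(center_of_mass(m2), center_of_mass(m) + c(1, 2, 3),
               tolerance = 1e-9)
})

test_that("droplet-vacuole distance follows collinear sphere geometry", {
  vx <- 19.6 / 1000
  d <- c(44, 44, 44)
  vac <- labels_to_meshes(array(as.integer(sphere3(d, c(22, 22, 22), 18)), d),
                          19.6, smooth_iters = 0, channel = "vacuole")[[1]]
  dro_in <- labels_to_meshes(array(as.integer(sphere3(d, c(22, 22, 22), 8)), d),
                             19.6, smooth_iters = 0, channel = "droplet")[[1]]
  expect_equal(droplet_vacuole_distance(dro_in, vac), 0)

  d2 <- c(48, 48, 48)
  dro <- labels_to_meshes(array(as.integer(sphere3(d2, c(12, 12, 12), 5)), d2),
                          19.6, smooth_iters = 0, channel = "droplet")[[1]]
  vac2 <- labels_to_meshes(array(as.integer(sphere3(d2, c(12, 12, 34), 10)), d2),
                           19.6, smooth_iters = 0, channel = "vacuole")[[1]]
  # centers 22 apart, radii 5 and 10; voxelized surfaces sit ~0.5 voxel
  # outside the nominal radius
  gap_vox <- droplet_vacuole_distance(dro, vac2) / vx
  expect_lt(abs(gap_vox - 6), 1)
})

test_that("consumption and contact calls agree with voxel-containment oracles", {
  set.seed(12)
  d <- c(36, 36, 36)
  agree <- 0; n_cases <- 60
  for (i in seq_len(n_cases)) {
    rv <- runif(1, 8, 12)
    rd <- runif(1, 3, 5)
    off <- runif(1, 0, 16)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    vac_ctr <- c(18, 18, 18)
    dro_ctr <- vac_ctr + off * u
    vmask <- sphere3(d, vac_ctr, rv)
    dmask <- sphere3(d, dro_ctr, rd)
    if (sum(dmask) < 8) next
    vm <- labels_to_meshes(array(as.integer(vmask), d), 19.6,
                           smooth_iters = 0, channel = "vacuole")[[1]]
    dm <- labels_to_meshes(array(as.integer(dmask), d), 19.6,
                           smooth_iters = 0, channel = "droplet")[[1]]
    # voxel oracle: is the droplet's voxel centroid inside the vacuole mask?
    com <- round(center_of_mass(dmask))
    oracle <- vmask[com[1], com[2], com[3]]
    if (is_consumed(dm, vm) == oracle) agree <- agree + 1
    cp <- contact_percent(dm, vm)
    expect_true(cp >= 0 && cp <= 100)
    if (oracle) expect_equal(cp, 100)
    # detached well beyond the contact epsilon (plus voxelization slack)
    if (off > rv + rd + 4) expect_equal(cp, 0)
  }
  expect_gte(agree / n_cases, 0.95)
})

test_that("droplet analytics record the expected consumption pattern", {
  expect_equal(nrow(analyze_droplets(list(), list())), 0)

  # 3 droplets inside the vacuole, 2 outside, constructed directly
  d <- c(40, 56, 56)
  vac <- sphere3(d, c(20, 24, 24), 14)
  centers_in <- list(c(20, 24, 24), c(16, 20, 22), c(24, 28, 26))
  centers_out <- list(c(20, 24, 46), c(20, 46, 24))
  lab <- array(0L, d)
  for (i in seq_along(centers_in)) lab[sphere3(d, centers_in[[i]], 3.5)] <- i
  for (i in seq_along(centers_out)) lab[sphere3(d, centers_out[[i]], 3.5)] <- 3L + i
  dm <- labels_to_meshes(lab, 19.6, smooth_iters = 0, channel = "droplet")
  vm <- labels_to_meshes(array(as.integer(vac), d), 19.6, smooth_iters = 0,
                         channel = "vacuole")
  rec <- analyze_droplets(dm, vm, condition = "phantom")
  expect_equal(sum(rec$consumed), 3)
  expect_equal(sum(!rec$consumed), 2)
  expect_true(all(rec$contact_percent[rec$consumed] == 100))
  expect_true(all(rec$distance_um[rec$consumed] == 0))
  expect_true(all(rec$distance_um[!rec$consumed] > 0))
  expect_true(all(rec$volume_um3 > 0))

  # no vacuole: fields unavailable
  rec0 <- analyze_droplets(dm, list(), condition = "edge")
  expect_true(all(is.na(rec0$distance_um)))
  expect_true(all(is.na(rec0$consumed)))

  # identical volume samples: Mann-Whitney p = 1 under tie handling
  cmp <- compare_droplet_volumes(rec, rec)
  expect_equal(cmp$p_mannwhitney, 1)
})
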