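ring_image <- function(h, w, center, radius, amp = 500, bg = 50) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  d <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
  matrix(bg + amp * exp(-(d - radius)^2 / (2 * 2^2)), h, w)
}

test_that("cell detection finds synthetic rings at their centers", {
  params <- hough_params(radius_min = 15, radius_max = 25,
                         peak_min_distance = 40, saturation = 2047)
  expect_equal(nrow(detect_cells(matrix(7, 128, 128), params)), 0)

  one <- ring_image(128, 160, c(60, 80), 20)
  det <- detect_cells(one, params)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det[1, "row"] - 60)^2 + (det[1, "col"] - 80)^2), 3)

  two <- ring_image(200, 200, c(60, 60), 20) +
    ring_image(200, 200, c(60, 180), 20) - 50
  det2 <- detect_cells(two, params)
  expect_equal(nrow(det2), 2)
  for (ctr in list(c(60, 60), c(60, 180)))
    expect_lt(min(sqrt((det2[, "row"] - ctr[1])^2 + (det2[, "col"] - ctr[2])^2)), 3)

  expect_error(detect_cells(matrix(rnorm(100), 10, 10), params), "radius")
})

test_that("detection on generated fields recovers the truth centers", {
  # recall >= 0.9 with center error <= 5 px, averaged over 5 seeds
  recall <- c(); cerr <- c()
  for (s in 1:5) {
    f <- make_fluor_field(fluor_phantom_spec(n_cells = 10, phenotype_mix = 0.5,
                                             seed = s))
    det <- detect_cells(f$red, hough_params())
    hits <- 0
    for (i in seq_len(nrow(f$truth))) {
      d <- sqrt((det[, "row"] - f$truth$row[i])^2 +
                  (det[, "col"] - f$truth$col[i])^2)
      if (length(d) > 0 && min(d) <= 5) {
        hits <- hits + 1
        cerr <- c(cerr, min(d))
      }
    }
    recall <- c(recall, hits / nrow(f$truth))
  }
  expect_gte(mean(recall), 0.9)
  expect_lte(mean(cerr), 5)
})

test_that("ROI extraction pads borders, normalizes and keeps every center", {
  params <- hough_params(roi_size_px = 100, roi_out_px = 64, saturation = 2047)
  img <- matrix(runif(300 * 300, 0, 2047), 300, 300)
  centers <- rbind(c(1, 1), c(150, 150), c(299, 299))
  rois <- extract_rois(list(img, img), centers, params)
  expect_length(rois, nrow(centers))
  for (r in rois) {
    expect_equal(dim(r$pixels), c(64, 64, 2))
    expect_true(all(r$pixels >= 0 & r$pixels <= 1))
  }
  # uniform field at saturation -> ROI of all ones
  sat <- matrix(2047, 300, 300)
  r1 <- extract_rois(list(sat), rbind(c(150, 150)), params)[[1]]
  expect_equal(r1$pixels[, , 1], matrix(1, 64, 64))
  expect_length(extract_rois(list(img), matrix(numeric(0), 0, 2), params), 0)

  # color-merged alternative: (red, green, empty blue)
  g <- matrix(100, 300, 300); r <- matrix(900, 300, 300)
  rgb <- extract_rois(list(g, r), rbind(c(150, 150)), params,
                      merge = "rgb")[[1]]
  expect_equal(dim(rgb$pixels)[3], 3)
  expect_equal(unique(as.vector(rgb$pixels[, , 1])), 900 / 2047)
  expect_equal(unique(as.vector(rgb$pixels[, , 2])), 100 / 2047)
  expect_true(all(rgb$pixels[, , 3] == 0))
  expect_error(extract_rois(list(g), rbind(c(150, 150)), params,
                            merge = "rgb"), "green and red")
})
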