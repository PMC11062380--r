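#' Specification of a synthetic two-channel fluorescence field
#'
#' Describes a wide-field image of stationary-phase yeast with the
#' vacuole membrane stained in the red channel and lipid droplets in the
#' green channel. A fully fused cell renders one bright ring (the single
#' central vacuole); a partially fused cell renders two or more tangent
#' smaller rings (a multi-vesicular vacuole). Droplets are bright puncta
#' in the green channel.
#'
#' Defaults emulate an automated 100x wide-field acquisition with a
#' 12-bit camera: 512 x 512 fields, cell radii 18-26 px, saturation 2047.
#'
#' @param field_size `(H, W)` in pixels.
#' @param n_cells Number of cells to place.
#' @param phenotype_mix Fraction of cells that are fully fused.
#' @param cell_radius_range Cell radius range in pixels.
#' @param vesicle_count_range Vesicle count range for partially fused
#'   cells (minimum 2).
#' @param droplet_count_range Droplets per cell.
#' @param droplet_radius_range Droplet radius range in pixels.
#' @param noise_sd Gaussian read-noise standard deviation (camera counts).
#' @param background Background level (camera counts).
#' @param saturation Camera saturation intensity (2047 for the 12-bit
#'   acquisition, 7500 for the alternative setup).
#' @param poisson_noise Add Poisson shot noise before the Gaussian term.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A validated list of class `fluor_phantom_spec`.
#' @export
fluor_phantom_spec <- function(field_size = c(512, 512), n_cells = 12,
                               phenotype_mix = 0.5,
                               cell_radius_range = c(18, 26),
                               vesicle_count_range = c(2, 4),
                               droplet_count_range = c(1, 5),
                               droplet_radius_range = c(2, 4),
                               noise_sd = 15, background = 80,
                               saturation = 2047, poisson_noise = TRUE,
                               seed = 1) {
  check_number(n_cells, "n_cells", 0, integer = TRUE)
  check_number(phenotype_mix, "phenotype_mix", 0, 1)
  check_range(cell_radius_range, "cell_radius_range", min = 1)
  check_range(vesicle_count_range, "vesicle_count_range", min = 2)
  check_range(droplet_count_range, "droplet_count_range", min = 0)
  check_range(droplet_radius_range, "droplet_radius_range", min = 0.5)
  check_number(noise_sd, "noise_sd", 0)
  check_number(background, "background", 0)
  check_number(saturation, "saturation", 1)
  structure(as.list(environment()), class = "fluor_phantom_spec")
}

# Add a Gaussian-profile ring (membrane cross-section) to an image.
render_ring <- function(img, center, radius, amplitude, width = 2) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(radius + 4 * width)
  rows <- clamp(round(center[1]) + (-r:r), 1, h)
  cols <- clamp(round(center[2]) + (-r:r), 1, w)
  rows <- unique(rows); cols <- unique(cols)
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  d <- sqrt(dr^2 + dc^2)
  img[rows, cols] <- img[rows, cols] + amplitude * exp(-(d - radius)^2 / (2 * width^2))
  img
}

# Add a Gaussian spot (droplet punctum).
render_spot <- function(img, center, radius, amplitude) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * radius)
  rows <- unique(clamp(round(center[1]) + (-r:r), 1, h))
  cols <- unique(clamp(round(center[2]) + (-r:r), 1, w))
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  img[rows, cols] <- img[rows, cols] + amplitude * exp(-(dr^2 + dc^2) / (2 * (radius / 1.5)^2))
  img
}

# Rejection-sample cell centers with a minimum separation.
place_centers <- function(n, h, w, radius_max, min_sep, max_tries = 2000) {
  centers <- matrix(0, 0, 2)
  margin <- radius_max + 2
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop2("could not place ", n, " cells with minimum separation ",
            round(min_sep), " px in a ", h, " x ", w, " field")
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2, byrow = TRUE))^2)) >= min_sep))
      centers <- rbind(centers, cand)
  }
  centers
}

#' Generate a synthetic two-channel fluorescence field
#'
#' @param spec A [fluor_phantom_spec()].
#' @return A list with `green` and `red` image matrices (camera counts,
#'   clipped to `[0, saturation]`) and `truth`, a data frame with one row
#'   per cell: `cell`, `row`, `col`, `radius`, `phenotype`
#'   (`"fused"`/`"partial"`), `n_vesicles`, `n_droplets`.
#' @export
make_fluor_field <- function(spec) {
  stopifnot(inherits(spec, "fluor_phantom_spec"))
  h <- spec$field_size[1]; w <- spec$field_size[2]
  with_seed(spec$seed, {
    red <- matrix(0, h, w); green <- matrix(0, h, w)
    truth <- data.frame(cell = integer(), row = numeric(), col = numeric(),
                        radius = numeric(), phenotype = character(),
                        n_vesicles = integer(), n_droplets = integer())
    if (spec$n_cells > 0) {
      min_sep <- 2 * mean(spec$cell_radius_range) * 1.05
      centers <- place_centers(spec$n_cells, h, w, spec$cell_radius_range[2], min_sep)
      n_fused <- round(spec$phenotype_mix * spec$n_cells)
      pheno <- rep(c("fused", "partial"), c(n_fused, spec$n_cells - n_fused))
      pheno <- sample(pheno)
      for (i in seq_len(spec$n_cells)) {
        cr <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        ctr <- centers[i, ]
        amp <- runif(1, 600, 1000)
        # faint cell outline (membrane background staining) at the cell
        # radius: the circle the Hough search interval targets
        red <- render_ring(red, ctr, cr, amp * 0.35, width = 1.5)
        if (pheno[i] == "fused") {
          vr <- cr * runif(1, 0.55, 0.75)
          off <- runif(2, -0.1, 0.1) * cr
          red <- render_ring(red, ctr + off, vr, amp)
          nv <- 1L
        } else {
          nv <- sample(seq(spec$vesicle_count_range[1], spec$vesicle_count_range[2]), 1)
          vr <- cr * runif(1, 0.28, 0.38)
          # vesicles tangent around an inner circle
          phi0 <- runif(1, 0, 2 * pi)
          ring_r <- vr / max(sin(pi / nv), 0.5)
          for (v in seq_len(nv)) {
            ang <- phi0 + 2 * pi * (v - 1) / nv
            vc <- ctr + ring_r * c(cos(ang), sin(ang))
            red <- render_ring(red, vc, vr, amp * runif(1, 0.8, 1.1))
          }
        }
        nd <- sample(seq(spec$droplet_count_range[1], spec$droplet_count_range[2]), 1)
        for (dd in seq_len(nd)) {
          dr <- runif(1, spec$droplet_radius_range[1], spec$droplet_radius_range[2])
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0.2, 0.85) * cr
          green <- render_spot(green, ctr + rad * c(cos(ang), sin(ang)), dr,
                               runif(1, 500, 900))
        }
        truth <- rbind(truth, data.frame(
          cell = i, row = ctr[1], col = ctr[2], radius = cr,
          phenotype = pheno[i], n_vesicles = nv, n_droplets = nd))
      }
    }
    finish <- function(img) {
      img <- img + spec$background
      if (spec$poisson_noise) img <- matrix(rpois(length(img), pmax(img, 0)), h, w)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), h, w)
      clamp(img, 0, spec$saturation)
    }
    list(green = finish(green), red = finish(red), truth = truth)
  })
}
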