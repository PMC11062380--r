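#' Specification of a 3D soft X-ray tomography phantom
#'
#' Describes a reconstructed-tomogram-like volume of ellipsoidal yeast
#' cells, each containing a low-absorbing vacuole (an inner ellipsoid)
#' and dark spherical lipid droplets. The gray convention is "higher =
#' more absorbing", so droplets are the brightest structures, membranes
#' intermediate, cytosol lower and the water-filled vacuole lumen lowest.
#' Two-voxel membrane shells around the cell and the vacuole give
#' edge-sensitive downstream steps realistic gradients.
#'
#' @param volume_size `(Z, Y, X)` in voxels.
#' @param voxel_size_nm Isotropic voxel size (default 19.6 nm).
#' @param n_cells Number of cells.
#' @param cell_axes_range Range of cell semi-axes in voxels.
#' @param vacuole_axes_range Range of vacuole semi-axes in voxels.
#' @param droplet_count_range Droplets per cell.
#' @param droplet_radius_range Droplet radius range in voxels.
#' @param droplets_inside_fraction Fraction of droplets whose center lies
#'   strictly inside the vacuole (consumed droplets).
#' @param absorption_levels Named gray levels; the ordering
#'   `droplet > membrane > cytosol > lumen > background` is enforced.
#' @param noise_sd Additive Gaussian noise after level assignment.
#' @param seed RNG seed.
#' @return A validated list of class `tomo_phantom_spec`.
#' @export
tomo_phantom_spec <- function(volume_size = c(48, 112, 112),
                              voxel_size_nm = 19.6, n_cells = 2,
                              cell_axes_range = c(15, 19),
                              vacuole_axes_range = c(9, 13),
                              droplet_count_range = c(2, 3),
                              droplet_radius_range = c(2.5, 4),
                              droplets_inside_fraction = 0.5,
                              absorption_levels = c(droplet = 1, membrane = 0.65,
                                                    cytosol = 0.35, lumen = 0.12,
                                                    background = 0.05),
                              noise_sd = 0.03, seed = 1) {
  if (length(volume_size) != 3L) stop2("'volume_size' must be (Z, Y, X)")
  check_number(n_cells, "n_cells", 0, integer = TRUE)
  check_range(cell_axes_range, "cell_axes_range", min = 2)
  check_range(vacuole_axes_range, "vacuole_axes_range", min = 2)
  check_range(droplet_count_range, "droplet_count_range", min = 0)
  check_range(droplet_radius_range, "droplet_radius_range", min = 1)
  check_number(droplets_inside_fraction, "droplets_inside_fraction", 0, 1)
  lv <- absorption_levels
  need <- c("droplet", "membrane", "cytosol", "lumen", "background")
  if (!all(need %in% names(lv))) stop2("absorption_levels must name ", paste(need, collapse = ", "))
  if (!(lv["droplet"] > lv["membrane"] && lv["membrane"] > lv["cytosol"] &&
        lv["cytosol"] > lv["lumen"] && lv["lumen"] > lv["background"]))
    stop2("absorption ordering droplet > membrane > cytosol > lumen > background violated")
  check_number(noise_sd, "noise_sd", 0)
  structure(as.list(environment()), class = "tomo_phantom_spec")
}

# Filled ellipsoid mask on the (z, y, x) grid.
ellipsoid_mask <- function(dim_zyx, center, axes) {
  z <- (seq_len(dim_zyx[1]) - center[1]) / axes[1]
  y <- (seq_len(dim_zyx[2]) - center[2]) / axes[2]
  x <- (seq_len(dim_zyx[3]) - center[3]) / axes[3]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= 1
}

sphere_mask <- function(dim_zyx, center, radius) {
  ellipsoid_mask(dim_zyx, center, rep(radius, 3))
}

inside_ellipsoid <- function(p, center, axes, shrink = 0) {
  sum(((p - center) / (axes - shrink))^2) < 1
}

#' Generate a 3D tomography phantom with full ground truth
#'
#' @param spec A [tomo_phantom_spec()].
#' @return A list with `volume` (a [tomogram_stack()]), `masks` (binary
#'   `(z, y, x)` arrays `cell`, `vacuole`, `droplet`), and `truth`, a data
#'   frame with one droplet per row: `cell`, `droplet`, center `(z, y,
#'   x)`, `radius`, `inside` (center strictly inside the vacuole) plus,
#'   as attributes, the per-cell geometry.
#' @export
make_tomo_phantom <- function(spec) {
  stopifnot(inherits(spec, "tomo_phantom_spec"))
  d <- spec$volume_size
  lv <- spec$absorption_levels
  with_seed(spec$seed, {
    vol <- array(lv[["background"]], d)
    cell_mask <- array(FALSE, d); vac_mask <- array(FALSE, d)
    drop_mask <- array(FALSE, d)
    truth <- NULL; cells <- NULL
    if (spec$n_cells > 0) {
      # place non-overlapping cells
      centers <- NULL; axes_list <- list()
      for (i in seq_len(spec$n_cells)) {
        ok <- FALSE
        for (try in 1:500) {
          ax <- runif(3, spec$cell_axes_range[1], spec$cell_axes_range[2])
          ax[1] <- min(ax[1], (d[1] - 6) / 2)  # fit the z extent
          ctr <- c(runif(1, ax[1] + 2, d[1] - ax[1] - 2),
                   runif(1, ax[2] + 2, d[2] - ax[2] - 2),
                   runif(1, ax[3] + 2, d[3] - ax[3] - 2))
          if (is.null(centers) ||
              all(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 3, byrow = TRUE))^2)) >
                  max(ax) + max(unlist(lapply(axes_list, max))) + 2)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop2("could not place ", spec$n_cells, " non-overlapping cells in the volume")
        centers <- rbind(centers, ctr); axes_list[[i]] <- ax
      }
      for (i in seq_len(spec$n_cells)) {
        ctr <- centers[i, ]; ax <- axes_list[[i]]
        cmask <- ellipsoid_mask(d, ctr, ax)
        cinner <- ellipsoid_mask(d, ctr, ax - 2)       # 2-voxel membrane shell
        vax <- runif(3, spec$vacuole_axes_range[1], spec$vacuole_axes_range[2])
        vax <- pmin(vax, (ax - 4) * 0.85)
        voff <- runif(3, -0.15, 0.15) * ax
        vctr <- ctr + voff
        if (!inside_ellipsoid(vctr, ctr, ax - 4 - vax)) vctr <- ctr
        vmask <- ellipsoid_mask(d, vctr, vax)
        vinner <- ellipsoid_mask(d, vctr, vax - 2)
        vol[cmask & !cinner] <- lv[["membrane"]]
        vol[cinner] <- lv[["cytosol"]]
        vol[vmask & !vinner & cinner] <- lv[["membrane"]]
        vol[vinner] <- lv[["lumen"]]
        cell_mask <- cell_mask | cmask
        vac_mask <- vac_mask | vmask
        nd <- sample(seq(spec$droplet_count_range[1], spec$droplet_count_range[2]), 1)
        if (nd > 0) {
          n_in <- round(spec$droplets_inside_fraction * nd)
          placed <- matrix(numeric(0), 0, 4)  # z, y, x, r
          for (k in seq_len(nd)) {
            want_inside <- k <= n_in
            ok <- FALSE
            for (try in 1:2000) {
              r <- if (try > 500) spec$droplet_radius_range[1]
                   else runif(1, spec$droplet_radius_range[1], spec$droplet_radius_range[2])
              if (want_inside) {
                if (all(vax - 1 - r <= 0.5)) next
                u <- runif(3, -1, 1); if (sum(u^2) > 1) next
                p <- vctr + u * pmax(vax - 1 - r, 0.5)
                if (!inside_ellipsoid(p, vctr, vax, shrink = 0)) next
              } else {
                u <- runif(3, -1, 1); if (sum(u^2) > 1) next
                p <- ctr + u * pmax(ax - 1.5 - r, 1)
                # center outside the vacuole (docking contact allowed)
                if (inside_ellipsoid(p, vctr, vax + 0.5)) next
                if (!inside_ellipsoid(p, ctr, ax, shrink = 1.5 + r)) next
              }
              if (nrow(placed) > 0 &&
                  any(sqrt(rowSums((placed[, 1:3, drop = FALSE] -
                                    matrix(p, nrow(placed), 3, byrow = TRUE))^2)) <
                      placed[, 4] + r + 2)) next
              ok <- TRUE; break
            }
            if (!ok) stop2("could not place droplet ", k, " in cell ", i,
                           ": geometry infeasible")
            placed <- rbind(placed, c(p, r))
            dmask <- sphere_mask(d, p, r)
            vol[dmask] <- lv[["droplet"]]
            drop_mask <- drop_mask | dmask
            truth <- rbind(truth, data.frame(
              cell = i, droplet = nrow(placed), z = p[1], y = p[2], x = p[3],
              radius = r, inside = inside_ellipsoid(p, vctr, vax)))
          }
        }
        cells <- rbind(cells, data.frame(
          cell = i, z = ctr[1], y = ctr[2], x = ctr[3],
          az = ax[1], ay = ax[2], ax_ = ax[3],
          vz = vctr[1], vy = vctr[2], vx = vctr[3],
          vaz = vax[1], vay = vax[2], vax_ = vax[3]))
      }
    }
    if (is.null(truth))
      truth <- data.frame(cell = integer(), droplet = integer(), z = numeric(),
                          y = numeric(), x = numeric(), radius = numeric(),
                          inside = logical())
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), d)
    attr(truth, "cells") <- cells
    list(volume = tomogram_stack(vol, spec$voxel_size_nm, id = "phantom"),
         masks = list(cell = cell_mask, vacuole = vac_mask, droplet = drop_mask),
         truth = truth)
  })
}
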