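# Surface meshing of label volumes and droplet/vacuole morphometry.
# Meshes are closed, consistently outward-oriented triangle surfaces;
# vertices are stored in micrometres, axis order (z, y, x) matching the
# volume layout (documented in the exporters).

# 6-tetrahedra (Kuhn) decomposition of the unit cube around the main
# diagonal c0-c7; corner id = dz + 2*dy + 4*dx. The same decomposition in
# every cube makes shared faces conforming, so meshes are watertight.
TET_DECOMP <- matrix(c(0, 5, 1, 7,
                       0, 1, 3, 7,
                       0, 3, 2, 7,
                       0, 2, 6, 7,
                       0, 6, 4, 7,
                       0, 4, 5, 7) + 1, ncol = 4, byrow = TRUE)
CORNER_OFF <- cbind(dz = c(0, 1, 0, 1, 0, 1, 0, 1),
                    dy = c(0, 0, 1, 1, 0, 0, 1, 1),
                    dx = c(0, 0, 0, 0, 1, 1, 1, 1))
TET_EDGES <- matrix(c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4), ncol = 2, byrow = TRUE)

# For each of the 16 inside-patterns of a tetrahedron, the triangles as
# triples of tet-edge ids (orientation fixed numerically afterwards).
tet_case_table <- function() {
  edge_id <- function(a, b) which(TET_EDGES[, 1] == min(a, b) & TET_EDGES[, 2] == max(a, b))
  tab <- vector("list", 16)
  for (code in 0:15) {
    inside <- which(bitwAnd(code, 2^(0:3)) > 0)
    outside <- setdiff(1:4, inside)
    tris <- list()
    if (length(inside) == 1) {
      a <- inside
      e <- vapply(outside, function(o) edge_id(a, o), numeric(1))
      tris <- list(e)
    } else if (length(inside) == 3) {
      a <- outside
      e <- vapply(inside, function(o) edge_id(a, o), numeric(1))
      tris <- list(e)
    } else if (length(inside) == 2) {
      a <- inside[1]; b <- inside[2]; cc <- outside[1]; dd <- outside[2]
      tris <- list(c(edge_id(a, cc), edge_id(a, dd), edge_id(b, dd)),
                   c(edge_id(a, cc), edge_id(b, dd), edge_id(b, cc)))
    }
    tab[[code + 1]] <- tris
  }
  tab
}
TET_CASES <- tet_case_table()

# Isosurface of a binary volume at level 0.5 via marching tetrahedra.
# Returns vertices in voxel coordinates (z, y, x; voxel centers at
# integers) and outward-oriented faces.
mesh_from_mask <- function(mask) {
  d <- dim(mask)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(mask != 0)
  dp <- dim(pad)
  # mixed cubes: corner sum strictly between 0 and 8
  zc <- seq_len(dp[1] - 1); yc <- seq_len(dp[2] - 1); xc <- seq_len(dp[3] - 1)
  csum <- array(0L, c(length(zc), length(yc), length(xc)))
  for (k in seq_len(8)) {
    o <- CORNER_OFF[k, ]
    csum <- csum + pad[zc + o[1], yc + o[2], xc + o[3], drop = FALSE]
  }
  mixed <- which(csum > 0 & csum < 8, arr.ind = TRUE)
  if (nrow(mixed) == 0)
    return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(numeric(0), 0, 3)))
  # corner coordinates and values for all mixed cubes
  ncube <- nrow(mixed)
  corner_val <- matrix(0L, ncube, 8)
  for (k in seq_len(8)) {
    o <- CORNER_OFF[k, ]
    corner_val[, k] <- pad[cbind(mixed[, 1] + o[1], mixed[, 2] + o[2], mixed[, 3] + o[3])]
  }
  vkey <- character(0)
  tri_a <- tri_b <- tri_c <- character(0)
  # accumulate triangles tet by tet, vectorized over cubes per case
  for (t in seq_len(6)) {
    slots <- TET_DECOMP[t, ]
    vals <- corner_val[, slots, drop = FALSE]
    code <- vals %*% 2^(0:3)
    for (cs in setdiff(unique(as.vector(code)), c(0, 15))) {
      rows <- which(code == cs)
      tris <- TET_CASES[[cs + 1]]
      inside <- which(bitwAnd(cs, 2^(0:3)) > 0)
      outside <- setdiff(1:4, inside)
      # corner coordinates (cube origin + offset), per slot
      slot_coord <- lapply(1:4, function(s) {
        o <- CORNER_OFF[slots[s], ]
        cbind(mixed[rows, 1] + o[1], mixed[rows, 2] + o[2], mixed[rows, 3] + o[3])
      })
      in_cent <- Reduce(`+`, slot_coord[inside]) / length(inside)
      out_cent <- Reduce(`+`, slot_coord[outside]) / length(outside)
      ref <- out_cent - in_cent
      edge_mid <- function(eid) {
        e <- TET_EDGES[eid, ]
        (slot_coord[[e[1]]] + slot_coord[[e[2]]]) / 2
      }
      for (tri in tris) {
        p1 <- edge_mid(tri[1]); p2 <- edge_mid(tri[2]); p3 <- edge_mid(tri[3])
        u <- p2 - p1; v <- p3 - p1
        nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                     u[, 3] * v[, 1] - u[, 1] * v[, 3],
                     u[, 1] * v[, 2] - u[, 2] * v[, 1])
        flip <- rowSums(nrm * ref) < 0
        key <- function(p) sprintf("%d_%d_%d", as.integer(round(2 * p[, 1])),
                                   as.integer(round(2 * p[, 2])),
                                   as.integer(round(2 * p[, 3])))
        k1 <- key(p1); k2 <- key(p2); k3 <- key(p3)
        a <- ifelse(flip, k1, k1); b <- ifelse(flip, k3, k2); cc <- ifelse(flip, k2, k3)
        tri_a <- c(tri_a, a); tri_b <- c(tri_b, b); tri_c <- c(tri_c, cc)
      }
    }
  }
  keys <- unique(c(tri_a, tri_b, tri_c))
  km <- do.call(rbind, strsplit(keys, "_"))
  verts <- matrix(as.numeric(km), ncol = 3) / 2
  # un-pad: coordinates back to the original voxel grid
  verts <- verts - 1
  idx <- stats::setNames(seq_along(keys), keys)
  faces <- cbind(idx[tri_a], idx[tri_b], idx[tri_c])
  dimnames(faces) <- NULL
  list(vertices = verts, faces = faces)
}

#' Laplacian smoothing of a triangle mesh
#'
#' Each iteration moves every vertex a fraction `relax` of the way to the
#' centroid of its edge neighbours.
#'
#' @param mesh A `triangle_mesh` (or a list with `vertices`, `faces`).
#' @param iterations Number of iterations (default 10).
#' @param relax Relaxation factor in `(0, 1]` (default 0.5).
#' @return The smoothed mesh.
#' @export
smooth_mesh <- function(mesh, iterations = 10, relax = 0.5) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0 || iterations <= 0) return(mesh)
  e1 <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  e2 <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  deg <- tabulate(e1, nbins = nrow(v))
  for (it in seq_len(iterations)) {
    nb <- rowsum(v[e2, , drop = FALSE], e1, reorder = TRUE)
    cent <- nb / deg
    v <- (1 - relax) * v + relax * cent
  }
  mesh$vertices <- v
  mesh
}

#' Meshes of every instance in a label volume
#'
#' Extracts one closed triangle mesh per label at isolevel 0.5 of the
#' label's indicator (marching-tetrahedra isosurface on the conforming
#' 6-tet cube decomposition), optionally Laplacian-smoothed, with vertex
#' coordinates scaled to micrometres.
#'
#' @param labels Integer `(z, y, x)` label array.
#' @param voxel_size_nm Voxel edge length in nanometres.
#' @param smooth_iters Laplacian smoothing iterations (default 10;
#'   0 = off).
#' @param relax Smoothing relaxation factor.
#' @param channel Channel role recorded in each mesh.
#' @return A list of `triangle_mesh` objects (fields: `vertices` in
#'   micrometres, `(z, y, x)` columns; `faces`; `id`; `channel`).
#' @export
labels_to_meshes <- function(labels, voxel_size_nm = 19.6, smooth_iters = 10,
                             relax = 0.5, channel = "object") {
  nlab <- max(labels)
  out <- list()
  for (lb in seq_len(nlab)) {
    m <- mesh_from_mask(labels == lb)
    if (nrow(m$faces) == 0) next
    mesh <- structure(list(vertices = m$vertices, faces = m$faces,
                           id = lb, channel = channel,
                           voxel_size_nm = voxel_size_nm),
                      class = "triangle_mesh")
    if (smooth_iters > 0) mesh <- smooth_mesh(mesh, smooth_iters, relax)
    mesh$vertices <- mesh$vertices * voxel_size_nm / 1000  # to micrometres
    out[[length(out) + 1]] <- mesh
  }
  out
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh (%s #%s): %d vertices, %d faces, volume %.4g um^3\n",
              x$channel, x$id, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem (signed tetrahedra) volume; the absolute value is
#' returned, in the cube of the vertex unit (micrometres cubed for
#' package meshes).
#'
#' @param mesh A `triangle_mesh`.
#' @return Volume as a single number.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6
}

#' Center of mass of a mesh or voxel set
#'
#' For a closed mesh the volume-weighted centroid (signed tetrahedra);
#' for a logical array or index matrix the voxel mean.
#'
#' @param x A `triangle_mesh`, a logical `(z, y, x)` array, or an `n x 3`
#'   coordinate matrix.
#' @return A length-3 point (same axis order and units as the input).
#' @export
center_of_mass <- function(x) {
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices; f <- x$faces
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    cent <- (a + b + cc) / 4  # tetrahedron centroid with the origin
    colSums(cent * det6) / sum(det6)
  } else if (is.array(x) && length(dim(x)) == 3) {
    colMeans(which(x != 0, arr.ind = TRUE))
  } else {
    colMeans(as.matrix(x))
  }
}

# All ray parameters t where origin + t * dir crosses mesh triangles
# (Moller-Trumbore, vectorized over faces).
ray_mesh_t <- function(mesh, origin, dir, eps = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cross_v <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                  u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                  u[, 1] * w[, 2] - u[, 2] * w[, 1])
  dmat <- matrix(dir, nrow(f), 3, byrow = TRUE)
  p <- cross_v(dmat, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > eps
  tvec <- matrix(origin, nrow(f), 3, byrow = TRUE) - a
  u <- rowSums(tvec * p) / det
  q <- cross_v(tvec, e1)
  vv <- rowSums(dmat * q) / det
  t <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9
  sort(t[hit])
}

# Parity point-in-mesh test along a fixed skew direction.
point_in_mesh <- function(mesh, point) {
  dir <- c(0.577215, 0.618034, 0.532088)
  dir <- dir / sqrt(sum(dir^2))
  t <- ray_mesh_t(mesh, point, dir)
  sum(t > 1e-9) %% 2 == 1
}

#' Is a droplet consumed by a vacuole?
#'
#' A droplet counts as consumed (a lipophagy event) when its center of
#' mass is enclosed by the vacuole's closed surface.
#'
#' @param droplet,vacuole `triangle_mesh` objects.
#' @return Logical.
#' @export
is_consumed <- function(droplet, vacuole) {
  point_in_mesh(vacuole, center_of_mass(droplet))
}

#' Distance from a droplet to the vacuolar membrane
#'
#' Casts the ray from the droplet's center of mass toward the vacuole's
#' center of mass and measures the gap between the droplet-surface exit
#' point and the vacuole-surface entry point along it. Returns 0 when the
#' droplet lies inside the vacuole or the surfaces overlap along the ray.
#' If the ray misses the vacuole surface entirely (pathological
#' concavity) the nearest-vertex distance is returned with attribute
#' `fallback = TRUE`.
#'
#' @param droplet,vacuole Watertight `triangle_mesh` objects.
#' @return Distance in micrometres.
#' @export
droplet_vacuole_distance <- function(droplet, vacuole) {
  o <- center_of_mass(droplet)
  target <- center_of_mass(vacuole)
  if (point_in_mesh(vacuole, o)) return(0)
  dir <- target - o
  nl <- sqrt(sum(dir^2))
  if (nl < 1e-12) return(0)
  dir <- dir / nl
  t_drop <- ray_mesh_t(droplet, o, dir)
  t_vac <- ray_mesh_t(vacuole, o, dir)
  exit_t <- if (length(t_drop[t_drop > 1e-9]) > 0) max(t_drop[t_drop > 1e-9]) else 0
  entry <- t_vac[t_vac > 1e-9]
  if (length(entry) == 0) {
    dmin <- min(sqrt(colSums((t(vacuole$vertices) - o)^2)))
    out <- max(dmin, 0)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  max(min(entry) - exit_t, 0)
}

face_centroids_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  list(centroid = (a + b + cc) / 3, area = sqrt(rowSums(cr^2)) / 2)
}

#' Percentage of a droplet's surface in contact with a vacuole
#'
#' A consumed droplet is in full contact by definition (100). Otherwise
#' the area-weighted fraction of droplet faces whose centroid lies inside
#' the vacuole or within `epsilon` of its surface is returned, as a
#' percentage; a detached droplet scores 0.
#'
#' @param droplet,vacuole `triangle_mesh` objects.
#' @param epsilon Contact tolerance in micrometres (default: two voxel
#'   lengths of the droplet mesh).
#' @return A number in `[0, 100]`.
#' @export
contact_percent <- function(droplet, vacuole,
                            epsilon = 2 * droplet$voxel_size_nm / 1000) {
  if (is_consumed(droplet, vacuole)) return(100)
  fc <- face_centroids_areas(droplet)
  vv <- vacuole$vertices
  # nearest-vertex distance, chunked
  n <- nrow(fc$centroid)
  dmin <- numeric(n)
  chunk <- 512
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    d2 <- outer(rowSums(fc$centroid[idx, , drop = FALSE]^2), rowSums(vv^2), `+`) -
      2 * fc$centroid[idx, , drop = FALSE] %*% t(vv)
    dmin[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  touching <- dmin <= epsilon
  if (!any(touching)) {
    # no centroid near the surface; check straddling via parity only for
    # the nearest centroid (cheap early exit for detached droplets)
    if (!point_in_mesh(vacuole, fc$centroid[which.min(dmin), ])) return(0)
  }
  maybe_inside <- which(!touching)
  inside <- logical(n)
  for (i in maybe_inside)
    inside[i] <- point_in_mesh(vacuole, fc$centroid[i, ])
  contact <- touching | inside
  100 * sum(fc$area[contact]) / sum(fc$area)
}

#' Per-droplet lipophagy morphometry
#'
#' For every droplet mesh: volume, the nearest vacuole (by
#' center-of-mass distance), distance to the vacuolar membrane, whether
#' it is consumed and the percentage of surface contact. Cells without a
#' segmented vacuole yield records with the vacuole-dependent fields
#' marked unavailable (`NA`).
#'
#' @param droplets List of droplet `triangle_mesh` objects.
#' @param vacuoles List of vacuole `triangle_mesh` objects (possibly
#'   empty).
#' @param condition Condition label recorded per row.
#' @param epsilon Contact tolerance in micrometres (see
#'   [contact_percent()]).
#' @return A data frame with columns `droplet`, `volume_um3`, `vacuole`,
#'   `distance_um`, `consumed`, `contact_percent`, `condition`,
#'   `distance_fallback`.
#' @export
analyze_droplets <- function(droplets, vacuoles, condition = "sample",
                             epsilon = NULL) {
  if (length(droplets) == 0)
    return(data.frame(droplet = integer(), volume_um3 = numeric(),
                      vacuole = integer(), distance_um = numeric(),
                      consumed = logical(), contact_percent = numeric(),
                      condition = character(), distance_fallback = logical()))
  vac_com <- if (length(vacuoles) > 0)
    t(vapply(vacuoles, center_of_mass, numeric(3))) else NULL
  rows <- lapply(seq_along(droplets), function(i) {
    dm <- droplets[[i]]
    vol <- mesh_volume(dm)
    if (is.null(vac_com)) {
      return(data.frame(droplet = i, volume_um3 = vol, vacuole = NA_integer_,
                        distance_um = NA_real_, consumed = NA,
                        contact_percent = NA_real_, condition = condition,
                        distance_fallback = FALSE))
    }
    com <- center_of_mass(dm)
    dc <- sqrt(rowSums((vac_com - matrix(com, nrow(vac_com), 3, byrow = TRUE))^2))
    nv <- which.min(dc)
    vm <- vacuoles[[nv]]
    cons <- is_consumed(dm, vm)
    dist <- if (cons) 0 else droplet_vacuole_distance(dm, vm)
    eps <- if (is.null(epsilon)) 2 * dm$voxel_size_nm / 1000 else epsilon
    cp <- if (cons) 100 else contact_percent(dm, vm, eps)
    data.frame(droplet = i, volume_um3 = vol, vacuole = nv,
               distance_um = as.numeric(dist), consumed = cons,
               contact_percent = cp, condition = condition,
               distance_fallback = isTRUE(attr(dist, "fallback")))
  })
  do.call(rbind, rows)
}

#' Compare droplet volume distributions between conditions
#'
#' Wilcoxon rank-sum (Mann-Whitney U) and Kolmogorov-Smirnov tests on the
#' per-droplet volumes of two record tables.
#'
#' @param records_a,records_b Data frames from [analyze_droplets()].
#' @return A list with the sample sizes, medians and both p-values.
#' @export
compare_droplet_volumes <- function(records_a, records_b) {
  va <- records_a$volume_um3; vb <- records_b$volume_um3
  mw <- suppressWarnings(wilcox.test(va, vb))
  ks <- suppressWarnings(ks.test(va, vb))
  list(n = c(length(va), length(vb)),
       median_um3 = c(median(va), median(vb)),
       p_mannwhitney = mw$p.value, p_ks = ks$p.value)
}
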