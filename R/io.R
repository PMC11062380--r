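# Stack and table I/O. TIFF stacks go through the tiff package (one page
# per z-slice, 32-bit float); MRC mode-2 (float32) volumes are read and
# written directly (1024-byte header, voxel size in the cell dimensions).

#' Read a volume stack from TIFF or MRC
#'
#' @param path File path; format chosen by extension (`.tif`/`.tiff` or
#'   `.mrc`/`.rec`).
#' @param voxel_size_nm Voxel size override; required for TIFF (no
#'   standard voxel metadata) unless a default is acceptable, and
#'   optional for MRC (header value used when `NULL`).
#' @param invert Negate intensities for data recorded with the opposite
#'   gray convention (package convention: higher = more absorbing).
#' @return A [tomogram_stack()].
#' @export
read_stack <- function(path, voxel_size_nm = NULL, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(voxel_size_nm))
      stop2("voxel_size_nm must be given for TIFF stacks (no voxel metadata)")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vol <- array(0, c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  } else if (ext %in% c("mrc", "rec")) {
    mrc <- read_mrc(path)
    vol <- mrc$volume
    if (is.null(voxel_size_nm)) voxel_size_nm <- mrc$voxel_size_nm
  } else stop2("unsupported stack format: .", ext)
  if (invert) vol <- max(vol) - vol
  tomogram_stack(vol, voxel_size_nm = voxel_size_nm,
                 id = tools::file_path_sans_ext(basename(path)))
}

#' Write a volume stack to TIFF or MRC
#'
#' @param stack A [tomogram_stack()] or 3D `(z, y, x)` array.
#' @param path Output path (`.tif`/`.tiff` or `.mrc`).
#' @param normalize Rescale TIFF output into `[0, 1]` (the tiff writer's
#'   float convention); MRC keeps raw values.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, normalize = FALSE) {
  ts <- as_tomogram_stack(stack)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    vol <- ts$voxels
    if (normalize) {
      rng <- range(vol)
      if (diff(rng) > 0) vol <- (vol - rng[1]) / diff(rng)
    }
    pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "mrc") {
    write_mrc(ts$voxels, path, ts$voxel_size_nm)
  } else stop2("unsupported stack format: .", ext)
  invisible(path)
}

# Minimal MRC (mode 2, float32) reader. Axis order on disk is x fastest,
# then y, then z; returned volume is (z, y, x).
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (mode != 2) stop2("only MRC mode 2 (float32) is supported")
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  raw_data <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  vol_xyz <- array(raw_data, c(nx, ny, nz))
  voxel_size_nm <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] / 10 else NA_real_
  # cella is in Angstrom by convention -> /10 to nm
  list(volume = aperm(vol_xyz, c(3, 2, 1)),
       voxel_size_nm = if (is.finite(voxel_size_nm) && voxel_size_nm > 0)
         voxel_size_nm else NULL)
}

write_mrc <- function(vol, path, voxel_size_nm = 19.6) {
  d <- dim(vol)  # (z, y, x)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, 2, 0, 0, 0, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * voxel_size_nm * 10), con,  # cella in Angstrom
           size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vol), max(vol), mean(vol))), con,
           size = 4, endian = "little")
  # pad the rest of the 1024-byte header
  writeBin(raw(1024 - (10 + 3 + 3 + 3 + 3) * 4), con)
  writeBin(as.numeric(aperm(vol, c(3, 2, 1))), con, size = 4, endian = "little")
  invisible(path)
}

#' Write ROIs as a multi-page TIFF plus a center table
#'
#' Pages are ordered ROI-major (all channels of ROI 1, then ROI 2, ...);
#' the CSV records 1-based `row`/`col` centers and the source field.
#'
#' @param rois List of [roi_image()] objects.
#' @param tiff_path,csv_path Output paths.
#' @return `tiff_path`, invisibly.
#' @export
write_rois <- function(rois, tiff_path, csv_path) {
  pages <- list()
  for (r in rois)
    for (ch in seq_len(dim(r$pixels)[3]))
      pages[[length(pages) + 1]] <- r$pixels[, , ch]
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  tab <- data.frame(roi = seq_along(rois),
                    row = vapply(rois, function(r) r$source_center[1], numeric(1)),
                    col = vapply(rois, function(r) r$source_center[2], numeric(1)),
                    field = vapply(rois, function(r) r$source_field_id, character(1)))
  write.csv(tab, csv_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Read ROIs written by [write_rois()]
#'
#' @param tiff_path,csv_path Paths written by [write_rois()].
#' @param channels Channels per ROI (default 2).
#' @return A list of [roi_image()] objects.
#' @export
read_rois <- function(tiff_path, csv_path, channels = 2) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  tab <- read.csv(csv_path)
  for (col in c("roi", "row", "col", "field"))
    if (!col %in% names(tab)) stop2("ROI table misses column '", col, "'")
  n <- length(pages) / channels
  if (n != nrow(tab)) stop2("page count does not match the ROI table")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- array(0, c(dim(pages[[1]]), channels))
    for (ch in seq_len(channels)) px[, , ch] <- pages[[(i - 1) * channels + ch]]
    out[[i]] <- roi_image(clamp(px, 0, 1), c(tab$row[i], tab$col[i]), tab$field[i])
  }
  out
}

#' Write / read a droplet record table
#'
#' Schema-checked CSV round trip for [analyze_droplets()] outputs.
#'
#' @param records Data frame from [analyze_droplets()].
#' @param path CSV path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_droplet_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_droplet_table
#' @export
read_droplet_table <- function(path) {
  tab <- read.csv(path)
  need <- c("droplet", "volume_um3", "vacuole", "distance_um", "consumed",
            "contact_percent", "condition")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop2("droplet table misses column '", miss[1], "'")
  tab
}

#' Export a rendered scene of all meshes as one colored PLY file
#'
#' Writes cells, vacuoles and droplets into a single ASCII PLY with
#' per-vertex colors following the package's rendering convention:
#' cells white, vacuoles red, consumed droplets purple, unconsumed
#' droplets green. Any PLY viewer displays the scene.
#'
#' @param meshes Named list of mesh lists (`cell`, `vacuole`, `droplet`)
#'   as returned by the pipeline.
#' @param path Output `.ply` path.
#' @param records Optional droplet table from [analyze_droplets()] used
#'   to color consumed droplets.
#' @return `path`, invisibly.
#' @export
export_scene <- function(meshes, path, records = NULL) {
  cols <- list(cell = c(255, 255, 255), vacuole = c(220, 40, 40),
               droplet = c(60, 200, 60), consumed = c(170, 60, 200))
  verts <- NULL; faces <- NULL; colors <- NULL; off <- 0
  for (ch in names(meshes)) {
    for (m in meshes[[ch]]) {
      col <- cols[[ch]]
      if (ch == "droplet" && !is.null(records)) {
        row <- records[records$droplet == m$id, , drop = FALSE]
        if (nrow(row) == 1 && isTRUE(row$consumed)) col <- cols$consumed
      }
      verts <- rbind(verts, m$vertices[, 3:1, drop = FALSE])
      colors <- rbind(colors, matrix(col, nrow(m$vertices), 3, byrow = TRUE))
      faces <- rbind(faces, m$faces + off)
      off <- off + nrow(m$vertices)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment units micrometres, axes x y z",
               paste("element vertex", if (is.null(verts)) 0 else nrow(verts)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               paste("element face", if (is.null(faces)) 0 else nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (!is.null(verts)) {
    writeLines(paste(format(verts[, 1], trim = TRUE),
                     format(verts[, 2], trim = TRUE),
                     format(verts[, 3], trim = TRUE),
                     colors[, 1], colors[, 2], colors[, 3]), con)
    writeLines(paste(3, faces[, 1] - 1, faces[, 2] - 1, faces[, 3] - 1), con)
  }
  invisible(path)
}

#' Export a mesh in PLY or STL format
#'
#' Vertices are written in micrometres as `(x, y, z)` (the reverse of
#' the internal `(z, y, x)` storage); the header notes the convention.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path ending in `.ply` or `.stl` (ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices[, 3:1, drop = FALSE]  # (x, y, z)
  f <- mesh$faces
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 "comment units micrometres, axes x y z",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(format(v, trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s_%s", mesh$channel, mesh$id), con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
               (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
             (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
               (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
             (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
      nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
      writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid", con)
  } else stop2("unsupported mesh format: .", ext)
  invisible(path)
}
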