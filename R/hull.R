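# 3D convex hull (quickhull) of a point cloud. Points are rows of an
# n x 3 matrix. Returns NULL for degenerate (collinear/coplanar) input.

# Outward-oriented face descriptor relative to an interior point.
make_face <- function(pts, i, j, k, interior) {
  a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
  n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
         (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
         (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  nl <- sqrt(sum(n^2))
  if (nl < 1e-12) return(NULL)
  n <- n / nl
  if (sum(n * (interior - a)) > 0) {  # flip to outward
    tmp <- j; j <- k; k <- tmp
    n <- -n
  }
  list(v = c(i, j, k), n = n, d = sum(n * pts[i, ]))
}

quickhull3 <- function(pts, tol = 1e-9) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4) return(NULL)
  # initial simplex: farthest pair among axis extremes, then max area,
  # then max volume
  ext <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  best <- c(ext[1], ext[2]); bd <- -1
  for (i in ext) for (j in ext) if (j > i) {
    dd <- sum((pts[i, ] - pts[j, ])^2)
    if (dd > bd) { bd <- dd; best <- c(i, j) }
  }
  if (bd < tol) return(NULL)
  a <- best[1]; b <- best[2]
  ab <- pts[b, ] - pts[a, ]
  rel <- sweep(pts, 2, pts[a, ])
  cr <- cbind(ab[2] * rel[, 3] - ab[3] * rel[, 2],
              ab[3] * rel[, 1] - ab[1] * rel[, 3],
              ab[1] * rel[, 2] - ab[2] * rel[, 1])
  area <- rowSums(cr^2)
  cc <- which.max(area)
  if (area[cc] < tol) return(NULL)
  nrm <- cr[cc, ]
  h <- abs(rel %*% nrm)
  dd <- which.max(h)
  if (h[dd] < tol * sqrt(sum(nrm^2))) return(NULL)
  interior <- colMeans(pts[c(a, b, cc, dd), ])
  faces <- list(make_face(pts, a, b, cc, interior),
                make_face(pts, a, b, dd, interior),
                make_face(pts, a, cc, dd, interior),
                make_face(pts, b, cc, dd, interior))
  if (any(vapply(faces, is.null, logical(1)))) return(NULL)
  # assign outside sets
  assign_outside <- function(face, cand) {
    if (length(cand) == 0) return(integer(0))
    s <- pts[cand, , drop = FALSE] %*% face$n - face$d
    cand[s > tol]
  }
  all_idx <- seq_len(nrow(pts))
  for (fi in seq_along(faces)) faces[[fi]]$outside <- assign_outside(faces[[fi]], all_idx)
  repeat {
    fi <- which(vapply(faces, function(f) length(f$outside) > 0, logical(1)))[1]
    if (is.na(fi)) break
    f <- faces[[fi]]
    s <- pts[f$outside, , drop = FALSE] %*% f$n - f$d
    p <- f$outside[which.max(s)]
    # faces visible from p
    vis <- vapply(faces, function(fc) sum(pts[p, ] * fc$n) - fc$d > tol, logical(1))
    # horizon: edges of visible faces shared with a hidden face
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    counts <- new.env()
    for (fc in faces[vis]) {
      v <- fc$v
      for (e in list(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))) {
        k <- edge_key(e[1], e[2])
        cur <- mget(k, envir = counts, ifnotfound = list(NULL))[[1]]
        assign(k, if (is.null(cur)) e else "dup", envir = counts)
      }
    }
    horizon <- Filter(function(e) !identical(e, "dup"),
                      mget(ls(counts), envir = counts))
    cand <- unique(unlist(lapply(faces[vis], function(fc) fc$outside)))
    cand <- setdiff(cand, p)
    faces <- faces[!vis]
    for (e in horizon) {
      nf <- make_face(pts, e[1], e[2], p, interior)
      if (is.null(nf)) next
      nf$outside <- assign_outside(nf, cand)
      faces[[length(faces) + 1]] <- nf
    }
  }
  list(points = pts,
       faces = t(vapply(faces, function(f) f$v, numeric(3))),
       normals = t(vapply(faces, function(f) f$n, numeric(3))),
       offsets = vapply(faces, function(f) f$d, numeric(1)))
}

# Which of the query points (rows) lie inside or on the hull.
hull_contains <- function(hull, query, tol = 1e-7) {
  s <- as.matrix(query) %*% t(hull$normals)
  apply(sweep(s, 2, hull$offsets) <= tol, 1, all)
}

# For voxel clouds: only the per-(y, x) column z-extremes can be hull
# vertices; shrinks quickhull input considerably.
column_extremes <- function(idx) {
  key <- paste(idx[, 2], idx[, 3])
  lo <- tapply(seq_len(nrow(idx)), key, function(r) r[which.min(idx[r, 1])])
  hi <- tapply(seq_len(nrow(idx)), key, function(r) r[which.max(idx[r, 1])])
  idx[unique(c(lo, hi)), , drop = FALSE]
}
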