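# Delaunay triangulation (Bowyer-Watson) for small 2-D point sets.
#
# The electrode clouds handled here have ~31 points, so an O(n^2) incremental
# construction is ample. Cocircular quadruples (the idealized montage is
# mirror-symmetric) are resolved deterministically by the fixed insertion
# order; every interpolation property used downstream holds for any valid
# triangulation.

# Signed doubled area of triangle abc (positive if counter-clockwise).
tri_orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# TRUE if point p lies inside the circumcircle of ccw triangle abc.
in_circumcircle <- function(a, b, c, p, eps = 1e-12) {
  ax <- a[1] - p[1]; ay <- a[2] - p[2]
  bx <- b[1] - p[1]; by <- b[2] - p[2]
  cx <- c[1] - p[1]; cy <- c[2] - p[2]
  det <- (ax * ax + ay * ay) * (bx * cy - cx * by) -
         (bx * bx + by * by) * (ax * cy - cx * ay) +
         (cx * cx + cy * cy) * (ax * by - bx * ay)
  det > eps * max(1, abs(ax), abs(ay), abs(bx), abs(by), abs(cx), abs(cy))^4
}

# Delaunay triangulation. Returns integer matrix (m x 3) of point indices,
# each row counter-clockwise.
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  if (anyDuplicated(round(pts, 12))) stop("duplicate points in triangulation input")
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1e-9)
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  m <- 20 * span
  super <- rbind(c(cx - 2 * m, cy - m), c(cx + 2 * m, cy - m), c(cx, cy + 2 * m))
  P <- rbind(pts, super)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- logical(nrow(tris))
    for (t in seq_len(nrow(tris))) {
      v <- tris[t, ]
      bad[t] <- in_circumcircle(P[v[1], ], P[v[2], ], P[v[3], ], p, eps = -1e-12)
    }
    # boundary of the cavity: edges of bad triangles not shared by two of them
    edges <- NULL
    for (t in which(bad)) {
      v <- tris[t, ]
      edges <- rbind(edges, c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))
    }
    keyf <- function(e) paste(min(e), max(e))
    keys <- apply(edges, 1, keyf)
    boundary <- edges[keys %in% names(which(table(keys) == 1L)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    for (k in seq_len(nrow(boundary))) {
      e <- boundary[k, ]
      if (tri_orient(P[e[1], 1], P[e[1], 2], P[e[2], 1], P[e[2], 2], p[1], p[2]) > 0)
        tris <- rbind(tris, c(e[1], e[2], i))
      else
        tris <- rbind(tris, c(e[2], e[1], i))
    }
  }
  keep <- apply(tris, 1, function(v) all(v <= n))
  tris <- tris[keep, , drop = FALSE]
  storage.mode(tris) <- "integer"
  tris
}

# Locate query points in a triangulation. Returns list(tri = index or NA,
# bary = k x 3 barycentric coordinates). Points within `tol` outside an edge
# are snapped to the nearest triangle.
tri_locate <- function(pts, tris, q, tol = 1e-9) {
  q <- as.matrix(q)
  nq <- nrow(q)
  nt <- nrow(tris)
  best_tri <- rep(NA_integer_, nq)
  best_min <- rep(-Inf, nq)
  B <- matrix(NA_real_, nq, 3)
  for (t in seq_len(nt)) {
    v <- tris[t, ]
    x1 <- pts[v[1], 1]; y1 <- pts[v[1], 2]
    x2 <- pts[v[2], 1]; y2 <- pts[v[2], 2]
    x3 <- pts[v[3], 1]; y3 <- pts[v[3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (q[, 1] - x3) + (x3 - x2) * (q[, 2] - y3)) / det
    l2 <- ((y3 - y1) * (q[, 1] - x3) + (x1 - x3) * (q[, 2] - y3)) / det
    l3 <- 1 - l1 - l2
    mn <- pmin(l1, l2, l3)
    upd <- mn > best_min
    if (any(upd)) {
      best_min[upd] <- mn[upd]
      best_tri[upd] <- t
      B[upd, ] <- cbind(l1, l2, l3)[upd, , drop = FALSE]
    }
  }
  inside <- best_min >= -tol
  best_tri[!inside] <- NA_integer_
  B[!inside, ] <- NA_real_
  list(tri = best_tri, bary = B)
}

# Convex-hull membership (via triangulation coverage).
tri_inhull <- function(pts, tris, q, tol = 1e-9) {
  !is.na(tri_locate(pts, tris, q, tol)$tri)
}
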