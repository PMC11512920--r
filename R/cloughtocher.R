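# Clough-Tocher C1 piecewise-cubic interpolation on a Delaunay triangulation.
#
# Each triangle is split at its centroid into three cubic Bezier mini-patches.
# Corner values and gradients fix the outer control points; the interior
# ordinate of each mini-patch comes from requiring a linear normal derivative
# along the outer edge (quadratic Bezier coefficient condition q1=(q0+q2)/2);
# the ring ordinates around the centroid and the centroid ordinate follow in
# closed form from the C1 conditions across the internal edges. Gradients at
# the data sites are estimated by distance-weighted least-squares plane fits
# over triangulation neighbours, so the whole interpolant is linear in the
# data values and reproduces affine fields exactly.

# Gradient estimation: n x 2 matrix of (df/dx, df/dy) at each data site.
ct_gradients <- function(pts, tris, f) {
  n <- nrow(pts)
  nb <- vector("list", n)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    nb[[v[1]]] <- c(nb[[v[1]]], v[2], v[3])
    nb[[v[2]]] <- c(nb[[v[2]]], v[1], v[3])
    nb[[v[3]]] <- c(nb[[v[3]]], v[1], v[2])
  }
  G <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- unique(nb[[i]])
    dx <- pts[j, 1] - pts[i, 1]
    dy <- pts[j, 2] - pts[i, 2]
    df <- f[j] - f[i]
    w <- 1 / (dx^2 + dy^2)
    a11 <- sum(w * dx * dx); a12 <- sum(w * dx * dy); a22 <- sum(w * dy * dy)
    r1 <- sum(w * dx * df); r2 <- sum(w * dy * df)
    det <- a11 * a22 - a12^2
    if (abs(det) < 1e-14 * max(a11 + a22, 1)) next  # collinear neighbourhood
    G[i, 1] <- (a22 * r1 - a12 * r2) / det
    G[i, 2] <- (a11 * r2 - a12 * r1) / det
  }
  G
}

# Interior ordinate of the mini-patch (V0, Va, Vb) with outer edge Va-Vb.
ct_b111 <- function(V0, Va, Vb, b120, b102, b030, b021, b012, b003) {
  e <- Vb - Va
  nvec <- c(-e[2], e[1])
  # barycentric direction coordinates of nvec in (V0, Va, Vb)
  M <- rbind(c(V0[1], Va[1], Vb[1]), c(V0[2], Va[2], Vb[2]), c(1, 1, 1))
  d <- solve(M, c(nvec, 0))
  du <- d[1]; dv <- d[2]; dw <- d[3]
  0.5 * (b120 + b102) +
    (dv * (b030 + b012 - 2 * b021) + dw * (b021 + b003 - 2 * b012)) / (2 * du)
}

# Precompute per-triangle Bezier ordinates. Returns list of per-triangle
# structures used by ct_evaluate().
ct_build <- function(pts, tris, f, grads = NULL) {
  if (is.null(grads)) grads <- ct_gradients(pts, tris, f)
  lapply(seq_len(nrow(tris)), function(t) {
    v <- tris[t, ]
    V <- list(pts[v[1], ], pts[v[2], ], pts[v[3], ])
    Fv <- f[v]
    G <- list(grads[v[1], ], grads[v[2], ], grads[v[3], ])
    V0 <- (V[[1]] + V[[2]] + V[[3]]) / 3
    # edge ordinate at corner m towards point P
    edge_ord <- function(m, P) Fv[m] + sum(G[[m]] * (P - V[[m]])) / 3
    e <- vapply(1:3, function(m) edge_ord(m, V0), 0)  # towards centroid
    # mini-patch p is opposite outer vertex p: patch 1 = (V0, V2, V3), etc.
    opp <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
    b111 <- numeric(3)
    outer_ord <- matrix(0, 3, 2)  # per patch: (b021, b012) on its outer edge
    for (p in 1:3) {
      a <- opp[[p]][1]; bidx <- opp[[p]][2]
      b021 <- edge_ord(a, V[[bidx]])
      b012 <- edge_ord(bidx, V[[a]])
      outer_ord[p, ] <- c(b021, b012)
      b111[p] <- ct_b111(V0, V[[a]], V[[bidx]], e[a], e[bidx],
                         Fv[a], b021, b012, Fv[bidx])
    }
    # ring ordinate on internal edge V0-Vm: patches adjacent to that edge are
    # the two patches not opposite m
    cring <- vapply(1:3, function(m) {
      adj <- setdiff(1:3, m)
      (b111[adj[1]] + b111[adj[2]] + e[m]) / 3
    }, 0)
    b0 <- mean(cring)
    list(V = V, V0 = V0, Fv = Fv, e = e, b111 = b111,
         outer = outer_ord, cring = cring, b0 = b0)
  })
}

# Evaluate the Clough-Tocher interpolant at query points already located in
# the triangulation (loc from tri_locate). Out-of-hull points get `fill`.
ct_evaluate <- function(built, loc, fill = 0) {
  nq <- length(loc$tri)
  out <- rep(fill, nq)
  inside <- which(!is.na(loc$tri))
  for (qi in inside) {
    t <- loc$tri[qi]
    st <- built[[t]]
    lam <- pmax(loc$bary[qi, ], 0)
    lam <- lam / sum(lam)
    p <- which.min(lam)               # mini-patch opposite the smallest coord
    a <- c(2L, 3L, 1L)[p]; bidx <- c(3L, 1L, 2L)[p]
    u <- 3 * lam[p]
    v <- lam[a] - lam[p]
    w <- lam[bidx] - lam[p]
    # ordinates of mini-patch (V0, Va, Vb)
    b300 <- st$b0
    b210 <- st$cring[a]; b201 <- st$cring[bidx]
    b120 <- st$e[a];     b102 <- st$e[bidx]
    b030 <- st$Fv[a];    b003 <- st$Fv[bidx]
    b021 <- st$outer[p, 1]; b012 <- st$outer[p, 2]
    b111 <- st$b111[p]
    out[qi] <-
      b300 * u^3 + b030 * v^3 + b003 * w^3 +
      3 * (b210 * u^2 * v + b201 * u^2 * w +
           b120 * u * v^2 + b102 * u * w^2 +
           b021 * v^2 * w + b012 * v * w^2) +
      6 * b111 * u * v * w
  }
  out
}

# One-call interface: interpolate values at scattered points onto queries.
ct_interpolate <- function(pts, f, query, tris = NULL, grads = NULL, fill = 0) {
  pts <- as.matrix(pts)
  if (is.null(tris)) tris <- delaunay2d(pts)
  loc <- tri_locate(pts, tris, as.matrix(query))
  built <- ct_build(pts, tris, f, grads)
  ct_evaluate(built, loc, fill = fill)
}
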