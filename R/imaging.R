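#' Topographic mesh geometry
#'
#' Fixed geometry shared by every frame and the feature mask: a square
#' `mesh x mesh` pixel grid covering the projected electrode cloud plus a 5%
#' margin, the Delaunay triangulation of the projected electrodes, the
#' per-pixel triangle location, and the in-hull mask. Because the
#' Clough-Tocher interpolant is linear in the electrode values, the geometry
#' also carries a precomputed `mesh^2 x n_electrode` render operator, making
#' per-frame rendering a single matrix product.
#'
#' @param projected an `eeg_projection` (31 electrodes for the default cap).
#' @param mesh mesh size in pixels per side (default 32).
#' @param margin fractional margin around the electrode cloud.
#' @return object of class `topo_geometry`.
#' @export
topo_geometry <- function(projected, mesh = 32, margin = 0.05) {
  pts <- as.matrix(projected[, c("x", "y")])
  if (anyDuplicated(round(pts, 9)))
    stop("duplicate projected electrode coordinates")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  half <- span / 2 * (1 + 2 * margin)
  gx <- seq(cx - half, cx + half, length.out = mesh)
  gy <- seq(cy + half, cy - half, length.out = mesh)  # row 1 = top of scalp
  grid <- cbind(rep(gx, each = mesh), rep(gy, times = mesh))
  # grid rows ordered column-major over (row=y, col=x): pixel (r, c) at
  # index (c - 1) * mesh + r
  tris <- delaunay2d(pts)
  loc <- tri_locate(pts, tris, grid)
  inhull <- !is.na(loc$tri)
  # render operator: CT interpolation of each basis vector
  R <- matrix(0, mesh * mesh, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    e <- numeric(nrow(pts)); e[i] <- 1
    R[, i] <- ct_evaluate(ct_build(pts, tris, e), loc, fill = 0)
  }
  structure(list(pts = pts, labels = projected$label, tris = tris,
                 mesh = mesh, gx = gx, gy = gy, grid = grid, loc = loc,
                 inhull = matrix(inhull, mesh, mesh), render_op = R),
            class = "topo_geometry")
}

# reshape a grid-ordered vector into a mesh x mesh matrix (rows = y top-down)
grid_to_image <- function(v, mesh) matrix(v, mesh, mesh)

#' Render one topographic layer
#'
#' Clough-Tocher interpolation of one value per electrode over the pixel
#' mesh; pixels outside the convex hull of the projected electrodes get
#' `fill` (0 = black, consistent with zero synchronisation).
#'
#' @param values numeric vector, one finite value per electrode.
#' @param geom a [topo_geometry()]; or pass `projected` to build one.
#' @param projected an `eeg_projection` (used when `geom` is missing).
#' @param mesh mesh size when building geometry on the fly.
#' @param fill out-of-hull fill value.
#' @return `mesh x mesh` numeric matrix (row 1 = anterior/top).
#' @export
render_layer <- function(values, geom = NULL, projected = NULL, mesh = 32,
                         fill = 0) {
  if (is.null(geom)) {
    if (is.null(projected)) stop("supply geom or projected")
    geom <- topo_geometry(projected, mesh)
  }
  if (length(values) != nrow(geom$pts))
    stop("need exactly one value per electrode")
  if (anyNA(values) || any(!is.finite(values)))
    stop("electrode values must be finite (NaN would propagate)")
  img <- grid_to_image(geom$render_op %*% values, geom$mesh)
  img[!geom$inhull] <- fill
  img
}

#' Stack CFS layers into an image sequence
#'
#' Builds, for each temporal segment, a three-layer `mesh x mesh x 3` frame
#' whose layers are the rendered topographies of the three selected band
#' pairs. Raw CFS values (already in \[0, 1\]) are stored; no per-layer
#' rescaling is applied.
#'
#' @param cfs a `cfs_matrix`.
#' @param triplet three band-pair names (e.g. `"Theta-Gamma"`) or 2-element
#'   vectors; default: the matrix's first three pairs.
#' @param geom a [topo_geometry()] for the matrix's electrode order.
#' @return object of class `cfs_image_sequence`: array
#'   `mesh x mesh x 3 x n_segments` with attributes `layers`, `inhull`,
#'   `subject_id`, `label`.
#' @export
stack_frames <- function(cfs, triplet = NULL, geom) {
  pair_names <- dimnames(cfs)[[2]]
  if (is.null(triplet)) triplet <- pair_names[1:3]
  if (is.list(triplet))
    triplet <- vapply(triplet, function(p) paste(p, collapse = "-"), "")
  if (length(triplet) != 3)
    stop("triplet must name exactly 3 band pairs")
  idx <- match(triplet, pair_names)
  if (anyNA(idx))
    stop(sprintf("band pairs not in CFS matrix: %s",
                 paste(triplet[is.na(idx)], collapse = ", ")))
  if (!identical(dimnames(cfs)[[1]], geom$labels))
    stop("geometry electrode order does not match the CFS matrix")
  ns <- dim(cfs)[3]
  mesh <- geom$mesh
  out <- array(0, dim = c(mesh, mesh, 3, ns))
  for (k in 1:3) {
    # linear render operator applied to all segments at once
    V <- geom$render_op %*% cfs[, idx[k], ]      # (mesh^2) x ns
    V[!as.vector(geom$inhull), ] <- 0
    out[, , k, ] <- array(V, dim = c(mesh, mesh, ns))
  }
  structure(out, class = "cfs_image_sequence", layers = triplet,
            inhull = geom$inhull, subject_id = attr(cfs, "subject_id"),
            label = attr(cfs, "label"))
}

#' @export
print.cfs_image_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cfs_image_sequence> %s [%s]: %d frames of %dx%dx3 (%s)\n",
              attr(x, "subject_id"), attr(x, "label"), d[4], d[1], d[2],
              paste(attr(x, "layers"), collapse = " / ")))
  invisible(x)
}

#' Electrode super-pixel feature mask
#'
#' Labels every in-hull pixel with the index (1..n) of its nearest projected
#' electrode (planar Euclidean distance); out-of-hull pixels are 0. The
#' resulting partition of the scalp image into electrode "areas of
#' influence" is the interpretable representation used by the explanation
#' module.
#'
#' @param geom a [topo_geometry()] (or `projected` + `mesh` as in
#'   [render_layer()]).
#' @inheritParams render_layer
#' @return object of class `feature_mask`: integer `mesh x mesh` matrix with
#'   attribute `labels` (electrode names, index order).
#' @export
build_feature_mask <- function(geom = NULL, projected = NULL, mesh = 32) {
  if (is.null(geom)) {
    if (is.null(projected)) stop("supply geom or projected")
    geom <- topo_geometry(projected, mesh)
  }
  d2 <- outer(rowSums(geom$grid^2), rowSums(geom$pts^2), "+") -
    2 * geom$grid %*% t(geom$pts)
  lab <- max.col(-d2, ties.method = "first")
  lab[!as.vector(geom$inhull)] <- 0L
  m <- matrix(as.integer(lab), geom$mesh, geom$mesh)
  structure(m, class = "feature_mask", labels = geom$labels)
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %dx%d, %d super-pixels\n",
              nrow(x), ncol(x), length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

#' Group-average CFS topographies
#'
#' Electrode-wise mean CFS per group, band pair and segment, rendered as
#' topographic images - the group-average topoplot panels used for
#' exploratory analysis.
#'
#' @param cohort_cfs list of `cfs_matrix` objects (same geometry).
#' @param groups character vector of group labels, one per subject
#'   (defaults to each matrix's own label).
#' @param pair band-pair name to average.
#' @param segments segment indices (default: all).
#' @param geom a [topo_geometry()].
#' @return array `mesh x mesh x n_segments x n_groups` with dimnames on the
#'   group axis, class `group_topoplots`.
#' @export
group_topoplots <- function(cohort_cfs, groups = NULL, pair, segments = NULL,
                            geom) {
  if (is.null(groups))
    groups <- vapply(cohort_cfs, function(m) attr(m, "label"), "")
  if (length(groups) != length(cohort_cfs))
    stop("one group label per subject required")
  glev <- unique(groups)
  if (any(table(groups) < 1)) stop("empty group")
  if (is.null(segments)) segments <- seq_len(dim(cohort_cfs[[1]])[3])
  mesh <- geom$mesh
  out <- array(0, dim = c(mesh, mesh, length(segments), length(glev)),
               dimnames = list(NULL, NULL, NULL, glev))
  for (g in seq_along(glev)) {
    idx <- which(groups == glev[g])
    for (si in seq_along(segments)) {
      vals <- rowMeans(vapply(idx, function(i)
        cohort_cfs[[i]][, pair, segments[si]],
        numeric(dim(cohort_cfs[[1]])[1])))
      out[, , si, g] <- render_layer(vals, geom)
    }
  }
  structure(out, class = "group_topoplots", pair = pair, segments = segments)
}

#' Plot topographic images
#'
#' ggplot2 rendering of one or more `mesh x mesh` layers (a topoplot, a
#' relevance map, or one frame layer), pixel-faithful with a common fill
#' scale.
#'
#' @param img a matrix, or a named list of matrices for facetting.
#' @param low,mid,high fill gradient colours; `mid` is used at 0 so signed
#'   relevance maps render red/green around zero.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_topo <- function(img, low = "darkblue", mid = "black", high = "white",
                      title = NULL) {
  if (!is.list(img)) img <- list(layer = img)
  df <- do.call(rbind, lapply(names(img), function(nm) {
    m <- img[[nm]]
    data.frame(panel = nm,
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               row = rep(rev(seq_len(nrow(m))), times = ncol(m)),
               value = as.vector(m))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = low, mid = mid, high = high,
                                  midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::theme_void()
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  p
}

#' Write frame previews as PNG
#'
#' Writes each frame of a sequence as an RGB preview (layer k = colour
#' channel k; zero CFS renders black, simultaneous maxima render white).
#'
#' @param seq_img a `cfs_image_sequence`.
#' @param dir output directory.
#' @param normalize stretch each frame to full range for display only.
#' @return paths, invisibly.
#' @export
write_frame_pngs <- function(seq_img, dir, normalize = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- dim(seq_img)[4]
  paths <- character(ns)
  for (t in seq_len(ns)) {
    fr <- seq_img[, , , t]
    if (normalize && max(fr) > 0) fr <- fr / max(fr)
    fr <- pmin(pmax(fr, 0), 1)
    paths[t] <- file.path(dir, sprintf("frame_%02d.png", t))
    grDevices::png(paths[t], width = dim(fr)[2], height = dim(fr)[1])
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(fr, 0, 0, 1, 1, interpolate = FALSE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(paths)
}
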