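proj32 <- project_montage(montage_standard32())
geom32 <- topo_geometry(proj32)

test_that("azimuthal equidistant projection maps the centre and axes correctly", {
  mon <- montage(c("Cz", "X"), rbind(c(0, 0, 1), c(0, -1, 0)))
  pr <- project_montage(mon, drop_reference = FALSE)
  expect_equal(unlist(pr[pr$label == "Cz", c("x", "y")]),
               c(x = 0, y = 0), tolerance = 1e-12)
  # angular distance pi/2 at azimuth 0 (posterior) -> (0, -pi/2)
  expect_equal(unlist(pr[pr$label == "X", c("x", "y")]),
               c(x = 0, y = -pi / 2), tolerance = 1e-9)
  anterior <- montage(c("Cz", "N"), rbind(c(0, 0, 1), c(0, 1, 0)))
  prn <- project_montage(anterior, drop_reference = FALSE)
  expect_gt(prn$y[prn$label == "N"], 0)             # nose-up orientation
  south <- montage(c("Cz", "S"), rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_error(project_montage(south), "antipodal")
})

test_that("left/right homologous pairs project mirror-symmetrically", {
  for (pair in list(c("C3", "C4"), c("F3", "F4"), c("P7", "P8"),
                    c("FC5", "FC6"), c("TP9", "TP10"), c("O1", "O2"))) {
    a <- proj32[proj32$label == pair[1], ]
    b <- proj32[proj32$label == pair[2], ]
    expect_equal(a$x, -b$x, tolerance = 1e-6)
    expect_equal(a$y, b$y, tolerance = 1e-6)
  }
})

test_that("projection preserves radial order from the reference", {
  mon <- montage_standard32()
  keep <- mon$label != "Cz"
  ang <- acos(pmin(1, mon$z[keep]))                 # angular distance from Cz
  r <- sqrt(proj32$x^2 + proj32$y^2)
  ang_aligned <- ang[match(proj32$label, mon$label[keep])]
  expect_equal(r, ang_aligned, tolerance = 1e-9)    # rho = R * c exactly
  # strict monotonicity for strictly increasing angular distance
  ord <- order(ang_aligned)
  grows <- diff(ang_aligned[ord]) > 1e-9
  expect_true(all(diff(r[ord])[grows] > 0))
})

test_that("interpolation reproduces constant and affine fields at 1e-9", {
  img <- render_layer(rep(0.7, 31), geom32)
  expect_identical(dim(img), c(32L, 32L))
  expect_lt(max(abs(img[geom32$inhull] - 0.7)), 1e-9)
  expect_true(all(img[!geom32$inhull] == 0))
  vals <- 0.2 + 0.3 * geom32$pts[, 1] - 0.15 * geom32$pts[, 2]
  img2 <- render_layer(vals, geom32)
  truth <- matrix(0.2 + 0.3 * geom32$grid[, 1] - 0.15 * geom32$grid[, 2],
                  32, 32)
  expect_lt(max(abs((img2 - truth)[geom32$inhull])), 1e-9)
  expect_error(render_layer(c(NaN, rep(0, 30)), geom32), "finite")
  expect_error(render_layer(rep(0, 30), geom32), "one value per electrode")
})

test_that("a one-hot field peaks at its own electrode", {
  for (e in c("FC5", "Oz", "Pz")) {
    i <- match(e, geom32$labels)
    v <- numeric(31); v[i] <- 1
    img <- render_layer(v, geom32)
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    ex <- which.min(abs(geom32$gx - geom32$pts[i, 1]))
    ey <- which.min(abs(geom32$gy - geom32$pts[i, 2]))
    expect_lte(max(abs(peak - c(ey, ex))), 1)
  }
})

test_that("our Clough-Tocher interpolant tracks the scipy reference", {
  o <- jsonlite::fromJSON(test_path("ct_scipy_oracle.json"))
  pts <- as.matrix(o$pts)
  q <- as.matrix(o$q)
  mine <- eegcfs:::ct_interpolate(pts, o$f, q, fill = NA)
  ref <- unlist(lapply(o$vals, function(v) if (is.null(v)) NA_real_ else v))
  both <- !is.na(ref) & !is.na(mine)
  expect_gt(sum(both), 80)
  expect_identical(sum(is.na(ref) != is.na(mine)), 0L)  # same hull
  # the mid-edge derivative estimate differs between the two constructions,
  # so values agree closely but not exactly (field range ~4)
  expect_lt(max(abs(mine[both] - ref[both])), 0.2)
  expect_lt(mean(abs(mine[both] - ref[both])), 0.05)
  # and both are exact at the data sites
  at_sites <- eegcfs:::ct_interpolate(pts, o$f, pts, fill = NA)
  expect_equal(at_sites, o$f, tolerance = 1e-10)
})

test_that("feature mask partitions the hull into 31 electrode super-pixels", {
  mask <- build_feature_mask(geom32)
  m <- unclass(mask)
  labs <- setdiff(sort(unique(as.vector(m))), 0L)
  expect_identical(labs, 1:31)
  expect_identical(m > 0, unclass(geom32$inhull))   # union = hull, disjoint
  for (i in c(1L, 8L, 17L, 31L)) {
    ex <- which.min(abs(geom32$gx - geom32$pts[i, 1]))
    ey <- which.min(abs(geom32$gy - geom32$pts[i, 2]))
    expect_identical(m[ey, ex], i)                  # own pixel carries label
  }
  dup <- proj32
  dup$x[2] <- dup$x[1]; dup$y[2] <- dup$y[1]
  expect_error(topo_geometry(dup), "duplicate")
})

test_that("stack_frames builds 3-layer frames without rescaling", {
  set.seed(51)
  cm <- structure(array(runif(31 * 3 * 4), dim = c(31, 3, 4),
                        dimnames = list(geom32$labels,
                                        c("Theta-Gamma", "Alpha-Beta",
                                          "Beta-Gamma"), NULL)),
                  class = "cfs_matrix", subject_id = "s", label = "control")
  sq <- stack_frames(cm, geom = geom32)
  expect_identical(dim(unclass(sq)), c(32L, 32L, 3L, 4L))
  expect_identical(attr(sq, "layers"),
                   c("Theta-Gamma", "Alpha-Beta", "Beta-Gamma"))
  cm0 <- cm; cm0[] <- 0
  expect_true(all(unclass(stack_frames(cm0, geom = geom32)) == 0))
  cm1 <- cm; cm1[] <- 1                              # max CFS -> white
  s1 <- unclass(stack_frames(cm1, geom = geom32))
  inh <- unclass(geom32$inhull)
  for (k in 1:3) for (t in 1:4)
    expect_lt(max(abs(s1[, , k, t][inh] - 1)), 1e-9)
  expect_error(stack_frames(cm, triplet = c("Alpha-Beta", "Beta-Gamma"),
                            geom = geom32), "exactly 3")
  expect_error(stack_frames(cm, triplet = c("A-B", "C-D", "E-F"),
                            geom = geom32), "not in CFS matrix")
})

test_that("group topoplots average electrode-wise and localise differences", {
  mk <- function(vals, label) {
    a <- array(rep(vals, 2), dim = c(31, 1, 2),
               dimnames = list(geom32$labels, "Alpha-Beta", NULL))
    structure(a, class = "cfs_matrix", subject_id = "x", label = label)
  }
  base <- rep(0.1, 31)
  single <- group_topoplots(list(mk(base, "control")), pair = "Alpha-Beta",
                            geom = geom32)
  expect_equal(single[, , 1, "control"], render_layer(base, geom32),
               tolerance = 1e-12)
  two <- group_topoplots(list(mk(base, "control"), mk(base, "dyslexic")),
                         pair = "Alpha-Beta", geom = geom32)
  expect_equal(two[, , , "control"], two[, , , "dyslexic"], tolerance = 1e-12)
  dx <- base; dx[match("TP9", geom32$labels)] <- 0.8
  gt <- group_topoplots(list(mk(base, "control"), mk(dx, "dyslexic")),
                        pair = "Alpha-Beta", geom = geom32)
  diffmap <- gt[, , 1, "dyslexic"] - gt[, , 1, "control"]
  peak <- which(diffmap == max(diffmap), arr.ind = TRUE)[1, ]
  i <- match("TP9", geom32$labels)
  ex <- which.min(abs(geom32$gx - geom32$pts[i, 1]))
  ey <- which.min(abs(geom32$gy - geom32$pts[i, 2]))
  expect_lte(max(abs(peak - c(ey, ex))), 1)
  expect_error(group_topoplots(list(), pair = "Alpha-Beta", geom = geom32))
})
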