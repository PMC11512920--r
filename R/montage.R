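#' Electrode montages
#'
#' An `eeg_montage` holds electrode labels together with 3-D positions on (or
#' normalised to) a unit sphere, plus the name of the reference electrode
#' (`Cz` for the default cap). The default 32-electrode cap is built
#' programmatically from the idealized 10-20/10-10 arc-placement rules: the
#' vertex is `Cz`, midline and coronal arcs are divided in 10% steps, the head
#' circumference ring lies at 72 degrees inclination and the lower ring
#' (`TP9`, `PO9`, ...) 18 degrees below it; intermediate rows (`FC`, `CP`,
#' ...) are spherical interpolations between their row ends.
#'
#' @param labels character vector of electrode labels.
#' @param xyz numeric matrix (n x 3) of positions; rows are normalised to the
#'   unit sphere.
#' @param reference name of the reference electrode (must occur in `labels`).
#' @return An object of class `eeg_montage`: a data.frame with columns
#'   `label`, `x`, `y`, `z` and attributes `reference`.
#' @examples
#' mon <- montage_standard32()
#' nrow(mon)            # 32 positions including the Cz reference
#' @export
montage <- function(labels, xyz, reference = "Cz") {
  labels <- as.character(labels)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != length(labels) || ncol(xyz) != 3)
    stop("xyz must be a length(labels) x 3 matrix")
  if (anyDuplicated(labels))
    stop("duplicate electrode labels in montage")
  if (!reference %in% labels)
    stop(sprintf("reference electrode '%s' not present in montage", reference))
  r <- sqrt(rowSums(xyz^2))
  if (any(r < 1e-9)) stop("electrode at sphere centre")
  xyz <- xyz / r
  out <- data.frame(label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_montage", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes, reference %s\n",
              nrow(x), attr(x, "reference")))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

# Spherical linear interpolation between two unit vectors.
slerp3 <- function(a, b, t) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

# Unit-sphere position from inclination (degrees from vertex) and azimuth
# (degrees from the anterior midline, negative left / positive right).
sph_pos <- function(incl, az) {
  i <- incl * pi / 180
  a <- az * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

#' @rdname montage
#' @export
montage_standard32 <- function() {
  p <- list()
  p[["Cz"]] <- sph_pos(0, 0)
  p[["Fz"]] <- sph_pos(36, 0)
  p[["Pz"]] <- sph_pos(36, 180)
  p[["Oz"]] <- sph_pos(72, 180)
  # head-circumference ring (72 deg inclination, 18 deg azimuthal steps)
  ring <- c(Fp1 = -18, Fp2 = 18, F7 = -54, F8 = 54, T7 = -90, T8 = 90,
            P7 = -126, P8 = 126, O1 = -162, O2 = 162)
  for (nm in names(ring)) p[[nm]] <- sph_pos(72, ring[[nm]])
  # lower ring, 18 deg below the circumference
  low <- c(TP9 = -108, TP10 = 108, PO9 = -144, PO10 = 144)
  for (nm in names(low)) p[[nm]] <- sph_pos(90, low[[nm]])
  # central coronal arc
  p[["C3"]] <- sph_pos(36, -90)
  p[["C4"]] <- sph_pos(36, 90)
  # frontal / parietal rows: halfway along the arc to the lateral electrode
  p[["F3"]] <- slerp3(p[["Fz"]], p[["F7"]], 0.5)
  p[["F4"]] <- slerp3(p[["Fz"]], p[["F8"]], 0.5)
  p[["P3"]] <- slerp3(p[["Pz"]], p[["P7"]], 0.5)
  p[["P4"]] <- slerp3(p[["Pz"]], p[["P8"]], 0.5)
  # FC / CP rows interpolated between their midline and lateral ends
  fcz <- sph_pos(18, 0); cpz <- sph_pos(18, 180)
  ft7 <- sph_pos(72, -72); ft8 <- sph_pos(72, 72)
  tp7 <- sph_pos(72, -108); tp8 <- sph_pos(72, 108)
  p[["FC1"]] <- slerp3(fcz, ft7, 0.25)
  p[["FC5"]] <- slerp3(fcz, ft7, 0.75)
  p[["FC2"]] <- slerp3(fcz, ft8, 0.25)
  p[["FC6"]] <- slerp3(fcz, ft8, 0.75)
  p[["CP1"]] <- slerp3(cpz, tp7, 0.25)
  p[["CP5"]] <- slerp3(cpz, tp7, 0.75)
  p[["CP2"]] <- slerp3(cpz, tp8, 0.25)
  p[["CP6"]] <- slerp3(cpz, tp8, 0.75)
  ord <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
           "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
           "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz",
           "O2", "PO10")
  montage(ord, do.call(rbind, p[ord]), reference = "Cz")
}

#' Read / write electrode position files
#'
#' `.sfp`-style plain text: one electrode per line, `label x y z` separated by
#' whitespace. Positions are normalised to the unit sphere on read.
#'
#' @param path file path.
#' @param reference reference electrode label.
#' @param mon an `eeg_montage`.
#' @return `read_montage` returns an `eeg_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
read_montage <- function(path, reference = "Cz") {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("label", "x", "y", "z"))
  montage(tb$label, as.matrix(tb[, c("x", "y", "z")]), reference = reference)
}

#' @rdname read_montage
#' @export
write_montage <- function(mon, path) {
  df <- as.data.frame(mon)
  utils::write.table(format(df, digits = 10), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Azimuthal equidistant projection of a montage
#'
#' Projects 3-D electrode positions to the plane with the azimuthal
#' equidistant projection centred on the reference electrode: each electrode
#' maps to polar coordinates (theta, rho) with rho = R*c, where c is the
#' angular (great-circle) distance from the centre and theta the azimuth seen
#' from the centre, and Cartesian coordinates x = rho*sin(theta),
#' y = -rho*cos(theta). The reference maps to the origin and anterior
#' electrodes to positive y (nose-up orientation). Distances from the centre
#' are preserved proportionally, which is why radial order on the sphere is
#' kept in the plane.
#'
#' @param mon an `eeg_montage`.
#' @param drop_reference drop the centre electrode from the output (default
#'   `TRUE`; the image pipeline works on the 31 non-reference channels).
#' @return data.frame of class `eeg_projection` with columns `label`, `x`,
#'   `y`.
#' @export
project_montage <- function(mon, drop_reference = TRUE) {
  stopifnot(inherits(mon, "eeg_montage"))
  ref_lab <- attr(mon, "reference")
  P <- as.matrix(mon[, c("x", "y", "z")])
  ref <- P[match(ref_lab, mon$label), ]
  # tangent basis at the centre: e_n points anterior, e_e to the right
  anterior <- c(0, 1, 0)
  if (abs(sum(anterior * ref)) > 1 - 1e-9) anterior <- c(0, 0, 1)
  e_n <- anterior - sum(anterior * ref) * ref
  e_n <- e_n / sqrt(sum(e_n^2))
  e_e <- c(e_n[2] * ref[3] - e_n[3] * ref[2],
           e_n[3] * ref[1] - e_n[1] * ref[3],
           e_n[1] * ref[2] - e_n[2] * ref[1])
  cosc <- pmin(1, pmax(-1, P %*% ref))
  cc <- acos(drop(cosc))
  if (any(cc > pi - 1e-6 & mon$label != ref_lab))
    stop("electrode antipodal to the projection centre: azimuthal equidistant projection is singular there")
  d <- P - outer(drop(cosc), ref)
  de <- drop(d %*% e_e)
  dn <- drop(d %*% e_n)
  theta <- atan2(de, -dn)
  theta[cc < 1e-12] <- 0
  rho <- cc  # R = 1 after normalisation
  out <- data.frame(label = mon$label,
                    x = rho * sin(theta),
                    y = -rho * cos(theta),
                    stringsAsFactors = FALSE)
  if (drop_reference) out <- out[out$label != ref_lab, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eeg_projection", "data.frame")
  attr(out, "reference") <- ref_lab
  out
}

# Default bundled montage file.
default_montage <- function() {
  path <- system.file("extdata", "standard_1020_32.sfp", package = "eegcfs")
  if (nzchar(path)) read_montage(path) else montage_standard32()
}
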