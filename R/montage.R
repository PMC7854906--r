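#' Electrode montage
#'
#' Channel names with head-centered 3-d positions normalized to the unit
#' sphere (+z through the vertex, +y through the nasion, +x through the
#' right preauricular point) and, after [azimuthal_project()], 2-d plane
#' coordinates.
#'
#' @param names unique channel labels.
#' @param pos3d numeric matrix `[n_channels, 3]` of positions; rows are
#'   normalized to unit length.
#' @return An object of class `montage`.
#' @export
montage <- function(names, pos3d) {
  names <- as.character(names)
  pos3d <- as.matrix(pos3d)
  if (any(duplicated(names)))
    stop("duplicate channel names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (nrow(pos3d) != length(names) || ncol(pos3d) != 3)
    stop("pos3d must be an [n_channels, 3] matrix")
  if (any(!is.finite(pos3d))) stop("non-finite electrode coordinates")
  r <- sqrt(rowSums(pos3d^2))
  if (any(r == 0)) stop("electrode at the head center cannot be normalized")
  pos3d <- pos3d / r
  rownames(pos3d) <- names
  structure(list(names = names, pos3d = pos3d, pos2d = NULL),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels%s\n", length(x$names),
              if (is.null(x$pos2d)) "" else " (projected)"))
  invisible(x)
}

#' Read a montage file
#'
#' Expects tab-separated `name  x  y  z` rows (header optional). Positions
#' are normalized onto the unit sphere, so the input scale (cm, mm,
#' normalized) is irrelevant.
#'
#' @param path montage file path.
#' @param exclude_ref character vector of channels to drop, e.g. the
#'   reference electrode; `NULL` keeps all.
#' @return A [montage()] object.
#' @export
load_montage <- function(path, exclude_ref = NULL) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 4 && is.na(suppressWarnings(as.numeric(fields[2])))
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("montage file must have columns name, x, y, z")
  m <- montage(tab[[1]], as.matrix(tab[, 2:4]))
  if (!is.null(exclude_ref)) {
    missing <- setdiff(exclude_ref, m$names)
    if (length(missing))
      warning("reference channel(s) not in montage: ",
              paste(missing, collapse = ", "))
    keep <- !(m$names %in% exclude_ref)
    m <- montage(m$names[keep], m$pos3d[keep, , drop = FALSE])
  }
  m
}

#' The packaged 62-channel 10-20 layout
#'
#' An idealized spherical layout of 62 extended 10-20 ("10-10") positions
#' constructed from the system's angular subdivision rules (midline arc in
#' 18-degree steps, outer ring at 72 degrees polar angle, intermediate
#' electrodes on equally subdivided great-circle arcs). With the reference
#' electrode excluded (the default) this yields 61 effective channels.
#'
#' @param exclude_ref reference channel(s) to drop; default `"Fz"`.
#' @return A [montage()] object.
#' @export
packaged_montage <- function(exclude_ref = "Fz") {
  path <- system.file("extdata", "montage_1020_62.tsv", package = "tdann",
                      mustWork = TRUE)
  load_montage(path, exclude_ref = exclude_ref)
}

# spherical point from polar angle (from vertex) and azimuth, degrees;
# azimuth measured counterclockwise from +x (right ear), nasion at 90.
sph_pt <- function(theta, phi) {
  t <- theta * pi / 180; p <- phi * pi / 180
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

# great-circle interpolation between unit vectors
slerp <- function(p, q, t) {
  o <- acos(max(-1, min(1, sum(p * q))))
  if (o < 1e-12) return(p)
  (sin((1 - t) * o) * p + sin(t * o) * q) / sin(o)
}

#' Construct the idealized 62-channel 10-20 layout
#'
#' Builds electrode positions from the 10-20 system's geometric rules on
#' a unit sphere rather than from any digitized head shape: midline
#' electrodes every 18 degrees along the nasion-inion arc, the outer ring
#' at 72 degrees polar angle in 18-degree azimuthal steps, and the
#' intermediate rows (F3, FC5, ...) on equally subdivided great-circle
#' arcs between the midline and the ring.
#'
#' @return A [montage()] object with 62 channels (including Fz).
#' @export
ideal_montage_1020 <- function() {
  pts <- list()
  add <- function(name, p) pts[[name]] <<- p
  # midline: polar angle 18 deg per 10% step; front azimuth 90, back 270
  add("Fpz", sph_pt(72, 90)); add("Fz", sph_pt(36, 90))
  add("FCz", sph_pt(18, 90)); add("Cz", sph_pt(0, 90))
  add("CPz", sph_pt(18, 270)); add("Pz", sph_pt(36, 270))
  add("POz", sph_pt(54, 270)); add("Oz", sph_pt(72, 270))
  # outer ring, 72 deg polar, 18 deg azimuthal steps (left then right)
  ring <- c(Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
            TP7 = 198, P7 = 216, PO7 = 234, O1 = 252,
            Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
            TP8 = -18, P8 = -36, PO8 = -54, O2 = -72)
  for (nm in names(ring)) add(nm, sph_pt(72, ring[[nm]]))
  # intermediate rows: equal subdivision of the arc midline -> ring
  row_arc <- function(mid, ringpt, labels, fracs)
    for (i in seq_along(labels)) add(labels[i], slerp(mid, ringpt, fracs[i]))
  afz <- sph_pt(54, 90) # AFz position used for construction only
  row_arc(afz, pts[["AF7"]], "AF3", 0.5)
  row_arc(afz, pts[["AF8"]], "AF4", 0.5)
  row_arc(pts[["Fz"]], pts[["F7"]], c("F1", "F3", "F5"), c(.25, .5, .75))
  row_arc(pts[["Fz"]], pts[["F8"]], c("F2", "F4", "F6"), c(.25, .5, .75))
  row_arc(pts[["FCz"]], pts[["FT7"]], c("FC1", "FC3", "FC5"), c(.25, .5, .75))
  row_arc(pts[["FCz"]], pts[["FT8"]], c("FC2", "FC4", "FC6"), c(.25, .5, .75))
  row_arc(pts[["Cz"]], pts[["T7"]], c("C1", "C3", "C5"), c(.25, .5, .75))
  row_arc(pts[["Cz"]], pts[["T8"]], c("C2", "C4", "C6"), c(.25, .5, .75))
  row_arc(pts[["CPz"]], pts[["TP7"]], c("CP1", "CP3", "CP5"), c(.25, .5, .75))
  row_arc(pts[["CPz"]], pts[["TP8"]], c("CP2", "CP4", "CP6"), c(.25, .5, .75))
  row_arc(pts[["Pz"]], pts[["P7"]], c("P1", "P3", "P5"), c(.25, .5, .75))
  row_arc(pts[["Pz"]], pts[["P8"]], c("P2", "P4", "P6"), c(.25, .5, .75))
  row_arc(pts[["POz"]], pts[["PO7"]], c("PO3", "PO5"), c(1 / 3, 2 / 3))
  row_arc(pts[["POz"]], pts[["PO8"]], c("PO4", "PO6"), c(1 / 3, 2 / 3))
  montage(names(pts), do.call(rbind, pts))
}

#' Project a montage to the plane
#'
#' Azimuthal equidistant ("polar coordinate") projection about the
#' vertex: an electrode at polar angle theta (arc distance from the
#' vertex) and azimuth phi maps to the plane point at radius theta and the
#' same azimuth, so distances along meridians and electrode adjacency are
#' preserved. The projection is singular at the antipode of the vertex.
#'
#' @param m a [montage()] object.
#' @return The montage with a `pos2d` `[n_channels, 2]` matrix attached.
#' @export
azimuthal_project <- function(m) {
  stopifnot(inherits(m, "montage"))
  z <- pmin(1, pmax(-1, m$pos3d[, 3]))
  theta <- acos(z)
  if (any(theta > pi - 1e-6))
    stop("electrode(s) at the projection antipode (polar angle pi): ",
         paste(m$names[theta > pi - 1e-6], collapse = ", "))
  phi <- atan2(m$pos3d[, 2], m$pos3d[, 1])
  pos2d <- cbind(theta * cos(phi), theta * sin(phi))
  # exact center for the vertex itself (phi undefined there)
  pos2d[theta < 1e-12, ] <- 0
  rownames(pos2d) <- m$names
  m$pos2d <- pos2d
  m
}
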