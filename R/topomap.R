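# Scattered-data rendering of per-channel values into square scalp
# images: Delaunay triangulation (Bowyer-Watson), per-vertex gradient
# estimation, and the reduced Clough-Tocher C1 piecewise-cubic element.
# No installed package provides scattered C1 interpolation, so the
# primitive is implemented here; the whole render is linear in the
# per-channel values, which lets a pixel-by-channel operator matrix be
# precomputed once per montage/resolution and reused for every window and
# band.

# Deterministic sub-nanometer jitter to break cocircular degeneracies
# (10-20 layouts put electrodes on exact circles). Derived from the
# coordinates themselves so that renders are equivariant under channel
# permutations.
.jitter_points <- function(p, eps = 1e-9) {
  scale <- max(apply(p, 2, function(v) diff(range(v))), 1e-12)
  xn <- p[, 1] / scale; yn <- p[, 2] / scale
  u1 <- (sin(xn * 127.1 + yn * 311.7) * 43758.5453) %% 1 - 0.5
  u2 <- (sin(xn * 269.5 + yn * 183.3) * 12578.1459) %% 1 - 0.5
  p + eps * scale * cbind(u1, u2)
}

# signed doubled area of triangle abc (positive if counterclockwise)
.orient2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# is d strictly inside the circumcircle of ccw triangle abc
.incircle <- function(a, b, c, d) {
  m <- rbind(c(a[1] - d[1], a[2] - d[2], (a[1]^2 - d[1]^2) + (a[2]^2 - d[2]^2)),
             c(b[1] - d[1], b[2] - d[2], (b[1]^2 - d[1]^2) + (b[2]^2 - d[2]^2)),
             c(c[1] - d[1], c[2] - d[2], (c[1]^2 - d[1]^2) + (c[2]^2 - d[2]^2)))
  det(m) > 0
}

# Bowyer-Watson Delaunay triangulation of n >= 3 points (rows of p).
# Returns an m x 3 integer matrix of counterclockwise triangles.
delaunay_triangulate <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) stop("triangulation needs at least 3 points")
  spans <- apply(p, 2, function(v) diff(range(v)))
  areas <- abs(vapply(3:n, function(i) .orient2(p[1, ], p[2, ], p[i, ]),
                      numeric(1)))
  if (max(spans) == 0 || all(areas < 1e-12 * max(spans)^2))
    stop("all points are collinear: cannot triangulate")
  ctr <- colMeans(p)
  rad <- max(sqrt(rowSums(sweep(p, 2, ctr)^2))) * 1e3 + 1
  sup <- rbind(ctr + rad * c(0, 2.1),
               ctr + rad * c(-2.0, -1.2),
               ctr + rad * c(2.0, -1.2))
  pts <- rbind(p, sup)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  if (.orient2(pts[tris[1, 1], ], pts[tris[1, 2], ], pts[tris[1, 3], ]) < 0)
    tris <- tris[, c(1, 3, 2), drop = FALSE]
  for (i in seq_len(n)) {
    d <- pts[i, ]
    bad <- vapply(seq_len(nrow(tris)), function(t)
      .incircle(pts[tris[t, 1], ], pts[tris[t, 2], ], pts[tris[t, 3], ], d),
      logical(1))
    if (!any(bad)) stop("triangulation failed: point ", i,
                        " inside no circumcircle (degenerate input?)")
    # boundary = edges of the bad region that appear exactly once
    edges <- do.call(rbind, lapply(which(bad), function(t)
      rbind(tris[t, c(1, 2)], tris[t, c(2, 3)], tris[t, c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    # keep counterclockwise orientation
    for (r in seq_len(nrow(newt))) {
      if (.orient2(pts[newt[r, 1], ], pts[newt[r, 2], ], pts[newt[r, 3], ]) < 0)
        newt[r, ] <- newt[r, c(2, 1, 3)]
    }
    tris <- rbind(tris, newt)
  }
  keep <- apply(tris <= n, 1, all)
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) stop("all points are collinear: cannot triangulate")
  storage.mode(tris) <- "integer"
  tris
}

# Per-vertex gradient estimation: weighted least-squares plane through a
# vertex and its triangulation neighbors (exact for linear fields).
# Returns a list of (neighbor indices, 2 x k coefficient matrix); the
# gradient at vertex i is coef %*% (f[nbr] - f[i]).
.vertex_gradients <- function(p, tris) {
  n <- nrow(p)
  nbrs <- vector("list", n)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    for (j in 1:3)
      nbrs[[v[j]]] <- union(nbrs[[v[j]]], v[-j])
  }
  lapply(seq_len(n), function(i) {
    nb <- nbrs[[i]]
    d <- sweep(p[nb, , drop = FALSE], 2, p[i, ])
    w <- 1 / sqrt(rowSums(d^2))
    a <- crossprod(d * w, d * w)
    if (rcond(a) < 1e-12)
      stop("degenerate neighborhood at point ", i, " (collinear electrodes)")
    list(nbr = nb, coef = solve(a, t(d * w^2)))
  })
}

# Reduced Clough-Tocher coefficients for one triangle, from vertex values
# f (3) and gradients g (3 x 2). Returns the 3 x 10 Bezier ordinates of
# the three subtriangles (V1,V2,V4), (V2,V3,V4), (V3,V1,V4) with V4 the
# centroid; column order b300,b030,b003,b210,b120,b021,b012,b102,b201,b111.
.ct_coefficients <- function(P, f, g) {
  P4 <- colMeans(P)
  c3000 <- f[1]; c0300 <- f[2]; c0030 <- f[3]
  c2100 <- f[1] + sum(g[1, ] * (P[2, ] - P[1, ])) / 3
  c2010 <- f[1] + sum(g[1, ] * (P[3, ] - P[1, ])) / 3
  c1200 <- f[2] + sum(g[2, ] * (P[1, ] - P[2, ])) / 3
  c0210 <- f[2] + sum(g[2, ] * (P[3, ] - P[2, ])) / 3
  c1020 <- f[3] + sum(g[3, ] * (P[1, ] - P[3, ])) / 3
  c0120 <- f[3] + sum(g[3, ] * (P[2, ] - P[3, ])) / 3
  c2001 <- (c3000 + c2100 + c2010) / 3
  c0201 <- (c0300 + c1200 + c0210) / 3
  c0021 <- (c0030 + c1020 + c0120) / 3
  # b111 of a subtriangle: impose that the derivative across the outer
  # edge (in the edge-normal direction) varies linearly along the edge
  b111_outer <- function(A, B, b300, b210, b120, b030, b201, b021) {
    e <- B - A; e4 <- P4 - A
    w <- c(-e[2], e[1]) # edge normal
    beta <- solve(cbind(e, e4), w)
    a1 <- -sum(beta); a2 <- beta[1]; a4 <- beta[2]
    ((a1 * (b300 + b120) + a2 * (b210 + b030) + a4 * (b201 + b021)) / 2 -
       a1 * b210 - a2 * b120) / a4
  }
  c1101 <- b111_outer(P[1, ], P[2, ], c3000, c2100, c1200, c0300, c2001, c0201)
  c0111 <- b111_outer(P[2, ], P[3, ], c0300, c0210, c0120, c0030, c0201, c0021)
  c1011 <- b111_outer(P[3, ], P[1, ], c0030, c1020, c2010, c3000, c0021, c2001)
  # C1 conditions across the three internal (vertex-centroid) edges
  c1002 <- (c1101 + c1011 + c2001) / 3
  c0102 <- (c1101 + c0111 + c0201) / 3
  c0012 <- (c1011 + c0111 + c0021) / 3
  c0003 <- (c1002 + c0102 + c0012) / 3
  rbind(
    c(c3000, c0300, c0003, c2100, c1200, c0201, c0102, c1002, c2001, c1101),
    c(c0300, c0030, c0003, c0210, c0120, c0021, c0012, c0102, c0201, c0111),
    c(c0030, c3000, c0003, c1020, c2010, c2001, c1002, c0012, c0021, c1011))
}

# evaluate a cubic Bezier triangle at barycentric (u, v, w) vectors
.bb3_eval <- function(b, u, v, w) {
  b[1] * u^3 + b[2] * v^3 + b[3] * w^3 +
    3 * (b[4] * u^2 * v + b[5] * u * v^2 + b[6] * v^2 * w +
           b[7] * v * w^2 + b[8] * u * w^2 + b[9] * u^2 * w) +
    6 * b[10] * u * v * w
}

#' Precompute a topographic rendering operator
#'
#' The Clough-Tocher interpolant is linear in the per-channel values, so
#' rendering reduces to one precomputed `[pixels, channels]` matrix per
#' montage/resolution pair. The grid is the square bounding box of the
#' projected electrodes plus a fractional margin; image row 1 is the
#' front of the head (nasion up), columns run left to right.
#'
#' @param pos2d projected electrode coordinates `[n, 2]` (see
#'   [azimuthal_project()]).
#' @param resolution image side length in pixels (default 32).
#' @param margin fractional margin added around the electrode bounding
#'   square.
#' @return A `topomap_operator` object with elements `matrix`
#'   (`[resolution^2, n]`, in-hull pixels only contribute), `mask`
#'   (logical `[resolution, resolution]`), `extent` and `resolution`.
#' @export
topomap_operator <- function(pos2d, resolution = 32L, margin = 0.05) {
  pos2d <- as.matrix(pos2d)
  n <- nrow(pos2d)
  if (n < 4) stop("need at least 4 electrodes to render a topomap")
  if (resolution < 2) stop("resolution must be at least 2")
  pj <- .jitter_points(pos2d)
  tris <- delaunay_triangulate(pj)
  grads <- .vertex_gradients(pj, tris)
  ctr <- c(mean(range(pj[, 1])), mean(range(pj[, 2])))
  hs <- max(diff(range(pj[, 1])), diff(range(pj[, 2]))) / 2 * (1 + margin)
  gx <- seq(ctr[1] - hs, ctr[1] + hs, length.out = resolution)
  gy <- seq(ctr[2] + hs, ctr[2] - hs, length.out = resolution) # row 1 = front
  # pixel grid in image order (row index fastest)
  px <- rep(gx, each = resolution)
  py <- rep(gy, times = resolution)
  npix <- resolution^2
  tri_of <- integer(npix)
  bary <- matrix(0, npix, 3)
  tol <- -1e-9
  for (t in seq_len(nrow(tris))) {
    A <- pj[tris[t, 1], ]; B <- pj[tris[t, 2], ]; C <- pj[tris[t, 3], ]
    det <- .orient2(A, B, C)
    l1 <- ((B[2] - C[2]) * (px - C[1]) + (C[1] - B[1]) * (py - C[2])) / det
    l2 <- ((C[2] - A[2]) * (px - C[1]) + (A[1] - C[1]) * (py - C[2])) / det
    l3 <- 1 - l1 - l2
    inside <- tri_of == 0L & l1 >= tol & l2 >= tol & l3 >= tol
    tri_of[inside] <- t
    bary[inside, ] <- cbind(l1[inside], l2[inside], l3[inside])
  }
  mask <- matrix(tri_of > 0L, resolution, resolution)
  M <- matrix(0, npix, n)
  for (j in seq_len(n)) {
    f <- numeric(n); f[j] <- 1
    g <- t(vapply(seq_len(n), function(i)
      as.numeric(grads[[i]]$coef %*% (f[grads[[i]]$nbr] - f[i])),
      numeric(2)))
    for (t in unique(tri_of[tri_of > 0L])) {
      v <- tris[t, ]
      if (all(f[v] == 0) && all(g[v, ] == 0)) next
      bez <- .ct_coefficients(pj[v, , drop = FALSE], f[v], g[v, , drop = FALSE])
      idx <- which(tri_of == t)
      l <- bary[idx, , drop = FALSE]
      # locate the subtriangle: k = index of the smallest barycentric
      u1 <- l[, 1] - l[, 3]; v1 <- l[, 2] - l[, 3] # sub 1: V1,V2,V4
      u2 <- l[, 2] - l[, 1]; v2 <- l[, 3] - l[, 1] # sub 2: V2,V3,V4
      u3 <- l[, 3] - l[, 2]; v3 <- l[, 1] - l[, 2] # sub 3: V3,V1,V4
      s1 <- pmin(u1, v1); s2 <- pmin(u2, v2); s3 <- pmin(u3, v3)
      sub <- max.col(cbind(s1, s2, s3), ties.method = "first")
      val <- numeric(length(idx))
      for (k in 1:3) {
        sel <- sub == k
        if (!any(sel)) next
        uu <- switch(k, u1, u2, u3)[sel]
        vv <- switch(k, v1, v2, v3)[sel]
        ww <- 3 * switch(k, l[sel, 3], l[sel, 1], l[sel, 2])
        val[sel] <- .bb3_eval(bez[k, ], uu, vv, ww)
      }
      M[idx, j] <- M[idx, j] + val
    }
  }
  structure(
    list(matrix = M, mask = mask, resolution = as.integer(resolution),
         extent = c(xmin = ctr[1] - hs, xmax = ctr[1] + hs,
                    ymin = ctr[2] - hs, ymax = ctr[2] + hs),
         n_channels = n, tri = tris),
    class = "topomap_operator")
}

#' Render one topographic map
#'
#' Clough-Tocher (C1 piecewise-cubic on the Delaunay triangulation)
#' interpolation of per-electrode values onto a square pixel grid; pixels
#' outside the electrode convex hull take the fill value.
#'
#' @param values numeric vector, one value per electrode.
#' @param pos2d projected electrode coordinates `[n, 2]`; ignored when
#'   `op` is supplied.
#' @param resolution image side length in pixels.
#' @param fill value assigned outside the convex hull.
#' @param margin see [topomap_operator()].
#' @param op optional precomputed [topomap_operator()] (reuse it when
#'   rendering many maps for the same montage).
#' @return Numeric `[resolution, resolution]` matrix, row 1 = front.
#' @export
render_topomap <- function(values, pos2d = NULL, resolution = 32L, fill = 0,
                           margin = 0.05, op = NULL) {
  if (is.null(op)) op <- topomap_operator(pos2d, resolution, margin)
  if (length(values) != op$n_channels)
    stop("expected ", op$n_channels, " values, got ", length(values))
  img <- matrix(op$matrix %*% as.numeric(values),
                op$resolution, op$resolution)
  img[!op$mask] <- fill
  img
}

#' Render a stack of per-band feature images
#'
#' One topographic map per window and band, sharing a single precomputed
#' interpolation operator. The montage is aligned to the feature channel
#' order (it may be a superset; unused montage channels are dropped);
#' feature channels absent from the montage are an error.
#'
#' @param features a `de_features` object from [extract_de_features()].
#' @param m a projected [montage()]; [azimuthal_project()] is applied if
#'   needed.
#' @param resolution image side length in pixels (default 32, giving the
#'   standard 32 x 32 x 5 image per window).
#' @param fill out-of-hull fill value.
#' @param margin see [topomap_operator()].
#' @return A `topo_images` object: `images` `[n_windows, H, W, n_bands]`,
#'   the grid `mask`/`extent`, and propagated `labels`/`domains`/`bands`.
#' @export
render_image_stack <- function(features, m, resolution = 32L, fill = 0,
                               margin = 0.05) {
  stopifnot(inherits(features, "de_features"), inherits(m, "montage"))
  if (is.null(m$pos2d)) m <- azimuthal_project(m)
  fn <- features$channel_names
  extra <- setdiff(fn, m$names)
  if (length(extra))
    stop("channel mismatch between features and montage; not in montage: ",
         paste(extra, collapse = ", "))
  pos2d <- m$pos2d[match(fn, m$names), , drop = FALSE]
  op <- topomap_operator(pos2d, resolution, margin)
  d <- dim(features$values)
  nw <- d[1]; nc <- d[2]; nb <- d[3]
  # one matrix product renders every window and band at once
  vals <- matrix(aperm(features$values, c(2, 1, 3)), nrow = nc) # nc x (nw*nb)
  pix <- op$matrix %*% vals                                     # npix x (nw*nb)
  pix[!op$mask, ] <- fill
  images <- aperm(array(pix, c(resolution, resolution, nw, nb)), c(3, 1, 2, 4))
  structure(
    list(images = images, resolution = as.integer(resolution),
         extent = op$extent, mask = op$mask, fill = fill,
         labels = features$labels, domains = features$domains,
         bands = features$bands, normalized = FALSE),
    class = "topo_images")
}

#' @export
print.topo_images <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<topo_images> %d windows x %d x %d x %d bands%s\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$normalized)) " (min-max standardized)" else ""))
  invisible(x)
}

#' Min-max standardize image stacks
#'
#' Affinely maps each scoped group of in-mask pixels so its minimum
#' becomes 0 and maximum 1 (a degenerate constant group maps to 0).
#' Out-of-hull pixels keep the fill value.
#'
#' @param x a `topo_images` object.
#' @param scope `"per_image_band"` (each window-band slice independently;
#'   the default) or `"per_band_global"` (one range per band across all
#'   windows).
#' @return The standardized `topo_images` object.
#' @export
minmax_standardize <- function(x, scope = c("per_image_band",
                                            "per_band_global")) {
  stopifnot(inherits(x, "topo_images"))
  scope <- match.arg(scope)
  mask <- as.vector(x$mask)
  if (!any(mask)) stop("empty in-hull mask")
  d <- dim(x$images)
  nw <- d[1]; npix <- d[2] * d[3]; nb <- d[4]
  # windows x pixels x bands with pixel axis flattened
  arr <- array(x$images, c(nw, npix, nb))
  for (b in seq_len(nb)) {
    sl <- arr[, mask, b, drop = FALSE]
    if (scope == "per_band_global") {
      lo <- min(sl); hi <- max(sl)
      arr[, mask, b] <- if (hi > lo) (sl - lo) / (hi - lo) else 0
    } else {
      lo <- apply(sl, 1, min); hi <- apply(sl, 1, max)
      rng <- hi - lo
      scaled <- sweep(sl, 1, lo)
      scaled <- sweep(scaled, 1, ifelse(rng > 0, rng, 1), "/")
      scaled[rng == 0, , ] <- 0
      arr[, mask, b] <- scaled
    }
    arr[, !mask, b] <- x$fill
  }
  x$images <- array(arr, d)
  x$normalized <- TRUE
  x
}
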