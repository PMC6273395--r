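# Linear interpolation between two geometries, in cartesian or internal
# (bond/angle/torsion) coordinates, for approximate reaction paths.

# internal coordinates of a geometry under the chain Z-matrix convention:
# atom i is placed by distance to i-1, angle to (i-1, i-2), torsion to
# (i-1, i-2, i-3)
.chain_internals <- function(g) {
  n <- nrow(g)
  bonds <- angles <- torsions <- numeric(0)
  if (n >= 2)
    bonds <- vapply(2:n, function(i) sqrt(sum((g[i, ] - g[i - 1, ])^2)), 0)
  if (n >= 3)
    angles <- vapply(3:n, function(i) {
      u <- g[i - 2, ] - g[i - 1, ]; v <- g[i, ] - g[i - 1, ]
      acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    }, 0)
  if (n >= 4)
    torsions <- vapply(4:n, function(i) {
      b1 <- g[i - 2, ] - g[i - 3, ]
      b2 <- g[i - 1, ] - g[i - 2, ]
      b3 <- g[i, ] - g[i - 1, ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
              n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
      atan2(sum(m1 * n2), sum(n1 * n2))
    }, 0)
  list(bonds = bonds, angles = angles, torsions = torsions)
}

# rebuild cartesian geometry from chain internals (natural extension
# reference frame placement)
.chain_rebuild <- function(ints, n) {
  g <- matrix(0, n, 3)
  if (n >= 2) g[2, ] <- c(ints$bonds[1], 0, 0)
  if (n >= 3) {
    a <- ints$angles[1]
    g[3, ] <- g[2, ] + ints$bonds[2] *
      c(-cos(a), sin(a), 0)
  }
  if (n >= 4) for (i in 4:n) {
    r <- ints$bonds[i - 1]
    a <- ints$angles[i - 2]
    tor <- ints$torsions[i - 3]
    b2 <- g[i - 1, ] - g[i - 2, ]
    b1 <- g[i - 2, ] - g[i - 3, ]
    u2 <- b2 / sqrt(sum(b2^2))
    nvec <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
    nvec <- nvec / sqrt(sum(nvec^2))
    mvec <- c(nvec[2] * u2[3] - nvec[3] * u2[2],
              nvec[3] * u2[1] - nvec[1] * u2[3],
              nvec[1] * u2[2] - nvec[2] * u2[1])
    d <- r * c(-cos(a), sin(a) * cos(tor), -sin(a) * sin(tor))
    g[i, ] <- g[i - 1, ] + d[1] * u2 + d[2] * mvec + d[3] * nvec
  }
  g
}

# rigid-body (Kabsch) alignment of g onto ref
.kabsch <- function(g, ref) {
  cg <- colMeans(g); cr <- colMeans(ref)
  A <- sweep(g, 2, cg); B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A %*% t(R), 2, cr, `+`)
}

#' Linearly interpolated path between two geometries
#'
#' Generates `n_images` geometries between (and including) the endpoints.
#' In `"cartesian"` mode coordinates are interpolated componentwise. In
#' `"internal"` mode (the default) chain bond/angle/torsion internals are
#' interpolated -- torsions along the shortest arc -- and each image is
#' rebuilt and rigidly aligned to the first endpoint's frame; this is the
#' usual way to avoid unphysically shrinking bonds along rotations. If the
#' internal set is degenerate (collinear triples), the cartesian route is
#' used with a warning.
#'
#' @param geom_a,geom_b `n_atoms x 3` matrices (Angstrom); optionally with
#'   an `elements` attribute, which must match between endpoints.
#' @param n_images Total number of images including endpoints (>= 2).
#' @param coords `"internal"` or `"cartesian"`.
#' @return List of `n_images` geometry matrices; attribute `coords` notes
#'   the coordinate system actually used.
#' @export
liic_path <- function(geom_a, geom_b, n_images = 10, coords = "internal") {
  geom_a <- as.matrix(geom_a); geom_b <- as.matrix(geom_b)
  if (!all(dim(geom_a) == dim(geom_b)))
    stop("endpoint geometries have different atom counts")
  ea <- attr(geom_a, "elements"); eb <- attr(geom_b, "elements")
  if (!is.null(ea) && !is.null(eb) && !identical(ea, eb))
    stop("endpoint element lists differ")
  stopifnot(n_images >= 2)
  s <- seq(0, 1, length.out = n_images)
  if (coords == "internal" && nrow(geom_a) >= 3) {
    ia <- .chain_internals(geom_a)
    ib <- .chain_internals(geom_b)
    ok <- all(ia$angles > 1e-3, ia$angles < pi - 1e-3,
              ib$angles > 1e-3, ib$angles < pi - 1e-3)
    if (!ok) {
      warning("degenerate internal coordinates (collinear atoms); ",
              "falling back to cartesian interpolation")
      coords <- "cartesian"
    } else {
      dtor <- ib$torsions - ia$torsions
      dtor <- (dtor + pi) %% (2 * pi) - pi   # shortest arc
      imgs <- lapply(s, function(w) {
        ints <- list(bonds = (1 - w) * ia$bonds + w * ib$bonds,
                     angles = (1 - w) * ia$angles + w * ib$angles,
                     torsions = ia$torsions + w * dtor)
        .kabsch(.chain_rebuild(ints, nrow(geom_a)), geom_a)
      })
      attr(imgs, "coords") <- "internal"
      return(imgs)
    }
  }
  imgs <- lapply(s, function(w) (1 - w) * geom_a + w * geom_b)
  attr(imgs, "coords") <- "cartesian"
  imgs
}
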