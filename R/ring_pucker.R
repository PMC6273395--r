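# Cremer-Pople puckering coordinates (Q, theta, phi) for six-membered
# rings, the inverse construction, Boeyens conformer classification and
# hop-geometry polar maps.
#
# Conventions: ring atoms are indexed 1..6 in traversal order (for
# thymine-like input N1, C2, N3, C4, C5, C6). The mean plane follows the
# original Cremer-Pople prescription (centroid origin, plane normal
# R' x R''); the m = 2 phase uses the negative-sine convention. The
# reference hexagon of the inverse map is traversed clockwise when viewed
# from +z, which makes a boat with atoms 3 and 6 displaced towards +z come
# out at (theta, phi) = (90, 120) -- the 3,6-boat.

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Computes out-of-plane displacements `z_j` relative to the mean plane
#' (centroid origin, normal along `R' x R''` with
#' `R' = sum_j r_j sin(2 pi (j-1)/6)`, `R'' = sum_j r_j cos(2 pi (j-1)/6)`),
#' then the puckering amplitudes from the trigonometric sums
#' `q2 cos(phi2) = sqrt(1/3) sum z_j cos(4 pi (j-1)/6)`,
#' `q2 sin(phi2) = -sqrt(1/3) sum z_j sin(4 pi (j-1)/6)`,
#' `q3 = sqrt(1/6) sum (-1)^(j-1) z_j`, and finally
#' `Q = sqrt(q2^2 + q3^2)`, `cos(theta) = q3/Q`.
#'
#' @param ring 6 x 3 matrix of atom positions (Angstrom) in ring order.
#' @param classify Attach the Boeyens conformer label? Default `TRUE`.
#' @return Object of class `pucker_params` with `Q` (Angstrom), `theta`,
#'   `phi` (degrees), `q2`, `q3`, `z` and the Boeyens `conformer` label.
#'   Rings with `Q < 1e-6` are flagged planar (`theta`/`phi` are `NA`).
#' @export
cremer_pople <- function(ring, classify = TRUE) {
  ring <- as.matrix(ring)
  if (!all(dim(ring) == c(6, 3)))
    stop("ring must be a 6 x 3 coordinate matrix")
  ctr <- colMeans(ring)
  r <- sweep(ring, 2, ctr)
  ang <- 2 * pi * (0:5) / 6
  Rp <- colSums(r * sin(ang))
  Rpp <- colSums(r * cos(ang))
  nrm <- c(Rp[2] * Rpp[3] - Rp[3] * Rpp[2],
           Rp[3] * Rpp[1] - Rp[1] * Rpp[3],
           Rp[1] * Rpp[2] - Rp[2] * Rpp[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate (collinear) ring geometry")
  nrm <- nrm / nn
  z <- drop(r %*% nrm)
  q2c <- sqrt(1 / 3) * sum(z * cos(2 * ang))
  q2s <- -sqrt(1 / 3) * sum(z * sin(2 * ang))
  q3 <- sqrt(1 / 6) * sum(z * c(1, -1, 1, -1, 1, -1))
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < 1e-6) {
    theta <- NA_real_; phi <- NA_real_; conf <- "planar"
  } else {
    theta <- acos(max(-1, min(1, q3 / Q))) * 180 / pi
    phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
    conf <- if (classify) boeyens_classify(theta, phi) else NA_character_
  }
  structure(list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3,
                 z = z, conformer = conf),
            class = "pucker_params")
}

#' @export
print.pucker_params <- function(x, ...) {
  if (x$conformer == "planar")
    cat(sprintf("<pucker: planar (Q = %.2e A)>\n", x$Q))
  else
    cat(sprintf("<pucker: Q = %.3f A, theta = %.1f deg, phi = %.1f deg, %s>\n",
                x$Q, x$theta, x$phi, x$conformer))
  invisible(x)
}

#' Ring geometry from Cremer-Pople parameters
#'
#' Builds a regular hexagon (clockwise seen from +z, consistent with the
#' forward map's plane convention) and adds the out-of-plane pattern
#' `z_j = sqrt(1/3) q2 cos(phi + 4 pi (j-1)/6) +
#' sqrt(1/6) q3 (-1)^(j-1)` with `q2 = Q sin(theta)`,
#' `q3 = Q cos(theta)`.
#'
#' @param Q Total puckering amplitude (Angstrom), non-negative.
#' @param theta,phi Puckering angles (degrees).
#' @param base_radius Hexagon circumradius (Angstrom), default 1.40.
#' @return 6 x 3 coordinate matrix.
#' @export
cremer_pople_inverse <- function(Q, theta, phi, base_radius = 1.40) {
  stopifnot(Q >= 0)
  th <- theta * pi / 180
  ph <- phi * pi / 180
  q2 <- Q * sin(th)
  q3 <- Q * cos(th)
  ang <- 2 * pi * (0:5) / 6
  z <- sqrt(1 / 3) * q2 * cos(ph + 2 * ang) +
    sqrt(1 / 6) * q3 * c(1, -1, 1, -1, 1, -1)
  cbind(base_radius * cos(-ang), base_radius * sin(-ang), z)
}

# ---- Boeyens canonical conformers -----------------------------------------

# The 38 canonical conformers are generated geometrically: chairs and
# boats/twist-boats from their ideal displacement patterns, envelopes and
# half-chairs from five-atoms-coplanar constructions, all pushed through
# the forward map so the canonical (theta, phi) automatically respect this
# package's sign conventions.
.boeyens_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    rows <- list()
    hex <- cremer_pople_inverse(0, 0, 0)
    add <- function(label, z) {
      g <- hex; g[, 3] <- z
      cp <- cremer_pople(g, classify = FALSE)
      rows[[length(rows) + 1]] <<-
        data.frame(label = label, theta = cp$theta, phi = cp$phi)
    }
    d <- 0.25
    alt <- c(1, -1, 1, -1, 1, -1)
    add("1C4", d * alt)          # atoms 1,3,5 up: theta = 0
    add("4C1", -d * alt)         # theta = 180
    boat <- c(-0.5, -0.5, 1, -0.5, -0.5, 1)  # atoms 3,6 up
    shift <- function(v, k) v[((seq_along(v) - 1 - k) %% 6) + 1]
    add("3,6B", d * boat)
    add("1,4B", d * shift(boat, 4))
    add("2,5B", d * shift(boat, 5))
    add("B3,6", -d * boat)
    add("B1,4", -d * shift(boat, 4))
    add("B2,5", -d * shift(boat, 5))
    # the twist pattern has period 3, so the six twist-boats are the three
    # cyclic shifts and their negations
    twist <- c(1, -1, 0, 1, -1, 0)           # atoms 1,4 up; 2,5 down
    for (k in 0:2) for (s in c(1, -1)) {
      v <- s * shift(twist, k)
      up <- which(v > 0.5); dn <- which(v < -0.5)
      add(sprintf("%dT%d", min(up), min(dn)), d * v)
    }
    for (j in 1:6) {            # envelopes: single atom out of plane
      z <- numeric(6); z[j] <- 1
      add(sprintf("%dE", j), d * z)
      add(sprintf("E%d", j), -d * z)
    }
    for (j in 1:6) {            # half-chairs: adjacent pair, opposite sides
      jj <- j %% 6 + 1
      z <- numeric(6); z[j] <- 1; z[jj] <- -1
      add(sprintf("%dH%d", j, jj), d * z)
      add(sprintf("%dH%d", jj, j), -d * z)
    }
    tab <<- do.call(rbind, rows)
    tab
  }
})

#' Canonical Boeyens conformer table
#'
#' The 38 canonical six-ring conformers (2 chairs, 6 boats, 6 twist-boats,
#' 12 envelopes, 12 half-chairs) with their canonical Cremer-Pople angles
#' under this package's conventions.
#'
#' @return Data frame with columns `label`, `theta`, `phi` (degrees).
#' @export
boeyens_table <- function() .boeyens_table()

#' Boeyens conformer classification
#'
#' Assigns the nearest canonical conformer on the (theta, phi) sphere by
#' great-circle distance. Exact ties (within 1e-9) are broken toward the
#' candidate with lower phi, then lower theta.
#'
#' @param theta,phi Puckering angles (degrees). `NA` returns `"planar"`.
#' @return Canonical conformer label.
#' @export
boeyens_classify <- function(theta, phi) {
  if (is.na(theta) || is.na(phi)) return("planar")
  tab <- .boeyens_table()
  t1 <- theta * pi / 180; p1 <- phi * pi / 180
  t2 <- tab$theta * pi / 180; p2 <- tab$phi * pi / 180
  d <- acos(pmax(-1, pmin(1, cos(t1) * cos(t2) +
                            sin(t1) * sin(t2) * cos(p1 - p2))))
  best <- which(d <= min(d) + 1e-9)
  if (length(best) > 1)
    best <- best[order(tab$phi[best], tab$theta[best])][1]
  tab$label[best]
}

#' Puckering map of hop geometries
#'
#' One row per hop event carrying ring coordinates: Cremer-Pople
#' parameters, conformer and hop time, with phi symmetry-projected into
#' the [0, 180) half (phi >= 180 reflected to 360 - phi). Hops without
#' ring coordinates are skipped and counted. The Pearson correlation of
#' projected phi with hop time is attached as attribute `phi_time_cor`.
#'
#' @param hops Data frame of hop events with a `coords` list column (model
#'   coordinates) or a `ring` list column (6 x 3 geometries), plus `time`.
#' @param ring_adapter Function mapping model coordinates to a 6 x 3 ring
#'   geometry; required when `hops` has no `ring` column.
#' @return Data frame with columns `time`, `Q`, `theta`, `phi`,
#'   `phi_projected`, `conformer`; attributes `n_skipped`, `phi_time_cor`.
#' @export
hop_pucker_map <- function(hops, ring_adapter = NULL) {
  if (!nrow(hops)) {
    out <- data.frame(time = numeric(0), Q = numeric(0),
                      theta = numeric(0), phi = numeric(0),
                      phi_projected = numeric(0),
                      conformer = character(0))
    attr(out, "n_skipped") <- 0L
    attr(out, "phi_time_cor") <- NA_real_
    return(out)
  }
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(hops))) {
    ring <- NULL
    if (!is.null(hops$ring)) ring <- hops$ring[[i]]
    else if (!is.null(ring_adapter) && !is.null(hops$coords))
      ring <- ring_adapter(hops$coords[[i]])
    if (is.null(ring)) { skipped <- skipped + 1L; next }
    cp <- cremer_pople(ring)
    phi_p <- if (is.na(cp$phi)) NA_real_
             else if (cp$phi >= 180) 360 - cp$phi else cp$phi
    rows[[length(rows) + 1]] <-
      data.frame(time = hops$time[i], Q = cp$Q, theta = cp$theta,
                 phi = cp$phi, phi_projected = phi_p,
                 conformer = cp$conformer)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(time = numeric(0), Q = numeric(0),
                         theta = numeric(0), phi = numeric(0),
                         phi_projected = numeric(0),
                         conformer = character(0))
  attr(out, "n_skipped") <- skipped
  attr(out, "phi_time_cor") <-
    if (nrow(out) > 2 && stats::sd(out$phi_projected) > 0 &&
        stats::sd(out$time) > 0)
      stats::cor(out$phi_projected, out$time)
    else NA_real_
  out
}
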