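## Structured tetrahedral meshing of axisymmetric cell shapes.
##
## The cell model is a solid of revolution about the z (division) axis.
## Meshes are built from a radial profile r(z): a stack of triangulated
## disks (one per axial station) connected by prisms, each prism split into
## three tetrahedra with face diagonals chosen through the smallest global
## vertex index, which makes the subdivision conforming across neighbouring
## prisms. The construction is fully deterministic.

#' Signed volumes of tetrahedra
#' @param nodes numeric n x 3 node coordinate matrix
#' @param elems integer m x 4 tetrahedron connectivity
#' @return numeric vector of signed volumes
#' @keywords internal
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c3 <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
     b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
     b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

## Triangulation template of a disk with one centre node and `m` concentric
## rings of `K` nodes. Local ids: centre = 1, ring j node k = 1 + (j-1)*K + k.
disk_triangles <- function(m, K) {
  tris <- vector("list", m)
  k1 <- seq_len(K)
  k2 <- c(seq_len(K - 1) + 1, 1)
  tris[[1]] <- cbind(1L, 1L + k1, 1L + k2)
  if (m > 1) {
    for (j in seq_len(m - 1)) {
      a <- 1L + (j - 1L) * K + k1   # ring j
      b <- 1L + (j - 1L) * K + k2
      d <- 1L + j * K + k1          # ring j + 1
      c3 <- 1L + j * K + k2
      tris[[j + 1]] <- rbind(cbind(a, b, c3), cbind(a, c3, d))
    }
  }
  do.call(rbind, tris)
}

## Split a stack of prisms into tetrahedra. `bot`, `top`: p x 3 global node
## ids, column i of `top` lies above column i of `bot`. Face diagonals pass
## through the smallest global index of each quad face, so the subdivision
## conforms between neighbouring prisms and slabs.
prisms_to_tets <- function(bot, top) {
  p <- nrow(bot)
  v <- cbind(bot, top)
  out <- matrix(0L, 3L * p, 4L)
  for (i in seq_len(p)) {
    w <- v[i, ]
    if (which.min(w) > 3L) w <- c(w[4:6], w[1:3])      # smallest on bottom
    rot <- (which.min(w[1:3]) - 1L)
    if (rot > 0L) {
      ord <- ((0:2 + rot) %% 3L) + 1L
      w <- c(w[1:3][ord], w[4:6][ord])
    }
    ## w[1] is the global minimum; forced diagonals w1-w5, w1-w6.
    q <- w[c(2, 3, 5, 6)]
    if (which.min(q) %in% c(1L, 4L)) {                  # diagonal w2-w6
      tets <- rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
    } else {                                            # diagonal w3-w5
      tets <- rbind(w[c(1, 2, 3, 5)], w[c(1, 3, 6, 5)], w[c(1, 5, 6, 4)])
    }
    out[(3L * i - 2L):(3L * i), ] <- tets
  }
  out
}

fix_orientation <- function(nodes, elems) {
  v <- tet_volumes(nodes, elems)
  bad <- v < 0
  if (any(bad)) elems[bad, c(3, 4)] <- elems[bad, c(4, 3)]
  elems
}

## Boundary faces (those belonging to exactly one tetrahedron), oriented
## outward. Returns list(tris, owner).
boundary_faces <- function(nodes, elems) {
  m <- nrow(elems)
  faces <- rbind(elems[, c(2, 3, 4)], elems[, c(1, 4, 3)],
                 elems[, c(1, 2, 4)], elems[, c(1, 3, 2)])
  owner <- rep(seq_len(m), 4)
  opp <- c(elems[, 1], elems[, 2], elems[, 3], elems[, 4])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  n <- nrow(nodes)
  key <- (as.numeric(lo) * n + mid) * n + hi
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  bi <- which(!dup)
  tris <- faces[bi, , drop = FALSE]
  ## orient outward: normal of (a,b,c) must point away from the opposite node
  a <- nodes[tris[, 1], , drop = FALSE]
  ab <- nodes[tris[, 2], , drop = FALSE] - a
  ac <- nodes[tris[, 3], , drop = FALSE] - a
  ad <- nodes[opp[bi], , drop = FALSE] - a
  s <- (ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]) * ad[, 1] +
       (ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]) * ad[, 2] +
       (ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]) * ad[, 3]
  flip <- s > 0
  if (any(flip)) tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  list(tris = tris, owner = owner[bi])
}

#' Build a tetrahedral mesh of a solid of revolution
#'
#' Constructs a structured, watertight tetrahedral mesh of the body obtained
#' by rotating the radial profile `r(z)` about the z axis. The first and
#' last stations are the poles (r = 0); every interior station carries a
#' triangulated disk of `n_rings` concentric rings with `n_theta` nodes each.
#'
#' @param stations strictly increasing vector of axial positions; the first
#'   and last entries are the poles.
#' @param radius_fun function of z returning the cross-sectional radius;
#'   must be positive at all interior stations.
#' @param n_theta number of angular nodes per ring.
#' @param n_rings number of radial rings per disk.
#' @return A `volume_mesh` object: `nodes`, `elems` (positively oriented
#'   tetrahedra), `boundary` (outward-oriented surface triangles),
#'   `surface_nodes`, `surface_info` (station/ring bookkeeping for the
#'   surface nodes), `tags`, and `params`.
#' @keywords internal
make_revolution_mesh <- function(stations, radius_fun, n_theta = 24,
                                 n_rings = 5) {
  N <- length(stations)
  if (N < 3) stop("need at least 3 axial stations")
  if (any(diff(stations) <= 0)) stop("stations must be strictly increasing")
  K <- as.integer(n_theta); m <- as.integer(n_rings)
  if (K < 6 || m < 2) stop("mesh resolution too coarse")
  rad <- vapply(stations[2:(N - 1)], radius_fun, numeric(1))
  if (any(!is.finite(rad)) || any(rad <= 0))
    stop("profile radius must be positive at interior stations")

  theta <- 2 * pi * (seq_len(K) - 1) / K
  dn <- 1L + m * K                       # nodes per interior disk
  n_nodes <- 2L + (N - 2L) * dn
  nodes <- matrix(0, n_nodes, 3)
  nodes[1, ] <- c(0, 0, stations[1])
  nodes[n_nodes, ] <- c(0, 0, stations[N])
  for (i in 2:(N - 1)) {
    base <- 2L + (i - 2L) * dn
    nodes[base, ] <- c(0, 0, stations[i])
    R <- rad[i - 1]
    for (j in seq_len(m)) {
      r <- R * j / m
      idx <- base + (j - 1L) * K + seq_len(K)
      nodes[idx, 1] <- r * cos(theta)
      nodes[idx, 2] <- r * sin(theta)
      nodes[idx, 3] <- stations[i]
    }
  }

  tri <- disk_triangles(m, K)            # local template, shared by all disks
  disk_base <- function(i) 2L + (i - 2L) * dn - 1L   # add to local ids
  elems <- vector("list", N - 1)
  ## bottom cap: pole 1 to first disk
  elems[[1]] <- cbind(1L, tri + disk_base(2))
  if (N > 3) {
    for (i in 2:(N - 2)) {
      bot <- matrix(as.integer(tri + disk_base(i)), ncol = 3)
      top <- matrix(as.integer(tri + disk_base(i + 1)), ncol = 3)
      elems[[i]] <- prisms_to_tets(bot, top)
    }
  }
  ## top cap
  elems[[N - 1]] <- cbind(n_nodes, tri + disk_base(N - 1))[, c(2, 3, 4, 1)]
  elems <- do.call(rbind, elems)
  storage.mode(elems) <- "integer"
  elems <- fix_orientation(nodes, elems)
  vol <- tet_volumes(nodes, elems)
  if (any(vol <= 0)) stop("meshing produced degenerate tetrahedra")

  bnd <- boundary_faces(nodes, elems)
  surface_nodes <- sort(unique(as.vector(bnd$tris)))
  ## surface bookkeeping: poles are ring 0 of stations 1 and N; the outer
  ## ring (j = m) of each interior disk forms the lateral surface.
  si <- data.frame(node = c(1L, n_nodes), station = c(1L, N), ring = 0L)
  for (i in 2:(N - 1)) {
    idx <- disk_base(i) + 1L + (m - 1L) * K + seq_len(K)
    si <- rbind(si, data.frame(node = idx, station = i, ring = m))
  }
  si <- si[order(si$node), ]
  structure(list(nodes = nodes, elems = elems, boundary = bnd$tris,
                 surface_nodes = surface_nodes, surface_info = si,
                 tags = list(),
                 params = list(kind = "revolution", n_theta = K, n_rings = m,
                               stations = stations)),
            class = "volume_mesh")
}

## Axial station layout along a radial profile (z, r): stations distributed
## uniformly in profile arc length (which concentrates them near the poles,
## where the profile turns vertical), refined around the equatorial furrow
## band when `half_band` is given, with optional required extra stations
## (e.g., spindle anchor planes).
station_layout <- function(prof_z, prof_r, coarse, half_band = NULL,
                           extra = numeric(0), grow = 1.6) {
  s <- cumsum(c(0, sqrt(diff(prof_z)^2 + diff(prof_r)^2)))
  zmin <- prof_z[1]; zmax <- prof_z[length(prof_z)]
  n <- max(8L, as.integer(ceiling(max(s) / coarse)))
  base <- stats::approx(s, prof_z, xout = seq(0, max(s),
                                              length.out = n + 1),
                        ties = "ordered")$y
  base[1] <- zmin; base[n + 1] <- zmax
  req <- numeric(0)
  if (!is.null(half_band) && half_band > 0) {
    hb <- half_band
    nb <- max(1L, as.integer(ceiling(hb / (0.5 * coarse))))
    inner <- seq(0, hb, length.out = nb + 1)
    step <- max(hb / nb, coarse / 8)
    outer <- numeric(0); h <- hb
    while (step < coarse) {
      step <- min(coarse, step * grow)
      h <- h + step
      outer <- c(outer, h)
    }
    req <- c(-rev(inner[-1]), inner, -outer, outer)
  }
  if (length(extra)) req <- c(req, extra)
  req <- sort(unique(req))
  req <- req[req > zmin + 1e-9 & req < zmax - 1e-9]
  if (length(req) > 1) req <- req[c(TRUE, diff(req) > 0.04 * coarse)]
  keep <- rep(TRUE, n + 1)
  if (length(req)) {
    gaps <- diff(base)
    loc <- pmin(c(gaps[1], gaps), c(gaps, gaps[n]))
    for (i in 2:n)
      if (min(abs(base[i] - req)) < 0.6 * loc[i]) keep[i] <- FALSE
  }
  sort(unique(c(base[keep], req)))
}

#' Tetrahedral mesh of a spherical cell
#'
#' Builds a structured tetrahedral mesh of a ball of the given radius. The
#' axial stations follow equal polar-angle spacing (uniform arc length), so
#' polar caps stay well shaped; the angular and radial resolution are
#' derived from `target_edge`. The construction is deterministic; `seed` is
#' accepted for interface stability but has no effect.
#'
#' @param radius sphere radius in model units.
#' @param target_edge characteristic edge length in model units; default
#'   `radius / 10`.
#' @param seed ignored (meshing is deterministic).
#' @param fine_band optional half-width of an equatorial refinement band
#'   (use `furrow_width / 2` when the mesh will drive furrow contraction).
#' @param extra_stations optional axial positions that must coincide with
#'   mesh stations (e.g., spindle anchor planes).
#' @param n_theta,n_rings optional explicit angular/radial resolution.
#' @return A `volume_mesh`; see [make_revolution_mesh()].
#' @examples
#' mesh <- make_sphere_mesh(50, target_edge = 10)
#' abs(mesh_volume(mesh) / (4 / 3 * pi * 50^3) - 1) < 0.05
#' @export
make_sphere_mesh <- function(radius, target_edge = radius / 10, seed = NULL,
                             fine_band = NULL, extra_stations = numeric(0),
                             n_theta = NULL, n_rings = NULL) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(target_edge) || target_edge <= 0 || target_edge >= radius)
    stop("target_edge must satisfy 0 < target_edge < radius")
  if (is.null(n_theta))
    n_theta <- max(12L, as.integer(round(2 * pi * radius / (2 * target_edge))))
  if (is.null(n_rings))
    n_rings <- max(3L, as.integer(round(radius / (1.5 * target_edge))))
  phi <- seq(0, pi, length.out = 361)
  prof_z <- -radius * cos(phi)
  prof_r <- radius * sin(phi)
  stations <- station_layout(prof_z, prof_r, coarse = target_edge,
                             half_band = fine_band, extra = extra_stations)
  mesh <- make_revolution_mesh(stations, function(z) {
    r2 <- radius^2 - z^2
    sqrt(max(r2, 0))
  }, n_theta = n_theta, n_rings = n_rings)
  mesh$params$kind <- "sphere"
  mesh$params$radius <- radius
  mesh$params$target_edge <- target_edge
  mesh
}

#' Total mesh volume
#' @param mesh a `volume_mesh`.
#' @return sum of tetrahedron volumes.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh$nodes, mesh$elems))

#' Tag furrow band and spindle anchor regions
#'
#' The cleavage-furrow band is the set of surface nodes with axial
#' coordinate `|z| <= furrow_width / 2` (the division axis is z, the furrow
#' plane z = 0). When `spindle_length` is given, the node sets nearest to
#' `(0, 0, +/- spindle_length / 2)` (excluding surface nodes) are tagged as
#' spindle anchors.
#'
#' @param mesh a `volume_mesh`.
#' @param furrow_width band width in model units; must be positive.
#' @param spindle_length optional pole-to-pole spindle length, model units.
#' @param anchor_radius nodes within this distance of the anchor points are
#'   included in the anchor sets (at minimum the nearest node).
#' @return the mesh with `tags$furrow_band` (and `tags$anchor_plus`,
#'   `tags$anchor_minus`) filled in.
#' @export
tag_regions <- function(mesh, furrow_width, spindle_length = NULL,
                        anchor_radius = 0) {
  if (!is.finite(furrow_width) || furrow_width <= 0)
    stop("furrow_width must be positive")
  z <- mesh$nodes[mesh$surface_nodes, 3]
  band <- mesh$surface_nodes[abs(z) <= furrow_width / 2 + 1e-12]
  if (length(band) == 0)
    stop("no surface nodes inside the furrow band; refine the mesh ",
         "(smaller target_edge or a fine_band matching the furrow width)")
  mesh$tags$furrow_band <- band
  if (!is.null(spindle_length)) {
    if (!is.finite(spindle_length) || spindle_length <= 0)
      stop("spindle_length must be positive")
    interior <- setdiff(seq_len(nrow(mesh$nodes)), mesh$surface_nodes)
    for (sgn in c(1, -1)) {
      tgt <- c(0, 0, sgn * spindle_length / 2)
      d <- sqrt(colSums((t(mesh$nodes[interior, , drop = FALSE]) - tgt)^2))
      sel <- interior[d <= max(min(d) + 1e-9, anchor_radius)]
      if (sgn > 0) mesh$tags$anchor_plus <- sel else mesh$tags$anchor_minus <- sel
    }
  }
  mesh
}

#' Extract the boundary surface of a volume mesh
#'
#' @param mesh a `volume_mesh`.
#' @return a `surface_mesh`: `nodes` (p x 3), `tris` (outward oriented,
#'   renumbered), and `info` (station/ring bookkeeping when available).
#' @export
extract_boundary <- function(mesh) {
  ids <- mesh$surface_nodes
  map <- integer(nrow(mesh$nodes)); map[ids] <- seq_along(ids)
  tris <- matrix(map[mesh$boundary], ncol = 3)
  info <- mesh$surface_info
  if (!is.null(info)) {
    info <- info[match(ids, info$node), ]
    info$node <- seq_along(ids)
  }
  structure(list(nodes = mesh$nodes[ids, , drop = FALSE], tris = tris,
                 info = info),
            class = "surface_mesh")
}

## closed-manifold check: every edge shared by exactly two triangles and
## Euler characteristic 2.
check_closed_surface <- function(surface) {
  tris <- surface$tris
  p <- nrow(surface$nodes); q <- nrow(tris)
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- e[, 1] * (p + 1) + e[, 2]
  cnt <- rle(sort(key))$lengths
  if (any(cnt != 2))
    stop("surface is not a closed manifold: ", sum(cnt != 2),
         " edge(s) not shared by exactly two triangles")
  n_edges <- length(cnt)
  if (p - n_edges + q != 2)
    stop("surface is not a topological sphere (Euler characteristic ",
         p - n_edges + q, ")")
  invisible(TRUE)
}

#' Regenerate a tetrahedral mesh from a deformed boundary surface
#'
#' Between incremental simulation steps the deformed cell surface is used to
#' regenerate a fresh, high-quality tetrahedral mesh. The model is
#' axisymmetric about the z axis, so the remesher recovers the radial
#' profile r(z) of the surface (averaging over surface rings when ring
#' bookkeeping is available, otherwise by axial binning) and rebuilds a
#' structured revolution mesh. The input must be a closed manifold surface;
#' strongly non-axisymmetric surfaces are rejected.
#'
#' @param surface a `surface_mesh` (see [extract_boundary()]).
#' @param target_edge characteristic edge length of the new mesh.
#' @param fine_band optional equatorial refinement half-width.
#' @param extra_stations axial positions forced to coincide with stations.
#' @param n_theta,n_rings optional explicit resolution (defaults derived
#'   from the surface extent and `target_edge`).
#' @param axisym_tol maximum allowed relative spread of ring radii before
#'   the surface is declared non-axisymmetric.
#' @param preserve_volume rescale the cross-sectional radii of the new mesh
#'   so its volume matches the volume enclosed by the input surface
#'   (compensates the chordal losses of profile resampling).
#' @return a fresh `volume_mesh` filling the surface.
#' @export
remesh_from_surface <- function(surface, target_edge = NULL, fine_band = NULL,
                                extra_stations = numeric(0), n_theta = NULL,
                                n_rings = NULL, axisym_tol = 0.2,
                                preserve_volume = TRUE) {
  stopifnot(inherits(surface, "surface_mesh"))
  check_closed_surface(surface)
  xyz <- surface$nodes
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  z <- xyz[, 3]
  if (!is.null(surface$info) && all(!is.na(surface$info$station))) {
    grp <- interaction(surface$info$station, surface$info$ring, drop = TRUE)
    pz <- tapply(z, grp, mean)
    pr <- tapply(r, grp, mean)
    spread <- tapply(r, grp, function(v) diff(range(v)))
    scale_r <- max(pr)
    if (any(spread > axisym_tol * scale_r))
      stop("surface is not axisymmetric about the z axis; cannot remesh")
    ord <- order(pz)
    prof_z <- as.numeric(pz[ord]); prof_r <- as.numeric(pr[ord])
  } else {
    nb <- max(12L, min(60L, as.integer(length(z) / 8)))
    br <- seq(min(z), max(z), length.out = nb + 1)
    bin <- cut(z, br, include.lowest = TRUE)
    pz <- tapply(z, bin, mean); pr <- tapply(r, bin, mean)
    spread <- tapply(r, bin, function(v) if (length(v) > 3) diff(range(v)) else 0)
    ok <- !is.na(pz)
    if (any(spread[ok] > axisym_tol * max(pr[ok])))
      stop("surface is not axisymmetric about the z axis; cannot remesh")
    prof_z <- c(min(z), as.numeric(pz[ok]), max(z))
    prof_r <- c(0, as.numeric(pr[ok]), 0)
    ord <- order(prof_z); prof_z <- prof_z[ord]; prof_r <- prof_r[ord]
  }
  ## ensure poles close the profile
  if (prof_r[1] > 1e-9) { prof_z <- c(min(z), prof_z); prof_r <- c(0, prof_r) }
  if (prof_r[length(prof_r)] > 1e-9) {
    prof_z <- c(prof_z, max(z)); prof_r <- c(prof_r, 0)
  }
  rfun <- stats::approxfun(prof_z, prof_r, rule = 2, ties = mean)
  zr <- range(prof_z)
  if (is.null(target_edge)) target_edge <- diff(zr) / 20
  if (is.null(n_theta))
    n_theta <- max(12L, as.integer(round(2 * pi * max(prof_r) /
                                           (2 * target_edge))))
  if (is.null(n_rings))
    n_rings <- max(3L, as.integer(round(max(prof_r) / (1.5 * target_edge))))
  stations <- station_layout(prof_z, prof_r, coarse = target_edge,
                             half_band = fine_band, extra = extra_stations)
  mesh <- make_revolution_mesh(stations, function(zz) max(rfun(zz), 1e-9),
                               n_theta = n_theta, n_rings = n_rings)
  if (preserve_volume) {
    v_target <- surface_volume(surface)
    s <- sqrt(v_target / mesh_volume(mesh))
    mesh$nodes[, 1:2] <- mesh$nodes[, 1:2] * s
  }
  mesh$params$target_edge <- target_edge
  mesh
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem sum over outward-oriented triangles.
#' @param surface a `surface_mesh`.
#' @return the enclosed volume.
#' @export
surface_volume <- function(surface) {
  a <- surface$nodes[surface$tris[, 1], , drop = FALSE]
  b <- surface$nodes[surface$tris[, 2], , drop = FALSE]
  c3 <- surface$nodes[surface$tris[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
        a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
        a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "tets,", nrow(x$boundary), "boundary triangles\n")
  cat("  volume:", format(mesh_volume(x)), " z-extent: [",
      format(min(x$nodes[, 3])), ",", format(max(x$nodes[, 3])), "]\n")
  if (length(x$tags))
    cat("  tags:", paste(names(x$tags), vapply(x$tags, length, 1L),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Triangulated surface:", nrow(x$nodes), "nodes,", nrow(x$tris),
      "triangles\n")
  invisible(x)
}
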