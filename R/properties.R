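# Geometric descriptors entering the fitness: cavity (pore) diameter, window
# diameters and the window-asymmetry penalty.

structure_vdw <- function(structure) {
  if (!is.null(structure$vdw)) {
    rep_len(structure$vdw, length(structure$elements))
  } else {
    vdw_radius(structure$elements)
  }
}

structure_masses <- function(structure) {
  if (!is.null(structure$masses)) {
    rep_len(structure$masses, length(structure$elements))
  } else {
    atomic_mass(structure$elements)
  }
}

#' Cavity (pore) diameter of a cage
#'
#' Twice the distance between the mass-weighted center of the molecule and
#' the surface of the closest atom: the diameter of the largest sphere that
#' fits in the cavity. With `vdw_correct = FALSE` the atom centers are used
#' instead of their van der Waals surfaces (sensitivity checks only).
#'
#' @param structure A `cage_structure` (>= 4 atoms).
#' @param vdw_correct Subtract van der Waals radii (default `TRUE`).
#' @return Pore diameter in Angstrom, floored at 0.
#' @export
pore_diameter <- function(structure, vdw_correct = TRUE) {
  stopifnot(length(structure$elements) >= 4L)
  m <- structure_masses(structure)
  com <- colSums(structure$coords * m) / sum(m)
  d <- sqrt(rowSums((structure$coords -
                       matrix(com, nrow(structure$coords), 3, byrow = TRUE))^2))
  if (vdw_correct) d <- d - structure_vdw(structure)
  max(0, 2 * min(d))
}

# Orthonormal in-plane basis + centroid + normal for a window face.
.face_frame <- function(face_pts) {
  ctr <- colMeans(face_pts)
  centered <- face_pts - matrix(ctr, nrow(face_pts), 3, byrow = TRUE)
  sv <- svd(centered)
  list(center = ctr, e1 = sv$v[, 1], e2 = sv$v[, 2], normal = sv$v[, 3],
       poly2d = centered %*% sv$v[, 1:2, drop = FALSE])
}

# Signed point-in-convex-polygon margin in 2D (positive inside, value is the
# distance to the nearest polygon edge line).
.polygon_margin <- function(p, poly) {
  n <- nrow(poly)
  ctr <- colMeans(poly)
  margins <- vapply(seq_len(n), function(k) {
    a <- poly[k, ]; b <- poly[k %% n + 1, ]
    edge <- b - a
    nrm <- c(-edge[2], edge[1]) / sqrt(sum(edge^2))
    if (sum((ctr - a) * nrm) < 0) nrm <- -nrm  # inward normal
    sum((p - a) * nrm)
  }, numeric(1))
  min(margins)
}

# Clearance objective for one face: largest value of
# min_i(|c - x_i| - R_i) over centers c in the face plane, restricted to the
# face polygon. Returns the optimum clearance (can be negative for a blocked
# face).
.window_clearance <- function(coords, radii, frame) {
  obj <- function(uv) {
    c3 <- frame$center + uv[1] * frame$e1 + uv[2] * frame$e2
    margin <- .polygon_margin(uv, frame$poly2d)
    d <- sqrt(rowSums((coords -
                         matrix(c3, nrow(coords), 3, byrow = TRUE))^2)) - radii
    min(d) - 1e3 * max(0, -margin)
  }
  rng <- max(sqrt(rowSums(frame$poly2d^2)))
  grid <- as.matrix(expand.grid(u = seq(-rng, rng, length.out = 9),
                                v = seq(-rng, rng, length.out = 9)))
  grid <- rbind(c(0, 0), grid)
  vals <- apply(grid, 1, obj)
  starts <- grid[order(-vals)[1:3], , drop = FALSE]
  best <- max(vals)
  for (s in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[s, ], function(uv) -obj(uv),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500))
    if (-opt$value > best) best <- -opt$value
  }
  best
}

#' Window diameters of a cage
#'
#' For each window face of the topology, the diameter of the largest circle
#' that fits through the window: twice the largest clearance
#' `min_i(|c - x_i| - R_i)` over circle centers `c` in the face plane
#' (restricted to the face polygon spanned by the vertex sites). Faces with
#' no free path get diameter 0.
#'
#' @param structure A `cage_structure` carrying assembly provenance
#'   (`topology` and `vertex_positions`).
#' @return Numeric vector of window diameters (Angstrom), ordered by face
#'   index.
#' @export
window_diameters <- function(structure) {
  topo <- structure$topology
  if (is.null(topo) || is.null(structure$vertex_positions)) {
    stop("structure carries no topology provenance; windows undefined")
  }
  radii <- structure_vdw(structure)
  vapply(topo$window_faces, function(face) {
    frame <- .face_frame(structure$vertex_positions[face, , drop = FALSE])
    cl <- .window_clearance(structure$coords, radii, frame)
    max(0, 2 * cl)
  }, numeric(1))
}

#' Window asymmetry
#'
#' The sum over groups of chemically identical windows of all absolute
#' pairwise window-diameter differences. Zero iff all windows within each
#' group are equal. For a single-topology, two-component cage all windows are
#' chemically identical and form one group.
#'
#' @param windows Numeric vector of window diameters.
#' @param groups List of index vectors partitioning `seq_along(windows)`.
#' @return Asymmetry in Angstrom.
#' @export
asymmetry <- function(windows, groups = list(seq_along(windows))) {
  idx <- sort(unlist(groups))
  if (!identical(idx, seq_along(windows))) {
    stop("groups must partition the window indices exactly")
  }
  total <- 0
  for (g in groups) {
    if (length(g) < 2L) next
    pr <- utils::combn(g, 2)
    total <- total + sum(abs(windows[pr[1, ]] - windows[pr[2, ]]))
  }
  total
}

#' All fitness-relevant properties of a cage
#'
#' @param structure A `cage_structure`.
#' @param persistent Optional shape-persistency flag to store.
#' @return A `cage_properties` list: `pore_diameter`, `window_diameters`,
#'   `asymmetry`, `persistent`.
#' @export
cage_properties <- function(structure, persistent = NA) {
  w <- window_diameters(structure)
  structure(
    list(pore_diameter = pore_diameter(structure), window_diameters = w,
         asymmetry = asymmetry(w), persistent = persistent),
    class = "cage_properties"
  )
}

#' Batch property table
#'
#' @param structures List of `cage_structure`s.
#' @return Data frame with one row per cage: id, pore, windows, asymmetry.
#' @export
properties_table <- function(structures) {
  rows <- lapply(structures, function(s) {
    p <- cage_properties(s)
    data.frame(id = chromosome_key(s$chromosome),
               pore = p$pore_diameter,
               t(stats::setNames(p$window_diameters,
                                 paste0("window", seq_along(p$window_diameters)))),
               asymmetry = p$asymmetry,
               persistent = p$persistent)
  })
  do.call(rbind, rows)
}
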