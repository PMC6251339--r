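# Cage assembly: place tri-topic building blocks on topology vertices and
# di-topic ones on edges, orient them by their reactive-group anchors, and
# condense each aldehyde/amine junction into an imine (C=N) bond with loss of
# one water equivalent (the aldehyde O and two amine H).

# Kabsch rotation (row-vector convention, x %*% R) mapping source onto target
# direction sets; proper rotation enforced.
.kabsch <- function(src, tgt) {
  h <- t(src) %*% tgt
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Minimal rotation taking unit vector a to unit vector b (Rodrigues), as a
# matrix for the row-vector convention.
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-10) {
    # antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(p - sum(p * a) * a)
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  r <- diag(3) + vx + vx %*% vx / (1 + c_)
  t(r)  # column convention -> row convention
}

# Rotation about unit axis by angle (row convention).
.rotation_about <- function(axis, theta) {
  axis <- .unit(axis)
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + sin(theta) * vx + (1 - cos(theta)) * (vx %*% vx)
  t(r)
}

.permutations3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                       c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Assemble a cage structure from a chromosome
#'
#' Tri-topic blocks go on vertices, oriented so their three carbonyl anchors
#' point toward the incident edge midpoints (best-fitting proper rotation over
#' all anchor/edge pairings); di-topic blocks go on edges with the N-N axis
#' along the edge. Each junction is condensed to an imine: the aldehyde O and
#' two amine H are removed and a C=N double bond added.
#'
#' @param chromosome A `cage_chromosome`.
#' @param db A `bb_database` holding both building blocks with conformers.
#' @param scale Cage radius in Angstrom (vertex distance from the center);
#'   defaults to 1.5 x the summed end-group distances of the two blocks.
#' @return A `cage_structure`: `elements`, `coords`, `bonds` (i, j, order),
#'   `imine_bond_indices`, assembly provenance (`topology`,
#'   `vertex_positions`) and `energy` (`NA` until relaxed).
#' @export
assemble <- function(chromosome, db, scale = NULL) {
  tri <- db_get(db, chromosome$bb_tri)
  di <- db_get(db, chromosome$bb_di)
  if (tri$role != "trialdehyde" || di$role != "diamine") {
    stop("chromosome roles do not match database entries")
  }
  if (is.null(tri$conformer) || is.null(di$conformer)) {
    stop("both building blocks need embedded conformers")
  }
  topo <- topology_graph(chromosome$topology)

  tri_anchors <- find_anchor_atoms(tri$conformer, "trialdehyde")
  di_anchors <- find_anchor_atoms(di$conformer, "diamine")
  if (length(tri_anchors) != 3L) stop("trialdehyde must expose 3 anchors")
  if (length(di_anchors) != 2L) stop("diamine must expose 2 anchors")

  egd <- function(conf, anchors) {
    pr <- utils::combn(anchors, 2)
    mean(apply(pr, 2, function(p) .dist3(conf$coords[p[1], ],
                                         conf$coords[p[2], ])))
  }
  if (is.null(scale)) {
    scale <- 1.5 * (egd(tri$conformer, tri_anchors) +
                    egd(di$conformer, di_anchors))
  }

  elements <- character(0)
  coords <- matrix(numeric(0), 0, 3)
  bonds <- matrix(integer(0), 0, 3)
  site_atoms <- list()            # global index range per site
  arm_anchor <- list()            # per vertex: edge index -> global C index
  vertex_positions <- topo$vertex_coords * scale

  add_unit <- function(conf, rot, shift) {
    offset <- nrow(coords)
    elements <<- c(elements, conf$elements)
    coords <<- rbind(coords, conf$coords %*% rot +
                       matrix(shift, nrow(conf$coords), 3, byrow = TRUE))
    if (nrow(conf$bonds)) {
      bonds <<- rbind(bonds, cbind(conf$bonds[, 1] + offset,
                                   conf$bonds[, 2] + offset,
                                   conf$bonds[, 3]))
    }
    offset
  }

  # --- vertices: tri-topic blocks -----------------------------------------
  for (v in seq_len(topo$n_vertices)) {
    conf <- tri$conformer
    a_pos <- conf$coords[tri_anchors, , drop = FALSE]
    a_ctr <- colMeans(a_pos)
    centered <- list(elements = conf$elements,
                     coords = conf$coords -
                       matrix(a_ctr, nrow(conf$coords), 3, byrow = TRUE),
                     bonds = conf$bonds)
    src <- t(apply(a_pos - matrix(a_ctr, 3, 3, byrow = TRUE), 1, .unit))
    vpos <- vertex_positions[v, ]
    edges_v <- incident_edges(topo, v)
    mids <- t(vapply(edges_v, function(e) {
      colMeans(vertex_positions[topo$edges[e, ], , drop = FALSE])
    }, numeric(3)))
    tgt_all <- t(apply(mids - matrix(vpos, 3, 3, byrow = TRUE), 1, .unit))

    best <- NULL
    for (perm in .permutations3) {
      rot <- .kabsch(src, tgt_all[perm, , drop = FALSE])
      cost <- sum((src %*% rot - tgt_all[perm, , drop = FALSE])^2)
      if (is.null(best) || cost < best$cost) best <- list(rot = rot, perm = perm,
                                                          cost = cost)
    }
    offset <- add_unit(centered, best$rot, vpos)
    site_atoms[[paste0("v", v)]] <- offset + seq_along(conf$elements)
    # anchor k points at edge edges_v[perm[k]]; invert to edge -> anchor
    inv <- integer(3); inv[best$perm] <- seq_len(3)
    arm_anchor[[v]] <- stats::setNames((tri_anchors + offset)[inv],
                                       as.character(edges_v))
  }

  # --- edges: di-topic blocks ---------------------------------------------
  edge_anchor <- list()  # per edge: vertex id -> global N index
  for (e in seq_len(topo$n_edges)) {
    conf <- di$conformer
    v1 <- topo$edges[e, 1]; v2 <- topo$edges[e, 2]
    p1 <- vertex_positions[v1, ]; p2 <- vertex_positions[v2, ]
    a1 <- conf$coords[di_anchors[1], ]; a2 <- conf$coords[di_anchors[2], ]
    am <- (a1 + a2) / 2
    centered <- conf$coords - matrix(am, nrow(conf$coords), 3, byrow = TRUE)
    rot <- .rotation_between(a2 - a1, p2 - p1)
    rotated <- centered %*% rot
    # roll about the edge so the molecular centroid points outward
    axis <- .unit(p2 - p1)
    ctr <- colMeans(rotated)
    perp <- ctr - sum(ctr * axis) * axis
    mid <- (p1 + p2) / 2
    out_dir <- mid - sum(mid * axis) * axis
    if (sqrt(sum(perp^2)) > 1e-6 && sqrt(sum(out_dir^2)) > 1e-6) {
      pu <- .unit(perp); ou <- .unit(out_dir)
      ang <- atan2(sum(axis * c(pu[2] * ou[3] - pu[3] * ou[2],
                                pu[3] * ou[1] - pu[1] * ou[3],
                                pu[1] * ou[2] - pu[2] * ou[1])),
                   sum(pu * ou))
      rot <- rot %*% .rotation_about(axis, ang)
    }
    unit_conf <- list(elements = conf$elements, coords = centered,
                      bonds = conf$bonds)
    offset <- add_unit(unit_conf, rot, mid)
    site_atoms[[paste0("e", e)]] <- offset + seq_along(conf$elements)
    edge_anchor[[e]] <- stats::setNames(di_anchors + offset,
                                        c(as.character(v1), as.character(v2)))
  }

  # --- imine condensation at every (vertex, edge) junction ----------------
  drop_atoms <- integer(0)
  imine_pairs <- matrix(integer(0), 0, 2)
  neighbor_rows <- function(i) which(bonds[, 1] == i | bonds[, 2] == i)
  for (v in seq_len(topo$n_vertices)) {
    for (e in incident_edges(topo, v)) {
      c_idx <- arm_anchor[[v]][[as.character(e)]]
      n_idx <- edge_anchor[[e]][[as.character(v)]]
      # aldehyde O: double-bonded O neighbor of the carbonyl C
      rows <- neighbor_rows(c_idx)
      oth <- ifelse(bonds[rows, 1] == c_idx, bonds[rows, 2], bonds[rows, 1])
      o_idx <- oth[elements[oth] == "O" & bonds[rows, 3] == 2][1]
      if (is.na(o_idx)) stop("no carbonyl oxygen found at a junction")
      # amine H: the two H neighbors of the N
      rows_n <- neighbor_rows(n_idx)
      oth_n <- ifelse(bonds[rows_n, 1] == n_idx, bonds[rows_n, 2],
                      bonds[rows_n, 1])
      h_idx <- oth_n[elements[oth_n] == "H"]
      if (length(h_idx) < 2L) stop("amine nitrogen lacks two hydrogens")
      drop_atoms <- c(drop_atoms, o_idx, h_idx[1:2])
      imine_pairs <- rbind(imine_pairs, c(c_idx, n_idx))
    }
  }

  keep <- setdiff(seq_along(elements), drop_atoms)
  remap <- integer(length(elements)); remap[keep] <- seq_along(keep)
  keep_bond <- !(bonds[, 1] %in% drop_atoms | bonds[, 2] %in% drop_atoms)
  bonds <- bonds[keep_bond, , drop = FALSE]
  bonds <- cbind(remap[bonds[, 1]], remap[bonds[, 2]], bonds[, 3])
  imine <- cbind(remap[imine_pairs[, 1]], remap[imine_pairs[, 2]],
                 rep(2L, nrow(imine_pairs)))
  imine_rows <- nrow(bonds) + seq_len(nrow(imine))
  bonds <- rbind(bonds, imine)
  site_atoms <- lapply(site_atoms, function(ix) remap[setdiff(ix, drop_atoms)])

  structure(
    list(chromosome = chromosome, elements = elements[keep],
         coords = coords[keep, , drop = FALSE],
         bonds = bonds, imine_bond_indices = imine_rows,
         energy = NA_real_, topology = topo,
         vertex_positions = vertex_positions, site_atoms = site_atoms,
         scale = scale, flags = character(0)),
    class = "cage_structure"
  )
}

#' @export
print.cage_structure <- function(x, ...) {
  cat("<cage_structure> ", chromosome_key(x$chromosome), ": ",
      length(x$elements), " atoms, ", nrow(x$bonds), " bonds (",
      length(x$imine_bond_indices), " imine), energy ",
      format(x$energy, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Molecular mass of a structure or conformer
#' @param x A `cage_structure` or conformer list with `elements`.
#' @return Mass in g/mol.
#' @export
structure_mass <- function(x) sum(atomic_mass(x$elements))

# Single connected bonded component?
is_connected_structure <- function(structure) {
  n <- length(structure$elements)
  if (n == 0L) return(FALSE)
  if (nrow(structure$bonds) == 0L) return(n == 1L)
  g <- igraph::graph_from_edgelist(structure$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$no == 1L
}

# ---------------------------------------------------------------------------
# Optimizers: pluggable backends sharing a harmonic bond-spring potential.

.BOND_R0 <- c("C|C|1" = 1.53, "C|C|2" = 1.34, "C|C|4" = 1.39, "C|N|1" = 1.47,
              "C|N|2" = 1.28, "C|N|4" = 1.34, "C|O|1" = 1.43, "C|O|2" = 1.22,
              "C|H|1" = 1.09, "N|H|1" = 1.01, "O|H|1" = 0.96, "C|F|1" = 1.35,
              "C|Cl|1" = 1.77, "C|Br|1" = 1.94, "C|S|1" = 1.82, "C|B|1" = 1.56)

reference_bond_length <- function(el_i, el_j, order) {
  key1 <- paste(el_i, el_j, order, sep = "|")
  key2 <- paste(el_j, el_i, order, sep = "|")
  r0 <- .BOND_R0[key1]
  r0[is.na(r0)] <- .BOND_R0[key2][is.na(r0)]
  fallback <- (.COV_RADII[el_i] + .COV_RADII[el_j])
  fallback[is.na(fallback)] <- 1.5
  fallback <- fallback * ifelse(order == 2, 0.87, ifelse(order == 3, 0.78, 1))
  ifelse(is.na(r0), fallback, unname(r0))
}

harmonic_energy <- function(structure, k = 50) {
  if (nrow(structure$bonds) == 0L) return(0)
  r <- bonded_distances(structure)
  r0 <- reference_bond_length(structure$elements[structure$bonds[, 1]],
                              structure$elements[structure$bonds[, 2]],
                              structure$bonds[, 3])
  sum(k * (r - r0)^2)
}

harmonic_gradient <- function(structure, k = 50) {
  g <- matrix(0, nrow(structure$coords), 3)
  if (nrow(structure$bonds) == 0L) return(g)
  i <- structure$bonds[, 1]; j <- structure$bonds[, 2]
  d <- structure$coords[i, , drop = FALSE] - structure$coords[j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  r0 <- reference_bond_length(structure$elements[i], structure$elements[j],
                              structure$bonds[, 3])
  coef <- 2 * k * (r - r0) / pmax(r, 1e-8)
  f <- d * coef
  for (col in 1:3) {
    g[, col] <- g[, col] +
      as.numeric(tapply(c(f[, col], -f[, col]), c(i, j), sum)[
        as.character(seq_len(nrow(g)))])
  }
  g[is.na(g)] <- 0
  g
}

#' Deterministic harmonic bond-spring optimizer
#'
#' Gradient descent with backtracking on a harmonic bond potential
#' `sum k (r - r0)^2` over all bonds. Only ever accepts energy decreases, so
#' relaxation never raises the energy. Angles and non-bonded terms are not
#' modeled; this backend exists for reproducible, license-free geometry
#' clean-up and testing, not for force-field accuracy.
#'
#' @param k Spring constant (energy per A^2).
#' @param maxiter Maximum descent iterations.
#' @param step0 Initial step length (A per unit gradient).
#' @param tol Energy-change convergence threshold.
#' @return An optimizer object (list with `name`, `potential`, `minimize`).
#' @export
optimizer_harmonic <- function(k = 50, maxiter = 1000L, step0 = 0.01,
                               tol = 1e-8) {
  list(
    name = "harmonic",
    potential = function(structure) harmonic_energy(structure, k = k),
    minimize = function(structure, free = NULL) {
      n <- nrow(structure$coords)
      if (is.null(free)) free <- rep(TRUE, n)
      e <- harmonic_energy(structure, k = k)
      step <- step0
      for (it in seq_len(maxiter)) {
        g <- harmonic_gradient(structure, k = k)
        g[!free, ] <- 0
        gn <- sqrt(sum(g^2))
        if (gn < 1e-10) break
        improved <- FALSE
        while (step > 1e-9) {
          trial <- structure
          trial$coords <- structure$coords - step * g
          et <- harmonic_energy(trial, k = k)
          if (et < e - tol) {
            structure <- trial; e <- et; improved <- TRUE
            step <- step * 1.2
            break
          }
          step <- step / 2
        }
        if (!improved) break
      }
      structure$energy <- e
      structure
    }
  )
}

#' Identity (frozen) optimizer
#'
#' Returns structures unchanged and reports the harmonic potential as energy.
#' Useful for testing invariances of downstream analysis.
#'
#' @return An optimizer object.
#' @export
optimizer_identity <- function() {
  list(
    name = "identity",
    potential = function(structure) harmonic_energy(structure),
    minimize = function(structure, free = NULL) {
      structure$energy <- harmonic_energy(structure)
      structure
    }
  )
}

# Atoms allowed to move in the constrained first relaxation stage: the imine
# C and N plus their directly bonded neighbors.
junction_free_mask <- function(structure) {
  free <- rep(FALSE, length(structure$elements))
  jb <- structure$bonds[structure$imine_bond_indices, , drop = FALSE]
  core <- unique(c(jb[, 1], jb[, 2]))
  nbr <- structure$bonds[structure$bonds[, 1] %in% core |
                           structure$bonds[, 2] %in% core, 1:2]
  free[unique(c(core, as.integer(nbr)))] <- TRUE
  free
}

#' Two-stage relaxation of an assembled cage
#'
#' Stage one relaxes the newly formed imine junctions (the new bonds and the
#' atoms directly linked to them) while all other atoms are constrained;
#' stage two then optimizes the whole cage freely.
#'
#' @param structure A `cage_structure`.
#' @param optimizer An optimizer object (default [optimizer_harmonic()]).
#' @return The relaxed structure; its `energy` is never above the input's
#'   potential energy. On optimizer failure the input is returned flagged
#'   `"unrelaxed"`.
#' @export
relax <- function(structure, optimizer = optimizer_harmonic()) {
  e0 <- optimizer$potential(structure)
  out <- tryCatch({
    s1 <- optimizer$minimize(structure, free = junction_free_mask(structure))
    optimizer$minimize(s1, free = NULL)
  }, error = function(e) NULL)
  if (is.null(out) || !is.finite(out$energy) || out$energy > e0 + 1e-9) {
    structure$flags <- union(structure$flags, "unrelaxed")
    structure$energy <- e0
    return(structure)
  }
  out
}

#' Conformer search by seeded perturbation
#'
#' Probes flexibility by applying `n_samples` seeded Gaussian coordinate
#' perturbations, re-optimizing each, and keeping the lowest-energy result
#' (the input included). Deterministic for a fixed seed. This takes the role
#' of the high-temperature molecular-dynamics sampling used with proprietary
#' force fields; any MD backend honoring the optimizer interface can be
#' plugged in instead.
#'
#' @param structure A relaxed `cage_structure`.
#' @param n_samples Number of perturbed conformers (0 returns the input).
#' @param seed Integer seed.
#' @param optimizer Optimizer object.
#' @param amplitude Gaussian displacement amplitude in Angstrom.
#' @return The lowest-energy structure found.
#' @export
conformer_search <- function(structure, n_samples, seed,
                             optimizer = optimizer_harmonic(),
                             amplitude = 0.3) {
  if (n_samples == 0L) return(structure)
  if (is.na(structure$energy)) structure$energy <- optimizer$potential(structure)
  best <- structure
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  n_fail <- 0L
  for (s in seq_len(n_samples)) {
    trial <- structure
    trial$coords <- structure$coords +
      matrix(stats::rnorm(length(structure$coords), sd = amplitude),
             nrow(structure$coords), 3)
    opt <- tryCatch(optimizer$minimize(trial, free = NULL),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$energy)) {
      n_fail <- n_fail + 1L
      next
    }
    if (opt$energy < best$energy) best <- opt
  }
  if (n_fail == n_samples) {
    warning("all conformer samples failed; returning input")
    structure$flags <- union(structure$flags, "conformer_search_failed")
    return(structure)
  }
  best
}

#' Shape persistency of a cage after conformational sampling
#'
#' A cage counts as shape persistent when its cavity survives the conformer
#' search: the post-search pore diameter must be at least `threshold_fraction`
#' of the pre-search one and above an absolute floor.
#'
#' @param before,after `cage_structure`s sharing a chromosome (before and
#'   after the conformer search).
#' @param threshold_fraction Retained-cavity fraction (default 0.5).
#' @param floor Absolute minimum pore diameter in Angstrom (default 2.8,
#'   roughly the smallest guest-relevant cavity).
#' @return Logical.
#' @export
shape_persistency <- function(before, after, threshold_fraction = 0.5,
                              floor = 2.8) {
  stopifnot(identical(chromosome_key(before$chromosome),
                      chromosome_key(after$chromosome)))
  p_before <- pore_diameter(before)
  p_after <- pore_diameter(after)
  p_after >= threshold_fraction * p_before && p_after >= floor
}

#' Write a structure as an XYZ file
#' @param structure A `cage_structure`.
#' @param path Output path.
#' @export
write_xyz <- function(structure, path) {
  n <- length(structure$elements)
  lines <- c(as.character(n),
             chromosome_key(structure$chromosome),
             sprintf("%-2s %12.6f %12.6f %12.6f", structure$elements,
                     structure$coords[, 1], structure$coords[, 2],
                     structure$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a structure as a V2000 MOL file
#' @param structure A `cage_structure`.
#' @param path Output path.
#' @export
write_mol <- function(structure, path) {
  n <- length(structure$elements); m <- nrow(structure$bonds)
  header <- c(chromosome_key(structure$chromosome), "  evocage", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   structure$coords[, 1], structure$coords[, 2],
                   structure$coords[, 3], structure$elements)
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", structure$bonds[, 1],
                   structure$bonds[, 2],
                   ifelse(structure$bonds[, 3] == 4L, 4L, structure$bonds[, 3]))
  writeLines(c(header, atoms, bonds, "M  END"), path)
  invisible(path)
}
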