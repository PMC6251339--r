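# Cage topology graphs: tri-topic building blocks sit on polyhedron vertices,
# di-topic ones on edges. Two members of the 2:3-ratio family are supported,
# the tetrahedral Tri4Di6 and the cubic Tri8Di12.

#' Topology graph of a two-component cage
#'
#' @param name `"Tri4Di6"` (tetrahedron: 4 vertices, 6 edges, 4 window faces)
#'   or `"Tri8Di12"` (cube: 8 vertices, 12 edges, 6 window faces).
#' @return A `cage_topology`: unit-sphere `vertex_coords`, `edges` (two-column
#'   vertex-index matrix), `window_faces` (list of cyclic vertex sequences),
#'   and counts `n_vertices` / `n_edges`.
#' @export
topology_graph <- function(name) {
  if (name == "Tri4Di6") {
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    edges <- t(utils::combn(4L, 2L))
    faces <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  } else if (name == "Tri8Di12") {
    v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
    v <- unname(v / sqrt(3))
    pairs <- t(utils::combn(8L, 2L))
    adj <- apply(pairs, 1, function(p) {
      sum(abs(v[p[1], ] - v[p[2], ]) > 1e-9) == 1L
    })
    edges <- pairs[adj, , drop = FALSE]
    faces <- list()
    for (dim in 1:3) for (s in c(-1, 1) / sqrt(3)) {
      idx <- which(abs(v[, dim] - s) < 1e-9)
      # cyclic order around the face centroid
      ctr <- colMeans(v[idx, , drop = FALSE])
      basis <- diag(3)[, -dim, drop = FALSE]
      ang <- atan2(
        as.numeric(v[idx, , drop = FALSE] %*% basis[, 2]) -
          sum(ctr * basis[, 2]),
        as.numeric(v[idx, , drop = FALSE] %*% basis[, 1]) -
          sum(ctr * basis[, 1])
      )
      faces[[length(faces) + 1L]] <- idx[order(ang)]
    }
  } else {
    stop("unknown topology: ", name,
         " (supported: Tri4Di6, Tri8Di12)")
  }
  topo <- structure(
    list(name = name, n_vertices = nrow(v), n_edges = nrow(edges),
         vertex_coords = v, edges = edges, window_faces = faces),
    class = "cage_topology"
  )
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  stopifnot(3L * topo$n_vertices == 2L * topo$n_edges)
  stopifnot(nrow(topo$edges) == topo$n_edges)
  per_vertex <- tabulate(topo$edges, nbins = topo$n_vertices)
  stopifnot(all(per_vertex == 3L))
  invisible(topo)
}

#' Names of the supported topologies
#' @return Character vector.
#' @export
supported_topologies <- function() c("Tri4Di6", "Tri8Di12")

# Edge indices incident to a vertex.
incident_edges <- function(topo, v) {
  which(topo$edges[, 1] == v | topo$edges[, 2] == v)
}

#' Construct a cage chromosome
#'
#' The fixed-length genome of the EA: a tri-topic building-block gene, a
#' di-topic building-block gene and a topology gene.
#'
#' @param bb_tri,bb_di Building-block ids (or `building_block`s).
#' @param topology Topology name.
#' @param db Optional `bb_database` used to validate roles.
#' @return A `cage_chromosome`.
#' @export
cage_chromosome <- function(bb_tri, bb_di, topology, db = NULL) {
  if (inherits(bb_tri, "building_block")) bb_tri <- bb_tri$id
  if (inherits(bb_di, "building_block")) bb_di <- bb_di$id
  if (!topology %in% supported_topologies()) {
    stop("unknown topology: ", topology)
  }
  if (!is.null(db)) {
    if (db_get(db, bb_tri)$role != "trialdehyde") {
      stop(bb_tri, " is not a trialdehyde")
    }
    if (db_get(db, bb_di)$role != "diamine") stop(bb_di, " is not a diamine")
  }
  structure(list(bb_tri = bb_tri, bb_di = bb_di, topology = topology),
            class = "cage_chromosome")
}

#' Canonical string key of a chromosome
#' @param chromosome A `cage_chromosome`.
#' @return A single string `tri|di|topology`.
#' @export
chromosome_key <- function(chromosome) {
  paste(chromosome$bb_tri, chromosome$bb_di, chromosome$topology, sep = "|")
}

key_to_chromosome <- function(key) {
  p <- strsplit(key, "|", fixed = TRUE)[[1]]
  cage_chromosome(p[1], p[2], p[3])
}

#' @export
print.cage_chromosome <- function(x, ...) {
  cat("<cage_chromosome>", chromosome_key(x), "\n")
  invisible(x)
}
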