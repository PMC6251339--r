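# Synthetic test data: programmatically generated building-block libraries
# (substituted triformyl-arenes, alpha,omega-diamines), toy cage geometries
# with closed-form properties, and synthetic fitness landscapes with a
# planted global optimum. Everything here is synthetic by construction and
# stands in for proprietary chemical databases in tests and examples.

# Enumerated trialdehyde candidates: triformylbenzene cores with ring
# substitutions, extended arms and larger aromatic cores.
.tri_candidates <- function() {
  subs <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "F", "Cl", "Br",
            "C#N", "CO", "N(C)C", "OC(C)C")
  base <- c(
    "O=Cc1cc(C=O)cc(C=O)c1",                       # triformylbenzene
    "O=Cc1c(O)c(C=O)c(O)c(C=O)c1O",                # triformylphloroglucinol
    "O=C/C=C/c1cc(/C=C/C=O)cc(/C=C/C=O)c1",        # extended vinyl arms
    "O=Cc1ccc(-c2cc(-c3ccc(C=O)cc3)cc(-c3ccc(C=O)cc3)c2)cc1"  # triphenyl core
  )
  mono <- sprintf("O=Cc1cc(C=O)c(%s)c(C=O)c1", subs)
  tri_sym <- sprintf("O=Cc1c(%s)c(C=O)c(%s)c(C=O)c1%s", subs, subs, subs)
  pair_idx <- utils::combn(length(subs), 2)
  tri_pair <- sprintf("O=Cc1c(%s)c(C=O)c(%s)c(C=O)c1",
                      subs[pair_idx[1, ]], subs[pair_idx[2, ]])
  c(base, mono, tri_sym, tri_pair)
}

# Enumerated diamine candidates: alkyl chains (2-8), methyl-branched chains,
# alicyclic and aromatic diamines, ether-linked chains.
.di_candidates <- function() {
  chains <- vapply(2:10, function(n) paste0("N", strrep("C", n), "N"),
                   character(1))
  branched <- unlist(lapply(2:7, function(n) {
    vapply(seq_len(n), function(j) {
      paste0("N", strrep("C", j - 1), "C(C)", strrep("C", n - j), "N")
    }, character(1))
  }))
  dibranched <- unlist(lapply(3:7, function(n) {
    pos <- utils::combn(n, 2)
    vapply(seq_len(ncol(pos)), function(k) {
      i <- pos[1, k]; j <- pos[2, k]
      paste0("N", strrep("C", i - 1), "C(C)", strrep("C", j - i - 1),
             "C(C)", strrep("C", n - j), "N")
    }, character(1))
  }))
  ethyl <- unlist(lapply(3:6, function(n) {
    vapply(seq_len(n), function(j) {
      paste0("N", strrep("C", j - 1), "C(CC)", strrep("C", n - j), "N")
    }, character(1))
  }))
  cyclic <- c("NC1CCCC1N", "NC1CCCCC1N", "NC1CCCCCC1N",
              "NCC1CCCCC1CN", "NCC1CCC(CN)CC1", "NC1CCC(N)CC1")
  aromatic <- c("Nc1ccccc1N", "Nc1cccc(N)c1", "Nc1ccc(N)cc1",
                "NCc1ccccc1CN", "NCc1cccc(CN)c1", "NCc1ccc(CN)cc1",
                "NCCc1ccccc1CCN")
  ether <- c("NCCOCCN", "NCCOCCOCCN", "NCCCOCCCN", "NCCOCCCOCCN")
  c(chains, branched, dibranched, ethyl, cyclic, aromatic, ether)
}

#' Generate a synthetic building-block library
#'
#' Draws `n_tri` trialdehydes and `n_di` diamines from deterministic
#' enumerations of substituted triformyl-arene and alkyl/aryl diamine
#' scaffolds, shuffled by `seed`, and passes them through the standard
#' database filter (with conformer embedding). Deterministic for a fixed
#' seed; every member is valid under [filter_database()].
#'
#' @param n_tri,n_di Requested library sizes (>= 1 each).
#' @param seed Integer seed (shuffling and embedding).
#' @param embed Embed 3D conformers (needed for assembly; similarity-only
#'   work can skip it).
#' @return A `bb_database` with exactly the requested member counts.
#' @export
generate_bb_library <- function(n_tri, n_di, seed = 1L, embed = TRUE) {
  stopifnot(n_tri >= 1L, n_di >= 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  tri_cand <- unique(canonical_smiles(.tri_candidates()))
  di_cand <- unique(canonical_smiles(.di_candidates()))
  tri_cand <- sample(tri_cand)
  di_cand <- sample(di_cand)
  if (n_tri > length(tri_cand) || n_di > length(di_cand)) {
    stop("requested library exceeds the scaffold enumeration (",
         length(tri_cand), " tri, ", length(di_cand), " di available)")
  }

  take_tri <- n_tri; take_di <- n_di
  for (attempt in 1:5) {
    sel <- c(tri_cand[seq_len(take_tri)], di_cand[seq_len(take_di)])
    db <- suppressWarnings(
      filter_database(sel, embed_seed = seed, embed = embed,
                      provenance = sprintf("synthetic(seed=%d)", seed))
    )
    n_tri_got <- length(db_ids(db, "trialdehyde"))
    n_di_got <- length(db_ids(db, "diamine"))
    if (n_tri_got >= n_tri && n_di_got >= n_di) break
    take_tri <- min(length(tri_cand), take_tri + (n_tri - n_tri_got))
    take_di <- min(length(di_cand), take_di + (n_di - n_di_got))
  }
  if (n_tri_got < n_tri || n_di_got < n_di) {
    stop("could not assemble the requested library sizes after filtering")
  }
  keep <- c(db_ids(db, "trialdehyde")[seq_len(n_tri)],
            db_ids(db, "diamine")[seq_len(n_di)])
  bb_database(db$members[keep], provenance = db$provenance)
}

#' Generate a toy cage with closed-form properties
#'
#' Dummy atoms are spread along the polyhedron edges and projected onto the
#' sphere of radius `shell_radius`, so the pore diameter is exactly
#' `2 * (shell_radius - vdw)` and all windows of the polyhedron are equal by
#' symmetry. The returned structure carries the matching topology provenance
#' so the window machinery applies unchanged.
#'
#' @param polyhedron `"tetrahedron"` (Tri4Di6) or `"cube"` (Tri8Di12).
#' @param shell_radius Sphere radius in Angstrom.
#' @param atoms_per_edge Dummy atoms per edge.
#' @param vdw Uniform van der Waals radius of the dummy atoms.
#' @return A `cage_structure` of dummy atoms (no bonds).
#' @export
generate_toy_cage <- function(polyhedron = c("tetrahedron", "cube"),
                              shell_radius = 5, atoms_per_edge = 5L,
                              vdw = 1.5) {
  polyhedron <- match.arg(polyhedron)
  stopifnot(shell_radius > vdw, atoms_per_edge >= 1L)
  topo <- topology_graph(if (polyhedron == "tetrahedron") "Tri4Di6"
                         else "Tri8Di12")
  coords <- NULL
  for (e in seq_len(topo$n_edges)) {
    a <- topo$vertex_coords[topo$edges[e, 1], ]
    b <- topo$vertex_coords[topo$edges[e, 2], ]
    for (t in seq_len(atoms_per_edge) / (atoms_per_edge + 1)) {
      p <- (1 - t) * a + t * b
      coords <- rbind(coords, shell_radius * p / sqrt(sum(p^2)))
    }
  }
  chrom <- structure(list(bb_tri = "toy-tri", bb_di = "toy-di",
                          topology = topo$name), class = "cage_chromosome")
  structure(
    list(chromosome = chrom,
         elements = rep("Du", nrow(coords)),
         coords = unname(coords),
         bonds = matrix(integer(0), 0, 3),
         imine_bond_indices = integer(0),
         energy = NA_real_, topology = topo,
         vertex_positions = topo$vertex_coords * shell_radius,
         site_atoms = list(), scale = shell_radius,
         vdw = vdw, masses = 1, flags = "synthetic_toy"),
    class = "cage_structure"
  )
}

# Synthetic stub database for abstract landscapes: ids plus index-correlated
# fingerprints (a sliding window of on-bits), so Dice similarity decays
# linearly with index distance and similarity-driven operators behave like
# they would in a correlated chemical space.
synthetic_stub_db <- function(tri_ids, di_ids, nbits = .FP_NBITS,
                              width = 64L, stride = 4L) {
  stub_fp <- function(i) {
    fp <- integer(nbits)
    fp[(((i - 1L) * stride) + seq_len(width) - 1L) %% nbits + 1L] <- 1L
    structure(fp, nbits = nbits, radius = .FP_RADIUS)
  }
  members <- c(
    lapply(seq_along(tri_ids), function(i) {
      synthetic_building_block(tri_ids[i], "trialdehyde", stub_fp(i))
    }),
    lapply(seq_along(di_ids), function(i) {
      synthetic_building_block(di_ids[i], "diamine", stub_fp(i))
    })
  )
  bb_database(members, provenance = "synthetic landscape stubs")
}

#' Generate a synthetic fitness landscape with a planted optimum
#'
#' Fitness is a smooth exponential decay in the (tri, di) index distance to
#' a seeded planted optimum, times log-normal noise scaled by `ruggedness`
#' and clipped below the planted value, so exactly one global optimum exists
#' by construction. The attached database holds synthetic stub fingerprints
#' whose Dice similarity decays with index distance, emulating a correlated
#' chemical space.
#'
#' @param n_tri,n_di Index-space dimensions (>= 2 each).
#' @param topologies Topology names included in the space.
#' @param ruggedness Standard deviation of the Gaussian noise on the
#'   log-fitness (0 = perfectly smooth).
#' @param seed Integer seed.
#' @return A `landscape`.
#' @export
generate_landscape <- function(n_tri, n_di, topologies = "Tri4Di6",
                               ruggedness = 0.1, seed = 1L) {
  stopifnot(n_tri >= 2L, n_di >= 2L, ruggedness >= 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  tri_ids <- sprintf("tri-%03d", seq_len(n_tri))
  di_ids <- sprintf("di-%03d", seq_len(n_di))
  opt_tri <- sample.int(n_tri, 1L)
  opt_di <- sample.int(n_di, 1L)
  opt_topo <- topologies[sample.int(length(topologies), 1L)]

  grid <- expand.grid(ti = seq_len(n_tri), di = seq_len(n_di),
                      topo = topologies, stringsAsFactors = FALSE)
  d <- sqrt(((grid$ti - opt_tri) / n_tri)^2 + ((grid$di - opt_di) / n_di)^2) +
    0.5 * (grid$topo != opt_topo)
  base <- exp(-4 * d)
  noise <- exp(ruggedness * stats::rnorm(nrow(grid)))
  fitness <- base * noise
  planted <- grid$ti == opt_tri & grid$di == opt_di & grid$topo == opt_topo
  fitness[planted] <- 1
  fitness[!planted] <- pmin(fitness[!planted], 1 - 1e-9)

  pore <- pmax(0, 5.72 - 3 * d)
  asym <- 2 * d
  tab <- data.frame(
    key = paste(tri_ids[grid$ti], di_ids[grid$di], grid$topo, sep = "|"),
    fitness = fitness,
    dpore = abs(pore - 5.72), dwindow = d, asym = asym,
    pore = pore, asymmetry = asym,
    stringsAsFactors = FALSE
  )
  landscape(tab, synthetic_stub_db(tri_ids, di_ids), topologies)
}

#' Emit all synthetic fixtures to a directory
#'
#' Writes the SMILES library (TSV), a toy tetrahedron cage (XYZ) and a
#' synthetic landscape (CSV).
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_tri,n_di Library sizes.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, n_tri = 6L, n_di = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- generate_bb_library(n_tri, n_di, seed = seed, embed = FALSE)
  write_bb_database(db, file.path(dir, "bb_library.tsv"))
  toy <- generate_toy_cage("tetrahedron", shell_radius = 5,
                           atoms_per_edge = 5L, vdw = 1.5)
  write_xyz(toy, file.path(dir, "toy_tetrahedron.xyz"))
  ls <- generate_landscape(20L, 50L, seed = seed)
  write_landscape(ls, file.path(dir, "landscape.csv"))
  invisible(dir)
}
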