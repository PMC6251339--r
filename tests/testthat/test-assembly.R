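# Topology graphs, cage assembly with imine condensation, relaxation and the
# conformer search contract.

test_that("topology graphs satisfy the arm/bond balance and window counts", {
  t4 <- topology_graph("Tri4Di6")
  expect_equal(t4$n_vertices, 4L)
  expect_equal(t4$n_edges, 6L)
  expect_length(t4$window_faces, 4L)

  t8 <- topology_graph("Tri8Di12")
  expect_equal(t8$n_vertices, 8L)
  expect_equal(t8$n_edges, 12L)
  expect_length(t8$window_faces, 6L)

  for (t in list(t4, t8)) {
    expect_equal(3L * t$n_vertices, 2L * t$n_edges)
    # every vertex carries exactly three arms
    expect_true(all(tabulate(t$edges, t$n_vertices) == 3L))
    # vertices sit on the unit sphere
    expect_equal(sqrt(rowSums(t$vertex_coords^2)), rep(1, t$n_vertices))
  }
  expect_error(topology_graph("Di2Tri3"), "unknown topology")
})

test_that("assembly forms 2E imine bonds and conserves mass", {
  db <- test_db()
  for (topo in c("Tri4Di6", "Tri8Di12")) {
    chrom <- make_chrom(db, topo)
    s <- assemble(chrom, db)
    t <- topology_graph(topo)
    expect_length(s$imine_bond_indices, 2L * t$n_edges)
    expect_true(all(s$bonds[s$imine_bond_indices, 3] == 2L))
    # mass balance: V*MW(tri) + E*MW(di) - 2E*MW(H2O), both sides computed
    # independently from element counts
    tri <- evocage:::db_get(db, chrom$bb_tri)
    di <- evocage:::db_get(db, chrom$bb_di)
    expected <- t$n_vertices * structure_mass(tri$conformer) +
      t$n_edges * structure_mass(di$conformer) -
      2 * t$n_edges * (2 * 1.00794 + 15.9994)
    expect_equal(structure_mass(s), expected, tolerance = 1e-9)
    expect_true(evocage:::is_connected_structure(s))
  }
})

test_that("assembled element counts follow the condensation stoichiometry", {
  db <- test_db()
  chrom <- make_chrom(db, "Tri4Di6")
  s <- assemble(chrom, db)
  tri <- evocage:::db_get(db, chrom$bb_tri)$conformer
  di <- evocage:::db_get(db, chrom$bb_di)$conformer
  count <- function(el, x) sum(x == el)
  for (el in unique(s$elements)) {
    expected <- 4L * count(el, tri$elements) + 6L * count(el, di$elements)
    if (el == "O") expected <- expected - 12L       # 2E oxygens leave
    if (el == "H") expected <- expected - 24L       # 4E hydrogens leave
    expect_equal(count(el, s$elements), expected)
  }
})

test_that("assembly is deterministic and respects chromosome roles", {
  db <- test_db()
  chrom <- make_chrom(db, "Tri4Di6")
  s1 <- assemble(chrom, db)
  s2 <- assemble(chrom, db)
  expect_identical(s1, s2)
  bad <- structure(list(bb_tri = chrom$bb_di, bb_di = chrom$bb_tri,
                        topology = "Tri4Di6"), class = "cage_chromosome")
  expect_error(assemble(bad, db), "roles")
})

test_that("relaxation never raises the energy and keeps bonds sane", {
  db <- test_db()
  s <- assemble(make_chrom(db, "Tri4Di6"), db)
  opt <- optimizer_harmonic()
  e0 <- opt$potential(s)
  sr <- relax(s, opt)
  expect_lte(sr$energy, e0)
  d <- evocage:::bonded_distances(sr)
  expect_true(all(d > 0.7 & d < 1.9))

  # relaxing further never raises the energy
  sr2 <- relax(sr, opt)
  expect_lte(sr2$energy, sr$energy)

  # a structure at its exact minimum is a fixed point: every bond at its
  # reference length, energy zero
  r0 <- evocage:::reference_bond_length("C", "C", 1L)
  min_s <- structure(list(
    elements = c("C", "C"), coords = rbind(c(0, 0, 0), c(r0, 0, 0)),
    bonds = cbind(1L, 2L, 1L), imine_bond_indices = integer(0),
    energy = NA_real_, flags = character(0)), class = "cage_structure")
  min_s$imine_bond_indices <- 1L   # junction mask covers both atoms
  relaxed <- relax(min_s, opt)
  expect_equal(relaxed$energy, 0, tolerance = 1e-12)
  expect_equal(relaxed$coords, min_s$coords, tolerance = 1e-9)
})

test_that("the junction-constrained stage moves only junction-adjacent atoms", {
  db <- test_db()
  s <- assemble(make_chrom(db, "Tri4Di6"), db)
  mask <- evocage:::junction_free_mask(s)
  opt <- optimizer_harmonic()
  s1 <- opt$minimize(s, free = mask)
  delta <- sqrt(rowSums((s1$coords - s$coords)^2))
  expect_true(all(delta[!mask] < 1e-12))
  expect_true(any(delta[mask] > 1e-6))
})

test_that("conformer search returns the lowest-energy sample deterministically", {
  db <- test_db()
  s <- relax(assemble(make_chrom(db, "Tri4Di6"), db))
  expect_identical(conformer_search(s, 0L, seed = 1), s)

  opt <- optimizer_harmonic()
  c1 <- conformer_search(s, 3L, seed = 7, optimizer = opt)
  c2 <- conformer_search(s, 3L, seed = 7, optimizer = opt)
  expect_identical(c1, c2)
  expect_lte(c1$energy, s$energy)

  # a frozen optimizer cannot change any property of a rigid cage
  toy <- generate_toy_cage("tetrahedron", 5, 4L, 1.5)
  toy$energy <- 0
  frozen <- optimizer_identity()
  out <- conformer_search(toy, 5L, seed = 2, optimizer = frozen)
  expect_equal(pore_diameter(out), pore_diameter(toy))
})

test_that("shape persistency compares pore retention against the floor", {
  toy <- generate_toy_cage("tetrahedron", 5, 4L, 1.5)
  expect_true(shape_persistency(toy, toy))

  collapsed <- toy
  collapsed$coords <- toy$coords * 0.2   # cavity implodes below the floor
  expect_false(shape_persistency(toy, collapsed))

  # ratio rule: 6.0 -> 2.9 A with threshold 0.5 and floor 2.8 fails (0.483)
  a <- generate_toy_cage("tetrahedron", 3.0 + 1.5, 4L, 1.5)   # pore 6.0
  b <- generate_toy_cage("tetrahedron", 1.45 + 1.5, 4L, 1.5)  # pore 2.9
  b$chromosome <- a$chromosome
  expect_equal(pore_diameter(a), 6.0)
  expect_equal(pore_diameter(b), 2.9)
  expect_false(shape_persistency(a, b, threshold_fraction = 0.5, floor = 2.8))
  # but a window-preserving relaxation to 3.1 A passes the same rule
  b2 <- generate_toy_cage("tetrahedron", 1.55 + 1.5, 4L, 1.5)
  b2$chromosome <- a$chromosome
  expect_true(shape_persistency(a, b2, threshold_fraction = 0.5, floor = 2.8))
})

test_that("structure files are written in XYZ and MOL formats", {
  toy <- generate_toy_cage("tetrahedron", 5, 3L, 1.5)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(toy, xyz)
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), length(toy$elements))
  expect_length(lines, length(toy$elements) + 2L)

  db <- test_db()
  s <- assemble(make_chrom(db, "Tri4Di6"), db)
  mol <- withr::local_tempfile(fileext = ".mol")
  write_mol(s, mol)
  lines <- readLines(mol)
  expect_match(lines[4], "V2000")
  expect_equal(lines[length(lines)], "M  END")
})
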