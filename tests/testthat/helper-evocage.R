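# Shared fixtures and independent oracles. Everything is generated in code;
# the embedded library is built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic library with conformers (4 trialdehydes x 8 diamines).
test_db <- function() {
  if (is.null(.fixture_env$db)) {
    .fixture_env$db <- suppressWarnings(
      generate_bb_library(4L, 8L, seed = 11L, embed = TRUE))
  }
  .fixture_env$db
}

# Larger conformer-free library for similarity work.
test_db_flat <- function(n_tri = 5L, n_di = 50L, seed = 23L) {
  key <- sprintf("flat_%d_%d_%d", n_tri, n_di, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- suppressWarnings(
      generate_bb_library(n_tri, n_di, seed = seed, embed = FALSE))
  }
  .fixture_env[[key]]
}

first_id <- function(db, role) evocage:::db_ids(db, role)[1]

make_chrom <- function(db, topology = "Tri4Di6", tri_i = 1L, di_i = 1L) {
  cage_chromosome(evocage:::db_ids(db, "trialdehyde")[tri_i],
                  evocage:::db_ids(db, "diamine")[di_i], topology, db = db)
}

# Independent brute-force pore oracle: explicit center-of-mass arithmetic and
# an O(N) loop over atoms.
oracle_pore <- function(s) {
  m <- if (!is.null(s$masses)) rep_len(s$masses, nrow(s$coords)) else
    evocage:::atomic_mass(s$elements)
  com <- c(0, 0, 0)
  for (i in seq_len(nrow(s$coords))) com <- com + m[i] * s$coords[i, ]
  com <- com / sum(m)
  radii <- if (!is.null(s$vdw)) rep_len(s$vdw, nrow(s$coords)) else
    evocage:::vdw_radius(s$elements)
  best <- Inf
  for (i in seq_len(nrow(s$coords))) {
    d <- sqrt(sum((s$coords[i, ] - com)^2)) - radii[i]
    if (d < best) best <- d
  }
  max(0, 2 * best)
}

# Independent window oracle: brute-force grid search over the face plane
# (coarse 0.05 A grid plus a 0.01 A refinement around the best point),
# maximizing the minimum distance to any atom surface inside the face
# polygon.
oracle_window <- function(s, face_i, grid = 0.05, fine = 0.01) {
  topo <- s$topology
  fp <- s$vertex_positions[topo$window_faces[[face_i]], , drop = FALSE]
  ctr <- colMeans(fp)
  cen <- sweep(fp, 2, ctr)
  sv <- svd(cen)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  poly2d <- cen %*% sv$v[, 1:2]
  radii <- if (!is.null(s$vdw)) rep_len(s$vdw, nrow(s$coords)) else
    evocage:::vdw_radius(s$elements)
  ctr2 <- colMeans(poly2d)
  npoly <- nrow(poly2d)
  inward <- t(vapply(seq_len(npoly), function(k) {
    a <- poly2d[k, ]; b <- poly2d[k %% npoly + 1, ]
    ed <- b - a
    nr <- c(-ed[2], ed[1]) / sqrt(sum(ed^2))
    if (sum((ctr2 - a) * nr) < 0) nr <- -nr
    c(nr, sum(a * nr))
  }, numeric(3)))
  inside <- function(p) all(inward[, 1] * p[1] + inward[, 2] * p[2] -
                              inward[, 3] >= 0)
  clearance <- function(u, v) {
    c3 <- ctr + u * e1 + v * e2
    min(sqrt(rowSums(sweep(s$coords, 2, c3)^2)) - radii)
  }
  scan <- function(us, vs) {
    best <- c(-Inf, 0, 0)
    for (u in us) for (v in vs) {
      if (!inside(c(u, v))) next
      d <- clearance(u, v)
      if (d > best[1]) best <- c(d, u, v)
    }
    best
  }
  rng <- max(sqrt(rowSums(poly2d^2)))
  coarse <- scan(seq(-rng, rng, by = grid), seq(-rng, rng, by = grid))
  fine_res <- scan(seq(coarse[2] - grid, coarse[2] + grid, by = fine),
                   seq(coarse[3] - grid, coarse[3] + grid, by = fine))
  max(0, 2 * max(coarse[1], fine_res[1]))
}

# Random synthetic fingerprint with the package's attributes.
random_fp <- function(n_on = 40L, nbits = 2048L) {
  fp <- integer(nbits)
  fp[sample.int(nbits, n_on)] <- 1L
  structure(fp, nbits = nbits, radius = 1L)
}

# Dice by explicit on-bit set enumeration (independent of dice_similarity).
dice_oracle <- function(fa, fb) {
  a <- which(fa != 0); b <- which(fb != 0)
  if (length(a) + length(b) == 0L) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Constant-fitness evaluator for convergence bookkeeping tests.
evaluator_frozen <- function(value = 1) {
  function(keys) {
    data.frame(key = keys, fitness = value, dpore = 0, dwindow = 0, asym = 0,
               pore = 5, asymmetry = 0, stringsAsFactors = FALSE)
  }
}
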