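# The evolutionary engine: initialization, selection, operators, one-step
# bookkeeping and full-run convergence behavior.

test_that("initialization yields n distinct valid chromosomes, reproducibly", {
  db <- test_db_flat(5L, 20L)
  p1 <- init_population(db, "Tri4Di6", method = "random", n = 25L, seed = 3L)
  expect_equal(nrow(p1$members), 25L)
  expect_equal(anyDuplicated(p1$members$key), 0L)
  expect_true(all(startsWith(p1$members$tri, "tri")))
  expect_true(all(startsWith(p1$members$di, "di")))

  p2 <- init_population(db, "Tri4Di6", method = "random", n = 25L, seed = 3L)
  expect_identical(p1$members, p2$members)
  p3 <- init_population(db, "Tri4Di6", method = "random", n = 25L, seed = 4L)
  expect_false(identical(p1$members, p3$members))

  # impossible request: more chromosomes than the space holds
  tiny <- test_db_flat(2L, 2L, seed = 9L)
  expect_error(init_population(tiny, "Tri4Di6", "random", n = 10L, seed = 1L),
               "distinct")
})

test_that("diverse initialization pulls in a chemical-space outlier", {
  # stub db where tri-020 (far index) is dissimilar to the clustered rest
  stub_fp <- function(i, nbits = 2048L) {
    fp <- integer(nbits)
    fp[((i - 1) * 4 + 1:64 - 1) %% nbits + 1] <- 1L
    structure(fp, nbits = nbits, radius = 1L)
  }
  members <- c(
    lapply(1:5, function(i) evocage:::synthetic_building_block(
      sprintf("tri-%03d", i), "trialdehyde", stub_fp(i))),
    list(evocage:::synthetic_building_block("tri-099", "trialdehyde",
                                            stub_fp(500))),
    lapply(1:6, function(i) evocage:::synthetic_building_block(
      sprintf("di-%03d", i), "diamine", stub_fp(i)))
  )
  db <- evocage:::bb_database(members)
  outlier <- db$members[["tri-099"]]
  others <- setdiff(evocage:::db_ids(db, "trialdehyde"), "tri-099")
  mean_sim <- mean(vapply(others, function(i)
    dice_similarity(outlier, db$members[[i]]), numeric(1)))
  expect_lt(mean_sim, 0.1)

  pop <- init_population(db, "Tri4Di6", method = "diverse", n = 10L, seed = 2L)
  expect_true("tri-099" %in% pop$members$tri)
})

test_that("selection methods honor their contracts", {
  db <- test_db_flat(5L, 20L)
  pop <- init_population(db, "Tri4Di6", "random", n = 6L, seed = 1L)
  pop$members$fitness <- c(5, 3, 8, 1, 7, 2)
  pop$members$pore <- 5; pop$members$asymmetry <- 0

  top2 <- select_parents(pop, "fittest", 2L, seed = 1L)
  expect_equal(top2$fitness, c(8, 7))

  # SUS with equal fitness selects every member exactly once
  eq <- pop; eq$members$fitness <- rep(2, 6)
  sus <- select_parents(eq, "sus", 6L, seed = 5L)
  expect_setequal(sus$key, eq$members$key)

  # roulette frequencies follow fitness proportions (3:1, binomial 3 sigma)
  two <- pop; two$members <- pop$members[1:2, ]; two$members$fitness <- c(3, 1)
  streams <- evocage:::rng_streams(42L)
  draws <- select_parents(two, "roulette", 10000L, streams = streams)
  frac <- mean(draws$key == two$members$key[1])
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # elitism always includes the incumbent best
  el <- select_parents(pop, "roulette_elitism", 3L, seed = 2L)
  expect_equal(el$key[1], pop$members$key[which.max(pop$members$fitness)])

  zero <- pop; zero$members$fitness <- rep(0, 6)
  expect_warning(select_parents(zero, "roulette", 2L, seed = 1L), "uniform")
  expect_warning(select_parents(zero, "sus", 2L, seed = 1L), "uniform")
})

test_that("crossover exchanges exactly one gene between the parents", {
  p1 <- cage_chromosome("tri-001", "di-001", "Tri4Di6")
  p2 <- cage_chromosome("tri-002", "di-002", "Tri8Di12")
  streams <- evocage:::rng_streams(8L)
  for (i in 1:20) {
    kids <- crossover(p1, p2, streams = streams)
    diff1 <- vapply(c("bb_tri", "bb_di", "topology"), function(g)
      !identical(kids[[1]][[g]], p1[[g]]), logical(1))
    diff2 <- vapply(c("bb_tri", "bb_di", "topology"), function(g)
      !identical(kids[[2]][[g]], p2[[g]]), logical(1))
    expect_equal(sum(diff1), 1L)
    expect_identical(diff1, diff2)
    # the exchanged gene values swap
    g <- names(diff1)[diff1]
    expect_identical(kids[[1]][[g]], p2[[g]])
    expect_identical(kids[[2]][[g]], p1[[g]])
  }
  # identical parents reproduce themselves
  kids <- crossover(p1, p1, streams = streams)
  expect_identical(chromosome_key(kids[[1]]), chromosome_key(p1))
})

test_that("random mutation changes one gene to a database alternative", {
  db <- test_db_flat(5L, 20L)
  ind <- cage_chromosome(evocage:::db_ids(db, "trialdehyde")[1],
                         evocage:::db_ids(db, "diamine")[1], "Tri4Di6")
  streams <- evocage:::rng_streams(3L)
  for (i in 1:20) {
    mut <- mutate(ind, db, mode = "random", streams = streams)
    diffs <- vapply(c("bb_tri", "bb_di", "topology"), function(g)
      !identical(mut[[g]], ind[[g]]), logical(1))
    expect_equal(sum(diffs), 1L)
  }
  # single-candidate database: replacement is that candidate
  solo <- test_db_flat(1L, 1L, seed = 4L)
  ind2 <- cage_chromosome(evocage:::db_ids(solo, "trialdehyde")[1],
                          evocage:::db_ids(solo, "diamine")[1], "Tri4Di6")
  mut2 <- mutate(ind2, solo, mode = "random", gene = "bb_di",
                 streams = streams)
  expect_identical(mut2$bb_di, ind2$bb_di)
})

test_that("similarity mutation steps through neighbor ranks 1, 2, 3, ...", {
  db <- test_db_flat(5L, 50L)
  di1 <- evocage:::db_ids(db, "diamine")[1]
  ind <- cage_chromosome(evocage:::db_ids(db, "trialdehyde")[1], di1,
                         "Tri4Di6")
  state <- mutation_state()
  streams <- evocage:::rng_streams(6L)
  target <- db$members[[di1]]
  for (k in 1:6) {
    mut <- mutate(ind, db, mode = "similarity", state = state,
                  gene = "bb_di", streams = streams)
    expect_identical(mut$bb_di, similarity_rank(target, db, k)$id)
  }
  # exhausting the neighbor list wraps with a warning
  tiny <- test_db_flat(2L, 3L, seed = 8L)
  di_t <- evocage:::db_ids(tiny, "diamine")[1]
  ind_t <- cage_chromosome(evocage:::db_ids(tiny, "trialdehyde")[1], di_t,
                           "Tri4Di6")
  st <- mutation_state()
  for (k in 1:2) mutate(ind_t, tiny, "similarity", st, gene = "bb_di",
                        streams = streams)
  expect_warning(
    m3 <- mutate(ind_t, tiny, "similarity", st, gene = "bb_di",
                 streams = streams),
    "wrap")
  expect_identical(m3$bb_di,
                   similarity_rank(tiny$members[[di_t]], tiny, 1L)$id)
})

test_that("one step keeps the population size and evicts the worst", {
  ls <- generate_landscape(6L, 8L, seed = 4L)
  ev <- evaluator_landscape(ls)
  cfg <- ea_config(population_size = 10L, n_crossover = 4L, n_mutation = 2L,
                   selection_method = "fittest", rng_seed = 2L)
  pop <- init_population(ls$db, ls$topologies, "random", 10L, seed = 2L)
  pop <- evocage:::evaluate_population_members(pop, ev)
  streams <- evocage:::rng_streams(2L)
  nxt <- suppressWarnings(
    ea_step(pop, cfg, ev, ls$db, ls$topologies, streams = streams))
  expect_equal(nrow(nxt$members), 10L)
  expect_gte(min(nxt$members$fitness), min(pop$members$fitness))
  expect_gte(max(nxt$members$fitness), max(pop$members$fitness))
  # evaluations are cached: distinct chromosomes <= pop + offspring
  expect_lte(length(ls(nxt$cache)), 10L + 6L)
})

test_that("a population of clones of the optimum is unchanged by a step", {
  ls <- generate_landscape(5L, 5L, seed = 6L)
  ev <- evaluator_landscape(ls)
  opt <- evocage:::key_to_chromosome(ls$global_optimum)
  members <- do.call(rbind, lapply(1:4, function(i) data.frame(
    key = ls$global_optimum, tri = opt$bb_tri, di = opt$bb_di,
    topology = opt$topology, fitness = NA_real_, pore = NA_real_,
    asymmetry = NA_real_, stringsAsFactors = FALSE)))
  pop <- structure(list(members = members, generation = 0L,
                        cache = new.env(parent = emptyenv())),
                   class = "population")
  pop <- evocage:::evaluate_population_members(pop, ev)
  cfg <- ea_config(population_size = 4L, n_crossover = 2L, n_mutation = 1L,
                   selection_method = "fittest", rng_seed = 1L)
  nxt <- suppressWarnings(ea_step(pop, cfg, ev, ls$db, ls$topologies,
                                  streams = evocage:::rng_streams(1L)))
  expect_equal(nxt$members$key, pop$members$key)
  expect_equal(nxt$members$fitness, pop$members$fitness)
})

test_that("runs stop on the generation budget, a target, or patience", {
  ls <- generate_landscape(8L, 10L, seed = 12L)
  ev <- evaluator_landscape(ls)

  # zero-generation budget: only the initial population row
  cfg0 <- ea_config(population_size = 8L, max_generations = 0L, rng_seed = 5L)
  r0 <- run_ea(ls$db, cfg0, ev, topologies = ls$topologies)
  expect_equal(nrow(r0$progress), 1L)
  expect_equal(r0$progress$generation, 0L)

  # target already in the initial population converges at generation 0
  cfg1 <- ea_config(population_size = 8L, max_generations = 10L, rng_seed = 5L)
  pop <- init_population(ls$db, ls$topologies, cfg1$init_method, 8L,
                         seed = cfg1$rng_seed)
  some_member <- pop$members$key[3]
  r1 <- run_ea(ls$db, cfg1, ev, topologies = ls$topologies,
               target = some_member)
  expect_true(r1$target_found)
  expect_equal(r1$target_generation, 0L)
  expect_equal(r1$convergence_generation, 0L)

  # frozen evaluator: top-5 never changes; stop after exactly the patience
  cfgf <- ea_config(population_size = 10L, n_crossover = 3L, n_mutation = 2L,
                    max_generations = 100L, convergence_patience = 20L,
                    selection_method = "fittest", rng_seed = 9L,
                    mutation_schedule = "random_only")
  rf <- run_ea(ls$db, cfgf, evaluator_frozen(), topologies = ls$topologies)
  expect_equal(rf$convergence_generation, 20L)
  expect_equal(nrow(rf$progress), 21L)
})

test_that("identical seeds give byte-identical run records", {
  ls <- generate_landscape(10L, 12L, seed = 21L)
  ev <- evaluator_landscape(ls)
  cfg <- ea_config(population_size = 12L, n_crossover = 6L, n_mutation = 3L,
                   max_generations = 15L, rng_seed = 77L)
  r1 <- suppressWarnings(run_ea(ls$db, cfg, ev, topologies = ls$topologies))
  r2 <- suppressWarnings(run_ea(ls$db, cfg, ev, topologies = ls$topologies))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(run_ea(ls$db, ea_config(population_size = 12L,
                                                 n_crossover = 6L,
                                                 n_mutation = 3L,
                                                 max_generations = 15L,
                                                 rng_seed = 78L),
                                ev, topologies = ls$topologies))
  # a different seed draws a different initial population / search path
  expect_false(identical(r1$progress, r3$progress))
})

test_that("best fitness is monotone and the explored count is bounded", {
  ls <- generate_landscape(10L, 12L, seed = 33L)
  ev <- evaluator_landscape(ls)
  cfg <- ea_config(population_size = 10L, n_crossover = 5L, n_mutation = 3L,
                   max_generations = 20L, convergence_patience = Inf,
                   rng_seed = 4L)
  r <- suppressWarnings(run_ea(ls$db, cfg, ev, topologies = ls$topologies))
  expect_true(all(diff(r$progress$best_fitness) >= -1e-12))
  gens <- nrow(r$progress) - 1L
  expect_lte(r$n_evaluated, 10L + gens * (5L + 3L))
})

test_that("progress statistics aggregate the population correctly", {
  ls <- generate_landscape(5L, 6L, seed = 2L)
  pop <- init_population(ls$db, "Tri4Di6", "random", 4L, seed = 3L)
  pop$members$fitness <- c(1, 3, 2, 0.5)
  pop$members$pore <- c(4, 5, 6, 7)
  pop$members$asymmetry <- c(0.1, 0.2, 0.3, 0.4)
  row <- progress_stats(pop, topologies = "Tri4Di6")
  expect_equal(row$best_fitness, 3)
  expect_equal(row$avg_fitness, mean(c(1, 3, 2, 0.5)))
  expect_equal(row$best_pore, 5)        # pore of the fittest member
  expect_equal(row$avg_pore, mean(c(4, 5, 6, 7)))
  expect_equal(row$frac_Tri4Di6, 1.0)

  # descriptor means equal hand-averaged values on a conformer-backed db
  db <- test_db()
  popd <- init_population(db, "Tri4Di6", "random", 4L, seed = 6L)
  popd$members$fitness <- 1; popd$members$pore <- 1
  popd$members$asymmetry <- 0
  rowd <- progress_stats(popd, db, topologies = "Tri4Di6",
                         descriptors = TRUE)
  hand <- mean(vapply(popd$members$di, function(id)
    bb_descriptors(db$members[[id]])$end_group_distance, numeric(1)))
  expect_equal(rowd$di_end_group_distance, hand)
})
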