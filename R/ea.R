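# The generational evolutionary loop: named RNG streams, initialization,
# selection, crossover, mutation, replacement, convergence and per-generation
# progress analytics.

#' EA configuration
#'
#' Defaults follow the published optimization protocol: a population of 25,
#' 20 crossover operations and 5 mutations per generation, up to 100
#' generations, with convergence declared once the top-5 chromosome set has
#' stayed unchanged for 20 consecutive generations.
#'
#' @param population_size Population size (>= 2).
#' @param n_crossover Crossover operations per generation.
#' @param n_mutation Mutation operations per generation.
#' @param max_generations Generation budget.
#' @param selection_method One of `"fittest"`, `"roulette"`,
#'   `"roulette_elitism"`, `"sus"`.
#' @param init_method `"random"` or `"diverse"` (alternates random draws with
#'   maximally dissimilar ones).
#' @param convergence_patience Unchanged-top-5 streak that stops the run; use
#'   `Inf` to disable.
#' @param rng_seed Master seed; spawns independent named streams.
#' @param mutation_schedule `"alternate_random_similarity"`, `"random_only"`
#'   or `"similarity_only"`.
#' @return An `ea_config`.
#' @export
ea_config <- function(population_size = 25L, n_crossover = 20L,
                      n_mutation = 5L, max_generations = 100L,
                      selection_method = c("roulette_elitism", "fittest",
                                           "roulette", "sus"),
                      init_method = c("diverse", "random"),
                      convergence_patience = 20L, rng_seed = 1L,
                      mutation_schedule = c("alternate_random_similarity",
                                            "random_only", "similarity_only")) {
  selection_method <- match.arg(selection_method)
  init_method <- match.arg(init_method)
  mutation_schedule <- match.arg(mutation_schedule)
  stopifnot(population_size >= 2L, n_crossover >= 0L, n_mutation >= 0L,
            max_generations >= 0L)
  structure(list(population_size = as.integer(population_size),
                 n_crossover = as.integer(n_crossover),
                 n_mutation = as.integer(n_mutation),
                 max_generations = as.integer(max_generations),
                 selection_method = selection_method,
                 init_method = init_method,
                 convergence_patience = convergence_patience,
                 rng_seed = as.integer(rng_seed),
                 mutation_schedule = mutation_schedule),
            class = "ea_config")
}

# --- named RNG streams ------------------------------------------------------
# One master seed spawns independent streams so a change in one subsystem
# does not shift the draws of another.

rng_streams <- function(seed) {
  env <- new.env(parent = emptyenv())
  nm <- c("init", "selection", "crossover", "mutation", "sampling")
  for (k in seq_along(nm)) {
    set.seed((abs(as.integer(seed)) + k * 104729L) %% 2147483629L)
    env[[nm[k]]] <- get(".Random.seed", globalenv())
  }
  env
}

with_stream <- function(streams, name, expr) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams[[name]], globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(expr)
}

# --- evaluation and caching -------------------------------------------------

# Evaluate chromosome keys through the cache; the evaluator is only called on
# keys never seen in this run. Returns a data frame aligned with `keys`
# holding raw penalties, properties and (for absolute evaluators) fitness.
evaluate_keys <- function(keys, evaluator, cache) {
  novel <- unique(keys[!vapply(keys, function(k) !is.null(cache[[k]]),
                               logical(1))])
  if (length(novel)) {
    rows <- evaluator(novel)
    stopifnot(nrow(rows) == length(novel))
    for (i in seq_along(novel)) cache[[novel[i]]] <- rows[i, , drop = FALSE]
  }
  do.call(rbind, lapply(keys, function(k) cache[[k]]))
}

# Pool fitness: absolute when the evaluator supplies it, otherwise
# population-mean normalized from the raw penalties.
pool_fitness <- function(rows, fitness_config) {
  if (!is.null(rows$fitness) && !anyNA(rows$fitness)) return(rows$fitness)
  if (is.null(fitness_config)) {
    stop("evaluator supplies no fitness; a fitness_config is required")
  }
  evaluate_population(as.matrix(rows[, c("dpore", "dwindow", "asym")]),
                      fitness_config)$fitness
}

#' Landscape-backed evaluator
#'
#' Serves precomputed fitness and properties from a [landscape] lookup, so EA
#' runs need no molecular calculations.
#'
#' @param landscape A `landscape`.
#' @return An evaluator function (character keys in, data frame out).
#' @export
evaluator_landscape <- function(landscape) {
  tab <- landscape$table
  function(keys) {
    idx <- match(keys, tab$key)
    if (anyNA(idx)) stop("chromosome absent from landscape: ",
                         paste(keys[is.na(idx)], collapse = ", "))
    tab[idx, c("key", "fitness", "dpore", "dwindow", "asym", "pore",
               "asymmetry"), drop = FALSE]
  }
}

#' Structure-based evaluator
#'
#' The full molecular pipeline: assemble, two-stage relax, conformer search,
#' property calculation, raw penalties. Fitness is left `NA`; the engine
#' normalizes penalties against the evaluation pool. Failures yield
#' non-finite penalties (and thus fitness 0).
#'
#' @param db A `bb_database` with conformers.
#' @param fitness_config A `fitness_config` (for the penalty definitions).
#' @param optimizer Optimizer object.
#' @param n_samples Conformer-search samples per cage.
#' @param sample_seed Seed for the conformer search.
#' @return An evaluator function.
#' @export
evaluator_structure <- function(db, fitness_config,
                                optimizer = optimizer_harmonic(),
                                n_samples = 0L, sample_seed = 1L) {
  function(keys) {
    rows <- lapply(keys, function(k) {
      res <- tryCatch({
        chrom <- key_to_chromosome(k)
        s <- assemble(chrom, db)
        s <- relax(s, optimizer)
        if (n_samples > 0L) {
          s <- conformer_search(s, n_samples, seed = sample_seed,
                                optimizer = optimizer)
        }
        p <- cage_properties(s)
        pen <- raw_penalties(p, fitness_config)
        data.frame(key = k, fitness = NA_real_, dpore = pen[["dpore"]],
                   dwindow = pen[["dwindow"]], asym = pen[["asymmetry"]],
                   pore = p$pore_diameter, asymmetry = p$asymmetry)
      }, error = function(e) NULL)
      if (is.null(res)) {
        data.frame(key = k, fitness = NA_real_, dpore = Inf, dwindow = Inf,
                   asym = Inf, pore = NA_real_, asymmetry = NA_real_)
      } else res
    })
    do.call(rbind, rows)
  }
}

# --- initialization ---------------------------------------------------------

#' Initialize a population of cage chromosomes
#'
#' Random mode draws building blocks and topologies uniformly. Diverse mode
#' alternates uniform draws with draws of the building block least similar
#' (lowest mean Dice similarity) to those already present, so distant areas
#' of chemical space enter the seed population.
#'
#' @param db A `bb_database`.
#' @param topologies Topology names to draw from.
#' @param method `"random"` or `"diverse"`.
#' @param n Number of distinct chromosomes.
#' @param seed Integer seed (ignored when `streams` given).
#' @param streams Optional RNG stream set (internal use).
#' @return A `population` (unevaluated; fitness `NA`).
#' @export
init_population <- function(db, topologies, method = "random", n, seed = 1L,
                            streams = NULL) {
  tri_ids <- db_ids(db, "trialdehyde")
  di_ids <- db_ids(db, "diamine")
  if (!length(tri_ids) || !length(di_ids)) {
    stop("database needs at least one member of each role")
  }
  if (is.null(streams)) streams <- rng_streams(seed)

  dissimilar_pick <- function(cand_ids, present_ids) {
    if (!length(present_ids)) return(NULL)
    mean_sim <- vapply(cand_ids, function(i) {
      mean(vapply(present_ids, function(j) {
        dice_similarity(db$members[[i]], db$members[[j]])
      }, numeric(1)))
    }, numeric(1))
    cand_ids[order(mean_sim, cand_ids)][1]
  }

  keys <- character(0)
  rows <- list()
  used_tri <- character(0); used_di <- character(0)
  tries <- 0L
  last_success <- 0L
  with_stream(streams, "init", {
    while (length(rows) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n) {
        stop("cannot produce ", n, " distinct chromosomes from this database")
      }
      # even slots of diverse mode take the most dissimilar blocks; a collision
      # with an existing chromosome falls back to random draws so the loop
      # always progresses (the dissimilar pick is deterministic given the set)
      diverse_draw <- method == "diverse" && length(rows) %% 2L == 1L &&
        tries == last_success + 1L
      tri <- if (diverse_draw) dissimilar_pick(tri_ids, used_tri) else NULL
      di <- if (diverse_draw) dissimilar_pick(di_ids, used_di) else NULL
      if (is.null(tri)) tri <- tri_ids[sample.int(length(tri_ids), 1L)]
      if (is.null(di)) di <- di_ids[sample.int(length(di_ids), 1L)]
      topo <- topologies[sample.int(length(topologies), 1L)]
      chrom <- cage_chromosome(tri, di, topo)
      key <- chromosome_key(chrom)
      if (key %in% keys) next
      last_success <- tries
      keys <- c(keys, key)
      used_tri <- union(used_tri, tri); used_di <- union(used_di, di)
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, tri = tri, di = di, topology = topo, fitness = NA_real_,
        pore = NA_real_, asymmetry = NA_real_, stringsAsFactors = FALSE)
    }
  })
  structure(list(members = do.call(rbind, rows), generation = 0L,
                 cache = new.env(parent = emptyenv())),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> generation ", x$generation, ", ", nrow(x$members),
      " members, best fitness ",
      format(suppressWarnings(max(x$members$fitness)), digits = 6), "\n",
      sep = "")
  invisible(x)
}

# --- selection --------------------------------------------------------------

#' Select parents from an evaluated population
#'
#' `fittest` takes the top n by fitness (ties by chromosome key);
#' `roulette` draws with probability proportional to fitness (with
#' replacement); `roulette_elitism` additionally always includes the current
#' best; `sus` is stochastic universal sampling (one spin, n equally spaced
#' pointers). When every fitness is zero, selection falls back to uniform
#' draws with a warning.
#'
#' @param population An evaluated `population`.
#' @param method Selection method name.
#' @param n Number of parents.
#' @param streams Optional RNG stream set; a fresh one is spawned from `seed`
#'   otherwise.
#' @param seed Seed used when `streams` is missing.
#' @return The selected member rows (data frame, n rows).
#' @export
select_parents <- function(population, method, n, streams = NULL, seed = 1L) {
  mem <- population$members
  stopifnot(!anyNA(mem$fitness))
  if (is.null(streams)) streams <- rng_streams(seed)
  fit <- mem$fitness
  pick_uniform <- function(k) sample.int(nrow(mem), k, replace = TRUE)
  idx <- with_stream(streams, "selection", {
    if (method == "fittest") {
      order(-fit, mem$key)[seq_len(n)]
    } else if (method %in% c("roulette", "roulette_elitism")) {
      draw <- function(k) {
        if (sum(fit) <= 0) {
          warning("all fitness values are zero; uniform selection fallback")
          pick_uniform(k)
        } else {
          sample.int(nrow(mem), k, replace = TRUE, prob = fit)
        }
      }
      if (method == "roulette_elitism") {
        best <- order(-fit, mem$key)[1]
        if (n == 1L) best else c(best, draw(n - 1L))
      } else {
        draw(n)
      }
    } else if (method == "sus") {
      if (sum(fit) <= 0) {
        warning("all fitness values are zero; uniform selection fallback")
        pick_uniform(n)
      } else {
        total <- sum(fit)
        pointers <- (stats::runif(1) + 0L:(n - 1L)) / n * total
        cum <- cumsum(fit)
        vapply(pointers, function(p) which(cum >= p - 1e-12)[1], integer(1))
      }
    } else {
      stop("unknown selection method: ", method)
    }
  })
  mem[idx, , drop = FALSE]
}

# --- variation operators ----------------------------------------------------

#' Single-gene crossover
#'
#' One gene position (tri block, di block or topology) is chosen uniformly
#' and exchanged between the parents, producing two offspring.
#'
#' @param p1,p2 Parent `cage_chromosome`s.
#' @param streams Optional RNG stream set.
#' @param seed Seed used when `streams` is missing.
#' @return List of two offspring chromosomes.
#' @export
crossover <- function(p1, p2, streams = NULL, seed = 1L) {
  if (is.null(streams)) streams <- rng_streams(seed)
  gene <- with_stream(streams, "crossover", {
    c("bb_tri", "bb_di", "topology")[sample.int(3L, 1L)]
  })
  o1 <- p1; o2 <- p2
  o1[[gene]] <- p2[[gene]]
  o2[[gene]] <- p1[[gene]]
  list(o1, o2)
}

#' Fresh similarity-mutation state
#'
#' Tracks, per (chromosome, gene), how many times the similarity mutation has
#' been applied, so repeated application steps through neighbor ranks
#' 1, 2, 3, ...
#'
#' @return An environment.
#' @export
mutation_state <- function() new.env(parent = emptyenv())

#' Mutate a chromosome
#'
#' Random mode replaces a uniformly chosen gene with a uniformly drawn
#' alternative from the database (or topology list). Similarity mode replaces
#' a building-block gene with its next-ranked Dice-similarity neighbor,
#' advancing a per-(chromosome, gene) counter; when the counter exhausts the
#' database it wraps around with a warning.
#'
#' @param ind A `cage_chromosome`.
#' @param db A `bb_database`.
#' @param mode `"random"` or `"similarity"`.
#' @param state A [mutation_state()] environment (similarity mode).
#' @param topologies Topology names available to the topology gene.
#' @param gene Optional fixed gene to mutate (otherwise drawn at random).
#' @param streams Optional RNG stream set.
#' @param seed Seed used when `streams` is missing.
#' @return The mutated chromosome.
#' @export
mutate <- function(ind, db, mode = c("random", "similarity"),
                   state = mutation_state(),
                   topologies = supported_topologies(), gene = NULL,
                   streams = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(streams)) streams <- rng_streams(seed)
  out <- ind
  if (mode == "random") {
    if (is.null(gene)) {
      gene <- with_stream(streams, "mutation", {
        c("bb_tri", "bb_di", "topology")[sample.int(3L, 1L)]
      })
    }
    cands <- if (gene == "topology") setdiff(topologies, ind$topology) else {
      role <- if (gene == "bb_tri") "trialdehyde" else "diamine"
      setdiff(db_ids(db, role), ind[[gene]])
    }
    if (!length(cands)) {
      # degenerate database: the only candidate is the current gene value
      cands <- ind[[gene]]
    }
    out[[gene]] <- with_stream(streams, "mutation", {
      cands[sample.int(length(cands), 1L)]
    })
  } else {
    if (is.null(gene)) {
      gene <- with_stream(streams, "mutation", {
        c("bb_tri", "bb_di")[sample.int(2L, 1L)]
      })
    }
    stopifnot(gene %in% c("bb_tri", "bb_di"))
    target <- db_get(db, ind[[gene]])
    ckey <- paste(chromosome_key(ind), gene, sep = "::")
    count <- if (is.null(state[[ckey]])) 0L else state[[ckey]]
    count <- count + 1L
    state[[ckey]] <- count
    avail <- length(db_ids(db, target$role)) -
      sum(db_ids(db, target$role) == target$id)
    if (avail < 1L) stop("no similarity-mutation candidates for ", target$id)
    n <- count
    if (n > avail) {
      warning("similarity counter exhausted the database; wrapping")
      n <- ((n - 1L) %% avail) + 1L
    }
    out[[gene]] <- similarity_rank(target, db, n)$id
  }
  out
}

# --- one generation ---------------------------------------------------------

# Internal per-run state bundle for schedules and caches.
run_state <- function() {
  env <- new.env(parent = emptyenv())
  env$mutation_counter <- 0L
  env$mstate <- mutation_state()
  env
}

#' Advance the population by one generation
#'
#' Performs the configured number of crossover and mutation operations on
#' parents picked by the selection method (one offspring enters the pool per
#' operation), evaluates novel offspring through the cache, merges offspring
#' with the current population and keeps the best `population_size` members.
#' At equal fitness incumbents are preferred over offspring, so replacement
#' only happens for strictly better offspring ("replace the worst").
#'
#' @param population An evaluated `population`.
#' @param config An `ea_config`.
#' @param evaluator An evaluator function.
#' @param db A `bb_database`.
#' @param topologies Topology names.
#' @param fitness_config Needed when the evaluator has no absolute fitness.
#' @param streams RNG stream set.
#' @param state A [run_state()] bundle (mutation schedule position).
#' @return The next `population`.
#' @export
ea_step <- function(population, config, evaluator, db,
                    topologies = supported_topologies(),
                    fitness_config = NULL, streams = NULL,
                    state = run_state()) {
  if (is.null(streams)) streams <- rng_streams(config$rng_seed)
  mem <- population$members
  offspring <- list()

  for (i in seq_len(config$n_crossover)) {
    par <- select_parents(population, config$selection_method, 2L,
                          streams = streams)
    kids <- crossover(cage_chromosome(par$tri[1], par$di[1], par$topology[1]),
                      cage_chromosome(par$tri[2], par$di[2], par$topology[2]),
                      streams = streams)
    pick <- with_stream(streams, "crossover", sample.int(2L, 1L))
    offspring[[length(offspring) + 1L]] <- kids[[pick]]
  }

  for (i in seq_len(config$n_mutation)) {
    par <- select_parents(population, config$selection_method, 1L,
                          streams = streams)
    chrom <- cage_chromosome(par$tri[1], par$di[1], par$topology[1])
    state$mutation_counter <- state$mutation_counter + 1L
    mode <- switch(config$mutation_schedule,
      alternate_random_similarity =
        if (state$mutation_counter %% 2L == 1L) "random" else "similarity",
      random_only = "random",
      similarity_only = "similarity")
    offspring[[length(offspring) + 1L]] <-
      mutate(chrom, db, mode = mode, state = state$mstate,
             topologies = topologies, streams = streams)
  }

  off_rows <- if (length(offspring)) {
    keys <- vapply(offspring, chromosome_key, character(1))
    ev <- evaluate_keys(keys, evaluator, population$cache)
    data.frame(key = keys,
               tri = vapply(offspring, `[[`, character(1), "bb_tri"),
               di = vapply(offspring, `[[`, character(1), "bb_di"),
               topology = vapply(offspring, `[[`, character(1), "topology"),
               fitness = NA_real_, pore = ev$pore, asymmetry = ev$asymmetry,
               stringsAsFactors = FALSE)
  } else NULL

  pool <- rbind(mem, off_rows)
  pool_rows <- evaluate_keys(pool$key, evaluator, population$cache)
  pool$fitness <- pool_fitness(pool_rows, fitness_config)
  pool$pore <- pool_rows$pore
  pool$asymmetry <- pool_rows$asymmetry

  ord <- order(-pool$fitness)   # stable: incumbents precede offspring on ties
  nxt <- pool[ord[seq_len(config$population_size)], , drop = FALSE]
  rownames(nxt) <- NULL
  structure(list(members = nxt, generation = population$generation + 1L,
                 cache = population$cache),
            class = "population")
}

# Evaluate a fresh (init) population in place.
evaluate_population_members <- function(population, evaluator,
                                        fitness_config = NULL) {
  rows <- evaluate_keys(population$members$key, evaluator, population$cache)
  population$members$fitness <- pool_fitness(rows, fitness_config)
  population$members$pore <- rows$pore
  population$members$asymmetry <- rows$asymmetry
  population
}

# --- progress analytics -----------------------------------------------------

#' Per-generation population statistics
#'
#' Best and average fitness, pore diameter and asymmetry (the "best" pore and
#' asymmetry are those of the highest-fitness individual), the population
#' fraction of each topology, and - when the database carries conformers -
#' the mean building-block descriptors per role.
#'
#' @param population An evaluated `population`.
#' @param db Optional `bb_database` for descriptor averages.
#' @param topologies Topology names to report fractions for.
#' @param descriptors Compute building-block descriptor means (slower).
#' @return A one-row data frame.
#' @export
progress_stats <- function(population, db = NULL,
                           topologies = supported_topologies(),
                           descriptors = FALSE) {
  mem <- population$members
  best_i <- order(-mem$fitness, mem$key)[1]
  row <- data.frame(
    generation = population$generation,
    best_fitness = mem$fitness[best_i],
    avg_fitness = mean(mem$fitness),
    best_pore = mem$pore[best_i],
    avg_pore = mean(mem$pore),
    best_asymmetry = mem$asymmetry[best_i],
    avg_asymmetry = mean(mem$asymmetry)
  )
  for (t in topologies) {
    row[[paste0("frac_", t)]] <- mean(mem$topology == t)
  }
  if (descriptors && !is.null(db)) {
    desc_mean <- function(ids) {
      ds <- lapply(unique(ids), function(i) .descriptor_cached(db, i))
      counts <- table(ids)[unique(ids)]
      w <- as.numeric(counts) / sum(counts)
      list(rot = sum(w * vapply(ds, `[[`, numeric(1), "pct_rotatable")),
           dbl = sum(w * vapply(ds, `[[`, numeric(1), "pct_double")),
           egd = sum(w * vapply(ds, `[[`, numeric(1), "end_group_distance")))
    }
    tri_d <- desc_mean(mem$tri); di_d <- desc_mean(mem$di)
    row$tri_pct_rotatable <- tri_d$rot
    row$tri_pct_double <- tri_d$dbl
    row$tri_end_group_distance <- tri_d$egd
    row$di_pct_rotatable <- di_d$rot
    row$di_pct_double <- di_d$dbl
    row$di_end_group_distance <- di_d$egd
  }
  row
}

.descriptor_cache <- new.env(parent = emptyenv())
.descriptor_cached <- function(db, id) {
  key <- paste(db$provenance, id, sep = "::")
  if (is.null(.descriptor_cache[[key]])) {
    .descriptor_cache[[key]] <- bb_descriptors(db_get(db, id))
  }
  .descriptor_cache[[key]]
}

# --- the full run -----------------------------------------------------------

#' Run the evolutionary algorithm
#'
#' Iterates [ea_step()] until the generation budget is spent, a designated
#' target chromosome has been evaluated, or the top-5 chromosome set has
#' stayed unchanged for `convergence_patience` consecutive generations.
#' Fully reproducible from `config$rng_seed`.
#'
#' @param db A `bb_database`.
#' @param config An `ea_config`.
#' @param evaluator An evaluator function (see [evaluator_landscape()],
#'   [evaluator_structure()]).
#' @param topologies Topology names the topology gene can take.
#' @param fitness_config Needed when the evaluator has no absolute fitness.
#' @param target Optional target chromosome key; the run stops as soon as it
#'   has been evaluated (entered the offspring pool or population).
#' @param descriptors Record building-block descriptor means per generation.
#' @return An `ea_run` record: `progress` (one row per generation),
#'   `final_population`, `convergence_generation` (`NA` if the budget ran
#'   out), `target_found`, `target_generation`, `n_evaluated`, `seed`.
#' @export
run_ea <- function(db, config, evaluator,
                   topologies = supported_topologies(),
                   fitness_config = NULL, target = NULL,
                   descriptors = FALSE) {
  streams <- rng_streams(config$rng_seed)
  state <- run_state()
  pop <- init_population(db, topologies, method = config$init_method,
                         n = config$population_size, streams = streams)
  pop <- evaluate_population_members(pop, evaluator, fitness_config)

  top5 <- function(p) {
    k <- p$members$key[order(-p$members$fitness, p$members$key)]
    sort(unique(k)[seq_len(min(5L, length(unique(k))))])
  }
  progress <- list(progress_stats(pop, db, topologies, descriptors))
  target_found <- !is.null(target) && !is.null(pop$cache[[target]])
  target_gen <- if (target_found) 0L else NA_integer_
  convergence_gen <- if (target_found) 0L else NA_integer_

  if (!target_found) {
    prev_top <- top5(pop)
    streak <- 0L
    gen <- 0L
    while (gen < config$max_generations) {
      pop <- ea_step(pop, config, evaluator, db, topologies,
                     fitness_config, streams, state)
      gen <- gen + 1L
      progress[[length(progress) + 1L]] <-
        progress_stats(pop, db, topologies, descriptors)
      if (!is.null(target) && !is.null(pop$cache[[target]])) {
        target_found <- TRUE
        target_gen <- gen
        convergence_gen <- gen
        break
      }
      cur_top <- top5(pop)
      if (identical(cur_top, prev_top)) streak <- streak + 1L else streak <- 0L
      prev_top <- cur_top
      if (is.finite(config$convergence_patience) &&
          streak >= config$convergence_patience) {
        convergence_gen <- gen
        break
      }
    }
  }

  structure(
    list(progress = do.call(rbind, progress),
         final_population = pop$members,
         convergence_generation = convergence_gen,
         target_found = target_found,
         target_generation = target_gen,
         n_evaluated = length(ls(pop$cache)),
         evaluated_keys = sort(ls(pop$cache)),
         seed = config$rng_seed,
         config = unclass(config)),
    class = "ea_run"
  )
}

#' @export
print.ea_run <- function(x, ...) {
  last <- x$progress[nrow(x$progress), ]
  cat("<ea_run> ", nrow(x$progress) - 1L, " generations, best fitness ",
      format(last$best_fitness, digits = 6),
      if (isTRUE(x$target_found)) {
        paste0(", target found at generation ", x$target_generation)
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Write run outputs (progress CSV, final population CSV, JSON record)
#'
#' @param run An `ea_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_record <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$progress, file.path(dir, "progress.csv"),
                   row.names = FALSE)
  utils::write.csv(run$final_population,
                   file.path(dir, "final_population.csv"), row.names = FALSE)
  jsonlite::write_json(
    run[c("convergence_generation", "target_found", "target_generation",
          "n_evaluated", "seed", "config")],
    file.path(dir, "run_record.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
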