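# Precomputed fitness landscapes and the rediscovery benchmarking protocol:
# run the EA many times against an in-memory chromosome -> properties lookup
# and estimate the probability of finding the known global optimum, compared
# with the analytic random-search baseline.

#' Construct a landscape object
#'
#' @param table Data frame with columns `key`, `fitness`, `dpore`, `dwindow`,
#'   `asym`, `pore`, `asymmetry` (one row per chromosome).
#' @param db The `bb_database` (real or synthetic) whose members the keys are
#'   built from.
#' @param topologies Topology names present in the keys.
#' @return A `landscape`; its `global_optimum` is the unique argmax of
#'   fitness (ties are a construction error).
#' @export
landscape <- function(table, db, topologies) {
  stopifnot(all(c("key", "fitness") %in% names(table)))
  if (anyDuplicated(table$key)) stop("duplicate chromosome keys in landscape")
  top <- which(table$fitness == max(table$fitness))
  if (length(top) != 1L) {
    stop("fitness tie at the landscape optimum; adjust the fitness ",
         "configuration so a unique global optimum exists")
  }
  structure(
    list(table = table, global_optimum = table$key[top], db = db,
         topologies = topologies,
         n_tri = length(db_ids(db, "trialdehyde")),
         n_di = length(db_ids(db, "diamine"))),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", nrow(x$table), " chromosomes (", x$n_tri, " tri x ",
      x$n_di, " di x ", length(x$topologies), " topologies), optimum ",
      x$global_optimum, "\n", sep = "")
  invisible(x)
}

#' Size of the combinatorial search space
#'
#' @param n_tri,n_di Numbers of tri- and di-topic building blocks.
#' @param n_topologies Number of allowed topologies.
#' @return `n_tri * n_di * n_topologies`.
#' @export
search_space_size <- function(n_tri, n_di, n_topologies = 1) {
  stopifnot(n_tri >= 0, n_di >= 0, n_topologies >= 1)
  n_tri * n_di * n_topologies
}

#' Exhaustively precompute a fitness landscape
#'
#' Evaluates every chromosome of the database x topology product once
#' through the given evaluator, then converts raw penalties to fitness
#' normalized against the full-space penalty means (so the precomputed
#' fitness is population independent).
#'
#' @param db A `bb_database`.
#' @param topologies Topology names.
#' @param fitness_config A `fitness_config`.
#' @param evaluator An evaluator function (defaults to the full structural
#'   pipeline over `db`).
#' @param max_size Enumeration guard (default 1e6 combinations).
#' @return A `landscape`.
#' @export
precompute_landscape <- function(db, topologies, fitness_config,
                                 evaluator = NULL, max_size = 1e6) {
  tri <- db_ids(db, "trialdehyde"); di <- db_ids(db, "diamine")
  n <- search_space_size(length(tri), length(di), length(topologies))
  if (n > max_size) {
    stop("search space of ", n, " combinations exceeds the enumeration guard")
  }
  if (is.null(evaluator)) evaluator <- evaluator_structure(db, fitness_config)
  grid <- expand.grid(tri = tri, di = di, topology = topologies,
                      stringsAsFactors = FALSE)
  keys <- paste(grid$tri, grid$di, grid$topology, sep = "|")
  rows <- evaluator(keys)
  if (is.null(rows$fitness) || anyNA(rows$fitness)) {
    rows$fitness <- evaluate_population(
      as.matrix(rows[, c("dpore", "dwindow", "asym")]), fitness_config)$fitness
  }
  landscape(rows, db, topologies)
}

#' Analytic random-search baseline
#'
#' Probability that uniform draws with replacement hit the global optimum at
#' least once: `1 - (1 - 1/space_size)^n_draws`.
#'
#' @param space_size Number of chromosomes in the space.
#' @param n_draws Number of uniform draws.
#' @return Probability in \[0, 1\].
#' @export
random_search_probability <- function(space_size, n_draws) {
  stopifnot(space_size >= 1, n_draws >= 0)
  1 - (1 - 1 / space_size)^n_draws
}

#' Simulated random-search baseline
#'
#' Monte-Carlo check of [random_search_probability()]: simulates runs of
#' `n_draws` uniform draws and reports the hit fraction.
#'
#' @param space_size,n_draws As in [random_search_probability()].
#' @param n_runs Number of simulated runs.
#' @param seed RNG seed.
#' @return List with `probability`, `se` (binomial standard error), `n_runs`.
#' @export
simulate_random_search <- function(space_size, n_draws, n_runs, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  hits <- vapply(seq_len(n_runs), function(i) {
    any(sample.int(space_size, n_draws, replace = TRUE) == 1L)
  }, logical(1))
  p <- mean(hits)
  list(probability = p, se = sqrt(p * (1 - p) / n_runs), n_runs = n_runs)
}

# Per-run seeds derived from the master seed by counter hashing (kept within
# the 32-bit integer range).
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483629)
}

#' Benchmark an EA setup on a precomputed landscape
#'
#' Runs the EA `n_runs` times with independently derived seeds, serving
#' fitness from the landscape lookup. A run succeeds when the global optimum
#' is obtained (evaluated into the run's pool) within the generation budget.
#'
#' @param landscape A `landscape`.
#' @param ea_config An `ea_config`; its `rng_seed` is overridden per run and
#'   its `convergence_patience` is disabled so only the optimum or the
#'   generation budget stops a run.
#' @param n_runs Number of independent runs (>= 1).
#' @param seed Master seed.
#' @param label Free-text setup label.
#' @return A `benchmark_result`: success counts and probability, mean
#'   generations to success, mean unique evaluations per run, the analytic
#'   random baseline at the same mean evaluation budget, and the seeds used.
#' @export
benchmark_setup <- function(landscape, ea_config, n_runs, seed = 1L,
                            label = "") {
  stopifnot(n_runs >= 1L)
  ev <- evaluator_landscape(landscape)
  seeds <- vapply(seq_len(n_runs), function(i) derive_seed(seed, i),
                  integer(1))
  success <- logical(n_runs)
  gens <- rep(NA_integer_, n_runs)
  n_eval <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- ea_config
    cfg$rng_seed <- seeds[i]
    cfg$convergence_patience <- Inf
    run <- run_ea(landscape$db, cfg, ev, topologies = landscape$topologies,
                  target = landscape$global_optimum)
    success[i] <- run$target_found
    gens[i] <- run$target_generation
    n_eval[i] <- run$n_evaluated
  }
  p <- mean(success)
  mean_evals <- mean(n_eval)
  structure(
    list(label = label, n_runs = n_runs, n_success = sum(success),
         success_probability = p,
         se = sqrt(p * (1 - p) / n_runs),
         mean_generations_to_success = mean(gens[success]),
         mean_evaluations = mean_evals,
         random_baseline = random_search_probability(nrow(landscape$table),
                                                     mean_evals),
         seeds = seeds),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", x$label, ": ", x$n_success, "/", x$n_runs,
      " runs found the optimum (p = ", format(x$success_probability,
                                              digits = 4),
      "), random baseline at the same budget ",
      format(x$random_baseline, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run a grid of benchmark setups
#'
#' @param landscape A `landscape`.
#' @param grid Data frame of `ea_config` field overrides (one setup per row,
#'   e.g. columns `selection_method`, `init_method`, `mutation_schedule`).
#' @param n_runs Runs per setup.
#' @param seed Master seed.
#' @return Data frame with one row of success statistics per setup.
#' @export
benchmark_grid <- function(landscape, grid, n_runs, seed = 1L) {
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- ea_config()
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][g]
    label <- paste(vapply(names(grid), function(nm)
      paste0(nm, "=", grid[[nm]][g]), character(1)), collapse = ",")
    res <- benchmark_setup(landscape, cfg, n_runs,
                           seed = derive_seed(seed, g), label = label)
    data.frame(label = label, n_runs = res$n_runs, n_success = res$n_success,
               success_probability = res$success_probability,
               mean_generations_to_success = res$mean_generations_to_success,
               mean_evaluations = res$mean_evaluations,
               random_baseline = res$random_baseline)
  })
  do.call(rbind, rows)
}

#' Write / read a landscape table
#'
#' Plain CSV (gzip-compressed when the path ends in `.gz`); the database
#' fingerprints are regenerated, not stored, so a read-back landscape serves
#' lookups but carries a synthetic stub database.
#'
#' @param landscape A `landscape`.
#' @param path Output path.
#' @export
write_landscape <- function(landscape, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  utils::write.csv(landscape$table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param db,topologies Passed to [landscape()] on read-back; when `db` is
#'   `NULL` a synthetic stub database with index-correlated fingerprints is
#'   rebuilt from the keys.
#' @export
read_landscape <- function(path, db = NULL, topologies = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.csv(con, stringsAsFactors = FALSE)
  parts <- strsplit(tab$key, "|", fixed = TRUE)
  tri <- sort(unique(vapply(parts, `[[`, character(1), 1)))
  di <- sort(unique(vapply(parts, `[[`, character(1), 2)))
  topo <- sort(unique(vapply(parts, `[[`, character(1), 3)))
  if (is.null(db)) db <- synthetic_stub_db(tri, di)
  if (is.null(topologies)) topologies <- topo
  landscape(tab, db, topologies)
}
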