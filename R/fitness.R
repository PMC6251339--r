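# Scalarized multi-objective fitness: penalties for deviation from ideal pore
# and window diameters plus the window asymmetry, combined as
# fitness = (a*dPore + b*dWindow + c*Asymmetry)^-1 after population-average
# normalization of each term.

#' Fitness configuration
#'
#' @param a,b,c Non-negative weights for the pore, window and asymmetry
#'   penalties (not all zero).
#' @param ideal_pore Target pore diameter (Angstrom).
#' @param ideal_window Target window diameter (Angstrom); may be `NA` when
#'   `b = 0` (the window term is then ignored).
#' @param epsilon Small positive floor inside the inverse, capping the
#'   maximum fitness at `1/epsilon` for an exact target match.
#' @return A `fitness_config`.
#' @export
fitness_config <- function(a, b, c, ideal_pore, ideal_window,
                           epsilon = 1e-9) {
  stopifnot(a >= 0, b >= 0, c >= 0, a + b + c > 0, epsilon > 0)
  stopifnot(is.na(ideal_pore) || ideal_pore > 0)
  if (b > 0 && is.na(ideal_window)) {
    stop("ideal_window required when b > 0")
  }
  structure(list(a = a, b = b, c = c, ideal_pore = ideal_pore,
                 ideal_window = ideal_window, epsilon = epsilon),
            class = "fitness_config")
}

#' Named fitness presets for the three published optimization targets
#'
#' `"cc3"`: rediscovery of the CC3 cage (a=10, b=10, c=1; ideal pore 5.72 A,
#' ideal window 3.91 A). `"persistency"`: shape-persistency screening (a=5,
#' b=1, c=10; ideal 5.0 A). `"big_pore"`: 16 A cavity target (a=10, b=0,
#' c=5).
#'
#' @param name Preset name.
#' @return A `fitness_config`.
#' @export
fitness_preset <- function(name = c("cc3", "persistency", "big_pore")) {
  name <- match.arg(name)
  switch(name,
    cc3 = fitness_config(10, 10, 1, ideal_pore = 5.72, ideal_window = 3.91),
    persistency = fitness_config(5, 1, 10, ideal_pore = 5.0,
                                 ideal_window = 5.0),
    big_pore = fitness_config(10, 0, 5, ideal_pore = 16.0,
                              ideal_window = NA_real_)
  )
}

#' Raw fitness penalties of a cage
#'
#' `dPore = |pore - ideal_pore|`, `dWindow = |mean(windows) - ideal_window|`
#' (0 when the window term is unweighted), and the asymmetry passed through
#' unchanged.
#'
#' @param props A `cage_properties` (or list with `pore_diameter`,
#'   `window_diameters`, `asymmetry`).
#' @param config A `fitness_config`.
#' @return Numeric triple `c(dpore, dwindow, asymmetry)`.
#' @export
raw_penalties <- function(props, config) {
  dpore <- abs(props$pore_diameter - config$ideal_pore)
  dwindow <- if (is.na(config$ideal_window)) 0 else
    abs(mean(props$window_diameters) - config$ideal_window)
  c(dpore = dpore, dwindow = dwindow, asymmetry = props$asymmetry)
}

#' Population-normalized fitness evaluation
#'
#' Each penalty column is divided by its population mean (over finite values;
#' columns with zero mean pass through unscaled), then combined as
#' `1 / (a*p + b*w + c*s + epsilon)`. Rows with any non-finite penalty
#' (failed assemblies or optimizations) receive fitness 0 so population
#' bookkeeping stays fixed-size.
#'
#' @param penalties A matrix (or data frame) with columns dpore, dwindow,
#'   asymmetry; one row per individual.
#' @param config A `fitness_config`.
#' @return Data frame with normalized penalties and `fitness`.
#' @export
evaluate_population <- function(penalties, config) {
  pen <- as.matrix(penalties)
  stopifnot(ncol(pen) == 3L, nrow(pen) >= 1L)
  failed <- !is.finite(rowSums(pen))
  norm <- pen
  for (j in 1:3) {
    mu <- mean(pen[!failed, j])
    if (is.finite(mu) && mu > 0) norm[, j] <- pen[, j] / mu
  }
  fit <- 1 / (config$a * norm[, 1] + config$b * norm[, 2] +
                config$c * norm[, 3] + config$epsilon)
  fit[failed] <- 0
  data.frame(dpore = pen[, 1], dwindow = pen[, 2], asym = pen[, 3],
             dpore_norm = norm[, 1], dwindow_norm = norm[, 2],
             asym_norm = norm[, 3], fitness = fit)
}
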