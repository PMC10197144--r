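#' Depth-coverage fitness specification
#'
#' The designer's cost counts the depths whose on-axis signal retains at
#' least `threshold` of the stack's global maximum `Imax`: depths inside the
#' target interval count in favor, depths outside are penalized with weight
#' `alpha`:
#' `cost = -(# on-depths in z_target) + alpha * (# on-depths outside)`.
#' Lower is better. The target interval is chosen from the scattering length,
#' which sets the practical one-photon imaging depth.
#'
#' @param z_target Length-2 numeric: the closed target depth interval (um).
#' @param threshold Fraction of `Imax` a depth must retain (default 0.5).
#' @param alpha Out-of-range penalty weight (default 4).
#' @return An object of class `edof_fitness_spec`.
#' @export
fitness_spec <- function(z_target, threshold = 0.5, alpha = 4) {
  if (length(z_target) != 2L || !is.numeric(z_target) ||
      z_target[2] <= z_target[1]) {
    abort("`z_target` must be an increasing length-2 numeric interval.")
  }
  stopifnot_scalar(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  stopifnot_scalar(alpha, "alpha")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  structure(list(z_target = as.numeric(z_target), threshold = threshold,
                 alpha = alpha),
            class = "edof_fitness_spec")
}

#' Genetic-algorithm configuration
#'
#' Queen-bee (elitist) GA hyperparameters. Defaults follow the published
#' design run: 10 generations of 60 candidates, top 20% elites copied
#' unchanged, tournament size 4, 10% per-trait mutation, crossover fraction
#' 0.4. Subpopulation sizes are `elite = round(elite_fraction * population)`,
#' `crossover = floor(crossover_fraction * (population - elite))`, and the
#' remainder are mutation children.
#'
#' @param generations Number of generations.
#' @param population Candidates per generation.
#' @param elite_fraction Fraction of the population copied unchanged.
#' @param tournament_size Candidates drawn per tournament (>= 2).
#' @param mutation_rate Per-trait probability of uniform-replacement mutation.
#' @param crossover_fraction Fraction of non-elite children produced by
#'   crossover (the rest are mutation children).
#' @param bounds Named list of closed intervals for `axicon`, `defocus_um`,
#'   `spherical_waves`. The defaults are wide enough to contain the published
#'   optimum and are a user choice, not a physical constant.
#' @param seed Integer seed making the run reproducible, or `NULL`.
#' @return An object of class `edof_ga_config`.
#' @export
ga_config <- function(generations = 10L, population = 60L,
                      elite_fraction = 0.20, tournament_size = 4L,
                      mutation_rate = 0.10, crossover_fraction = 0.4,
                      bounds = list(axicon = c(0, 5),
                                    defocus_um = c(-300, 300),
                                    spherical_waves = c(-60, 60)),
                      seed = NULL) {
  generations <- as.integer(generations)
  population <- as.integer(population)
  tournament_size <- as.integer(tournament_size)
  if (generations < 1L) abort("`generations` must be >= 1.")
  if (population < 2L) abort("`population` must be >= 2.")
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    abort("`elite_fraction` must be in (0, 1).")
  }
  n_elite <- round(elite_fraction * population)
  if (n_elite >= population) abort("elite count must be < population.")
  if (tournament_size < 2L) abort("`tournament_size` must be >= 2.")
  if (tournament_size > population) abort("tournament larger than population.")
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("`mutation_rate` must be in [0, 1].")
  }
  if (crossover_fraction < 0 || crossover_fraction > 1) {
    abort("`crossover_fraction` must be in [0, 1].")
  }
  need <- c("axicon", "defocus_um", "spherical_waves")
  if (!all(need %in% names(bounds))) {
    abort("`bounds` must name axicon, defocus_um and spherical_waves.")
  }
  for (nm in need) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[2] <= b[1]) {
      abort(sprintf("bounds$%s must be a non-degenerate interval.", nm))
    }
  }
  structure(
    list(generations = generations, population = population,
         elite_fraction = elite_fraction, tournament_size = tournament_size,
         mutation_rate = mutation_rate, crossover_fraction = crossover_fraction,
         bounds = bounds[need], seed = seed),
    class = "edof_ga_config"
  )
}

#' Fitness of an intensity stack
#'
#' Scores a simulated stack against a [fitness_spec()]. In the default
#' `"depth"` mode a depth is "on" when its on-axis (per-slice maximum)
#' profile retains at least `threshold * Imax`, `Imax` being the stack's
#' global maximum. The `"voxel"` mode instead counts above-threshold voxels
#' slice by slice (requires the full intensity cube).
#'
#' @param stack An [simulate_stack()] result (or [as_stack()]).
#' @param spec A [fitness_spec()].
#' @param mode `"depth"` (default) or `"voxel"`.
#' @return The scalar cost (lower is better).
#' @export
fitness <- function(stack, spec, mode = c("depth", "voxel")) {
  stopifnot(inherits(stack, "edof_stack"), inherits(spec, "edof_fitness_spec"))
  mode <- match.arg(mode)
  if (max(stack$profile) <= 0) {
    abort("All-zero stack: Imax is undefined.")
  }
  z <- stack$z_um
  if (spec$z_target[1] < min(z) || spec$z_target[2] > max(z)) {
    abort("`z_target` must lie within the simulated depth range.")
  }
  inside <- z >= spec$z_target[1] & z <= spec$z_target[2]
  if (mode == "depth") {
    profile_cost(stack$profile, inside, spec)
  } else {
    if (is.null(stack$data)) abort("voxel mode needs the full stack (keep_stack = TRUE).")
    on_count <- apply(stack$data >= spec$threshold * max(stack$data), 3, sum)
    -sum(on_count[inside]) + spec$alpha * sum(on_count[!inside])
  }
}

# Depth-mode cost from a bare profile; the GA hot path.
profile_cost <- function(profile, inside, spec) {
  on <- profile >= spec$threshold * max(profile)
  -sum(on & inside) + spec$alpha * sum(on & !inside)
}

#' Evaluate one candidate end to end
#'
#' Compose the continuous phase, wrap and binarize it, form the +/-1 pupil
#' transmission, run the forward model over the design depth window and score
#' the result. A pure function of its inputs.
#'
#' Candidates are scored in `"depth"` mode by default: a depth counts when
#' its on-axis (per-slice maximum) profile retains the threshold fraction of
#' the stack maximum. The `"voxel"` alternative sums binarized voxels over
#' (x, y, z) instead (see the methods vignette for the trade-offs).
#'
#' @param coeffs A [basis_coefficients()] (or numeric length-3 vector in the
#'   order axicon, defocus_um, spherical_waves).
#' @param spec A [fitness_spec()].
#' @param grid An [pupil_grid()].
#' @param aberration An [aberration_model()] (or `NULL`).
#' @param source An [make_source()].
#' @param depths_um Simulated depth planes (um).
#' @param ls_um Scattering length (um, `Inf` for none).
#' @param coherent Model reading passed to the forward model (default
#'   incoherent; see [simulate_stack()]).
#' @param mode Fitness mode: `"depth"` (default) or `"voxel"`.
#' @return The scalar cost.
#' @export
evaluate_candidate <- function(coeffs, spec, grid, aberration, source,
                               depths_um, ls_um, coherent = FALSE,
                               mode = c("depth", "voxel")) {
  mode <- match.arg(mode)
  if (is.numeric(coeffs) && length(coeffs) == 3L) {
    coeffs <- basis_coefficients(coeffs[1], coeffs[2], coeffs[3])
  }
  stopifnot(inherits(coeffs, "edof_coeffs"))
  mask <- binarize_phase(compose_phase(coeffs, grid), coeffs)
  io <- incoherent_inputs(source, mask, aberration, grid, coherent)
  inside <- depths_um >= spec$z_target[1] & depths_um <= spec$z_target[2]
  if (mode == "voxel") {
    counts <- cpp_voxel_counts(io$P, defocus_rate(grid),
                               as.numeric(depths_um), ls_um, io$OTF,
                               spec$threshold)
    if (sum(counts) <= 0) abort("All-zero stack: Imax is undefined.")
    return(-sum(counts[inside]) + spec$alpha * sum(counts[!inside]))
  }
  profile <- cpp_profile(io$P, defocus_rate(grid), as.numeric(depths_um),
                         ls_um, io$OTF)
  if (max(profile) <= 0) abort("All-zero stack: Imax is undefined.")
  profile_cost(profile, inside, spec)
}

# Tournament selection: draw `size` distinct indices, return the two with
# the lowest cost (ties broken by earlier index).
tournament_pick <- function(costs, size) {
  idx <- sample.int(length(costs), size)
  idx[order(costs[idx], idx)][1:2]
}

#' Produce the next GA generation
#'
#' Builds the three subpopulations: elite children (verbatim copies of the
#' best candidates), crossover children (per-trait uniform mix of the two
#' winners of a tournament), and mutation children (a crossover-style child
#' whose traits then each mutate with probability `mutation_rate` to a
#' uniform draw from the bounds).
#'
#' @param population Numeric matrix, one row per candidate, columns
#'   `axicon`, `defocus_um`, `spherical_waves`.
#' @param costs Numeric vector of candidate costs, aligned with rows.
#' @param ga An [ga_config()].
#' @return A matrix of the same shape: the next population. Row order is
#'   elites first (best first), then crossover, then mutation children; the
#'   `subpop` attribute records the three counts.
#' @export
next_generation <- function(population, costs, ga) {
  stopifnot(inherits(ga, "edof_ga_config"))
  m <- nrow(population)
  if (m != ga$population || length(costs) != m) {
    abort("population/costs must match ga$population.")
  }
  n_elite <- round(ga$elite_fraction * m)
  n_cross <- floor(ga$crossover_fraction * (m - n_elite))
  n_mut <- m - n_elite - n_cross
  rank <- order(costs, seq_len(m)) # deterministic tie-break: earlier index
  nxt <- matrix(NA_real_, m, 3, dimnames = list(NULL, colnames(population)))
  nxt[seq_len(n_elite), ] <- population[rank[seq_len(n_elite)], , drop = FALSE]
  lower <- vapply(ga$bounds, `[`, numeric(1), 1L)
  upper <- vapply(ga$bounds, `[`, numeric(1), 2L)
  make_child <- function() {
    parents <- tournament_pick(costs, ga$tournament_size)
    pick <- runif(3) < 0.5
    ifelse(pick, population[parents[1], ], population[parents[2], ])
  }
  for (i in seq_len(n_cross)) nxt[n_elite + i, ] <- make_child()
  for (i in seq_len(n_mut)) {
    child <- make_child()
    mut <- runif(3) < ga$mutation_rate
    if (any(mut)) {
      child[mut] <- lower[mut] + runif(sum(mut)) * (upper[mut] - lower[mut])
    }
    nxt[n_elite + n_cross + i, ] <- child
  }
  structure(nxt, subpop = c(elite = n_elite, crossover = n_cross,
                            mutation = n_mut))
}

#' Run the queen-bee genetic algorithm
#'
#' Initializes a uniform population over the bounds, evaluates every
#' candidate through the forward model, and iterates [next_generation()].
#' Elitism guarantees the best cost is monotone non-increasing. Previously
#' evaluated coefficient triples are cached, so elites are not re-simulated.
#'
#' @inheritParams evaluate_candidate
#' @param ga An [ga_config()]; its `seed` (when non-`NULL`) makes the run
#'   fully reproducible without touching the caller's RNG state.
#' @param mode Fitness mode handed to [evaluate_candidate()].
#' @param verbose Print per-generation progress.
#' @return An object of class `edof_ga`: list with `best_coefficients`
#'   ([basis_coefficients()]), `best_cost`, `history` (tibble: generation,
#'   best_cost, mean_cost), `population`, `costs`, `evaluations`, `seed`.
#' @export
run_ga <- function(ga, spec, grid, aberration, source, depths_um, ls_um,
                   mode = c("depth", "voxel"), verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ga, "edof_ga_config"), inherits(spec, "edof_fitness_spec"))
  if (spec$z_target[1] < min(depths_um) || spec$z_target[2] > max(depths_um)) {
    abort("`z_target` must lie within `depths_um`.")
  }
  run <- function() {
    lower <- vapply(ga$bounds, `[`, numeric(1), 1L)
    upper <- vapply(ga$bounds, `[`, numeric(1), 2L)
    m <- ga$population
    pop <- matrix(runif(3 * m), m, 3, byrow = TRUE)
    pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
    colnames(pop) <- names(ga$bounds)
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    eval_pop <- function(p) {
      vapply(seq_len(nrow(p)), function(i) {
        key <- paste(format(p[i, ], digits = 17), collapse = "|")
        if (!is.null(cache[[key]])) return(cache[[key]])
        n_eval <<- n_eval + 1L
        v <- evaluate_candidate(p[i, ], spec, grid, aberration, source,
                                depths_um, ls_um, mode = mode)
        cache[[key]] <- v
        v
      }, numeric(1))
    }
    hist <- vector("list", ga$generations)
    costs <- eval_pop(pop)
    for (g in seq_len(ga$generations)) {
      if (g > 1L) {
        pop <- next_generation(pop, costs, ga)
        costs <- eval_pop(pop)
      }
      hist[[g]] <- tibble(generation = g, best_cost = min(costs),
                          mean_cost = mean(costs))
      if (verbose) {
        message(sprintf("generation %d: best %g, mean %g",
                        g, min(costs), mean(costs)))
      }
    }
    best <- order(costs, seq_along(costs))[1]
    structure(
      list(
        best_coefficients = basis_coefficients(pop[best, 1], pop[best, 2],
                                               pop[best, 3]),
        best_cost = costs[best],
        history = dplyr::bind_rows(hist),
        population = pop,
        costs = costs,
        evaluations = n_eval,
        seed = ga$seed
      ),
      class = "edof_ga"
    )
  }
  if (is.null(ga$seed)) run() else withr::with_seed(ga$seed, run())
}

#' @export
print.edof_ga <- function(x, ...) {
  cat(sprintf("<edof_ga> best cost %g after %d generations (%d evaluations)\n",
              x$best_cost, nrow(x$history), x$evaluations))
  print(x$best_coefficients)
  invisible(x)
}

#' Tidy a GA run
#'
#' `tidy()` returns the per-generation fitness history; `glance()` a one-row
#' summary with the best coefficients and cost.
#'
#' @param x An `edof_ga`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.edof_ga <- function(x, ...) x$history

#' @rdname tidy.edof_ga
#' @export
glance.edof_ga <- function(x, ...) {
  b <- x$best_coefficients
  tibble(
    best_cost = x$best_cost,
    axicon = b$axicon,
    defocus_um = b$defocus_um,
    spherical_waves = b$spherical_waves,
    generations = nrow(x$history),
    evaluations = x$evaluations,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Plot GA convergence
#'
#' Best and mean cost per generation.
#'
#' @param object An `edof_ga`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edof_ga <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("best_cost", "mean_cost"),
                           names_to = "series", values_to = "cost")
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$cost,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation", y = "cost (lower is better)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
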