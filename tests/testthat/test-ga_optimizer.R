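test_that("depth-coverage cost matches explicit enumeration", {
  z <- 0:19
  spec <- fitness_spec(c(5, 14))
  mk <- function(profile) {
    as_stack(array(rep(profile, each = 4), c(2, 2, length(profile))), z)
  }
  # exactly on over the target and nowhere else
  p1 <- ifelse(z >= 5 & z <= 14, 1, 0.1)
  expect_equal(fitness(mk(p1), spec), -10)
  # on everywhere: -|target| + alpha * |outside|
  expect_equal(fitness(mk(rep(1, 20)), spec), -10 + 4 * 10)
  # enumeration oracle on arbitrary profiles
  set.seed(42)
  for (rep in 1:5) {
    prof <- runif(20)
    inside <- z >= 5 & z <= 14
    on <- prof >= 0.5 * max(prof)
    oracle <- -sum(on & inside) + 4 * sum(on & !inside)
    expect_equal(fitness(mk(prof), spec), oracle)
  }
  # a narrow focus loses to an elongated one spanning the target
  narrow <- exp(-(z - 9)^2 / 2)
  long <- exp(-(z - 9.5)^2 / (2 * 16))
  expect_lt(fitness(mk(long), spec), fitness(mk(narrow), spec))
  expect_error(fitness(mk(rep(0, 20)), spec), "All-zero")
  expect_error(fitness(mk(p1), fitness_spec(c(5, 30))), "within")
})

test_that("voxel-mode fitness counts above-threshold voxels", {
  z <- 0:4
  a <- array(0, c(3, 3, 5))
  a[1, 1, ] <- c(1, 0.8, 0.2, 0.9, 0.1)
  a[2, 2, ] <- c(0.6, 0.1, 0.1, 0.1, 0.55)
  st <- as_stack(a, z)
  spec <- fitness_spec(c(0, 1), alpha = 2)
  on <- a >= 0.5
  oracle <- -sum(on[, , 1:2]) + 2 * sum(on[, , 3:5])
  expect_equal(fitness(st, spec, mode = "voxel"), oracle)
})

test_that("candidate evaluation is pure and rewards on-target masks", {
  setup <- design_setup(optical_config(grid_size = 256L, n_depths = 25L,
                                       depth_step_um = 4))
  # a defocus + spherical-aberration mask steering an extended focus onto
  # the target window
  co <- basis_coefficients(0, 120, 25)
  c1 <- evaluate_candidate(co, setup$spec, setup$grid, setup$aberration,
                           setup$source, setup$depths_um, setup$ls_um)
  c2 <- evaluate_candidate(co, setup$spec, setup$grid, setup$aberration,
                           setup$source, setup$depths_um, setup$ls_um)
  expect_identical(c1, c2)
  open_cost <- evaluate_candidate(basis_coefficients(), setup$spec,
                                  setup$grid, setup$aberration, setup$source,
                                  setup$depths_um, setup$ls_um)
  expect_lt(c1, open_cost)
  # both fitness modes agree with the full-stack scoring path (the voxel
  # hot path runs in single precision: a few threshold-edge voxels may flip)
  mask0 <- binarize_phase(compose_phase(basis_coefficients(), setup$grid))
  st <- simulate_stack(setup$source, mask0, setup$aberration,
                       setup$depths_um, setup$ls_um, setup$grid,
                       keep_stack = TRUE)
  expect_equal(open_cost, fitness(st, setup$spec))
  open_vox <- evaluate_candidate(basis_coefficients(), setup$spec,
                                 setup$grid, setup$aberration,
                                 setup$source, setup$depths_um,
                                 setup$ls_um, mode = "voxel")
  vox_ref <- fitness(st, setup$spec, mode = "voxel")
  expect_lt(abs(open_vox - vox_ref), 1 + 0.01 * abs(vox_ref))
})

test_that("generation transition honors subpopulation counts and elitism", {
  ga <- ga_config(population = 60L, seed = 1)
  set.seed(7)
  pop <- cbind(runif(60, 0, 5), runif(60, -300, 300), runif(60, -60, 60))
  colnames(pop) <- c("axicon", "defocus_um", "spherical_waves")
  costs <- rnorm(60)
  nxt <- next_generation(pop, costs, ga)
  expect_identical(attr(nxt, "subpop"),
                   c(elite = 12, crossover = 19, mutation = 29))
  # elite children are verbatim copies of the best candidates
  best <- order(costs)[1:12]
  expect_equal(nxt[1:12, ], pop[best, ], ignore_attr = TRUE)
  # with no mutation and full crossover, every trait value already existed
  ga2 <- ga_config(population = 20L, mutation_rate = 0,
                   crossover_fraction = 1)
  pop2 <- pop[1:20, ]
  nxt2 <- next_generation(pop2, costs[1:20], ga2)
  for (j in 1:3) expect_true(all(nxt2[, j] %in% pop2[, j]))
  # all candidates stay inside the bounds under heavy mutation
  ga3 <- ga_config(population = 20L, mutation_rate = 1,
                   crossover_fraction = 0)
  nxt3 <- next_generation(pop2, costs[1:20], ga3)
  expect_true(all(nxt3[, 1] >= 0 & nxt3[, 1] <= 5))
  expect_true(all(nxt3[, 2] >= -300 & nxt3[, 2] <= 300))
  expect_true(all(nxt3[, 3] >= -60 & nxt3[, 3] <= 60))
})

test_that("alpha monotonicity: more out-of-range coverage never gets cheaper", {
  z <- 0:19
  prof <- ifelse(z <= 16, 1, 0.1) # covers the target and 7 outside depths
  st <- as_stack(array(rep(prof, each = 4), c(2, 2, 20)), z)
  costs <- vapply(c(0, 1, 2, 4, 8), function(a) {
    fitness(st, fitness_spec(c(5, 14), alpha = a))
  }, numeric(1))
  expect_true(all(diff(costs) >= 0))
})

test_that("the GA is elitist, reproducible and bound-closed", {
  setup <- tiny_setup(n = 64L, n_depths = 20L, depth_step = 5)
  ga <- ga_config(generations = 3L, population = 8L, seed = 11L,
                  bounds = list(axicon = c(0, 2), defocus_um = c(-200, 200),
                                spherical_waves = c(-40, 40)))
  res <- run_ga(ga, setup$spec, setup$grid, setup$aberration, setup$source,
                setup$depths_um, setup$ls_um)
  expect_s3_class(res, "edof_ga")
  expect_true(all(diff(res$history$best_cost) <= 0))
  res2 <- run_ga(ga, setup$spec, setup$grid, setup$aberration, setup$source,
                 setup$depths_um, setup$ls_um)
  expect_identical(glance(res), glance(res2))
  expect_true(all(res$population[, 1] >= 0 & res$population[, 1] <= 2))
  expect_true(all(res$population[, 2] >= -200 & res$population[, 2] <= 200))
  expect_true(all(res$population[, 3] >= -40 & res$population[, 3] <= 40))
  expect_lte(res$evaluations, 3L * 8L)
  # single generation returns the best of the random initial population
  ga1 <- ga_config(generations = 1L, population = 6L, seed = 5L)
  r1 <- run_ga(ga1, setup$spec, setup$grid, setup$aberration, setup$source,
               setup$depths_um, setup$ls_um)
  expect_identical(nrow(r1$history), 1L)
  expect_equal(r1$best_cost, min(r1$costs))
  # tidy/glance interfaces
  expect_named(tidy(res), c("generation", "best_cost", "mean_cost"))
  expect_identical(nrow(glance(res)), 1L)
})

test_that("the GA recovers a defocus-dominated optimum on a defocus-only problem", {
  cfg <- optical_config(grid_size = 64L, n_depths = 21L, depth_step_um = 2)
  grid <- pupil_grid(cfg)
  src <- make_source(0, grid)
  depths <- seq(-20, 20, 2)
  spec <- fitness_spec(c(-14, -2), alpha = 0.5)
  ga <- ga_config(generations = 4L, population = 10L, seed = 3L,
                  bounds = list(axicon = c(0, 1e-9),
                                defocus_um = c(-30, 30),
                                spherical_waves = c(-1e-9, 1e-9)))
  res <- run_ga(ga, spec, grid, NULL, src, depths, Inf)
  best <- res$best_coefficients
  # the target interval centered at -8 um is reachable by defocus alone;
  # either sign solves it (the binary mask is sign degenerate)
  expect_gt(abs(best$defocus_um), 2)
  expect_lt(abs(best$defocus_um), 16)
  open_cost <- evaluate_candidate(basis_coefficients(), spec, grid, NULL,
                                  src, depths, Inf)
  expect_lt(res$best_cost, open_cost)
})
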