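# Cheap deterministic fitness surface: fraction of a fixed target subset
# recovered by the decoded genes.
target_fitness <- function(target) {
  function(genes) length(intersect(genes, target)) / length(target)
}

test_that("population initialization is uniform on [0,1]^d and reproducible", {
  set.seed(7)
  p1 <- init_population(10, 5)
  set.seed(7)
  p2 <- init_population(10, 5)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(10L, 5L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(init_population(3, 5), ">= 4")
  expect_error(init_population(10, 0), ">= 1")
})

test_that("the heated neutron averages two distinct peers other than i", {
  pop_eq <- matrix(0.4, 4, 3)
  expect_equal(heated_neutron(pop_eq, 1), rep(0.4, 3))

  pop01 <- rbind(rep(0.7, 2), rep(0, 2), rep(1, 2))
  # with n = 3 and i = 1 the only admissible pair is rows 2 and 3
  for (r in 1:200) expect_equal(heated_neutron(pop01, 1), c(0.5, 0.5))
  expect_error(heated_neutron(matrix(0, 2, 2), 1), ">= 3")
})

test_that("fission respects bounds, degenerates at g = 1, and rejects g < 1", {
  cfg <- nro_config(population_size = 6)
  zero_pop <- matrix(0, 6, 4)
  # all-zero population and best: every term vanishes regardless of branch
  expect_equal(fission_step(zero_pop, rep(0, 4), g = 1, cfg), zero_pop)
  expect_equal(fission_step(zero_pop, rep(0, 4), g = 7, cfg), zero_pop)

  set.seed(1)
  pop <- init_population(8, 5)
  for (g in c(1, 2, 10)) {
    cand <- fission_step(pop, pop[1, ], g, nro_config(population_size = 8))
    expect_true(all(cand >= 0 & cand <= 1))
  }
  expect_error(fission_step(pop, pop[1, ], 0, cfg), ">= 1")
})

test_that("ionization worked example and branch selection behave as specified", {
  # dissimilar branch: X_r1 + rand * (X_r2 - X_i) with rand = 0.3
  expect_equal(fnro:::ion_update(0.5, 0.9, 0.1, 0.3), 0.74)
  # minus branch for rand > 0.5
  expect_equal(fnro:::ion_update(0.5, 0.9, 0.1, 0.6), 0.5 - 0.6 * 0.8)

  cfg <- nro_config(population_size = 5)
  same <- matrix(0.3, 5, 4)
  # identical population, i == best: Levy term multiplies a zero difference
  expect_equal(ionization_step(same, rep(0.3, 4), cfg), same)
  expect_error(ionization_step(matrix(0, 2, 2), rep(0, 2), cfg), ">= 3")

  # with tol -> Inf every dimension takes the Levy branch (here: identity)
  cfg_inf <- nro_config(population_size = 5, similarity_tol = 1e6)
  set.seed(2)
  pop <- init_population(5, 3)
  out <- ionization_step(pop, pop[2, ], cfg_inf)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("fusion worked example and degenerate cases behave as specified", {
  expect_equal(fnro:::fusion_update(0.2, 0.6, 0.4, 0.3, 0.5, 0.5), 0.4)
  # r1 = r2 = best: both difference terms vanish
  expect_equal(fnro:::fusion_update(0.2, 0.3, 0.3, 0.3, 0.8, 0.1), 0.2)

  cfg <- nro_config(population_size = 5)
  same <- matrix(0.6, 5, 4)
  expect_equal(fusion_step(same, rep(0.6, 4), cfg), same)

  set.seed(3)
  pop <- init_population(6, 4)
  out <- fusion_step(pop, pop[1, ], nro_config(population_size = 6))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("Levy steps follow Mantegna's construction with heavy tails", {
  expect_equal(mantegna_sigma(1.5),
    (gamma(2.5) * sin(0.75 * pi) / (gamma(1.25) * 1.5 * 2^0.25))^(2 / 3),
    tolerance = 1e-12
  )
  set.seed(5)
  s1 <- levy_step(1.5, 100)
  set.seed(5)
  s2 <- levy_step(1.5, 100)
  expect_identical(s1, s2)

  set.seed(6)
  big <- levy_step(1.5, 1e5)
  tail_frac <- mean(abs(big) > 10 * median(abs(big)))
  expect_gt(tail_frac, 0.001)
  gauss <- rnorm(1e5, sd = sd(big[abs(big) < quantile(abs(big), 0.99)]))
  expect_gt(tail_frac, mean(abs(gauss) > 10 * median(abs(gauss))))
  expect_error(levy_step(2.5, 10), "\\(0, 2]")
})

test_that("top-k decoding returns exactly k indices with index tie-breaks", {
  expect_equal(decode_top_k(c(0.9, 0.1, 0.8, 0.2), 2), c(1L, 3L))
  expect_equal(decode_top_k(c(0.5, 0.5, 0.1), 1), 1L)
  expect_equal(decode_top_k(c(0.2, 0.4), 2), 1:2)
  expect_error(decode_top_k(c(0.2, 0.4), 3), "exceeds")
})

test_that("a constant fitness stops the search after exactly `patience` generations", {
  cfg <- nro_config(
    population_size = 6, max_generations = 20, patience = 5, seed = 1
  )
  res <- run_nro(function(genes) 0.5, d = 8, k = 3, config = cfg)
  expect_equal(res$generations_run, 5L)
  expect_true(res$stopped_early)
  expect_equal(res$best_fitness, 0.5)
})

test_that("runs are reproducible and traces are monotone within budget", {
  cfg <- nro_config(population_size = 8, max_generations = 10, patience = 4, seed = 42)
  fit <- target_fitness(c(1, 4, 6))
  r1 <- run_nro(fit, d = 10, k = 3, config = cfg)
  r2 <- run_nro(fit, d = 10, k = 3, config = cfg)
  expect_identical(r1$best_genes, r2$best_genes)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$evaluations, r2$evaluations)
  expect_true(all(diff(r1$trace$best_fitness) >= 0))
  expect_lte(r1$evaluations, 8 * (1 + 3 * r1$generations_run))
  # the reported fitness is the trace maximum and belongs to the reported subset
  expect_equal(r1$best_fitness, max(r1$trace$best_fitness))
  expect_equal(fit(r1$best_genes), r1$best_fitness)
  expect_error(run_nro(fit, d = 3, k = 5, config = cfg), "exceeds")
})

test_that("non-finite fitness values abort the run", {
  cfg <- nro_config(population_size = 4, max_generations = 2, seed = 1)
  expect_error(
    run_nro(function(genes) NaN, d = 5, k = 2, config = cfg),
    "non-finite"
  )
})

test_that("nro_config validates its invariants", {
  expect_error(nro_config(population_size = 3), ">= 4")
  expect_error(nro_config(p_beta = 1.5), "p_beta")
  expect_error(nro_config(levy_exponent = 0), "levy_exponent")
  expect_error(nro_config(similarity_tol = 0), "similarity_tol")
})
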