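# A small, quickly separable dataset reused across orchestration tests.
easy_data <- function(seed = 21) {
  preprocess_expression(simulate_expression(
    n_samples = 24, n_genes = 30, n_informative = 3,
    effect_size = 5, seed = seed
  ))
}

test_that("the 95% CI follows mean +/- 1.96 s/sqrt(n) with degenerate cases", {
  ci <- aggregate_ci(c(rep(0.90, 15), rep(1.00, 15)))
  expect_equal(ci$mean, 0.95)
  expect_equal(ci$ci_low, 0.9318, tolerance = 1e-4)
  expect_equal(ci$ci_high, 0.9682, tolerance = 1e-4)

  flat <- aggregate_ci(rep(0.95, 30))
  expect_equal(flat$ci_low, 0.95)
  expect_equal(flat$ci_high, 0.95)

  single <- aggregate_ci(0.8)
  expect_equal(unlist(single[c("mean", "ci_low", "ci_high")]),
    c(mean = 0.8, ci_low = 0.8, ci_high = 0.8)
  )
  expect_error(aggregate_ci(numeric(0)), "empty")

  tci <- aggregate_ci(c(0.9, 1.0, 0.95), method = "t")
  expect_lt(tci$ci_low, min(0.95, tci$mean)) # t interval is wider than normal
})

test_that("CI width shrinks like 1/sqrt(repeats)", {
  set.seed(14)
  draws <- rnorm(80, 0.9, 0.05)
  w <- sapply(c(5, 20, 80), function(n) {
    ci <- aggregate_ci(draws[seq_len(n)])
    ci$ci_high - ci$ci_low
  })
  # widths should drop roughly 2x per 4x sample size; allow slack for the
  # sd estimate itself moving
  expect_lt(w[2], w[1])
  expect_lt(w[3], w[2] / 1.3)
})

test_that("evaluate_filters returns a full grid and breaks ties by size then method order", {
  d <- easy_data()
  ev <- evaluate_filters(d,
    methods = c("fscore", "infogain"),
    filter_sizes = c(5, 10), n_neighbors = 3,
    fitness_cfg = fitness_config()
  )
  expect_equal(nrow(ev$grid), 4L)
  expect_true(all(ev$grid$accuracy >= 0 & ev$grid$accuracy <= 1))
  # effect size 5 makes every pool perfect -> total tie -> smallest size,
  # earliest method in the fixed order
  expect_equal(ev$best_accuracy, 1)
  expect_equal(ev$best_size, 5L)
  expect_equal(ev$best_method, "fscore")
  expect_error(
    evaluate_filters(d, filter_sizes = 500),
    "exceeds the gene count"
  )

  single <- evaluate_filters(d, methods = "fscore", filter_sizes = 10)
  expect_equal(nrow(single$grid), 1L)
  expect_equal(single$best_method, "fscore")
  expect_equal(single$best_size, 10L)
})

test_that("a one-repeat sweep collapses best/average/worst and its CI", {
  d <- easy_data()
  pool <- top_k(gene_scores(d, "fscore"), 10)
  sw <- run_fnro_sweep(d, pool,
    sweep = sweep_config(subset_sizes = 3, repeats = 1, base_seed = 5),
    nro_cfg = nro_config(population_size = 6, max_generations = 3, patience = 2)
  )
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$best_accuracy, sw$average_accuracy)
  expect_equal(sw$best_accuracy, sw$worst_accuracy)
  expect_equal(sw$ci_low, sw$ci_high)
  expect_equal(lengths(sw$best_genes), 3L)
  expect_equal(sw$seeds[[1]], 5L)
})

test_that("sweeps are deterministic, ordered, and stop at the first perfect size", {
  d <- easy_data()
  pool <- top_k(gene_scores(d, "fscore"), 10)
  sweep <- sweep_config(subset_sizes = 2:6, repeats = 2, base_seed = 3)
  cfg <- nro_config(population_size = 6, max_generations = 4, patience = 2)
  s1 <- run_fnro_sweep(d, pool, sweep = sweep, nro_cfg = cfg)
  s2 <- run_fnro_sweep(d, pool, sweep = sweep, nro_cfg = cfg)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))

  expect_true(all(s1$worst_accuracy <= s1$average_accuracy + 1e-12))
  expect_true(all(s1$average_accuracy <= s1$best_accuracy + 1e-12))
  expect_true(all(s1$ci_low <= s1$average_accuracy & s1$average_accuracy <= s1$ci_high))
  expect_equal(lengths(s1$best_genes), s1$k)

  # stop_at_perfect: no sizes beyond the first k reaching accuracy 1
  if (any(s1$best_accuracy >= 1)) {
    first_perfect <- min(which(s1$best_accuracy >= 1))
    expect_equal(nrow(s1), first_perfect)
    expect_equal(s1$k, (2:6)[seq_len(first_perfect)])
  }

  full <- run_fnro_sweep(d, pool,
    sweep = sweep_config(subset_sizes = 2:3, repeats = 1, stop_at_perfect = FALSE),
    nro_cfg = cfg
  )
  expect_equal(full$k, 2:3)
  expect_error(
    run_fnro_sweep(d, pool, sweep = sweep_config(subset_sizes = 11)),
    "smaller than the largest"
  )
})

test_that("reports render to CSV percentages and round-trip through JSON", {
  d <- easy_data()
  pool <- top_k(gene_scores(d, "fscore"), 8)
  sw <- run_fnro_sweep(d, pool,
    sweep = sweep_config(subset_sizes = 2, repeats = 2, base_seed = 1),
    nro_cfg = nro_config(population_size = 6, max_generations = 2, patience = 2)
  )
  sw$best_accuracy[1] <- 0.98387 # exercise the two-decimal convention

  csv <- tempfile(fileext = ".csv")
  render_report(sw, csv, "csv")
  lines <- readLines(csv)
  expect_equal(length(lines), 2L)
  expect_match(lines[2], "98.39%", fixed = TRUE)

  js <- tempfile(fileext = ".json")
  render_report(sw, js, "json")
  back <- read_report(js)
  expect_equal(back$best_accuracy, sw$best_accuracy)
  expect_equal(back$best_genes, sw$best_genes)
  expect_equal(back$seeds, sw$seeds)

  expect_error(render_report(sw, tempfile(), "xml"), "must be one of")
  expect_error(render_report(sw[0, ], tempfile(), "csv"), "no summaries")
})

test_that("the fnro() front door runs filter + sweep end to end", {
  raw <- simulate_expression(
    n_samples = 24, n_genes = 30, n_informative = 3,
    effect_size = 5, missing_rate = 0.02, seed = 33
  )
  sw <- fnro(raw,
    filter_method = "fscore", pool_size = 10,
    sweep = sweep_config(subset_sizes = 2:3, repeats = 2, base_seed = 1),
    nro_cfg = nro_config(population_size = 6, max_generations = 3, patience = 2)
  )
  expect_s3_class(sw, "fnro_sweep")
  expect_true(all(sw$best_accuracy >= 0 & sw$best_accuracy <= 1))
  expect_equal(length(attr(sw, "pool")), 10L)
})
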