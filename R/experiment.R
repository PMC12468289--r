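#' Configuration for the subset-size sweep
#'
#' Defaults mirror the published protocol: candidate-pool sizes 50-500,
#' subset sizes 2-25, 30 repeated stochastic runs per size, and reporting
#' stops once a subset size reaches perfect accuracy.
#'
#' @param filter_sizes Candidate-pool sizes to compare across filters.
#' @param subset_sizes Gene-subset sizes `k` to optimize.
#' @param repeats Repeated NRO runs per subset size (>= 1).
#' @param base_seed Seed of the first repeat; repeat `r` uses
#'   `base_seed + r - 1`.
#' @param stop_at_perfect Stop enlarging `k` once best accuracy hits 1.
#' @return A validated list of class `sweep_config`.
#' @export
sweep_config <- function(filter_sizes = c(50, 100, 200, 300, 400, 500),
                         subset_sizes = 2:25, repeats = 30, base_seed = 1L,
                         stop_at_perfect = TRUE) {
  cfg <- list(
    filter_sizes = as.integer(filter_sizes),
    subset_sizes = as.integer(subset_sizes),
    repeats = as.integer(repeats), base_seed = as.integer(base_seed),
    stop_at_perfect = isTRUE(stop_at_perfect)
  )
  if (cfg$repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (any(cfg$subset_sizes < 1)) stop("subset sizes must be >= 1", call. = FALSE)
  structure(cfg, class = "sweep_config")
}

#' Compare filter methods across candidate-pool sizes
#'
#' For every method and pool size, selects the top-`s` genes with that
#' filter and evaluates their cross-validated SVM accuracy (no optimizer).
#' The winning pair maximizes accuracy, with ties broken toward the smaller
#' pool and then the method order fscore, infogain, relieff, mrmr.
#'
#' @param data Preprocessed expression tibble.
#' @param methods Filter methods to compare (subset of
#'   `c("fscore", "infogain", "relieff", "mrmr")`).
#' @param filter_sizes Pool sizes to evaluate.
#' @param fitness_cfg A [fitness_config()].
#' @param ... Estimator settings passed to [gene_scores()].
#' @return An object of class `filter_eval`: list with `grid` (tibble of
#'   `method`, `size`, `accuracy`), `best_method`, `best_size`,
#'   `best_accuracy`, and `rankings` (one `filter_scores` per method).
#' @export
evaluate_filters <- function(data, methods = c("fscore", "infogain", "relieff", "mrmr"),
                             filter_sizes = c(50, 100, 200, 300, 400, 500),
                             fitness_cfg = fitness_config(), ...) {
  order_ref <- c("fscore", "infogain", "relieff", "mrmr")
  methods <- match.arg(methods, order_ref, several.ok = TRUE)
  methods <- order_ref[order_ref %in% methods]
  ed <- check_expr(data)
  filter_sizes <- as.integer(filter_sizes)
  if (any(filter_sizes > length(ed$gene_cols))) {
    stop("a filter size exceeds the gene count (", length(ed$gene_cols), ")",
      call. = FALSE
    )
  }
  rankings <- lapply(methods, function(m) {
    gene_scores(data, method = m, mrmr_k = max(filter_sizes), ...)
  })
  names(rankings) <- methods
  grid <- tidyr::expand_grid(method = methods, size = sort(filter_sizes))
  grid$accuracy <- purrr::map2_dbl(grid$method, grid$size, function(m, s) {
    evaluate_subset(data, top_k(rankings[[m]], s), fitness_cfg)$accuracy
  })
  ord <- order(-grid$accuracy, grid$size, match(grid$method, order_ref))
  best <- grid[ord[1], ]
  structure(
    list(
      grid = grid, best_method = best$method, best_size = best$size,
      best_accuracy = best$accuracy, rankings = rankings
    ),
    class = "filter_eval"
  )
}

#' @export
print.filter_eval <- function(x, ...) {
  cat(
    "<filter_eval> best:", x$best_method, "with pool size", x$best_size,
    "(accuracy", sprintf("%.4f", x$best_accuracy), ")\n"
  )
  print(x$grid)
  invisible(x)
}

#' Run the full F-NRO sweep over subset sizes
#'
#' For each subset size `k`, runs the NRO search `repeats` times (seeds
#' `base_seed .. base_seed + repeats - 1`) over the candidate gene pool,
#' collects the final best accuracies, and summarizes them as
#' best/average/worst with a 95% confidence interval of the mean.
#' Precision, recall and F1 are recomputed on the best run's subset. A
#' single fitness cache is shared across repeats and subset sizes, since
#' all runs score subsets of the same dataset. When `stop_at_perfect` is
#' set, the sweep stops after the first `k` whose best accuracy reaches 1.
#'
#' @param data Preprocessed expression tibble.
#' @param pool Integer vector of candidate gene (column) indices, e.g. from
#'   [top_k()]; the NRO search space has one dimension per pool gene.
#' @param sweep A [sweep_config()].
#' @param nro_cfg An [nro_config()] (its `seed` is overridden per repeat).
#' @param fitness_cfg A [fitness_config()].
#' @return An object of class `fnro_sweep`: a tibble with one row per
#'   subset size — `k`, `best_accuracy`, `average_accuracy`,
#'   `worst_accuracy`, `precision`, `recall`, `f1`, `ci_low`, `ci_high`,
#'   `best_genes` (list of gene-id character vectors), `seeds` (list).
#' @export
run_fnro_sweep <- function(data, pool, sweep = sweep_config(),
                           nro_cfg = nro_config(), fitness_cfg = fitness_config()) {
  ed <- check_expr(data)
  pool <- resolve_genes(pool, ed)
  if (length(pool) < max(sweep$subset_sizes)) {
    stop("pool (", length(pool), " genes) is smaller than the largest subset size (",
      max(sweep$subset_sizes), ")",
      call. = FALSE
    )
  }
  pool_data <- data[c(ed$gene_cols[pool], "label")]
  fit_fn <- cached_fitness(pool_data, fitness_cfg)
  d <- length(pool)
  rows <- list()
  for (k in sweep$subset_sizes) {
    seeds <- sweep$base_seed + seq_len(sweep$repeats) - 1L
    runs <- lapply(seeds, function(s) {
      cfg <- nro_cfg
      cfg$seed <- s
      run_nro(fit_fn, d = d, k = k, config = cfg)
    })
    accs <- vapply(runs, function(r) r$best_fitness, numeric(1))
    best_run <- runs[[which.max(accs)]]
    best_eval <- cache_result(fit_fn, best_run$best_genes)
    ci <- aggregate_ci(accs)
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = k,
      best_accuracy = max(accs),
      average_accuracy = ci$mean,
      worst_accuracy = min(accs),
      precision = best_eval$precision,
      recall = best_eval$recall,
      f1 = best_eval$f1,
      ci_low = ci$ci_low,
      ci_high = ci$ci_high,
      best_genes = list(ed$gene_cols[pool[best_run$best_genes]]),
      seeds = list(seeds)
    )
    if (sweep$stop_at_perfect && max(accs) >= 1) break
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fnro_sweep", class(out))
  attr(out, "pool") <- pool
  attr(out, "sweep_config") <- sweep
  out
}

#' Mean and 95% confidence interval of repeated-run accuracies
#'
#' Normal-approximation interval `mean +/- 1.96 * s / sqrt(n)` with `s`
#' the sample standard deviation (`n - 1` divisor); a single value yields a
#' zero-width interval. A Student-t interval is available via `method`.
#'
#' @param accuracies Numeric vector of per-run accuracies (nonempty).
#' @param method `"normal"` (default) or `"t"`.
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' aggregate_ci(c(rep(0.90, 15), rep(1.00, 15)))
#' @export
aggregate_ci <- function(accuracies, method = c("normal", "t")) {
  method <- rlang::arg_match(method)
  if (length(accuracies) == 0) stop("empty accuracy vector", call. = FALSE)
  n <- length(accuracies)
  m <- mean(accuracies)
  if (n == 1) {
    return(tibble::tibble(mean = m, ci_low = m, ci_high = m, n = n))
  }
  s <- stats::sd(accuracies)
  crit <- if (method == "normal") 1.96 else stats::qt(0.975, df = n - 1)
  half <- crit * s / sqrt(n)
  tibble::tibble(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Write a sweep summary to CSV or JSON
#'
#' CSV output formats the accuracy-like columns as percentages with two
#' decimals (e.g. `98.39%`), matching the conventional presentation of
#' classification tables; JSON keeps raw numeric values and round-trips to
#' the same summaries.
#'
#' @param summaries An `fnro_sweep` tibble from [run_fnro_sweep()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(summaries, path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (nrow(summaries) == 0) stop("no summaries to render", call. = FALSE)
  flat <- dplyr::mutate(
    tibble::as_tibble(summaries),
    best_genes = purrr::map_chr(.data$best_genes, paste, collapse = ";"),
    seeds = purrr::map_chr(.data$seeds, paste, collapse = ";")
  )
  if (format == "csv") {
    pct <- c(
      "best_accuracy", "average_accuracy", "worst_accuracy",
      "precision", "recall", "f1", "ci_low", "ci_high"
    )
    flat[pct] <- lapply(flat[pct], function(v) sprintf("%.2f%%", 100 * v))
    readr::write_csv(flat, path, progress = FALSE)
  } else {
    jsonlite::write_json(flat, path, digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read a JSON sweep report back into a tibble
#'
#' @param path JSON file written by [render_report()].
#' @return Tibble with list-columns `best_genes` and `seeds` restored.
#' @export
read_report <- function(path) {
  raw <- tibble::as_tibble(jsonlite::fromJSON(path))
  raw$best_genes <- strsplit(raw$best_genes, ";", fixed = TRUE)
  raw$seeds <- lapply(strsplit(raw$seeds, ";", fixed = TRUE), as.integer)
  raw
}

#' Run the complete F-NRO pipeline on one dataset
#'
#' Convenience front door: preprocess (impute + Z-score), rank genes with
#' one filter, keep the top-`pool_size` pool, and sweep NRO over the
#' requested subset sizes.
#'
#' @param data Raw expression tibble (gene columns + `label`).
#' @param filter_method Filter used to build the candidate pool.
#' @param pool_size Candidate-pool size (top-ranked genes kept).
#' @param sweep A [sweep_config()].
#' @param nro_cfg An [nro_config()].
#' @param fitness_cfg A [fitness_config()].
#' @return An `fnro_sweep` tibble (see [run_fnro_sweep()]); the pool's
#'   gene indices are in `attr(., "pool")`.
#' @export
fnro <- function(data, filter_method = "fscore", pool_size = 500,
                 sweep = sweep_config(), nro_cfg = nro_config(),
                 fitness_cfg = fitness_config()) {
  pre <- preprocess_expression(data)
  scores <- gene_scores(pre, method = filter_method, mrmr_k = pool_size)
  pool <- top_k(scores, pool_size)
  run_fnro_sweep(pre, pool,
    sweep = sweep, nro_cfg = nro_cfg,
    fitness_cfg = fitness_cfg
  )
}
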