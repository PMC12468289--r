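#' Simulate a microarray-like expression dataset with planted signal
#'
#' Generates a samples-by-genes matrix emulating benchmark microarray data:
#' tens of samples, thousands of genes, 2-4 classes, and a small set of
#' class-informative genes. Non-informative genes are `N(0, noise_sd^2)`
#' independent of class; each informative gene has class-specific means laid
#' out on a ladder `0, delta, 2*delta, ...` with
#' `delta = effect_size * noise_sd`, which guarantees pairwise separability
#' for any class count. Optionally a fraction of cells is set missing
#' uniformly at random. Everything is reproducible from `seed`.
#'
#' The planted truth (which genes are informative, and their class means) is
#' attached as the `truth` attribute and retrievable with
#' [synthetic_truth()]; [recovery_score()] measures how much of it a
#' selection recovered.
#'
#' @param n_samples Number of samples (default 62, a typical benchmark size).
#' @param n_genes Number of genes (default 2000).
#' @param n_informative Number of class-informative genes (default 10).
#' @param n_classes Number of classes, >= 2 (default 2).
#' @param effect_size Class-mean spacing in units of `noise_sd` (default 2).
#' @param noise_sd Residual standard deviation (default 1).
#' @param missing_rate Fraction of cells set missing, in `[0, 1)` (default 0).
#' @param class_proportions Optional vector of class proportions (defaults
#'   to balanced); every class must end up with at least 2 samples.
#' @param seed Integer seed.
#' @return Expression tibble (gene columns `g0001`... + factor `label` with
#'   levels `c1..cm`), with attribute `truth`.
#' @examples
#' d <- simulate_expression(n_samples = 20, n_genes = 50, n_informative = 3, seed = 1)
#' synthetic_truth(d)$informative_genes
#' @export
simulate_expression <- function(n_samples = 62, n_genes = 2000, n_informative = 10,
                                n_classes = 2, effect_size = 2, noise_sd = 1,
                                missing_rate = 0, class_proportions = NULL,
                                seed = 1L) {
  if (n_informative > n_genes) stop("n_informative exceeds n_genes", call. = FALSE)
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes || any(class_proportions <= 0)) {
    stop("class_proportions must give one positive share per class", call. = FALSE)
  }
  class_proportions <- class_proportions / sum(class_proportions)
  counts <- floor(class_proportions * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    give <- order(class_proportions * n_samples - counts, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }
  if (any(counts < 2)) {
    stop("every class needs >= 2 samples; got sizes ",
      paste(counts, collapse = ", "),
      call. = FALSE
    )
  }

  set.seed(seed)
  labels <- rep(seq_len(n_classes), counts)
  labels <- labels[sample.int(n_samples)] # interleave classes
  x <- matrix(stats::rnorm(n_samples * n_genes, 0, noise_sd), n_samples, n_genes)
  informative <- sort(sample.int(n_genes, n_informative))
  delta <- effect_size * noise_sd
  class_means <- outer(seq_len(n_classes) - 1, rep(delta, n_informative)) # m x p ladder
  for (j in seq_along(informative)) {
    x[, informative[j]] <- x[, informative[j]] + class_means[labels, j]
  }
  if (missing_rate > 0) {
    miss <- which(stats::runif(n_samples * n_genes) < missing_rate)
    x[miss] <- NA_real_
  }

  gene_ids <- sprintf("g%0*d", max(4, nchar(n_genes)), seq_len(n_genes))
  out <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(out) <- gene_ids
  out$label <- factor(paste0("c", labels), levels = paste0("c", seq_len(n_classes)))
  attr(out, "truth") <- list(
    informative_genes = informative,
    informative_ids = gene_ids[informative],
    class_means = class_means,
    spec = list(
      n_samples = n_samples, n_genes = n_genes, n_informative = n_informative,
      n_classes = n_classes, effect_size = effect_size, noise_sd = noise_sd,
      missing_rate = missing_rate, seed = seed
    )
  )
  attr(out, "meta") <- list(source = "simulate_expression", seed = seed)
  out
}

#' Planted truth of a simulated dataset
#'
#' @param data A tibble from [simulate_expression()].
#' @return List with `informative_genes` (column indices),
#'   `informative_ids`, `class_means`, and the generating `spec`.
#' @export
synthetic_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("no planted truth attached; was this simulated?", call. = FALSE)
  tr
}

#' Fraction of planted informative genes recovered by a selection
#'
#' `|selected intersect informative| / |informative|`.
#'
#' @param selected Integer vector of selected gene (column) indices, or
#'   gene names.
#' @param truth A truth list from [synthetic_truth()] (or a simulated
#'   dataset carrying one).
#' @return Recovery fraction in `[0, 1]`.
#' @examples
#' d <- simulate_expression(n_samples = 20, n_genes = 50, n_informative = 4, seed = 2)
#' recovery_score(synthetic_truth(d)$informative_genes, d) # 1
#' @export
recovery_score <- function(selected, truth) {
  if (is.data.frame(truth)) truth <- synthetic_truth(truth)
  planted <- if (is.character(selected)) truth$informative_ids else truth$informative_genes
  length(intersect(selected, planted)) / length(planted)
}
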