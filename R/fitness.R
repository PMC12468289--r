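#' Configuration for subset fitness evaluation
#'
#' A gene subset is scored by the cross-validated accuracy of a linear
#' support-vector machine trained on just those genes. The linear kernel
#' with `C = 1` is fixed as the reference classifier for high-dimensional,
#' small-n expression data.
#'
#' @param C Regularization parameter of the linear SVM (default 1).
#' @param cv `"loocv"` (default) or `"kfold"`.
#' @param folds Number of folds when `cv = "kfold"` (>= 2).
#' @param average `"weighted"` (class-support-weighted, default) or
#'   `"macro"` averaging for multiclass precision/recall/F1.
#' @param cache Whether [cached_fitness()] memoizes results (default TRUE).
#' @param seed Seed for the stratified fold shuffle in k-fold CV.
#' @return A validated list of class `fitness_config`.
#' @export
fitness_config <- function(C = 1, cv = c("loocv", "kfold"), folds = 5,
                           average = c("weighted", "macro"), cache = TRUE,
                           seed = 1L) {
  cfg <- list(
    C = C, cv = rlang::arg_match(cv), folds = as.integer(folds),
    average = rlang::arg_match(average), cache = isTRUE(cache),
    seed = as.integer(seed)
  )
  if (cfg$C <= 0) stop("C must be positive", call. = FALSE)
  if (cfg$folds < 2) stop("folds must be >= 2", call. = FALSE)
  structure(cfg, class = "fitness_config")
}

#' Leave-one-out cross-validated SVM accuracy of a gene subset
#'
#' Each sample is held out once; a linear SVM is trained on the remaining
#' samples restricted to the gene subset and predicts the held-out sample.
#' Accuracy is the fraction of correct held-out predictions;
#' precision/recall/F1 are computed from the pooled predictions.
#'
#' @param data Expression tibble (gene columns + `label`), already
#'   preprocessed.
#' @param genes Integer vector of gene (column) indices, or gene names.
#' @param config A [fitness_config()].
#' @return An `evaluation_result` list: `accuracy`, `precision`, `recall`,
#'   `f1` (all in `[0, 1]`), and `predictions`, a tibble of per-sample
#'   `truth` and `predicted` labels.
#' @export
loocv_accuracy <- function(data, genes, config = fitness_config()) {
  ed <- check_expr(data)
  genes <- resolve_genes(genes, ed)
  check_min_class(ed$labels, 2)
  n <- nrow(ed$x)
  eval_cv(ed, genes, folds_index = as.list(seq_len(n)), config)
}

#' Stratified k-fold cross-validated SVM accuracy of a gene subset
#'
#' Samples are shuffled within each class (seeded by `config$seed`) and
#' dealt round-robin into `config$folds` folds, so every fold has nearly
#' proportional class composition. With `folds` equal to the sample count
#' this degenerates to leave-one-out.
#'
#' @inheritParams loocv_accuracy
#' @return An `evaluation_result`, as for [loocv_accuracy()].
#' @export
kfold_accuracy <- function(data, genes, config = fitness_config(cv = "kfold")) {
  ed <- check_expr(data)
  genes <- resolve_genes(genes, ed)
  check_min_class(ed$labels, 2)
  n <- nrow(ed$x)
  folds <- config$folds
  if (folds > n) stop("folds (", folds, ") exceeds sample count (", n, ")", call. = FALSE)
  smallest <- min(table(ed$labels))
  if (folds > smallest && folds != n) {
    stop("folds (", folds, ") exceeds the smallest class (", smallest,
      " samples); stratification impossible (folds = n is allowed as LOOCV)",
      call. = FALSE
    )
  }
  assign_fold <- integer(n)
  set.seed(config$seed)
  for (lv in levels(ed$labels)) {
    idx <- which(ed$labels == lv)
    idx <- idx[sample.int(length(idx))]
    assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  eval_cv(ed, genes, folds_index = split(seq_len(n), assign_fold), config)
}

# Shared CV engine: train linear SVM on each training fold, pool held-out
# predictions, compute metrics.
eval_cv <- function(ed, genes, folds_index, config) {
  if (length(genes) == 0) stop("gene subset must be nonempty", call. = FALSE)
  x <- ed$x[, genes, drop = FALSE]
  y <- ed$labels
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (fold in folds_index) {
    xtr <- x[-fold, , drop = FALSE]
    ytr <- droplevels(y[-fold])
    if (nlevels(ytr) < 2) {
      stop("a training fold lost a class; every class needs >= 2 samples",
        call. = FALSE
      )
    }
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = config$C, scale = FALSE)
    p <- stats::predict(fit, x[fold, , drop = FALSE])
    pred[fold] <- factor(as.character(p), levels = levels(y))
  }
  classification_metrics(y, pred, average = config$average)
}

# Pooled confusion-matrix metrics. Per-class precision/recall/F1 with 0/0
# defined as 0, averaged weighted-by-support or macro.
classification_metrics <- function(truth, predicted, average = "weighted") {
  lev <- levels(truth)
  acc <- mean(as.character(predicted) == as.character(truth))
  pr <- rc <- f1 <- numeric(length(lev))
  for (j in seq_along(lev)) {
    tp <- sum(predicted == lev[j] & truth == lev[j], na.rm = TRUE)
    fp <- sum(predicted == lev[j] & truth != lev[j], na.rm = TRUE)
    fn <- sum(predicted != lev[j] & truth == lev[j], na.rm = TRUE)
    pr[j] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc[j] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (pr[j] + rc[j] > 0) 2 * pr[j] * rc[j] / (pr[j] + rc[j]) else 0
  }
  w <- if (average == "weighted") {
    as.numeric(table(truth)) / length(truth)
  } else {
    rep(1 / length(lev), length(lev))
  }
  structure(
    list(
      accuracy = acc,
      precision = sum(w * pr), recall = sum(w * rc), f1 = sum(w * f1),
      predictions = tibble::tibble(
        sample = seq_along(truth),
        truth = as.character(truth), predicted = as.character(predicted)
      )
    ),
    class = "evaluation_result"
  )
}

#' Evaluate a gene subset under the configured cross-validation scheme
#'
#' Dispatches to [loocv_accuracy()] or [kfold_accuracy()] according to
#' `config$cv`.
#'
#' @inheritParams loocv_accuracy
#' @return An `evaluation_result`.
#' @export
evaluate_subset <- function(data, genes, config = fitness_config()) {
  if (config$cv == "loocv") {
    loocv_accuracy(data, genes, config)
  } else {
    kfold_accuracy(data, genes, config)
  }
}

#' Memoizing fitness function over gene subsets
#'
#' Returns a function mapping a gene-index vector to cross-validated
#' accuracy, memoized on the sorted index tuple — the NRO search
#' re-evaluates duplicate subsets constantly, so caching removes most
#' classifier fits. [cache_stats()] exposes hit/miss counters and
#' [cache_result()] retrieves the full stored metrics for a subset.
#'
#' @inheritParams loocv_accuracy
#' @return A function `genes -> accuracy` of class `cached_fitness`.
#' @export
cached_fitness <- function(data, config = fitness_config()) {
  force(data)
  force(config)
  store <- new.env(parent = emptyenv())
  hits <- 0L
  misses <- 0L
  fn <- function(genes) {
    key <- paste(sort(as.integer(genes)), collapse = ",")
    got <- store[[key]]
    if (!is.null(got)) {
      hits <<- hits + 1L
      return(got$accuracy)
    }
    misses <<- misses + 1L
    res <- evaluate_subset(data, genes, config)
    if (config$cache) store[[key]] <- res
    res$accuracy
  }
  class(fn) <- c("cached_fitness", "function")
  fn
}

#' @rdname cached_fitness
#' @param fn A `cached_fitness` function.
#' @export
cache_stats <- function(fn) {
  e <- environment(fn)
  list(hits = e$hits, misses = e$misses, size = length(ls(e$store)))
}

#' @rdname cached_fitness
#' @param genes Gene-index vector whose stored evaluation to fetch (it is
#'   computed and cached if absent).
#' @export
cache_result <- function(fn, genes) {
  e <- environment(fn)
  key <- paste(sort(as.integer(genes)), collapse = ",")
  got <- e$store[[key]]
  if (is.null(got)) got <- evaluate_subset(e$data, genes, e$config)
  got
}

resolve_genes <- function(genes, ed) {
  if (is.character(genes)) {
    idx <- match(genes, ed$gene_cols)
    if (anyNA(idx)) stop("unknown gene name(s): ", paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
    return(idx)
  }
  genes <- as.integer(genes)
  if (length(genes) && (min(genes) < 1 || max(genes) > length(ed$gene_cols))) {
    stop("gene index out of range", call. = FALSE)
  }
  genes
}

check_min_class <- function(labels, minimum) {
  sizes <- table(labels)
  if (any(sizes < minimum)) {
    stop("class '", names(sizes)[which.min(sizes)], "' has ", min(sizes),
      " sample(s); every class needs >= ", minimum,
      call. = FALSE
    )
  }
  invisible(TRUE)
}
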