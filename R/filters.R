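#' Shannon entropy of a class-label vector
#'
#' `-sum(p_i * log2(p_i))` over the observed classes, the uncertainty (in
#' bits) of the class of a random sample.
#'
#' @param labels Vector of class labels (any type; treated categorically).
#' @return Entropy in bits, in `[0, log2(m)]` for `m` observed classes.
#' @examples
#' entropy(c(0, 0, 1, 1)) # 1 bit
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  p <- tabulate(factor(labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# Equal-frequency discretization into at most `bins` intervals.
# Constant (or near-constant) features collapse to a single bin.
discretize_ef <- function(x, bins) {
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
    names = FALSE, type = 7
  ))
  if (length(br) < 3) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# Mutual information (bits) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Information gain of one feature for the class labels
#'
#' The expected reduction in class entropy after partitioning the samples by
#' the (discretized) feature value: `Info(D) - sum_j |D_j|/|D| * Info(D_j)`.
#' Continuous features are discretized into equal-frequency bins first.
#'
#' @param feature Numeric vector, one value per sample.
#' @param labels Class labels, same length as `feature`.
#' @param bins Number of equal-frequency bins for discretization (default 10).
#' @return Gain in bits, in `[0, entropy(labels)]`.
#' @examples
#' information_gain(c(1, 1, 9, 9), c(0, 0, 1, 1), bins = 2) # 1: perfect split
#' @export
information_gain <- function(feature, labels, bins = 10) {
  if (length(feature) != length(labels)) {
    stop("feature and labels differ in length", call. = FALSE)
  }
  d <- discretize_ef(feature, bins)
  h <- entropy(labels)
  cond <- 0
  for (v in unique(d)) {
    idx <- d == v
    cond <- cond + mean(idx) * entropy(labels[idx])
  }
  max(0, h - cond)
}

#' Two-class F-score of one feature
#'
#' Ratio of between-class to within-class variation for a binary problem:
#' `[(mu_+ - mu)^2 + (mu_- - mu)^2] / (s2_+ + s2_-)` with sample variances
#' (divide by `n - 1`) within each class. A feature with zero within-class
#' variance but distinct class means is a perfect separator and scores
#' `Inf`; a feature with equal class means scores 0.
#'
#' @inheritParams information_gain
#' @return Nonnegative score, possibly `Inf`.
#' @examples
#' fscore_binary(c(1, 2, 3, -1, -2, -3), c(1, 1, 1, 0, 0, 0)) # 4
#' @export
fscore_binary <- function(feature, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2) {
    stop("fscore_binary requires exactly 2 classes (use anova_f for more)",
      call. = FALSE
    )
  }
  if (any(table(f) < 2)) {
    stop("each class needs >= 2 samples for a sample variance", call. = FALSE)
  }
  mu <- mean(feature)
  xp <- feature[f == levels(f)[1]]
  xn <- feature[f == levels(f)[2]]
  num <- (mean(xp) - mu)^2 + (mean(xn) - mu)^2
  den <- stats::var(xp) + stats::var(xn)
  if (num == 0) {
    return(0)
  }
  if (den == 0) {
    return(Inf)
  }
  num / den
}

#' One-way ANOVA F statistic of one feature
#'
#' Between-group mean square over within-group mean square, the multiclass
#' generalization of the two-class F-score used to rank genes when there are
#' more than two classes. Zero within-group variance with unequal group
#' means scores `Inf`.
#'
#' @inheritParams information_gain
#' @return Nonnegative F statistic, possibly `Inf`.
#' @examples
#' anova_f(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 8
#' @export
anova_f <- function(feature, labels) {
  f <- droplevels(factor(labels))
  m <- nlevels(f)
  n <- length(feature)
  if (m < 2) stop("need at least 2 classes", call. = FALSE)
  if (n <= m) stop("need n > number of classes for within-group df", call. = FALSE)
  gm <- tapply(feature, f, mean)
  gn <- tabulate(f)
  ssb <- sum(gn * (gm - mean(feature))^2)
  ssw <- sum((feature - gm[as.integer(f)])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (n - m)
  if (msb == 0) {
    return(0)
  }
  if (msw == 0) {
    return(Inf)
  }
  msb / msw
}

# Vectorized per-column ANOVA F over a matrix (the workhorse for ranking
# thousands of genes at once). Same semantics as anova_f per column.
col_anova_f <- function(x, f) {
  f <- droplevels(factor(f))
  m <- nlevels(f)
  n <- nrow(x)
  ind <- stats::model.matrix(~ f - 1) # n x m indicator
  gn <- colSums(ind)
  gmean <- sweep(crossprod(ind, x), 1, gn, "/") # m x d group means
  grand <- colMeans(x)
  ssb <- colSums(gn * sweep(gmean, 2, grand, "-")^2)
  ssw <- colSums((x - ind %*% gmean)^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (n - m)
  out <- ifelse(msb == 0, 0, ifelse(msw == 0, Inf, msb / msw))
  as.numeric(out)
}

# Vectorized per-column binary F-score (sample variances within class).
col_fscore <- function(x, f) {
  f <- droplevels(factor(f))
  stopifnot(nlevels(f) == 2)
  i1 <- f == levels(f)[1]
  mu <- colMeans(x)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!i1, , drop = FALSE], 2, stats::var)
  num <- (m1 - mu)^2 + (m2 - mu)^2
  den <- v1 + v2
  ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
}

#' ReliefF gene weights
#'
#' Multiclass ReliefF: for each sampled instance, each gene's weight is
#' decreased by its mean range-scaled difference to the `n_neighbors`
#' nearest same-class neighbours (hits) and increased by the
#' class-prior-weighted mean difference to the nearest neighbours of every
#' other class (misses). Neighbours are found by Manhattan distance on
#' range-scaled genes. Genes that vary between classes but not within them
#' get large positive weights; weights lie in `[-1, 1]`.
#'
#' @param data Expression tibble (gene columns + `label`).
#' @param n_neighbors Number of hits/misses per class (default 10; must be
#'   smaller than the smallest class).
#' @param n_iterations Number of instances to sample, or `NULL` (default)
#'   for one deterministic pass over all samples.
#' @param seed Optional seed for the instance sample when
#'   `n_iterations` is given.
#' @return Named numeric vector of per-gene weights.
#' @export
relieff_scores <- function(data, n_neighbors = 10, n_iterations = NULL, seed = NULL) {
  ed <- check_expr(data)
  x <- ed$x
  f <- ed$labels
  n <- nrow(x)
  cls_sizes <- table(f)
  if (any(cls_sizes < n_neighbors + 1)) {
    stop("class '", names(cls_sizes)[which.min(cls_sizes)], "' has ",
      min(cls_sizes), " samples; lower n_neighbors below ", min(cls_sizes),
      call. = FALSE
    )
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1 # constant genes contribute zero differences anyway
  xs <- sweep(x, 2, rng, "/") # range-scaled
  priors <- as.numeric(cls_sizes) / n

  if (is.null(n_iterations)) {
    picks <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    picks <- sample.int(n, n_iterations, replace = n_iterations > n)
  }
  m <- length(picks)
  k <- n_neighbors
  w <- numeric(ncol(x))
  dmat <- as.matrix(stats::dist(xs, method = "manhattan"))
  lev <- levels(f)
  for (i in picks) {
    ci <- as.integer(f[i])
    for (cj in seq_along(lev)) {
      pool <- which(as.integer(f) == cj & seq_len(n) != i)
      ord <- pool[order(dmat[i, pool], pool)][seq_len(k)]
      dif <- colMeans(abs(sweep(xs[ord, , drop = FALSE], 2, xs[i, ], "-")))
      if (cj == ci) {
        w <- w - dif / m
      } else {
        w <- w + (priors[cj] / (1 - priors[ci])) * dif / m
      }
    }
  }
  stats::setNames(w, ed$gene_cols)
}

#' Greedy mRMR gene ranking
#'
#' Minimum-redundancy maximum-relevance forward selection. The first gene
#' maximizes mutual information with the class; each subsequent gene `f`
#' maximizes `MI(f, c) - mean(MI(f, s))` over the already-selected set `S`
#' (the difference form). All mutual informations are estimated on
#' equal-frequency discretized values. Ties break toward the lower gene
#' index; because the discrete MI estimator produces exact ties whenever two
#' genes share a contingency table, candidates within `1e-9` of the maximum
#' criterion count as tied (floating-point summation order must not decide
#' a tie).
#'
#' @inheritParams relieff_scores
#' @param k Number of genes to select (`k <=` gene count).
#' @param bins Equal-frequency bins for the MI estimator (default 10).
#' @return Integer vector of `k` selected gene (column) indices, in
#'   selection order.
#' @export
mrmr_rank <- function(data, k, bins = 10) {
  ed <- check_expr(data)
  d <- ncol(ed$x)
  if (k > d) stop("k (", k, ") exceeds gene count (", d, ")", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  disc <- apply(ed$x, 2, discretize_ef, bins = bins)
  rel <- apply(disc, 2, discrete_mi, b = ed$codes)
  selected <- integer(0)
  red_sum <- numeric(d) # running sum of MI(f, s) over selected s
  avail <- rep(TRUE, d)
  for (step in seq_len(k)) {
    crit <- if (step == 1) rel else rel - red_sum / length(selected)
    crit[!avail] <- -Inf
    # lowest index among near-ties of the maximum (exact estimator ties
    # perturbed only by summation order)
    pick <- unname(which(crit >= max(crit) - 1e-9))[1]
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    if (step < k) {
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(j) discrete_mi(disc[, j], disc[, pick]), numeric(1))
    }
  }
  selected
}

#' Score and rank all genes with one filter method
#'
#' Applies one of the four filter criteria to every gene and returns a
#' ranking. `fscore` uses the two-class F-score for binary labels and the
#' ANOVA F statistic for more classes; `infogain` the discretized
#' information gain; `relieff` the ReliefF weights; `mrmr` the greedy
#' mRMR selection order (selected genes rank first in selection order,
#' remaining genes follow by class relevance). Ties always break toward the
#' lower gene index, so rankings are deterministic.
#'
#' @inheritParams relieff_scores
#' @param method One of `"fscore"`, `"infogain"`, `"relieff"`, `"mrmr"`.
#' @param bins Bins for discretization-based estimators.
#' @param mrmr_k Genes to select greedily when `method = "mrmr"` (default:
#'   all genes).
#' @return A `filter_scores` tibble with one row per gene: `index`, `gene`,
#'   `score`, `rank` (1 = most relevant). The method and estimator settings
#'   are kept in attributes `method` and `params`.
#' @export
gene_scores <- function(data, method = c("fscore", "infogain", "relieff", "mrmr"),
                        bins = 10, n_neighbors = 10, n_iterations = NULL,
                        seed = NULL, mrmr_k = NULL) {
  method <- rlang::arg_match(method)
  ed <- check_expr(data)
  d <- ncol(ed$x)
  params <- list(bins = bins)
  if (method == "fscore") {
    scores <- if (nlevels(ed$labels) == 2) {
      col_fscore(ed$x, ed$labels)
    } else {
      col_anova_f(ed$x, ed$labels)
    }
    params <- list()
  } else if (method == "infogain") {
    scores <- vapply(
      seq_len(d),
      function(j) information_gain(ed$x[, j], ed$codes, bins = bins),
      numeric(1)
    )
  } else if (method == "relieff") {
    scores <- unname(relieff_scores(data,
      n_neighbors = n_neighbors,
      n_iterations = n_iterations, seed = seed
    ))
    params <- list(n_neighbors = n_neighbors, n_iterations = n_iterations)
  } else {
    kk <- if (is.null(mrmr_k)) d else min(mrmr_k, d)
    sel <- mrmr_rank(data, k = kk, bins = bins)
    rest <- setdiff(seq_len(d), sel)
    if (length(rest) > 0) {
      disc <- apply(ed$x[, rest, drop = FALSE], 2, discretize_ef, bins = bins)
      rel <- apply(disc, 2, discrete_mi, b = ed$codes)
      rest <- rest[order(-rel, rest)]
    }
    ranking <- c(sel, rest)
    scores <- numeric(d)
    scores[ranking] <- seq(d, 1) # selection-order rank score
    params <- list(bins = bins, mrmr_k = kk)
  }
  ord <- order(-scores, seq_len(d)) # Inf first; ties by ascending index
  rk <- integer(d)
  rk[ord] <- seq_len(d)
  out <- tibble::tibble(
    index = seq_len(d), gene = ed$gene_cols,
    score = as.numeric(scores), rank = rk
  )
  class(out) <- c("filter_scores", class(out))
  attr(out, "method") <- method
  attr(out, "params") <- params
  out
}

#' Top-k genes of a filter ranking
#'
#' @param scores A `filter_scores` tibble from [gene_scores()], or a bare
#'   numeric score vector (higher = more relevant, ties to the lower index).
#' @param k Pool size to keep.
#' @return Integer vector of the `k` top-ranked gene (column) indices, in
#'   rank order.
#' @examples
#' top_k(c(3, 1, 2), 2) # genes 1 and 3
#' @export
top_k <- function(scores, k) {
  if (is.data.frame(scores)) {
    d <- nrow(scores)
    ord <- order(scores$rank)
    idx <- scores$index[ord]
  } else {
    d <- length(scores)
    idx <- order(-as.numeric(scores), seq_len(d))
  }
  if (k > d) stop("k (", k, ") exceeds gene count (", d, ")", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  idx[seq_len(k)]
}
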