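# Independent brute-force oracles used to verify the filter statistics.
# These deliberately avoid the package's vectorized code paths: explicit
# loops, split(), and stats::lm().

oracle_entropy <- function(labels) {
  h <- 0
  for (cl in unique(labels)) {
    p <- sum(labels == cl) / length(labels)
    h <- h - p * log2(p)
  }
  h
}

# Equal-frequency binning shared by convention with the implementation
# (the bin edges are a design parameter, not part of the statistic).
oracle_bins <- function(x, bins) {
  br <- unique(quantile(x, seq(0, 1, length.out = bins + 1), names = FALSE))
  if (length(br) < 3) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, br, include.lowest = TRUE))
}

oracle_ig <- function(feature, labels, bins = 10) {
  d <- oracle_bins(feature, bins)
  h <- oracle_entropy(labels)
  for (part in split(labels, d)) {
    h <- h - (length(part) / length(labels)) * oracle_entropy(part)
  }
  max(0, h)
}

oracle_fscore <- function(feature, labels) {
  lev <- sort(unique(labels))
  xp <- feature[labels == lev[1]]
  xn <- feature[labels == lev[2]]
  mu <- mean(feature)
  num <- (mean(xp) - mu)^2 + (mean(xn) - mu)^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
    sum((xn - mean(xn))^2) / (length(xn) - 1)
  if (num == 0) 0 else if (den == 0) Inf else num / den
}

oracle_anova_f <- function(feature, labels) {
  fit <- stats::lm(feature ~ factor(labels))
  stats::anova(fit)[["F value"]][1]
}

oracle_mi <- function(a, b) {
  mi <- 0
  n <- length(a)
  for (va in unique(a)) {
    for (vb in unique(b)) {
      pab <- sum(a == va & b == vb) / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
      }
    }
  }
  mi
}

# Exhaustive greedy mRMR (difference form) on pre-discretized columns.
oracle_mrmr <- function(x, labels, k, bins = 10) {
  disc <- apply(x, 2, oracle_bins, bins = bins)
  d <- ncol(x)
  sel <- integer(0)
  for (step in seq_len(k)) {
    best_j <- NA
    best_crit <- -Inf
    for (j in setdiff(seq_len(d), sel)) {
      crit <- oracle_mi(disc[, j], labels)
      if (length(sel) > 0) {
        crit <- crit - mean(sapply(sel, function(s) oracle_mi(disc[, j], disc[, s])))
      }
      # keep the earliest gene unless the improvement clears the tie
      # tolerance (discrete MI estimates tie exactly up to summation order)
      if (crit > best_crit + 1e-9) {
        best_crit <- crit
        best_j <- j
      }
    }
    sel <- c(sel, best_j)
  }
  sel
}

# Small labelled expression tibble with well-separated classes.
make_clumps <- function(n_per_class = 10, sep = 5, noise = 0.1, genes = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * genes, 0, noise), n, genes)
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] - sep
  x[-seq_len(n_per_class), 1] <- x[-seq_len(n_per_class), 1] + sep
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- paste0("g", seq_len(genes))
  out$label <- factor(rep(c("a", "b"), each = n_per_class))
  out
}

random_expression <- function(n = 10, d = 20, classes = 2, seed = 1) {
  set.seed(seed)
  out <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * d), n, d)))
  names(out) <- paste0("g", seq_len(d))
  out$label <- factor(rep_len(paste0("c", seq_len(classes)), n))
  out
}
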