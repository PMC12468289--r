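#' Configuration for the Nuclear Reaction Optimization search
#'
#' Collects the NRO hyperparameters. Defaults follow the protocol used for
#' microarray gene selection: a population of 500 candidate subsets evolved
#' for at most 30 generations with early stopping after 5 stagnant
#' generations.
#'
#' @param population_size Number of candidate solutions `N` (>= 4; the
#'   operators draw up to two distinct random peers besides the current
#'   solution and the best).
#' @param max_generations Generation cap `T`.
#' @param patience Early-stopping patience `P`: stop after this many
#'   consecutive generations without strict improvement of the global best.
#' @param p_beta Probability of the "subaltern" fission branch (perturbation
#'   around the global best) versus the "essential" branch (perturbation
#'   around the current solution). Default 0.5.
#' @param levy_alpha Scale `alpha` of the Levy-flight escape steps.
#' @param levy_exponent Stability exponent `beta` of the Levy distribution,
#'   in `(0, 2]`; 1.5 is the canonical Mantegna choice.
#' @param similarity_tol Threshold under which two candidates count as "too
#'   similar", triggering the Levy escape branch (per dimension during
#'   ionization, by vector norm during fusion).
#' @param seed Integer seed fixing all randomness of a [run_nro()] call.
#' @param decode `"top_k"` (default): a position decodes to the genes with
#'   the `k` largest components; `"threshold"`: components `>= 0.5` are
#'   selected (variable subset size).
#' @param neutron How the "heated neutron" combines two random peers:
#'   `"mean"` (default, stays inside the search bounds) or `"product"`
#'   (elementwise).
#' @return A validated list of class `nro_config`.
#' @export
nro_config <- function(population_size = 500, max_generations = 30, patience = 5,
                       p_beta = 0.5, levy_alpha = 0.01, levy_exponent = 1.5,
                       similarity_tol = 1e-10, seed = 1L,
                       decode = c("top_k", "threshold"),
                       neutron = c("mean", "product")) {
  cfg <- list(
    population_size = as.integer(population_size),
    max_generations = as.integer(max_generations),
    patience = as.integer(patience),
    p_beta = p_beta, levy_alpha = levy_alpha, levy_exponent = levy_exponent,
    similarity_tol = similarity_tol, seed = seed,
    decode = rlang::arg_match(decode), neutron = rlang::arg_match(neutron)
  )
  if (cfg$population_size < 4) {
    stop("population_size must be >= 4 (operators need two distinct peers)",
      call. = FALSE
    )
  }
  if (cfg$max_generations < 1 || cfg$patience < 1) {
    stop("max_generations and patience must be >= 1", call. = FALSE)
  }
  if (cfg$p_beta < 0 || cfg$p_beta > 1) stop("p_beta must lie in [0, 1]", call. = FALSE)
  if (cfg$levy_exponent <= 0 || cfg$levy_exponent > 2) {
    stop("levy_exponent must lie in (0, 2]", call. = FALSE)
  }
  if (cfg$similarity_tol <= 0) stop("similarity_tol must be positive", call. = FALSE)
  structure(cfg, class = "nro_config")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Initialize an NRO population
#'
#' Positions drawn uniformly on `[0, 1]^d` from the current RNG state.
#'
#' @param n Population size (>= 4).
#' @param d Search-space dimension (number of pooled genes).
#' @return An `n x d` matrix of positions.
#' @export
init_population <- function(n, d) {
  if (n < 4) stop("population size must be >= 4", call. = FALSE)
  if (d < 1) stop("dimension must be >= 1", call. = FALSE)
  matrix(stats::runif(n * d), nrow = n, ncol = d)
}

#' Heated-neutron vector for one solution
#'
#' Combines two random peers `X_p`, `X_q` (distinct from each other and from
#' solution `i`) into the diversification term injected by the fission
#' update — by default their elementwise mean, which keeps the neutron
#' inside the search bounds.
#'
#' @param pop Population matrix (rows = solutions).
#' @param i Row index of the current solution.
#' @param neutron `"mean"` or `"product"`.
#' @return Numeric vector of length `ncol(pop)`.
#' @export
heated_neutron <- function(pop, i, neutron = "mean") {
  n <- nrow(pop)
  if (n < 3) stop("population must have >= 3 solutions", call. = FALSE)
  pq <- sample(setdiff(seq_len(n), i), 2)
  if (neutron == "product") {
    pop[pq[1], ] * pop[pq[2], ]
  } else {
    (pop[pq[1], ] + pop[pq[2], ]) / 2
  }
}

#' Mantegna scale for Levy-stable steps
#'
#' The standard deviation `sigma_u` of the Gaussian numerator in Mantegna's
#' algorithm:
#' `{Gamma(1+b) sin(pi b / 2) / [Gamma((1+b)/2) b 2^((b-1)/2)]}^(1/b)`.
#'
#' @param beta Stability exponent in `(0, 2]`.
#' @return The scalar `sigma_u`.
#' @examples
#' mantegna_sigma(1.5) # ~0.6966
#' @export
mantegna_sigma <- function(beta) {
  if (beta <= 0 || beta > 2) stop("beta must lie in (0, 2]", call. = FALSE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Heavy-tailed Levy-flight steps (Mantegna's algorithm)
#'
#' `step = u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)`,
#' producing mostly small moves with occasional very large jumps.
#'
#' @param beta Stability exponent in `(0, 2]`.
#' @param n Number of steps to draw.
#' @return Numeric vector of `n` steps.
#' @export
levy_step <- function(beta, n) {
  su <- mantegna_sigma(beta)
  u <- stats::rnorm(n, 0, su)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Fission phase: exploratory perturbation
#'
#' For each solution, with probability `p_beta` a new candidate is drawn
#' around the global best ("subaltern" products), otherwise around the
#' solution itself ("essential" products). The Gaussian spread shrinks as
#' `log(g)/g` with the generation `g`, and a heated-neutron recoil term
#' `randn * (X_best - Pne * Nei)` with mutation factor `Pne`
#' (`round(rand)+1` in `{1,2}` for the subaltern branch, `round(rand)+2` in
#' `{2,3}` for the essential branch) diversifies the move. Candidates are
#' clipped to `[0, 1]`.
#'
#' @param pop Population matrix.
#' @param best_pos Position vector of the global best solution.
#' @param g Current generation (>= 1; at `g = 1` the Gaussian spread is 0).
#' @param cfg An [nro_config()].
#' @return Matrix of candidate positions, same shape as `pop`.
#' @export
fission_step <- function(pop, best_pos, g, cfg) {
  if (g < 1) stop("generation index must be >= 1", call. = FALSE)
  n <- nrow(pop)
  d <- ncol(pop)
  shrink <- log(g) / g
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    branch_rand <- stats::runif(1)
    nei <- heated_neutron(pop, i, cfg$neutron)
    if (branch_rand <= cfg$p_beta) {
      sigma <- shrink * abs(pop[i, ] - best_pos)
      pne <- round(stats::runif(1) + 1) # {1, 2}
      center <- best_pos
    } else {
      r <- sample(setdiff(seq_len(n), i), 1)
      sigma <- shrink * abs(pop[r, ] - best_pos)
      pne <- round(stats::runif(1) + 2) # {2, 3}
      center <- pop[i, ]
    }
    cand <- stats::rnorm(d, mean = center, sd = sigma) +
      stats::rnorm(d) * (best_pos - pne * nei)
    out[i, ] <- clip01(cand)
  }
  out
}

# Pure ionization update for the dissimilar branch: X_r1 +/- rand * (X_r2 - X_i),
# sign chosen by rand <= 0.5. Vectorized over dimensions.
ion_update <- function(xr1, xr2, xi, rand) {
  if (rand <= 0.5) xr1 + rand * (xr2 - xi) else xr1 - rand * (xr2 - xi)
}

# Pure fusion update for the dissimilar branch:
# X_i + rand1 * (X_r1 - best) + rand2 * (X_r2 - best).
fusion_update <- function(xi, xr1, xr2, best, rand1, rand2) {
  xi + rand1 * (xr1 - best) + rand2 * (xr2 - best)
}

# Pure Levy escape shared by Eqs for stagnating ionization/fusion moves:
# X_i + alpha * levy * (X_i - best).
levy_escape <- function(xi, best, alpha, levy) {
  xi + alpha * levy * (xi - best)
}

#' Ionization sub-phase: difference-driven adjustment with Levy escapes
#'
#' Per solution, two distinct random peers `r1`, `r2` are drawn. Each
#' dimension where `|X[r2] - X[i]|` exceeds `similarity_tol` is updated to
#' `X[r1] +/- rand * (X[r2] - X[i])` (sign by `rand <= 0.5`, one `rand`
#' per solution); dimensions too similar take a Levy-flight escape
#' `X[i] + alpha * Levy(beta) * (X[i] - X_best)` instead. Clipped to
#' `[0, 1]`.
#'
#' @inheritParams fission_step
#' @return Matrix of ionized positions.
#' @export
ionization_step <- function(pop, best_pos, cfg) {
  n <- nrow(pop)
  d <- ncol(pop)
  if (n < 3) stop("population must have >= 3 solutions", call. = FALSE)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    rs <- sample(setdiff(seq_len(n), i), 2)
    dif <- pop[rs[2], ] - pop[i, ]
    ok <- abs(dif) >= cfg$similarity_tol
    rand <- stats::runif(1)
    cand <- numeric(d)
    cand[ok] <- ion_update(pop[rs[1], ok], pop[rs[2], ok], pop[i, ok], rand)
    if (any(!ok)) {
      lv <- levy_step(cfg$levy_exponent, sum(!ok))
      cand[!ok] <- levy_escape(pop[i, !ok], best_pos[!ok], cfg$levy_alpha, lv)
    }
    out[i, ] <- clip01(cand)
  }
  out
}

#' Fusion sub-phase: recombination toward the best solution
#'
#' Per solution, two distinct random peers are drawn from the ionized
#' population. If they differ (vector norm above `similarity_tol`) the
#' solution moves by `rand * (X[r1] - X_best) + rand * (X[r2] - X_best)`
#' (two independent uniform draws); otherwise a Levy-flight escape
#' `alpha * Levy(beta) * (X[i] - X_best)` is applied. Clipped to `[0, 1]`.
#'
#' @inheritParams fission_step
#' @return Matrix of fused positions.
#' @export
fusion_step <- function(pop, best_pos, cfg) {
  n <- nrow(pop)
  d <- ncol(pop)
  if (n < 3) stop("population must have >= 3 solutions", call. = FALSE)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    rs <- sample(setdiff(seq_len(n), i), 2)
    if (sqrt(sum((pop[rs[1], ] - pop[rs[2], ])^2)) >= cfg$similarity_tol) {
      cand <- fusion_update(
        pop[i, ], pop[rs[1], ], pop[rs[2], ], best_pos,
        stats::runif(1), stats::runif(1)
      )
    } else {
      lv <- levy_step(cfg$levy_exponent, d)
      cand <- levy_escape(pop[i, ], best_pos, cfg$levy_alpha, lv)
    }
    out[i, ] <- clip01(cand)
  }
  out
}

#' Decode a continuous position to a fixed-size gene subset
#'
#' The `k` largest components mark the selected genes; ties break toward
#' the lower index. This keeps the continuous NRO operators applicable
#' verbatim while guaranteeing subsets of exactly `k` genes.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @param k Subset size, `1 <= k <= length(position)`.
#' @return Sorted integer vector of `k` gene indices.
#' @examples
#' decode_top_k(c(0.9, 0.1, 0.8, 0.2), 2) # genes 1 and 3
#' @export
decode_top_k <- function(position, k) {
  d <- length(position)
  if (k > d) stop("k (", k, ") exceeds dimension (", d, ")", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sort(order(-position, seq_len(d))[seq_len(k)])
}

# Threshold decoder: components >= 0.5 selected; falls back to the single
# largest component when none reach the threshold.
decode_threshold <- function(position) {
  sel <- which(position >= 0.5)
  if (length(sel) == 0) sel <- which.max(position)
  sel
}

#' Run the Nuclear Reaction Optimization search
#'
#' Evolves a population of continuous positions on `[0, 1]^d`: each
#' generation applies the fission (exploration), ionization and fusion
#' (exploitation) operators in turn; every candidate is decoded to a gene
#' subset and scored with `fitness_fn`; a candidate replaces its parent only
#' if strictly better (greedy elitist replacement); the search stops at
#' `max_generations` or after `patience` generations without strict
#' improvement of the global best. Fully reproducible from `config$seed`.
#'
#' @param fitness_fn Function taking an integer vector of gene indices
#'   (within the pool) and returning a fitness in `[0, 1]` — typically
#'   [cached_fitness()].
#' @param d Search dimension (pool size).
#' @param k Gene-subset size decoded from each position (used by the
#'   `"top_k"` decoder).
#' @param config An [nro_config()].
#' @return An object of class `nro_result`: list with `best_genes` (sorted
#'   indices), `best_fitness`, `best_position`, `trace` (tibble of
#'   `generation`, `best_fitness`), `generations_run`, `stopped_early`,
#'   `evaluations`, and `config`.
#' @export
run_nro <- function(fitness_fn, d, k, config = nro_config()) {
  cfg <- if (inherits(config, "nro_config")) config else do.call(nro_config, config)
  if (k > d) stop("subset size k (", k, ") exceeds dimension (", d, ")", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  decode <- if (cfg$decode == "top_k") {
    function(pos) decode_top_k(pos, k)
  } else {
    decode_threshold
  }
  evals <- 0L
  score <- function(pos) {
    f <- fitness_fn(decode(pos))
    evals <<- evals + 1L
    if (!is.finite(f)) stop("fitness function returned a non-finite value", call. = FALSE)
    f
  }
  n <- cfg$population_size
  pop <- init_population(n, d)
  fit <- apply(pop, 1, score)
  bi <- which.max(fit)
  best_pos <- pop[bi, ]
  best_fit <- fit[bi]

  trace <- numeric(0)
  no_improve <- 0L
  gens <- 0L
  stopped_early <- FALSE
  for (g in seq_len(cfg$max_generations)) {
    gen_start_best <- best_fit
    cand <- fission_step(pop, best_pos, g, cfg)
    cf <- apply(cand, 1, score)
    imp <- cf > fit
    pop[imp, ] <- cand[imp, ]
    fit[imp] <- cf[imp]
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_pos <- pop[which.max(fit), ]
    }

    ion <- ionization_step(cand, best_pos, cfg)
    cf <- apply(ion, 1, score)
    imp <- cf > fit
    pop[imp, ] <- ion[imp, ]
    fit[imp] <- cf[imp]
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_pos <- pop[which.max(fit), ]
    }

    fus <- fusion_step(ion, best_pos, cfg)
    cf <- apply(fus, 1, score)
    imp <- cf > fit
    pop[imp, ] <- fus[imp, ]
    fit[imp] <- cf[imp]
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_pos <- pop[which.max(fit), ]
    }

    gens <- g
    trace <- c(trace, best_fit)
    if (best_fit > gen_start_best) {
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    if (no_improve >= cfg$patience) {
      stopped_early <- TRUE
      break
    }
  }

  structure(
    list(
      best_genes = decode(best_pos),
      best_fitness = best_fit,
      best_position = best_pos,
      trace = tibble::tibble(
        generation = seq_along(trace),
        best_fitness = trace
      ),
      generations_run = gens,
      stopped_early = stopped_early,
      evaluations = evals,
      config = cfg
    ),
    class = "nro_result"
  )
}

#' @export
print.nro_result <- function(x, ...) {
  cat(
    "<nro_result> best fitness", format(x$best_fitness, digits = 4),
    "| genes:", paste(x$best_genes, collapse = ", "), "\n"
  )
  cat(
    " ", x$generations_run, "generations",
    if (x$stopped_early) "(stopped early)" else "(hit generation cap)",
    "|", x$evaluations, "fitness evaluations\n"
  )
  invisible(x)
}
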